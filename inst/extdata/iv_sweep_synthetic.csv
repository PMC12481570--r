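# synthetic ohmic sweep for an ~8 nm pore in 3.6 M LiCl
voltage_mV,current_nA
-200,-9.072604
-175,-7.938528
-150,-6.804453
-125,-5.670377
-100,-4.536302
-75,-3.402226
-50,-2.268151
-25,-1.134075
0,0.000000
25,1.134075
50,2.268151
75,3.402226
100,4.536302
125,5.670377
150,6.804453
175,7.938528
200,9.072604
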