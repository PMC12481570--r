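#' Rolling circle amplification synthesis length
#'
#' Deterministic concatemer-length bounds from a polymerase rate range:
#' Phi29 DNA polymerase extends at roughly 50-100 nt/s, so a reaction of
#' duration `t` yields between `50 t` and `100 t` nucleotides of product.
#'
#' @param duration_s Reaction duration (s, > 0).
#' @param rate_nt_per_s Two-element rate range `(lo, hi)` in nt/s,
#'   `0 < lo <= hi`. Default `c(50, 100)`.
#' @return Named numeric `c(lo_nt, hi_nt)`; exact integers for integral
#'   inputs.
#' @seealso [repeat_count()], [rca_kinetics()]
#' @export
#' @examples
#' synthesis_length(1800)           # 30 min: 90,000-180,000 nt
#' synthesis_length(7200)           # 2 h: 360,000-720,000 nt
synthesis_length <- function(duration_s, rate_nt_per_s = c(50, 100)) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be a single positive number")
  r <- as.numeric(rate_nt_per_s)
  if (length(r) != 2L || r[1] <= 0 || r[2] < r[1])
    stop("rate_nt_per_s must be (lo, hi) with 0 < lo <= hi")
  c(lo_nt = r[1] * duration_s, hi_nt = r[2] * duration_s)
}

#' Tandem-repeat count of a concatemer
#'
#' Number of template repeats in a concatemer of a given length. With
#' `rounding = "nearest_100"` the raw ratio is rounded to the nearest 100
#' repeats (the convention behind headline figures such as "approximately
#' 1200-9500 tandem repeats"); `"floor"` counts complete repeats;
#' `"none"` returns the raw ratio.
#'
#' @param length_nt Concatemer length (nt, >= `template_len_nt`). Vectorised.
#' @param template_len_nt Circular template length (nt, default 76).
#' @param rounding `"none"`, `"nearest_100"` or `"floor"`.
#' @return Repeat count(s).
#' @export
#' @examples
#' repeat_count(720000, 76, "nearest_100")  # 9500
#' repeat_count(2000, 76, "floor")          # 26
repeat_count <- function(length_nt, template_len_nt = 76,
                         rounding = c("none", "nearest_100", "floor")) {
  rounding <- match.arg(rounding)
  if (template_len_nt < 1) stop("template_len_nt must be >= 1")
  if (any(length_nt < template_len_nt))
    stop("length_nt must be at least one template length")
  raw <- length_nt / template_len_nt
  switch(rounding,
         none = raw,
         nearest_100 = round(raw / 100) * 100,
         floor = floor(raw))
}

#' RCA kinetics summary
#'
#' Convenience wrapper joining [synthesis_length()] and [repeat_count()]
#' for one reaction duration.
#'
#' @param duration_s Reaction duration (s).
#' @param rate_nt_per_s Rate range, see [synthesis_length()].
#' @param template_len_nt Template length (nt).
#' @param rounding Repeat-count rounding, see [repeat_count()].
#' @return An object of class `rca_kinetics` with `length_nt` and
#'   `repeats`.
#' @export
#' @examples
#' rca_kinetics(7200)
rca_kinetics <- function(duration_s, rate_nt_per_s = c(50, 100),
                         template_len_nt = 76, rounding = "nearest_100") {
  len <- synthesis_length(duration_s, rate_nt_per_s)
  structure(list(duration_s = duration_s, rate_nt_per_s = rate_nt_per_s,
                 template_len_nt = template_len_nt,
                 length_nt = len,
                 repeats = repeat_count(len, template_len_nt, rounding),
                 rounding = rounding),
            class = "rca_kinetics")
}

#' @export
print.rca_kinetics <- function(x, ...) {
  cat(sprintf("<rca_kinetics> %g s at %g-%g nt/s, template %d nt\n",
              x$duration_s, x$rate_nt_per_s[1], x$rate_nt_per_s[2],
              as.integer(x$template_len_nt)))
  cat(sprintf("  product length: %s-%s nt\n",
              format(x$length_nt[[1]], big.mark = ","),
              format(x$length_nt[[2]], big.mark = ",")))
  cat(sprintf("  tandem repeats (%s): %s-%s\n", x$rounding,
              format(x$repeats[[1]], big.mark = ","),
              format(x$repeats[[2]], big.mark = ",")))
  invisible(x)
}

#' Concentration after a dilution chain
#'
#' Final concentration of a serially diluted stock. Each step is an
#' `(aliquot_volume, final_volume)` pair; the concentration is
#' `stock * prod(aliquot / final)`, accumulated as a single numerator /
#' denominator product before the one final division, so chains of small
#' integer-ratio steps stay exact. Order-invariant.
#'
#' @param stock_nM Stock concentration (nM, > 0).
#' @param steps List of two-element vectors `c(aliquot, final)` in any
#'   common volume unit; `0 < aliquot <= final`. An empty list returns the
#'   stock unchanged.
#' @return Final concentration (nM).
#' @export
#' @examples
#' # 100 nM probe: 1 uL into a 10 uL reaction, then 25-fold into buffer
#' final_concentration(100, list(c(1, 10), c(1, 25)))  # 0.4 nM
final_concentration <- function(stock_nM, steps = list()) {
  if (!is.numeric(stock_nM) || length(stock_nM) != 1L || stock_nM <= 0)
    stop("stock_nM must be a single positive number")
  num <- 1; den <- 1
  for (s in steps) {
    s <- as.numeric(s)
    if (length(s) != 2L || any(!is.finite(s)) || s[1] <= 0 || s[2] <= 0)
      stop("each step must be c(aliquot, final) with positive volumes")
    if (s[1] > s[2])
      stop("aliquot volume (", s[1], ") exceeds final volume (", s[2], ")")
    num <- num * s[1]
    den <- den * s[2]
  }
  stock_nM * num / den
}
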