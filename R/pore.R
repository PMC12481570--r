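# Unit conversions are centralised here: geometry in nm, conductivity in
# S/m, conductance reported in nS, I-V sweeps in mV and nA.
.units <- list(nm_to_m = 1e-9, S_to_nS = 1e9,
               nA_per_mV_to_nS = 1e3)  # (1e-9 A) / (1e-3 V) = 1e-6 S

#' Conductance of a cylindrical pore
#'
#' The cylindrical-pore conductance model with access resistance,
#' `G = sigma * (4 L / (pi d^2) + 1 / d)^-1`, which assumes a cylindrical
#' geometry and neglects surface-charge effects. Monotone increasing in `d`
#' and `sigma`, decreasing in `L`.
#'
#' @param d_nm Pore diameter (nm, > 0).
#' @param L_nm Membrane thickness (nm, > 0).
#' @param sigma_S_per_m Bulk electrolyte conductivity (S/m, > 0); e.g.
#'   16.5 S/m for 3.6 M LiCl.
#' @return Conductance in nS. Vectorised.
#' @seealso [diameter_from_conductance()], [fit_iv()]
#' @export
#' @examples
#' conductance_from_geometry(8, 12, 16.5)  # ~45.4 nS
conductance_from_geometry <- function(d_nm, L_nm, sigma_S_per_m) {
  if (any(d_nm <= 0) || any(L_nm <= 0) || any(sigma_S_per_m <= 0))
    stop("d, L and sigma must all be positive")
  d <- d_nm * .units$nm_to_m
  L <- L_nm * .units$nm_to_m
  sigma_S_per_m / (4 * L / (pi * d^2) + 1 / d) * .units$S_to_nS
}

#' Pore diameter from conductance
#'
#' Inverts the cylindrical-pore conductance model in closed form: the
#' positive root of `sigma * pi * d^2 - G * pi * d - 4 G L = 0`,
#' `d = (G pi + sqrt(G^2 pi^2 + 16 sigma pi G L)) / (2 sigma pi)`.
#' Round-trips [conductance_from_geometry()] to better than 1e-9 relative.
#'
#' @param G_nS Measured conductance (nS, > 0).
#' @param L_nm Membrane thickness (nm, > 0).
#' @param sigma_S_per_m Bulk conductivity (S/m, > 0).
#' @return Diameter in nm. Vectorised.
#' @export
#' @examples
#' diameter_from_conductance(45.4, 12, 16.5)  # ~8 nm
diameter_from_conductance <- function(G_nS, L_nm, sigma_S_per_m) {
  if (any(G_nS <= 0) || any(L_nm <= 0) || any(sigma_S_per_m <= 0))
    stop("G, L and sigma must all be positive")
  G <- G_nS / .units$S_to_nS
  L <- L_nm * .units$nm_to_m
  s <- sigma_S_per_m
  d <- (G * pi + sqrt(G^2 * pi^2 + 16 * s * pi * G * L)) / (2 * s * pi)
  d / .units$nm_to_m
}

#' First-order uncertainty on the derived diameter
#'
#' Propagates standard errors on `G`, `L` and `sigma` through
#' [diameter_from_conductance()] by numerical first-order partials. The
#' cylindrical model itself carries no uncertainty here; this is measurement
#' propagation only.
#'
#' @param G_nS,L_nm,sigma_S_per_m Point values.
#' @param se_G,se_L,se_sigma Standard errors (0 for exactly known inputs).
#' @return A list with `d_nm` and `se_d_nm`.
#' @export
propagate_diameter_error <- function(G_nS, L_nm, sigma_S_per_m,
                                     se_G = 0, se_L = 0, se_sigma = 0) {
  f <- function(G, L, s) diameter_from_conductance(G, L, s)
  d0 <- f(G_nS, L_nm, sigma_S_per_m)
  h <- function(v) max(abs(v) * 1e-6, 1e-9)
  dG <- (f(G_nS + h(G_nS), L_nm, sigma_S_per_m) - d0) / h(G_nS)
  dL <- (f(G_nS, L_nm + h(L_nm), sigma_S_per_m) - d0) / h(L_nm)
  ds <- (f(G_nS, L_nm, sigma_S_per_m + h(sigma_S_per_m)) - d0) / h(sigma_S_per_m)
  list(d_nm = d0,
       se_d_nm = sqrt((dG * se_G)^2 + (dL * se_L)^2 + (ds * se_sigma)^2))
}

#' Fit an I-V sweep
#'
#' Least-squares line through a current-voltage sweep. The slope gives the
#' pore conductance; separate slopes through the non-negative and
#' non-positive voltage branches give the rectification ratio
#' `(|G+| - |G-|) / ((|G+| + |G-|) / 2)`, a symmetric asymmetry measure
#' that is exactly zero for an antisymmetric (ohmic, geometrically
#' symmetric) sweep. Rectification needs at least 2 points on each polarity
#' and is `NA` otherwise.
#'
#' @param iv An [iv_dataset()].
#' @return An object of class `iv_fit` with `G_nS`, `se_G_nS`,
#'   `intercept_nA`, `rectification_ratio`, `r_squared`, `n`.
#' @export
#' @examples
#' iv <- iv_dataset(seq(-200, 200, 50), 0.0454 * seq(-200, 200, 50))
#' fit_iv(iv)
fit_iv <- function(iv) {
  stopifnot(inherits(iv, "iv_dataset"))
  if (diff(range(iv$voltage_mV)) == 0) stop("zero voltage span")
  fit <- stats::lm(current_nA ~ voltage_mV, data = iv)
  # summary.lm warns on exactly linear (noise-free) sweeps; those are valid here
  smry <- suppressWarnings(summary(fit))
  sl <- smry$coefficients
  G <- stats::coef(fit)[["voltage_mV"]] * .units$nA_per_mV_to_nS
  se_G <- if (nrow(sl) == 2 && !is.na(sl["voltage_mV", "Std. Error"]))
    sl["voltage_mV", "Std. Error"] * .units$nA_per_mV_to_nS else NA_real_

  rect <- NA_real_
  pos <- iv$voltage_mV >= 0; neg <- iv$voltage_mV <= 0
  if (sum(pos) >= 2 && sum(neg) >= 2 &&
      any(iv$voltage_mV > 0) && any(iv$voltage_mV < 0)) {
    gp <- abs(stats::coef(stats::lm(current_nA ~ voltage_mV,
                                    data = iv[pos, ]))[["voltage_mV"]])
    gn <- abs(stats::coef(stats::lm(current_nA ~ voltage_mV,
                                    data = iv[neg, ]))[["voltage_mV"]])
    rect <- (gp - gn) / ((gp + gn) / 2)
  }
  structure(list(G_nS = G, se_G_nS = se_G,
                 intercept_nA = stats::coef(fit)[["(Intercept)"]],
                 rectification_ratio = rect,
                 r_squared = smry$r.squared,
                 n = nrow(iv), lm = fit),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit> G = %.4g nS (SE %.2g), intercept %.3g nA, n = %d\n",
              x$G_nS, x$se_G_nS, x$intercept_nA, x$n))
  cat(sprintf("  rectification ratio = %s, R^2 = %.6f\n",
              ifelse(is.na(x$rectification_ratio), "NA (one polarity)",
                     sprintf("%.4g", x$rectification_ratio)), x$r_squared))
  invisible(x)
}

#' Pore geometry record
#'
#' Ties the cylindrical conductance model together: given any three of
#' diameter, thickness, conductivity and conductance, the fourth is
#' computed; given all four, their mutual consistency is checked to 1e-9
#' relative.
#'
#' @param d_nm,L_nm,sigma_S_per_m,G_nS Geometry and conductance; supply at
#'   least three of the four (with `L_nm` and `sigma_S_per_m` always
#'   required).
#' @param rectification_ratio Optional measured rectification ratio.
#' @return An object of class `pore_geometry`.
#' @export
#' @examples
#' pore_geometry(L_nm = 12, sigma_S_per_m = 16.5, G_nS = 45.4)
pore_geometry <- function(d_nm = NULL, L_nm, sigma_S_per_m, G_nS = NULL,
                          rectification_ratio = NA_real_) {
  if (is.null(d_nm) && is.null(G_nS))
    stop("supply at least one of d_nm or G_nS")
  if (is.null(G_nS)) {
    G_nS <- conductance_from_geometry(d_nm, L_nm, sigma_S_per_m)
  } else if (is.null(d_nm)) {
    d_nm <- diameter_from_conductance(G_nS, L_nm, sigma_S_per_m)
  } else {
    G_chk <- conductance_from_geometry(d_nm, L_nm, sigma_S_per_m)
    if (abs(G_chk - G_nS) / G_nS > 1e-9)
      stop(sprintf("inconsistent geometry: G(d=%g, L=%g, sigma=%g) = %.9g nS != %.9g nS",
                   d_nm, L_nm, sigma_S_per_m, G_chk, G_nS))
  }
  structure(list(d_nm = d_nm, L_nm = L_nm, sigma_S_per_m = sigma_S_per_m,
                 G_nS = G_nS, rectification_ratio = rectification_ratio),
            class = "pore_geometry")
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf("<pore_geometry> d = %.3g nm, L = %g nm, sigma = %g S/m, G = %.4g nS\n",
              x$d_nm, x$L_nm, x$sigma_S_per_m, x$G_nS))
  if (!is.na(x$rectification_ratio))
    cat(sprintf("  rectification ratio = %.4g\n", x$rectification_ratio))
  invisible(x)
}
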