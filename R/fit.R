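#' Fit blockage-depth populations with a Gaussian mixture
#'
#' Maximum-likelihood Gaussian mixture fit to percentage-blockage values,
#' for 1 and (optionally) 2 components, selecting the component count by BIC.
#' Translocation experiments on circularised probes commonly show two
#' blockage populations (e.g. hybridised vs unhybridised circles); this fit
#' makes that call automatically and reproducibly.
#'
#' The 2-component fit runs expectation-maximisation from `n_restarts`
#' seeded k-means++-style initialisations (first centre drawn uniformly from
#' the data, second weighted by squared distance); the best log-likelihood
#' wins. The EM log-likelihood is non-decreasing by construction and the
#' whole fit is bit-reproducible for a fixed `seed`.
#'
#' @param blockages Numeric vector of percentage blockages; at least
#'   `20 * max_components` values.
#' @param max_components 1 or 2.
#' @param seed Integer seed for the initialisations.
#' @param n_restarts Number of EM restarts per candidate count (default 20).
#' @return An object of class `blockage_fit`: components ordered by mean,
#'   each with `weight`, `mean_pct`, `sd_pct`, `se_mean`; plus `bic` per
#'   candidate, `loglik`, `loglik_trace` (selected fit), `n_events`.
#' @seealso [fit_dwell_exponential()], [summarize_condition()]
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 13.2, 0.5), rnorm(300, 18.4, 0.5))
#' fit_blockage_populations(x, max_components = 2, seed = 1)
fit_blockage_populations <- function(blockages, max_components = 2, seed = 1,
                                     n_restarts = 20) {
  x <- as.numeric(blockages)
  if (!all(is.finite(x))) stop("blockages must be finite")
  if (!max_components %in% 1:2) stop("max_components must be 1 or 2")
  n <- length(x)
  if (n < 20 * max_components)
    stop("need at least ", 20 * max_components, " events for ",
         max_components, " component(s); got ", n)

  if (length(unique(x)) == 1L) {
    warning("degenerate data (all values equal); returning a single component ",
            "with a floored SD")
    sd_floor <- 1e-8 * max(1, abs(x[1]))
    comp <- data.frame(weight = 1, mean_pct = x[1], sd_pct = sd_floor,
                       se_mean = sd_floor / sqrt(n))
    return(new_blockage_fit(comp, n, bic = c(`1` = NA_real_),
                            loglik = NA_real_, loglik_trace = NA_real_,
                            seed = seed))
  }

  set.seed(seed)
  candidates <- list()
  # k = 1: closed form MLE
  mu <- mean(x); sdev <- sqrt(mean((x - mu)^2))
  ll1 <- sum(stats::dnorm(x, mu, sdev, log = TRUE))
  candidates[[1]] <- list(k = 1,
                          par = data.frame(weight = 1, mean_pct = mu, sd_pct = sdev),
                          loglik = ll1, loglik_trace = ll1)
  if (max_components >= 2) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(x)
      fit <- em_gauss2(x, init)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    candidates[[2]] <- c(list(k = 2), best)
  }

  bic <- vapply(candidates, function(cand) {
    p <- 3 * cand$k - 1
    -2 * cand$loglik + p * log(n)
  }, numeric(1))
  names(bic) <- vapply(candidates, function(cand) as.character(cand$k), "")
  sel <- candidates[[which.min(bic)]]

  par <- sel$par[order(sel$par$mean_pct), , drop = FALSE]
  par$se_mean <- par$sd_pct / sqrt(pmax(par$weight * n, 1))
  new_blockage_fit(par, n, bic = bic, loglik = sel$loglik,
                   loglik_trace = sel$loglik_trace, seed = seed)
}

new_blockage_fit <- function(components, n, bic, loglik, loglik_trace, seed) {
  rownames(components) <- NULL
  structure(list(n_components = nrow(components), components = components,
                 bic = bic, loglik = loglik, loglik_trace = loglik_trace,
                 n_events = n, seed = seed),
            class = "blockage_fit")
}

# k-means++-style initialisation for the 2-component fit
kmeanspp_init <- function(x) {
  c1 <- x[sample.int(length(x), 1)]
  d2 <- (x - c1)^2
  if (all(d2 == 0)) c2 <- c1 + stats::sd(x) else
    c2 <- x[sample.int(length(x), 1, prob = d2)]
  s0 <- stats::sd(x) / 2
  list(weight = c(0.5, 0.5), mean = c(c1, c2), sd = c(s0, s0))
}

# 1-D two-component Gaussian EM; log-likelihood is monotone non-decreasing
em_gauss2 <- function(x, init, max_iter = 500, tol = 1e-10) {
  n <- length(x)
  w <- init$weight; mu <- init$mean; sdev <- pmax(init$sd, 1e-12)
  sd_floor <- 1e-6 * (max(x) - min(x))
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    la <- log(w[1]) + stats::dnorm(x, mu[1], sdev[1], log = TRUE)
    lb <- log(w[2]) + stats::dnorm(x, mu[2], sdev[2], log = TRUE)
    mx <- pmax(la, lb)
    lse <- mx + log(exp(la - mx) + exp(lb - mx))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol * (abs(ll) + 1)) break
    ll_old <- ll
    g1 <- exp(la - lse)
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # component collapsed
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sdev <- pmax(c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
                   sqrt(sum((1 - g1) * (x - mu[2])^2) / n2)), sd_floor)
  }
  list(par = data.frame(weight = w, mean_pct = mu, sd_pct = sdev),
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace)
}

#' @export
print.blockage_fit <- function(x, ...) {
  cat(sprintf("<blockage_fit> %d component(s), n = %d, logLik = %.4f\n",
              x$n_components, x$n_events, x$loglik))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  component %d: %.1f%% weight, blockage %.2f +/- %.2f %% (SE %.3f)\n",
                i, 100 * comp$weight[i], comp$mean_pct[i], comp$sd_pct[i],
                comp$se_mean[i]))
  if (length(x$bic) > 1)
    cat("  BIC:", paste(sprintf("k=%s %.2f", names(x$bic), x$bic),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.blockage_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.blockage_fit <- function(object, ...) {
  object$components
}

#' @export
logLik.blockage_fit <- function(object, ...) {
  structure(object$loglik, df = 3 * object$n_components - 1,
            nobs = object$n_events, class = "logLik")
}

#' @export
plot.blockage_fit <- function(x, data = NULL, breaks = 40,
                              xlab = "current blockage (%)", ...) {
  comp <- x$components
  if (!is.null(data)) {
    graphics::hist(data, breaks = breaks, freq = FALSE, xlab = xlab,
                   main = "blockage populations", ...)
    xs <- seq(min(data), max(data), length.out = 400)
  } else {
    xs <- seq(min(comp$mean_pct - 4 * comp$sd_pct),
              max(comp$mean_pct + 4 * comp$sd_pct), length.out = 400)
    graphics::plot(NA, xlim = range(xs), ylim = c(0, NA_real_), xlab = xlab,
                   ylab = "density", main = "blockage populations", ...)
  }
  dens <- rowSums(vapply(seq_len(nrow(comp)), function(i)
    comp$weight[i] * stats::dnorm(xs, comp$mean_pct[i], comp$sd_pct[i]),
    numeric(length(xs))))
  graphics::lines(xs, dens, lwd = 2)
  invisible(x)
}

#' Exponential dwell-time fit
#'
#' Maximum-likelihood fit of an exponential distribution to dwell times:
#' `tau` is the sample mean, with standard error `tau / sqrt(n)`. Fitting
#' raw dwells avoids the histogram-binning sensitivity of curve fitting; a
#' binned least-squares mode is available for comparison.
#'
#' @param dwells_ms Positive dwell times (ms); at least 5.
#' @param method `"mle"` (default) or `"histogram"` (least-squares fit of
#'   `log` counts over exponentially spaced bins; provided for comparison
#'   with legacy curve-fitting workflows).
#' @param n_bins Bin count for the histogram method.
#' @return An object of class `dwell_fit` with `tau_ms`, `se_tau_ms`, `n`,
#'   `method`.
#' @export
#' @examples
#' fit_dwell_exponential(rexp(100, 1 / 4.7))
fit_dwell_exponential <- function(dwells_ms, method = c("mle", "histogram"),
                                  n_bins = 20) {
  method <- match.arg(method)
  x <- as.numeric(dwells_ms)
  if (length(x) < 5L) stop("need at least 5 dwell times; got ", length(x))
  if (any(!is.finite(x) | x <= 0))
    stop("all dwell times must be positive and finite")
  if (method == "mle") {
    tau <- mean(x)
  } else {
    h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
    mids <- h$mids[h$counts > 0]; cnt <- h$counts[h$counts > 0]
    if (length(mids) < 3) stop("too few occupied bins for histogram fitting")
    fit <- stats::lm(log(cnt) ~ mids)
    tau <- -1 / stats::coef(fit)[["mids"]]
    if (tau <= 0) stop("histogram fit produced a nonpositive tau")
  }
  n <- length(x)
  structure(list(tau_ms = tau, se_tau_ms = tau / sqrt(n), n = n,
                 method = method,
                 loglik = if (method == "mle") -n * (1 + log(tau)) else NA_real_),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> tau = %.4g +/- %.2g ms (SE), n = %d, method = %s\n",
              x$tau_ms, x$se_tau_ms, x$n, x$method))
  invisible(x)
}

#' @export
coef.dwell_fit <- function(object, ...) c(tau_ms = object$tau_ms)

#' @export
logLik.dwell_fit <- function(object, ...) {
  structure(object$loglik, df = 1, nobs = object$n, class = "logLik")
}

#' Summarise one experimental condition
#'
#' Joins the blockage-population fit and dwell-time fit of an event table
#' into one record with the sample size and provenance, and formats
#' `mean +/- SE` strings in the layout used for condition tables.
#'
#' @param events An [event_table()] (or data frame with `blockage_pct` and
#'   `dwell_ms`); non-empty, at least 5 events for the dwell fit and
#'   `20 * max_components` for the blockage fit.
#' @param max_components Passed to [fit_blockage_populations()].
#' @param seed Seed for the mixture fit.
#' @param use_peak Fit `peak_blockage_pct` instead of the event-mean
#'   `blockage_pct`.
#' @param label Condition label for printing.
#' @return An object of class `condition_summary`.
#' @export
summarize_condition <- function(events, max_components = 2, seed = 1,
                                use_peak = FALSE, label = NULL) {
  if (is.null(nrow(events)) || nrow(events) == 0L) stop("empty event table")
  blk <- if (use_peak) events$peak_blockage_pct else events$blockage_pct
  bf <- fit_blockage_populations(blk, max_components = max_components,
                                 seed = seed)
  df <- fit_dwell_exponential(events$dwell_ms)
  comp <- bf$components
  structure(list(
    label = label %||% (attr(events, "trace_label") %||% ""),
    n_events = nrow(events),
    blockage = bf, dwell = df,
    blockage_text = paste(sprintf("%.1f ± %.2g", comp$mean_pct,
                                  comp$se_mean), collapse = " and "),
    dwell_text = sprintf("%.1f ± %.2g", df$tau_ms, df$se_tau_ms)),
    class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> '%s', n = %d events\n", x$label, x$n_events))
  cat(sprintf("  mean %% blockage: %s\n", x$blockage_text))
  cat(sprintf("  dwell time (ms): %s\n", x$dwell_text))
  invisible(x)
}
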