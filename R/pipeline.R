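#' Run the simulate -> detect -> fit -> classify pipeline
#'
#' Executes the configured stages in order, writing each stage's artifact
#' plus a manifest (`manifest.json`) with input checksums, the full config
#' snapshot and the package version. Reruns with an identical config
#' reproduce byte-identical artifacts: all stochastic stages are seeded.
#'
#' Config structure (R list, or a path to an equivalent JSON document):
#' \describe{
#'   \item{`simulate`}{arguments for [simulation_spec()] (requires `seed`),
#'     or omitted when `trace` gives an input file instead.}
#'   \item{`trace`}{path to an existing trace file (alternative to
#'     `simulate`).}
#'   \item{`detect`}{arguments for [detection_config()].}
#'   \item{`fit`}{`max_components`, `seed` for [summarize_condition()].}
#'   \item{`classify`}{`edges_ms`, `f_lo`, `f_hi` for
#'     [summarize_classes()].}
#' }
#' Stages later in the chain are skipped when their config section is
#' absent (except `detect`, which is required whenever `fit` or `classify`
#' is present).
#'
#' @param config R list or path to a JSON config file.
#' @param outdir Output directory; created if needed.
#' @param force Overwrite existing artifacts (default `FALSE`: refuse).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, outdir, force = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  artifacts <- character(0)
  created <- character(0)
  emit <- function(name) {
    p <- file.path(outdir, name)
    if (file.exists(p) && !force)
      stop("artifact exists (use force = TRUE to overwrite): ", p)
    created <<- c(created, p, if (grepl("\\.csv$|\\.bin$", p)) paste0(p, ".json"))
    artifacts <<- c(artifacts, p)
    p
  }
  stages <- list()

  run <- function() {
    # -- input trace -----------------------------------------------------
    ledger <- NULL
    if (!is.null(config$simulate)) {
      if (is.null(config$simulate$seed))
        stop("simulate stage requires an explicit seed")
      spec <- do.call(simulation_spec, config$simulate)
      sim <- simulate_trace(spec)
      trace <- sim$trace
      ledger <- sim$ledger
      p_trace <- emit("trace.bin")
      write_trace(trace, p_trace, format = "container")
      p_ledger <- emit("ledger.csv")
      utils::write.csv(ledger, p_ledger, row.names = FALSE, quote = FALSE)
      stages$simulate <<- list(artifact = basename(p_trace),
                               n_samples = length(trace$samples),
                               n_events_injected = nrow(ledger),
                               seed = config$simulate$seed)
    } else if (!is.null(config$trace)) {
      trace <- read_trace(config$trace)
      stages$input <<- list(path = config$trace,
                            md5 = unname(tools::md5sum(config$trace)))
    } else if (!is.null(config$detect) || !is.null(config$fit) ||
               !is.null(config$classify)) {
      stop("config needs either a 'simulate' section or a 'trace' path")
    }

    # -- detection -------------------------------------------------------
    events <- NULL
    if (!is.null(config$detect)) {
      dcfg <- do.call(detection_config, config$detect)
      events <- detect_events(trace, dcfg)
      p_events <- emit("events.csv")
      write_events(events, p_events, format = "delimited")
      stages$detect <<- list(artifact = basename(p_events),
                             n_events = nrow(events),
                             n_boundary_discarded =
                               attr(events, "n_boundary_discarded"))
    } else if (!is.null(config$fit) || !is.null(config$classify)) {
      stop("'fit' and 'classify' stages need a 'detect' section")
    }

    # -- population fitting ----------------------------------------------
    if (!is.null(config$fit)) {
      fit <- summarize_condition(
        events,
        max_components = config$fit$max_components %||% 2,
        seed = config$fit$seed %||% 1)
      p_fit <- emit("fit_summary.json")
      jsonlite::write_json(condition_summary_record(fit), p_fit,
                           auto_unbox = TRUE, digits = NA, na = "null")
      stages$fit <<- list(artifact = basename(p_fit),
                          n_components = fit$blockage$n_components,
                          tau_ms = fit$dwell$tau_ms)
    }

    # -- classification --------------------------------------------------
    if (!is.null(config$classify)) {
      cls <- summarize_classes(
        events,
        edges_ms = unlist(config$classify$edges_ms) %||% c(0.3, 1.0),
        f_lo = config$classify$f_lo %||% 0.35,
        f_hi = config$classify$f_hi %||% 0.65)
      p_cls <- emit("classes.json")
      jsonlite::write_json(unclass(cls), p_cls, auto_unbox = TRUE,
                           digits = NA, na = "null")
      stages$classify <<- list(artifact = basename(p_cls),
                               n_events = cls$n_events)
    }

    manifest <- list(package = "nanoevent",
                     version = as.character(utils::packageVersion("nanoevent")),
                     config = config,
                     stages = stages,
                     checksums = as.list(tools::md5sum(
                       c(artifacts,
                         Filter(file.exists, paste0(artifacts, ".json"))))))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    p_manifest <- emit("manifest.json")
    jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE,
                         digits = NA, na = "null")
    manifest
  }

  manifest <- tryCatch(run(), error = function(e) {
    unlink(created)  # remove partial outputs
    stop(e)
  })
  invisible(manifest)
}

# flat, JSON-friendly record of a condition summary
condition_summary_record <- function(x) {
  list(schema = "nanoevent/condition_summary/v1",
       label = x$label, n_events = x$n_events,
       blockage = list(n_components = x$blockage$n_components,
                       components = x$blockage$components,
                       bic = as.list(x$blockage$bic),
                       loglik = x$blockage$loglik),
       dwell = list(tau_ms = x$dwell$tau_ms, se_tau_ms = x$dwell$se_tau_ms,
                    n = x$dwell$n, method = x$dwell$method),
       blockage_text = x$blockage_text, dwell_text = x$dwell_text)
}
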