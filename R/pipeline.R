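# Orchestration: a validated run configuration and the end-to-end pipeline
# fit -> trajectory -> QC -> endpoint statistics (-> calcium-switch report),
# with a JSON run log recording seeds, settings and every QC exclusion.

#' Build a validated pipeline configuration
#'
#' @param spectra_file Path to a spectrum CSV (see [read_spectra()]);
#'   `NULL` skips the EIS branch.
#' @param switch_file Path to a calcium-switch CSV (see
#'   [read_switch_table()]); `NULL` skips the switch branch.
#' @param out_dir Output directory for reports (created if needed).
#' @param qc_threshold_ohm,qc_day Barrier-formation QC rule (defaults 95
#'   Ohm at day 14).
#' @param endpoint_days The two co-culture days compared by the endpoint
#'   test (default 0 and 14).
#' @param alpha Significance level (default 0.05).
#' @param family Within-platform comparison family size, 2 or 3.
#' @param multistart,seed Fit multistart count and seed.
#' @return A `run_config` list.
#' @export
run_config <- function(spectra_file = NULL, switch_file = NULL,
                       out_dir = tempfile("barriereis-run-"),
                       qc_threshold_ohm = 95, qc_day = 14,
                       endpoint_days = c(0L, 14L), alpha = 0.05,
                       family = 2, multistart = 5, seed = 1L) {
  stopifnot(qc_threshold_ohm > 0, length(endpoint_days) == 2,
            family %in% c(2, 3), alpha > 0, alpha < 1)
  for (p in c(spectra_file, switch_file)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p,
                                             call. = FALSE)
  }
  structure(
    list(
      spectra_file = spectra_file, switch_file = switch_file,
      out_dir = out_dir, qc_threshold_ohm = qc_threshold_ohm,
      qc_day = qc_day, endpoint_days = as.integer(endpoint_days),
      alpha = alpha, family = family, multistart = multistart,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full barrier-integrity pipeline
#'
#' Reads the configured inputs and runs every applicable stage: CNLS
#' fitting of all spectra, |Z|(100 Hz) trajectories, the barrier-formation
#' QC filter, the day-0 vs day-14 endpoint test on fitted Rb of QC-passing
#' devices, and the calcium-switch normalisation + significance table.
#' Writes `fit_report.csv`, `trajectory_report.csv`,
#' `switch_normalized.csv`, `switch_significance.csv` and `run_log.json`
#' (seed, settings, package version, QC exclusions) into the output
#' directory. Reruns with the same configuration produce identical reports.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the report tibbles (`fits`,
#'   `trajectories`, `qc`, `endpoint`, `switch_normalized`,
#'   `switch_summary`, `switch_significance`) and the log list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(
    package = "barriereis",
    version = as.character(utils::packageVersion("barriereis")),
    seed = config$seed,
    settings = config[c("qc_threshold_ohm", "qc_day", "endpoint_days",
                        "alpha", "family", "multistart")],
    warnings = character()
  )
  out <- list()

  if (!is.null(config$spectra_file)) {
    spectra <- tryCatch(read_spectra(config$spectra_file), error = function(e) {
      stop("EIS stage failed reading spectra: ", conditionMessage(e),
           call. = FALSE)
    })
    if (nrow(spectra) == 0) {
      log$warnings <- c(log$warnings, "spectra file contains no rows")
      out$fits <- fit_eis_cohort(spectra)
    } else {
      out$fits <- fit_eis_cohort(spectra, multistart = config$multistart,
                                 seed = config$seed)
      out$trajectories <- eis_trajectories(spectra, fits = out$fits)
      qc <- qc_filter(out$trajectories,
                      threshold_ohm = config$qc_threshold_ohm,
                      at_day = config$qc_day)
      out$qc <- qc
      log$qc_excluded <- as.list(stats::setNames(qc$rejected$reason,
                                                 qc$rejected$device_id))
      kept_fits <- dplyr::filter(out$fits,
                                 .data$device_id %in% qc$kept$device_id)
      d0 <- dplyr::filter(kept_fits, .data$day == config$endpoint_days[[1]],
                          is.finite(.data$rb_ohm))
      d14 <- dplyr::filter(kept_fits, .data$day == config$endpoint_days[[2]],
                           is.finite(.data$rb_ohm))
      if (nrow(d0) >= 2 && nrow(d14) >= 2) {
        out$endpoint <- endpoint_test(
          d0$rb_ohm, d14$rb_ohm,
          ids_day0 = d0$device_id, ids_day14 = d14$device_id
        )
      } else {
        log$warnings <- c(log$warnings,
                          "too few QC-passing devices for the endpoint test")
      }
      write_report(out$fits, file.path(config$out_dir, "fit_report.csv"),
                   rounded = TRUE)
      traj_out <- out$trajectories |>
        dplyr::left_join(
          dplyr::bind_rows(qc$kept, qc$rejected)[c("device_id", "qc_pass")],
          by = "device_id"
        )
      write_report(traj_out,
                   file.path(config$out_dir, "trajectory_report.csv"),
                   rounded = TRUE)
    }
  }

  if (!is.null(config$switch_file)) {
    series <- read_switch_table(config$switch_file)
    if (nrow(series) == 0) {
      log$warnings <- c(log$warnings, "switch file contains no rows")
    } else {
      out$switch_normalized <- normalize_switch(series)
      out$switch_summary <- platform_summary(out$switch_normalized)
      out$switch_significance <- withCallingHandlers(
        compare_phases(out$switch_normalized, family = config$family,
                       alpha = config$alpha),
        warning = function(w) {
          log$warnings <<- c(log$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      write_report(out$switch_normalized,
                   file.path(config$out_dir, "switch_normalized.csv"))
      write_report(out$switch_significance,
                   file.path(config$out_dir, "switch_significance.csv"),
                   rounded = TRUE)
    }
  }

  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$log <- log
  invisible(out)
}
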