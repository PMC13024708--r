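# Platform-specific resistance readouts: TEER from voltohmmeter readings
# (2D inserts), Ussing-chamber resistance from clamped current traces
# (ex vivo tissue), and impedance-trajectory metrics for the 3D device
# (|Z| at 100 Hz, the day-14 QC filter, endpoint tests).

#' TEER from raw voltohmmeter readings
#'
#' Converts raw and blank (cell-free insert) resistances to transepithelial
#' electrical resistance: `(raw - blank) * area`, in Ohm.cm^2. A negative
#' TEER (blank exceeding raw) signals a measurement problem; it is flagged
#' in `teer_negative`, not discarded -- exclusion is the caller's policy.
#'
#' @param records Data frame with columns `raw_ohm`, `blank_ohm` and
#'   optionally `area_cm2` (filled with `area_cm2` argument if absent).
#' @param area_cm2 Insert growth area in cm^2 used where the table has no
#'   `area_cm2` column (default 0.33, a 24-well insert).
#' @return The input as a tibble with `teer_ohm_cm2` and `teer_negative`
#'   columns appended.
#' @examples
#' compute_teer(data.frame(raw_ohm = 263.6, blank_ohm = 100))
#' @export
compute_teer <- function(records, area_cm2 = 0.33) {
  stopifnot(all(c("raw_ohm", "blank_ohm") %in% names(records)))
  records <- tibble::as_tibble(records)
  if (!"area_cm2" %in% names(records)) records$area_cm2 <- area_cm2
  if (any(records$area_cm2 <= 0)) stop("`area_cm2` must be > 0", call. = FALSE)
  if (any(records$raw_ohm < 0) || any(records$blank_ohm < 0)) {
    stop("raw and blank resistances must be >= 0", call. = FALSE)
  }
  dplyr::mutate(
    records,
    teer_ohm_cm2 = (.data$raw_ohm - .data$blank_ohm) * .data$area_cm2,
    teer_negative = .data$teer_ohm_cm2 < 0
  )
}

#' Per-group TEER summary (mean, SD) by culture day
#'
#' Replicate readings of a well are blank-subtracted first and then averaged
#' within the well; wells are then summarised per group and day with the
#' sample mean and sample SD (n - 1 denominator). A group/day with a single
#' well reports `sd = NA`.
#'
#' @param records TEER records with columns `well_id`, `group`, `day`,
#'   `raw_ohm`, `blank_ohm` and optionally `reading_index`, `area_cm2`.
#' @param area_cm2 Default growth area, see [compute_teer()].
#' @return A tibble with `group`, `day`, `n` (wells), `mean_teer`,
#'   `sd_teer`, `sem_teer`.
#' @export
teer_group_summary <- function(records, area_cm2 = 0.33) {
  stopifnot(all(c("well_id", "group", "day") %in% names(records)))
  per_well <- compute_teer(records, area_cm2 = area_cm2) |>
    dplyr::group_by(.data$group, .data$day, .data$well_id) |>
    dplyr::summarise(teer_ohm_cm2 = mean(.data$teer_ohm_cm2), .groups = "drop")
  per_well |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_teer = mean(.data$teer_ohm_cm2),
      sd_teer = ifelse(dplyr::n() >= 2, stats::sd(.data$teer_ohm_cm2), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem_teer = .data$sd_teer / sqrt(.data$n))
}

#' Has a Ussing-chamber trace reached equilibrium?
#'
#' Operationalises "equilibrated" as: the trace is at least `min_duration_s`
#' long, and the linear drift of the baseline current over its final
#' `window_s` is below `max_drift_per_min` (fractional, per minute) of the
#' window's mean current.
#'
#' @param trace Data frame with `time_s` (strictly increasing) and
#'   `current_a`.
#' @param baseline_end_s Time at which the baseline ends (e.g. the first
#'   clamp pulse); default is the end of the trace.
#' @param window_s Drift-assessment window, seconds (default 600).
#' @param max_drift_per_min Maximum tolerated |slope| * 60 / |mean| (default
#'   0.01, i.e. 1 % per minute).
#' @param min_duration_s Minimum baseline duration, seconds (default 1800).
#' @return A logical scalar with attributes `reason` (character) and
#'   `drift_per_min` (numeric, NA if not assessed).
#' @export
equilibrium_reached <- function(trace, baseline_end_s = NULL,
                                window_s = 600, max_drift_per_min = 0.01,
                                min_duration_s = 1800) {
  stopifnot(all(c("time_s", "current_a") %in% names(trace)))
  if (any(diff(trace$time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  t_end <- if (is.null(baseline_end_s)) max(trace$time_s) else baseline_end_s
  base <- trace[trace$time_s <= t_end, , drop = FALSE]
  ans <- function(ok, reason, drift = NA_real_) {
    structure(ok, reason = reason, drift_per_min = drift)
  }
  if (nrow(base) < 3 || diff(range(base$time_s)) < min_duration_s) {
    return(ans(FALSE, sprintf("baseline shorter than %g min",
                              min_duration_s / 60)))
  }
  win <- base[base$time_s >= max(base$time_s) - window_s, , drop = FALSE]
  slope <- stats::coef(stats::lm(current_a ~ time_s, data = win))[["time_s"]]
  mean_i <- mean(win$current_a)
  if (mean_i == 0) return(ans(FALSE, "zero mean baseline current"))
  drift <- abs(slope) * 60 / abs(mean_i)
  if (drift < max_drift_per_min) {
    ans(TRUE, "equilibrated", drift)
  } else {
    ans(FALSE, sprintf("baseline drifting at %.3g/min", drift), drift)
  }
}

detect_clamp_start <- function(trace) {
  i <- trace$current_a
  n <- length(i)
  k <- max(3L, min(11L, (n - 1) %/% 4))
  # coarse location from the smoothed derivative, then refine on the raw
  # sample-to-sample jump so smoothing lag cannot shift the edge estimate
  sm <- stats::filter(i, rep(1 / k, k), sides = 2)
  d <- diff(sm)
  d[is.na(d)] <- 0
  # the clamp deflection is positive, so only rising edges qualify
  approx_idx <- which.max(d)
  lo <- max(1L, approx_idx - k)
  hi <- min(n - 1L, approx_idx + k)
  dr <- diff(i)[lo:hi]
  j <- lo + which.max(dr) - 1L
  (trace$time_s[j] + trace$time_s[j + 1]) / 2
}

#' Ussing-chamber resistance from a clamped current trace
#'
#' Applies Ohm's law `V = dI * R` to a voltage-clamped current trace: the
#' current deflection `dI` is the mean current inside the clamp window
#' minus the mean over the baseline window immediately preceding it, and
#' `R = clamp_voltage_v / dI`. A short guard band around the clamp edge is
#' excluded from both windows.
#'
#' @param trace Data frame `time_s`, `current_a` (see [read_ussing_trace()]).
#' @param clamp_voltage_v Clamp voltage in V (default 5e-3).
#' @param area_cm2 Exposed tissue area in cm^2 (default 0.33).
#' @param clamp_start_s Time of the clamp step; `NULL` (default) detects the
#'   largest current step in the trace.
#' @param window_s Length of the baseline and clamp averaging windows,
#'   seconds (default 60).
#' @param guard_s Guard band excluded on either side of the step (default 2).
#' @param noise_floor_a Deflections at or below this value raise a
#'   "no deflection" error (default 1e-9 A).
#' @param check_equilibrium Require [equilibrium_reached()] on the baseline
#'   before the clamp (default TRUE).
#' @return A one-row tibble: `delta_i_a`, `r_ohm`, `r_ohm_cm2`
#'   (`r_ohm * area_cm2`), `clamp_start_s`, `window_s`.
#' @export
ussing_resistance <- function(trace, clamp_voltage_v = 5e-3, area_cm2 = 0.33,
                              clamp_start_s = NULL, window_s = 60,
                              guard_s = 2, noise_floor_a = 1e-9,
                              check_equilibrium = TRUE) {
  stopifnot(all(c("time_s", "current_a") %in% names(trace)))
  if (clamp_voltage_v <= 0) stop("`clamp_voltage_v` must be > 0", call. = FALSE)
  if (any(diff(trace$time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (is.null(clamp_start_s)) clamp_start_s <- detect_clamp_start(trace)
  if (check_equilibrium) {
    eq <- equilibrium_reached(trace, baseline_end_s = clamp_start_s - guard_s)
    if (!isTRUE(as.logical(eq))) {
      stop("trace not equilibrated before clamp: ", attr(eq, "reason"),
           call. = FALSE)
    }
  }
  in_base <- trace$time_s >= clamp_start_s - guard_s - window_s &
    trace$time_s < clamp_start_s - guard_s
  in_clamp <- trace$time_s > clamp_start_s + guard_s &
    trace$time_s <= clamp_start_s + guard_s + window_s
  if (sum(in_base) < 2 || sum(in_clamp) < 2) {
    stop("trace does not cover the baseline and clamp windows", call. = FALSE)
  }
  delta_i <- mean(trace$current_a[in_clamp]) - mean(trace$current_a[in_base])
  if (!is.finite(delta_i) || delta_i <= noise_floor_a) {
    stop("no clamp deflection above the noise floor (dI = ",
         format(delta_i), " A)", call. = FALSE)
  }
  r <- clamp_voltage_v / delta_i
  tibble::tibble(
    delta_i_a = delta_i, r_ohm = r, r_ohm_cm2 = r * area_cm2,
    clamp_start_s = clamp_start_s, window_s = window_s
  )
}

#' Impedance magnitude at 100 Hz
#'
#' Extracts |Z| at the mid-frequency reference point used to track barrier
#' growth. An exact grid hit (the default sweep contains 100 Hz by
#' construction) returns |Z| at that point; otherwise |Z| is interpolated
#' linearly in log10(frequency) between the bracketing grid points.
#'
#' @param spectrum A tidy spectrum for one device/day.
#' @param f0 Reference frequency in Hz (default 100).
#' @return |Z| at `f0`, in Ohm.
#' @export
zmag_at_100hz <- function(spectrum, f0 = 100) {
  validate_spectrum(spectrum)
  f <- spectrum$frequency_hz
  zmag <- Mod(spectrum_z(spectrum))
  if (f0 < min(f) || f0 > max(f)) {
    stop("reference frequency ", f0, " Hz lies outside the grid span",
         call. = FALSE)
  }
  hit <- which(abs(f - f0) <= f0 * 1e-9)
  if (length(hit)) return(zmag[hit[[1]]])
  o <- order(f)
  stats::approx(x = log10(f[o]), y = zmag[o], xout = log10(f0))$y
}

#' Per-device impedance trajectories from a cohort of spectra
#'
#' Computes |Z|(100 Hz) for every device/day sweep and, when a fit report
#' from [fit_eis_cohort()] is supplied, joins the fitted barrier and
#' electrolyte resistances.
#'
#' @param spectra Long spectrum table (`device_id`, `day`, ...).
#' @param fits Optional fit report from [fit_eis_cohort()].
#' @return A tibble `device_id`, `day`, `zmag100_ohm` (+ `rb_ohm`, `r1_ohm`
#'   if `fits` given), one row per device/day, days ascending.
#' @export
eis_trajectories <- function(spectra, fits = NULL) {
  stopifnot(all(c("device_id", "day") %in% names(spectra)))
  key <- paste(spectra$device_id, spectra$day, sep = "\r")
  groups <- split(seq_len(nrow(spectra)), factor(key, levels = unique(key)))
  traj <- purrr::map(groups, function(idx) {
    sp <- spectra[idx, , drop = FALSE]
    tibble::tibble(
      device_id = sp$device_id[[1]], day = as.integer(sp$day[[1]]),
      zmag100_ohm = zmag_at_100hz(sp)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$device_id, .data$day)
  if (!is.null(fits)) {
    traj <- dplyr::left_join(
      traj,
      dplyr::select(fits, "device_id", "day", "rb_ohm", "r1_ohm"),
      by = c("device_id", "day")
    )
  }
  traj
}

#' Barrier-formation quality-control filter
#'
#' Partitions devices by the barrier-formation criterion: a device is kept
#' if and only if its |Z|(100 Hz) at the assessment day is at or above the
#' threshold (the boundary value passes). Devices with no measurement at
#' the assessment day are rejected with a reason. The filter partitions its
#' input (`kept` + `rejected` = all devices) and is idempotent.
#'
#' @param trajectories Trajectory table with `device_id`, `day`,
#'   `zmag100_ohm` (see [eis_trajectories()]).
#' @param threshold_ohm QC threshold in Ohm (default 95).
#' @param at_day Assessment day on the co-culture clock (default 14).
#' @return A list of two device-level tibbles, `kept` and `rejected`, each
#'   with `device_id`, `zmag100_ohm` (at `at_day`), `qc_pass`, `reason`.
#' @export
qc_filter <- function(trajectories, threshold_ohm = 95, at_day = 14) {
  empty <- tibble::tibble(
    device_id = character(), zmag100_ohm = double(),
    qc_pass = logical(), reason = character()
  )
  if (is.null(trajectories) || nrow(trajectories) == 0) {
    return(list(kept = empty, rejected = empty))
  }
  stopifnot(all(c("device_id", "day", "zmag100_ohm") %in% names(trajectories)))
  per_device <- trajectories |>
    dplyr::group_by(.data$device_id) |>
    dplyr::summarise(
      zmag100_ohm = .data$zmag100_ohm[match(at_day, .data$day)],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      qc_pass = !is.na(.data$zmag100_ohm) & .data$zmag100_ohm >= threshold_ohm,
      reason = dplyr::case_when(
        is.na(.data$zmag100_ohm) ~ sprintf("no measurement at day %d", at_day),
        .data$qc_pass ~ sprintf("|Z|(100 Hz) >= %g Ohm at day %d",
                                threshold_ohm, at_day),
        TRUE ~ sprintf("|Z|(100 Hz) < %g Ohm at day %d", threshold_ohm, at_day)
      )
    )
  list(
    kept = dplyr::filter(per_device, .data$qc_pass),
    rejected = dplyr::filter(per_device, !.data$qc_pass)
  )
}

# t.test() refuses constant data; the degenerate case of identical
# (or jointly constant) samples is well defined for our use: no difference
# means t = 0, p = 1, and a non-zero difference with zero spread is an
# infinite statistic with p = 0.
safe_t_test <- function(x, y, paired = FALSE, var.equal = TRUE) {
  spread <- if (paired) stats::sd(x - y) else max(stats::sd(x), stats::sd(y))
  if (is.na(spread) || spread > 0) {
    return(stats::t.test(x, y, paired = paired, var.equal = var.equal))
  }
  d <- mean(x) - mean(y)
  df <- if (paired) length(x) - 1 else length(x) + length(y) - 2
  structure(
    list(
      statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
      parameter = c(df = df),
      p.value = if (d == 0) 1 else 0,
      estimate = if (paired) c(`mean difference` = d) else
        c(`mean of x` = mean(x), `mean of y` = mean(y)),
      method = if (paired) "Paired t-test (degenerate)" else
        "Two Sample t-test (degenerate)"
    ),
    class = "htest"
  )
}

#' Day-0 vs day-14 endpoint comparison
#'
#' Two-tailed Student's t-test between two endpoint samples (e.g. fitted Rb
#' or |Z|(100 Hz) at the start and end of co-culture). With
#' `paired = "auto"` the test is paired when both arms carry device
#' identifiers forming complete pairs, and unpaired (classic equal-variance
#' Student) otherwise -- the situation that arises when technical failures
#' break pairing. Welch's unequal-variance flavour is available via
#' `var_equal = FALSE`.
#'
#' @param values_day0,values_day14 Numeric endpoint samples (>= 2 each).
#' @param paired `"auto"`, `TRUE` or `FALSE`.
#' @param ids_day0,ids_day14 Optional device identifiers used by
#'   `"auto"`/`TRUE` pairing; arms are matched by identifier.
#' @param var_equal Pool variances in the unpaired test (default TRUE,
#'   classic Student).
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `estimate`
#'   (mean difference day14 - day0), `method`, `paired`.
#' @export
endpoint_test <- function(values_day0, values_day14, paired = "auto",
                          ids_day0 = NULL, ids_day14 = NULL,
                          var_equal = TRUE) {
  if (length(values_day0) < 2 || length(values_day14) < 2) {
    stop("need at least 2 values per arm", call. = FALSE)
  }
  has_ids <- !is.null(ids_day0) && !is.null(ids_day14)
  if (identical(paired, "auto")) {
    paired <- has_ids &&
      length(ids_day0) == length(ids_day14) &&
      setequal(ids_day0, ids_day14) &&
      !anyDuplicated(ids_day0) && !anyDuplicated(ids_day14)
  }
  if (isTRUE(paired)) {
    if (has_ids) {
      if (!setequal(ids_day0, ids_day14) ||
          length(ids_day0) != length(ids_day14)) {
        stop("paired test requested but arms are not complete pairs",
             call. = FALSE)
      }
      values_day14 <- values_day14[match(ids_day0, ids_day14)]
    } else if (length(values_day0) != length(values_day14)) {
      stop("paired test requested but arms have unequal lengths",
           call. = FALSE)
    }
    tt <- safe_t_test(values_day14, values_day0, paired = TRUE)
  } else {
    tt <- safe_t_test(values_day14, values_day0,
                      var.equal = var_equal, paired = FALSE)
  }
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    estimate = if (isTRUE(paired)) unname(tt$estimate) else
      unname(tt$estimate[1] - tt$estimate[2]),
    method = tt$method,
    paired = isTRUE(paired)
  )
}
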