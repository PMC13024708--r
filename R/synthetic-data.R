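# Seeded generators emulating all three measurement platforms: EIS cohorts
# with day-dependent barrier growth, TEER tables, Ussing current traces and
# calcium-switch triplets. Every generator is a pure function of its
# arguments and a seed, and emits its ground truth alongside the data so
# downstream recovery error is always measurable.

# Endpoint conditions the EIS generator is calibrated to: cohort-mean
# barrier resistance and |Z|(100 Hz) at the start and end of co-culture.
eis_endpoint_defaults <- function() {
  list(
    rb_day0_mean = 14.97, rb_day0_sd = 3.36,
    rb_day14_mean = 25.37, rb_day14_sd = 3.30,
    zmag100_day0 = 82.08, zmag100_day14 = 107.26
  )
}

#' Default calcium-switch cohort parameters per platform
#'
#' Replicate counts and normalised effect-size distributions (multiplicative,
#' relative to each replicate's baseline) for the three platforms, together
#' with a platform-native baseline scale: TEER in Ohm.cm^2 for the 2D
#' inserts, fitted Rb in Ohm for the 3D devices, and Ussing resistance in
#' Ohm for ex vivo tissue (the ex vivo baseline scale is a synthetic choice;
#' absolute ex vivo resistances are not part of the calibration).
#'
#' @return A tibble with one row per platform: `platform`, `n`,
#'   `baseline_mean`, `baseline_sd`, `egta_effect_mean`, `egta_effect_sd`,
#'   `washout_effect_mean`, `washout_effect_sd`.
#' @export
switch_platform_defaults <- function() {
  tibble::tribble(
    ~platform, ~n, ~baseline_mean, ~baseline_sd,
    ~egta_effect_mean, ~egta_effect_sd,
    ~washout_effect_mean, ~washout_effect_sd,
    "2D",      11L, 54,    6,    0.83, 0.09, 0.68, 0.13,
    "3D",       9L, 25.37, 3.30, 0.99, 0.13, 0.83, 0.03,
    "ex-vivo",  9L, 50,    10,   0.85, 0.16, 0.54, 0.14
  )
}

#' Solve the CPE magnitude against a |Z|(100 Hz) target
#'
#' One-dimensional calibration of the scaffold CPE: holding `r1`, `cp`,
#' `alpha` and the barrier resistance fixed, finds the CPE magnitude `q`
#' such that the noiseless model satisfies `|Z|(f0) = zmag_target`.
#' |Z|(f0) decreases monotonically in `q`, so the root is unique when it
#' exists; it is found by [stats::uniroot()] on log10(q).
#'
#' @param rb Barrier resistance, Ohm.
#' @param zmag_target Target |Z| at `f0`, Ohm.
#' @param r1,cp,alpha Fixed nuisance parameters (defaults 60 Ohm, 5e-6 F,
#'   0.85).
#' @param f0 Calibration frequency, Hz (default 100).
#' @param q_range Search interval for `q`, S.s^alpha.
#' @param tol Root tolerance on log10(q) (default 1e-12).
#' @return The solved `q`.
#' @export
calibrate_nuisance_q <- function(rb, zmag_target, r1 = 60, cp = 5e-6,
                                 alpha = 0.85, f0 = 100,
                                 q_range = c(1e-7, 10), tol = 1e-12) {
  objective <- function(log10_q) {
    p <- circuit_params(r1 = r1, rb = rb, cp = cp, q = 10^log10_q,
                        alpha = alpha)
    Mod(impedance(p, f0)) - zmag_target
  }
  lo <- log10(q_range[[1]]); hi <- log10(q_range[[2]])
  if (objective(lo) < 0 || objective(hi) > 0) {
    stop("no CPE magnitude in [", q_range[[1]], ", ", q_range[[2]],
         "] reaches |Z|(", f0, " Hz) = ", zmag_target,
         " Ohm with rb = ", rb, " Ohm", call. = FALSE)
  }
  root <- stats::uniroot(objective, lower = lo, upper = hi, tol = tol)
  10^root$root
}

#' Calibrated day-0 / day-14 parameter sets for the mean device
#'
#' Produces the two circuit-parameter sets the EIS generator anchors its
#' trajectories to: barrier resistance fixed at the cohort day-0 and day-14
#' means, electrolyte resistance, barrier capacitance and CPE exponent held
#' fixed, and the CPE magnitude solved per day (via [calibrate_nuisance_q()])
#' so the noiseless mean device reproduces the cohort-mean |Z|(100 Hz)
#' endpoints simultaneously with the Rb endpoints. The |Z|(100 Hz) rise
#' over co-culture exceeds the Rb rise; the surplus is attributed to the
#' scaffold CPE (q falling as cells infill the pores), keeping the
#' electrolyte resistance constant.
#'
#' @param endpoints Endpoint condition list; see the defaults in the
#'   returned attribute.
#' @param r1,cp,alpha Fixed nuisance parameters.
#' @return A tibble with rows day 0 and day 14 and columns `day`, `r1_ohm`,
#'   `rb_ohm`, `cp_farad`, `q_cpe`, `alpha`, `zmag100_target_ohm`.
#' @export
calibrate_defaults <- function(endpoints = eis_endpoint_defaults(),
                               r1 = 60, cp = 5e-6, alpha = 0.85) {
  q0 <- calibrate_nuisance_q(endpoints$rb_day0_mean, endpoints$zmag100_day0,
                             r1 = r1, cp = cp, alpha = alpha)
  q14 <- calibrate_nuisance_q(endpoints$rb_day14_mean, endpoints$zmag100_day14,
                              r1 = r1, cp = cp, alpha = alpha)
  tibble::tibble(
    day = c(0L, 14L),
    r1_ohm = r1,
    rb_ohm = c(endpoints$rb_day0_mean, endpoints$rb_day14_mean),
    cp_farad = cp,
    q_cpe = c(q0, q14),
    alpha = alpha,
    zmag100_target_ohm = c(endpoints$zmag100_day0, endpoints$zmag100_day14)
  )
}

# Convex growth weight: fraction of the total day-0 -> day-14 increase
# realised by day d. 40 % of the rise is allocated linearly to days 0-10
# and 60 % to days 10-14, reflecting accelerated barrier growth after
# confluence.
growth_weight <- function(day, split_day = 10, early_fraction = 0.4) {
  day <- pmin(pmax(day, 0), 14)
  ifelse(
    day <= split_day,
    early_fraction * day / split_day,
    early_fraction + (1 - early_fraction) * (day - split_day) / (14 - split_day)
  )
}

rnorm_pos <- function(n, mean, sd, lower = .Machine$double.eps) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic EIS cohort with day-dependent barrier growth
#'
#' Draws per-device day-0 and day-14 barrier resistances from the endpoint
#' distributions (correlated across days, truncated so every trajectory is
#' non-decreasing), interpolates `rb(day)` with the convex 40/60 growth
#' schedule around day 10, holds the electrolyte resistance constant per
#' device, interpolates the scaffold CPE magnitude log-linearly between its
#' calibrated day-0 and day-14 values along the same schedule, and
#' simulates each sweep on the default 61-point grid with proportional
#' complex Gaussian noise (independent real/imaginary components, each of
#' standard deviation `noise_rel * |Z|` per point).
#'
#' @param n_devices Number of devices (default 10).
#' @param days Measurement days on the co-culture clock
#'   (default 0, 2, ..., 14).
#' @param rb_day0_mean,rb_day0_sd,rb_day14_mean,rb_day14_sd Endpoint
#'   barrier-resistance distributions, Ohm.
#' @param r1_mean,r1_sd Electrolyte resistance distribution, Ohm
#'   (constant within a device).
#' @param endpoint_cor Correlation between a device's day-0 and day-14
#'   barrier resistance (default 0.5).
#' @param noise_rel Proportional noise level (default 0.01).
#' @param frequencies Sweep grid (default [make_frequency_grid()]).
#' @param calibration Nuisance calibration table from
#'   [calibrate_defaults()].
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return A list with `spectra` (long tidy table, one row per device, day
#'   and frequency) and `truth` (one row per device/day: the generating
#'   `r1_ohm`, `rb_ohm`, `cp_farad`, `q_cpe`, `alpha`).
#' @export
gen_eis_cohort <- function(n_devices = 10,
                           days = seq(0L, 14L, by = 2L),
                           rb_day0_mean = 14.97, rb_day0_sd = 3.36,
                           rb_day14_mean = 25.37, rb_day14_sd = 3.30,
                           r1_mean = 60, r1_sd = 5,
                           endpoint_cor = 0.5,
                           noise_rel = 0.01,
                           frequencies = make_frequency_grid(),
                           calibration = calibrate_defaults(),
                           seed = 1L) {
  stopifnot(n_devices >= 1, rb_day0_mean > 0, rb_day14_mean > 0,
            rb_day0_sd >= 0, rb_day14_sd >= 0, noise_rel >= 0,
            abs(endpoint_cor) <= 1)
  q0 <- calibration$q_cpe[calibration$day == 0L]
  q14 <- calibration$q_cpe[calibration$day == 14L]
  cp <- calibration$cp_farad[[1]]
  alpha <- calibration$alpha[[1]]

  withr::with_seed(seed, {
    draw_endpoints <- function(n) {
      z1 <- stats::rnorm(n)
      z2 <- stats::rnorm(n)
      rb0 <- rb_day0_mean + rb_day0_sd * z1
      rb14 <- rb_day14_mean +
        rb_day14_sd * (endpoint_cor * z1 + sqrt(1 - endpoint_cor^2) * z2)
      cbind(rb0, rb14)
    }
    ep <- draw_endpoints(n_devices)
    # truncation: endpoints positive and non-decreasing per device
    while (any(bad <- ep[, 1] <= 0 | ep[, 2] < ep[, 1])) {
      ep[bad, ] <- draw_endpoints(sum(bad))
    }
    r1 <- rnorm_pos(n_devices, r1_mean, r1_sd, lower = 1)

    per_device <- purrr::map(seq_len(n_devices), function(i) {
      dev <- sprintf("device-%02d", i)
      w <- growth_weight(days)
      rb_t <- ep[i, 1] + w * (ep[i, 2] - ep[i, 1])
      q_t <- 10^((1 - w) * log10(q0) + w * log10(q14))
      truth <- tibble::tibble(
        device_id = dev, day = as.integer(days),
        r1_ohm = r1[[i]], rb_ohm = rb_t, cp_farad = cp, q_cpe = q_t,
        alpha = alpha
      )
      spectra <- purrr::map2(days, seq_along(days), function(d, k) {
        p <- circuit_params(r1 = r1[[i]], rb = rb_t[[k]], cp = cp,
                            q = q_t[[k]], alpha = alpha)
        sp <- simulate_spectrum(p, frequencies, device_id = dev, day = d)
        if (noise_rel > 0) {
          zm <- Mod(complex(real = sp$z_real_ohm, imaginary = sp$z_imag_ohm))
          sp$z_real_ohm <- sp$z_real_ohm +
            stats::rnorm(nrow(sp), sd = noise_rel * zm)
          sp$z_imag_ohm <- sp$z_imag_ohm +
            stats::rnorm(nrow(sp), sd = noise_rel * zm)
        }
        sp
      }) |>
        dplyr::bind_rows()
      list(spectra = spectra, truth = truth)
    })
    list(
      spectra = dplyr::bind_rows(purrr::map(per_device, "spectra")),
      truth = dplyr::bind_rows(purrr::map(per_device, "truth"))
    )
  })
}

#' Generate a synthetic TEER cohort
#'
#' Draws a day-14 TEER target per well from its group distribution, scales
#' it along a logistic rise over the culture period (midpoint day 7, scale
#' 2 days, normalised so the day-14 value hits the target exactly), and
#' emits raw/blank reading pairs that invert the TEER formula:
#' `raw = blank + teer / area`. Blanks are drawn per well around 100 Ohm.
#'
#' @param group_specs Tibble with columns `group`, `teer_mean`, `teer_sd`
#'   (day-14 targets, Ohm.cm^2). Defaults to the three culture groups:
#'   co-culture 54 +/- 6, IEC-6 monoculture 27 +/- 8, 208F monoculture
#'   20 +/- 3.
#' @param n_wells Wells per group (default 9).
#' @param days Measurement days (default 1, 4, 7, 10, 14).
#' @param n_readings Voltohmmeter readings per well per day (default 3;
#'   identical unless `reading_sd > 0`).
#' @param reading_sd Per-reading instrument noise on the raw resistance,
#'   Ohm (default 0).
#' @param blank_mean,blank_sd Blank-insert resistance distribution, Ohm
#'   (defaults 100 +/- 5).
#' @param area_cm2 Insert growth area (default 0.33).
#' @param seed Integer seed.
#' @return A list with `records` (TEER record table: `well_id`, `group`,
#'   `day`, `reading_index`, `raw_ohm`, `blank_ohm`, `area_cm2`) and
#'   `truth` (per well/day generating TEER, Ohm.cm^2).
#' @export
gen_teer_cohort <- function(group_specs = tibble::tibble(
                              group = c("co-culture", "monoculture-IEC6",
                                        "monoculture-208F"),
                              teer_mean = c(54, 27, 20),
                              teer_sd = c(6, 8, 3)
                            ),
                            n_wells = 9, days = c(1L, 4L, 7L, 10L, 14L),
                            n_readings = 3, reading_sd = 0,
                            blank_mean = 100, blank_sd = 5,
                            area_cm2 = 0.33, seed = 1L) {
  stopifnot(all(group_specs$teer_mean > 0), all(group_specs$teer_sd >= 0),
            n_wells >= 1, n_readings >= 1, area_cm2 > 0)
  logistic <- function(d) 1 / (1 + exp(-(d - 7) / 2))
  rise <- logistic(days) / logistic(14)

  withr::with_seed(seed, {
    per_group <- purrr::pmap(group_specs, function(group, teer_mean, teer_sd) {
      target <- rnorm_pos(n_wells, teer_mean, teer_sd)
      purrr::map(seq_len(n_wells), function(w) {
        well <- sprintf("%s-well-%02d", group, w)
        blank <- rnorm_pos(length(days), blank_mean, blank_sd, lower = 1)
        teer_d <- target[[w]] * rise
        raw0 <- blank + teer_d / area_cm2
        records <- purrr::map(seq_along(days), function(k) {
          raw <- raw0[[k]] +
            if (reading_sd > 0) stats::rnorm(n_readings, sd = reading_sd)
            else rep(0, n_readings)
          tibble::tibble(
            well_id = well, group = group, day = days[[k]],
            reading_index = seq_len(n_readings),
            raw_ohm = raw, blank_ohm = blank[[k]], area_cm2 = area_cm2
          )
        }) |>
          dplyr::bind_rows()
        truth <- tibble::tibble(
          well_id = well, group = group, day = as.integer(days),
          teer_ohm_cm2 = teer_d
        )
        list(records = records, truth = truth)
      })
    })
    flat <- purrr::flatten(per_group)
    list(
      records = dplyr::bind_rows(purrr::map(flat, "records")),
      truth = dplyr::bind_rows(purrr::map(flat, "truth"))
    )
  })
}

#' Generate a synthetic Ussing-chamber current trace
#'
#' Emits an equilibrated baseline current followed by a square voltage-clamp
#' pulse whose deflection obeys Ohm's law, `dI = clamp_voltage_v / r_tissue`,
#' with proportional Gaussian noise on every sample.
#'
#' @param r_tissue Tissue resistance to encode, Ohm (> 0).
#' @param noise_rel Proportional noise level (default 0.01).
#' @param duration_s Trace length, seconds (default 2400 = 40 min).
#' @param dt_s Sampling interval, seconds (default 1).
#' @param baseline_a Baseline current, A (default 2e-5).
#' @param clamp_voltage_v Clamp voltage, V (default 5e-3).
#' @param clamp_start_s,clamp_duration_s Pulse timing (defaults 2000 s,
#'   120 s).
#' @param area_cm2 Exposed tissue area (default 0.33), stamped as an
#'   attribute.
#' @param seed Integer seed.
#' @return A tibble `time_s`, `current_a` with attributes
#'   `clamp_voltage_v`, `area_cm2`, `clamp_start_s`.
#' @export
gen_ussing_trace <- function(r_tissue, noise_rel = 0.01,
                             duration_s = 2400, dt_s = 1,
                             baseline_a = 2e-5, clamp_voltage_v = 5e-3,
                             clamp_start_s = 2000, clamp_duration_s = 120,
                             area_cm2 = 0.33, seed = 1L) {
  stopifnot(r_tissue > 0, noise_rel >= 0, clamp_voltage_v > 0,
            clamp_start_s + clamp_duration_s <= duration_s)
  time_s <- seq(0, duration_s, by = dt_s)
  delta_i <- clamp_voltage_v / r_tissue
  current <- rep(baseline_a, length(time_s))
  on <- time_s > clamp_start_s & time_s <= clamp_start_s + clamp_duration_s
  current[on] <- current[on] + delta_i
  trace <- withr::with_seed(seed, {
    if (noise_rel > 0) {
      current <- current + stats::rnorm(length(current),
                                        sd = noise_rel * abs(current))
    }
    tibble::tibble(time_s = time_s, current_a = current)
  })
  attr(trace, "clamp_voltage_v") <- clamp_voltage_v
  attr(trace, "area_cm2") <- area_cm2
  attr(trace, "clamp_start_s") <- clamp_start_s
  trace
}

#' Generate a synthetic calcium-switch cohort
#'
#' Draws a platform-native baseline resistance per replicate and applies
#' multiplicative phase effects: `egta = baseline * e`, `washout =
#' baseline * w`, with `e` and `w` drawn per replicate from the platform's
#' effect distributions (truncated positive). Defaults come from
#' [switch_platform_defaults()].
#'
#' @param platform One of `"2D"`, `"3D"`, `"ex-vivo"`.
#' @param n Replicates; default is the platform default.
#' @param baseline_mean,baseline_sd Baseline distribution, platform-native
#'   units; platform defaults if `NULL`.
#' @param egta_effect_mean,egta_effect_sd,washout_effect_mean,washout_effect_sd
#'   Effect distributions (multiplicative, dimensionless); platform
#'   defaults if `NULL`.
#' @param seed Integer seed.
#' @return A list with `series` (columns `replicate_id`, `platform`,
#'   `baseline`, `egta`, `washout`) and `truth` (the effect draws).
#' @export
gen_switch_cohort <- function(platform = c("2D", "3D", "ex-vivo"),
                              n = NULL,
                              baseline_mean = NULL, baseline_sd = NULL,
                              egta_effect_mean = NULL, egta_effect_sd = NULL,
                              washout_effect_mean = NULL,
                              washout_effect_sd = NULL,
                              seed = 1L) {
  platform <- match.arg(platform)
  defaults <- switch_platform_defaults()
  defaults <- defaults[defaults$platform == platform, ]
  n <- if (is.null(n)) defaults$n else n
  baseline_mean <- baseline_mean %||% defaults$baseline_mean
  baseline_sd <- baseline_sd %||% defaults$baseline_sd
  egta_effect_mean <- egta_effect_mean %||% defaults$egta_effect_mean
  egta_effect_sd <- egta_effect_sd %||% defaults$egta_effect_sd
  washout_effect_mean <- washout_effect_mean %||% defaults$washout_effect_mean
  washout_effect_sd <- washout_effect_sd %||% defaults$washout_effect_sd
  stopifnot(n >= 2, baseline_mean > 0, egta_effect_mean > 0,
            washout_effect_mean > 0)

  withr::with_seed(seed, {
    baseline <- rnorm_pos(n, baseline_mean, baseline_sd)
    e <- rnorm_pos(n, egta_effect_mean, egta_effect_sd)
    w <- rnorm_pos(n, washout_effect_mean, washout_effect_sd)
    series <- tibble::tibble(
      replicate_id = sprintf("%s-rep-%02d", platform, seq_len(n)),
      platform = platform,
      baseline = baseline,
      egta = baseline * e,
      washout = baseline * w
    )
    truth <- tibble::tibble(
      replicate_id = series$replicate_id, platform = platform,
      egta_effect = e, washout_effect = w
    )
    list(series = series, truth = truth)
  })
}
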