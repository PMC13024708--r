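test_that("TEER conversion follows (raw - blank) * area and flags negatives", {
  expect_equal(compute_teer(data.frame(raw_ohm = 100, blank_ohm = 100))$teer_ohm_cm2, 0)
  r <- compute_teer(data.frame(raw_ohm = 263.6, blank_ohm = 100, area_cm2 = 0.33))
  expect_equal(r$teer_ohm_cm2, 163.6 * 0.33, tolerance = 1e-12)
  neg <- compute_teer(data.frame(raw_ohm = 90, blank_ohm = 100))
  expect_equal(neg$teer_ohm_cm2, -3.3, tolerance = 1e-12)
  expect_true(neg$teer_negative)
})

test_that("TEER is invariant to a common offset in raw and blank", {
  a <- compute_teer(data.frame(raw_ohm = 250, blank_ohm = 100))$teer_ohm_cm2
  b <- compute_teer(data.frame(raw_ohm = 250 + 37, blank_ohm = 100 + 37))$teer_ohm_cm2
  expect_equal(a, b)
})

test_that("group summary computes sample mean and SD per group/day", {
  rec <- data.frame(
    well_id = c("w1", "w2", "w3"), group = "g", day = 14,
    raw_ohm = 100 + c(1, 2, 3) / 0.33, blank_ohm = 100
  )
  s <- teer_group_summary(rec)
  expect_equal(s$mean_teer, 2, tolerance = 1e-12)
  expect_equal(s$sd_teer, 1, tolerance = 1e-12)
  expect_equal(s$n, 3)

  two <- teer_group_summary(data.frame(
    well_id = c("w1", "w2"), group = "g", day = 1,
    raw_ohm = 200, blank_ohm = 100
  ))
  expect_equal(two$sd_teer, 0)

  single <- teer_group_summary(data.frame(
    well_id = "w1", group = "g", day = 1, raw_ohm = 200, blank_ohm = 100
  ))
  expect_true(is.na(single$sd_teer))
})

test_that("readings of a well are blank-subtracted then averaged", {
  rec <- data.frame(
    well_id = "w1", group = "g", day = 14, reading_index = 1:3,
    raw_ohm = c(260, 263.6, 267.2), blank_ohm = 100
  )
  s <- teer_group_summary(rec)
  expect_equal(s$n, 1)
  expect_equal(s$mean_teer, 163.6 * 0.33, tolerance = 1e-12)
})

test_that("Ussing resistance applies Ohm's law to the clamp deflection", {
  tr <- gen_ussing_trace(r_tissue = 50, noise_rel = 0, seed = 1)
  res <- ussing_resistance(tr)
  expect_equal(res$r_ohm, 50, tolerance = 1e-9)
  expect_equal(res$delta_i_a, 1e-4, tolerance = 1e-9)
  expect_equal(res$r_ohm_cm2, 50 * 0.33, tolerance = 1e-9)

  tr1 <- gen_ussing_trace(r_tissue = 1, noise_rel = 0, seed = 1)
  expect_equal(ussing_resistance(tr1)$delta_i_a, 5e-3, tolerance = 1e-9)

  # doubling the deflection halves the resistance
  tr2 <- tr
  base <- tr2$current_a[1]
  tr2$current_a <- base + 2 * (tr2$current_a - base)
  expect_equal(ussing_resistance(tr2)$r_ohm, 25, tolerance = 1e-9)

  # noiseless trace: R * dI returns the clamp voltage exactly
  expect_equal(res$r_ohm * res$delta_i_a, 5e-3, tolerance = 1e-12)
})

test_that("Ussing recovery stays within 3 % at 1 % proportional noise", {
  tr <- gen_ussing_trace(r_tissue = 50, noise_rel = 0.01, seed = 42)
  expect_lt(abs(ussing_resistance(tr)$r_ohm - 50) / 50, 0.03)
})

test_that("equilibrium criterion accepts flat and rejects ramping baselines", {
  t_s <- 0:2100
  flat <- tibble::tibble(time_s = t_s, current_a = 2e-5)
  expect_true(as.logical(equilibrium_reached(flat)))

  ramp <- tibble::tibble(time_s = t_s,
                         current_a = 2e-5 * (1 + 0.10 * t_s / 60))
  expect_false(as.logical(equilibrium_reached(ramp)))

  short <- tibble::tibble(time_s = 0:600, current_a = 2e-5)
  eq <- equilibrium_reached(short)
  expect_false(as.logical(eq))
  expect_match(attr(eq, "reason"), "shorter")

  noisy <- withr::with_seed(5, tibble::tibble(
    time_s = t_s, current_a = 2e-5 * (1 + rnorm(length(t_s), sd = 0.01))
  ))
  expect_true(as.logical(equilibrium_reached(noisy)))

  ramped <- tibble::tibble(time_s = t_s,
                           current_a = 2e-5 * (1 + 0.10 * t_s / 60))
  expect_error(ussing_resistance(ramped, clamp_start_s = 2000),
               "not equilibrated")
})

test_that("|Z| at 100 Hz uses exact grid hits and log-f interpolation", {
  p <- ref_params()
  sp <- simulate_spectrum(p)
  expect_equal(zmag_at_100hz(sp), Mod(z_oracle(60, 25, 5e-6, 2e-3, 0.85, 100)),
               tolerance = 1e-12)

  resistor <- tibble::tibble(frequency_hz = c(1000, 200, 50, 10),
                             z_real_ohm = 100, z_imag_ohm = 0)
  expect_equal(zmag_at_100hz(resistor), 100)

  # off-grid: |Z| interpolated linearly in log10(f); 100 Hz is the midpoint
  # of [10, 1000] on the log axis
  interp <- tibble::tibble(frequency_hz = c(1000, 10),
                           z_real_ohm = c(20, 10), z_imag_ohm = 0)
  expect_equal(zmag_at_100hz(interp), 15)

  out_of_span <- tibble::tibble(frequency_hz = c(50, 10),
                                z_real_ohm = 100, z_imag_ohm = 0)
  expect_error(zmag_at_100hz(out_of_span), "outside")
})

test_that("QC filter keeps the inclusive 95-Ohm boundary and partitions", {
  traj <- tibble::tibble(
    device_id = c("a", "b", "c"), day = 14,
    zmag100_ohm = c(94.9, 95.0, 120.0)
  )
  qc <- qc_filter(traj)
  expect_setequal(qc$kept$device_id, c("b", "c"))
  expect_equal(qc$rejected$device_id, "a")
  expect_equal(nrow(qc$kept) + nrow(qc$rejected), 3)

  # idempotent on the kept subset
  again <- qc_filter(traj[traj$device_id %in% qc$kept$device_id, ])
  expect_setequal(again$kept$device_id, qc$kept$device_id)
  expect_equal(nrow(again$rejected), 0)

  empty <- qc_filter(tibble::tibble(device_id = character(), day = integer(),
                                    zmag100_ohm = double()))
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)

  # missing assessment day routes to rejected with a reason
  no14 <- tibble::tibble(device_id = "d", day = 10, zmag100_ohm = 120)
  qc2 <- qc_filter(no14)
  expect_equal(qc2$rejected$device_id, "d")
  expect_match(qc2$rejected$reason, "no measurement")
})

test_that("QC counts match a constructed cohort with known pass fraction", {
  coh <- gen_eis_cohort(n_devices = 10, days = 14L, noise_rel = 0, seed = 21)
  spectra <- coh$spectra
  # push three devices below threshold by scaling their impedance down
  low <- c("device-01", "device-02", "device-03")
  idx <- spectra$device_id %in% low
  spectra$z_real_ohm[idx] <- spectra$z_real_ohm[idx] * 0.5
  spectra$z_imag_ohm[idx] <- spectra$z_imag_ohm[idx] * 0.5
  qc <- qc_filter(eis_trajectories(spectra))
  expect_equal(nrow(qc$kept), 7)
  expect_setequal(qc$rejected$device_id, low)
})

test_that("endpoint test matches the textbook two-sample formula", {
  res <- endpoint_test(c(1, 2, 3), c(2, 3, 4), paired = FALSE)
  expect_equal(res$statistic, 1.224745, tolerance = 1e-6)  # day14 - day0 > 0
  expect_equal(res$df, 4)
  expect_equal(res$p.value, 2 * stats::pt(-1.224745, 4), tolerance = 1e-6)
  expect_false(res$paired)

  same <- endpoint_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("auto pairing requires complete device pairs", {
  ids <- letters[1:4]
  auto_paired <- endpoint_test(1:4, c(2, 3, 4, 6), ids_day0 = ids,
                               ids_day14 = rev(ids))
  expect_true(auto_paired$paired)
  # matched by id, not position: pairs are (1,6), (2,4), (3,3), (4,2)
  expect_equal(auto_paired$estimate, mean(c(6 - 1, 4 - 2, 3 - 3, 2 - 4)),
               tolerance = 1e-9)

  broken <- endpoint_test(1:4, c(2, 3, 4), ids_day0 = ids,
                          ids_day14 = ids[1:3])
  expect_false(broken$paired)

  expect_error(endpoint_test(1:4, 1:3, paired = TRUE), "unequal")
})

test_that("day-0 vs day-14 barrier growth is detected with high power", {
  hits <- sapply(1:100, function(s) {
    withr::with_seed(s, {
      rb0 <- rnorm(10, 14.97, 3.36)
      rb14 <- rnorm(10, 25.37, 3.30)
      endpoint_test(rb0, rb14)$p.value < 0.05
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the mean-device trajectory accelerates after day 10", {
  coh <- gen_eis_cohort(n_devices = 1, days = seq(0L, 14L, 2L),
                        rb_day0_sd = 0, rb_day14_sd = 0, r1_sd = 0,
                        noise_rel = 0, seed = 1)
  fits <- fit_eis_cohort(coh$spectra)
  expect_true(all(diff(fits$rb_ohm) >= -1e-6))
  early_slope <- (fits$rb_ohm[fits$day == 10] - fits$rb_ohm[fits$day == 0]) / 10
  late_slope <- (fits$rb_ohm[fits$day == 14] - fits$rb_ohm[fits$day == 10]) / 4
  expect_gt(late_slope, early_slope)
})
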