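test_that("noiseless spectra are recovered to < 0.1 % from a perturbed start", {
  truth <- ref_params()
  sp <- simulate_spectrum(truth)
  init <- withr::with_seed(7, {
    v <- unlist(truth) * runif(5, 0.7, 1.3)
    circuit_params(v[["r1"]], v[["rb"]], v[["cp"]], v[["q"]], v[["alpha"]])
  })
  fit <- fit_spectrum(sp, init = init)
  expect_true(fit$converged)
  est <- tidy(fit)$estimate
  expect_true(all(rel_err(est, unlist(truth)) < 1e-3))
})

test_that("the heuristic initializer lands in the basin of attraction", {
  # flat spectrum of a pure resistor: r1 start reads ~100 Ohm off the data
  flat <- simulate_spectrum(circuit_params(100, 1e-9, 1e-9, 1e3, 0.5))
  flat$z_real_ohm <- 100
  flat$z_imag_ohm <- -1e-9
  init <- initialize_params(flat)
  expect_equal(init$r1, 100, tolerance = 1e-6)

  # day-0 calibrated mean device: fit from the heuristic start hits truth
  cal <- calibrate_defaults()
  p0 <- circuit_params(cal$r1_ohm[1], cal$rb_ohm[1], cal$cp_farad[1],
                       cal$q_cpe[1], cal$alpha[1])
  fit <- fit_spectrum(simulate_spectrum(p0))
  expect_true(fit$converged)
  expect_true(all(rel_err(tidy(fit)$estimate, unlist(p0)) < 1e-3))
})

test_that("the day-14 cohort-mean barrier resistance round-trips", {
  cal <- calibrate_defaults()
  p14 <- circuit_params(cal$r1_ohm[2], cal$rb_ohm[2], cal$cp_farad[2],
                        cal$q_cpe[2], cal$alpha[2])
  fit <- fit_spectrum(simulate_spectrum(p14))
  expect_lt(rel_err(fit$params$rb, 25.37), 1e-3)
})

test_that("CNLS beats a coarse grid-search oracle on noisy data", {
  truth <- ref_params()
  sp <- add_prop_noise(simulate_spectrum(truth), 0.01, seed = 42)
  fit <- fit_spectrum(sp)
  expect_true(fit$converged)

  # exhaustive 11-point/parameter log grid around truth; minimal weighted
  # residual over the grid is the oracle the optimizer must not lose to
  f <- sp$frequency_hz
  z_data <- complex(real = sp$z_real_ohm, imaginary = sp$z_imag_ohm)
  w <- Mod(z_data)
  axis <- function(center) center * 10^seq(-0.15, 0.15, length.out = 11)
  r1s <- axis(60); rbs <- axis(25); cps <- axis(5e-6); qs <- axis(2e-3)
  alphas <- seq(0.75, 0.95, length.out = 11)
  M <- as.matrix(expand.grid(rb = rbs, cp = cps, q = qs, alpha = alphas))
  wv <- 2 * pi * f
  # grid points x frequencies, evaluated by the oracle's algebraic route
  zb <- M[, "rb"] / (1 + 1i * outer(M[, "rb"] * M[, "cp"], wv))
  zcpe <- exp(-outer(M[, "alpha"], log(1i * wv))) / M[, "q"]
  zd_mat <- matrix(z_data, nrow(M), length(f), byrow = TRUE)
  w_mat <- matrix(w, nrow(M), length(f), byrow = TRUE)
  best <- Inf
  for (r1 in r1s) {
    ssr <- rowSums((Mod(r1 + zb + zcpe - zd_mat) / w_mat)^2)
    best <- min(best, ssr)
  }
  expect_lte(fit$residual_norm, best)
  # and the fitted parameters sit near truth at this noise level
  expect_true(all(rel_err(tidy(fit)$estimate, unlist(truth)) < 0.15))
})

test_that("parameter recovery is accurate across random noiseless draws", {
  draws <- withr::with_seed(42, {
    lapply(1:50, function(i) {
      circuit_params(
        r1 = 10^runif(1, 1, 2.5), rb = 10^runif(1, 0.5, 2),
        cp = 10^runif(1, -7, -5), q = 10^runif(1, -4, -2),
        alpha = runif(1, 0.6, 0.95)
      )
    })
  })
  errs <- sapply(draws, function(p) {
    fit <- fit_spectrum(simulate_spectrum(p))
    max(rel_err(tidy(fit)$estimate, unlist(p)))
  })
  expect_lt(stats::median(errs), 0.005)
})

test_that("rb estimates are nearly unbiased at 1 % proportional noise", {
  truth <- ref_params()
  sp0 <- simulate_spectrum(truth)
  rb_hat <- sapply(1:100, function(i) {
    fit_spectrum(add_prop_noise(sp0, 0.01, seed = 1000 + i))$params$rb
  })
  expect_lt(abs(mean(rb_hat) - truth$rb) / truth$rb, 0.02)
})

test_that("rescaling a spectrum rescales the fit by the exact scaling law", {
  truth <- ref_params()
  sp <- add_prop_noise(simulate_spectrum(truth), 0.005, seed = 9)
  c_scale <- 3
  sp_scaled <- dplyr::mutate(sp, z_real_ohm = z_real_ohm * c_scale,
                             z_imag_ohm = z_imag_ohm * c_scale)
  a <- fit_spectrum(sp)$params
  b <- fit_spectrum(sp_scaled)$params
  expect_equal(b$r1, c_scale * a$r1, tolerance = 1e-6)
  expect_equal(b$rb, c_scale * a$rb, tolerance = 1e-6)
  expect_equal(b$cp, a$cp / c_scale, tolerance = 1e-6)
  expect_equal(b$q, a$q / c_scale, tolerance = 1e-6)
  expect_equal(b$alpha, a$alpha, tolerance = 1e-8)
})

test_that("fitted rb and r1 are uncorrelated when generated independently", {
  coh <- gen_eis_cohort(n_devices = 60, days = 14L, noise_rel = 0.01,
                        seed = 11)
  fits <- fit_eis_cohort(coh$spectra)
  expect_true(all(fits$converged))
  expect_lt(abs(pearson_cor(fits$rb_ohm, fits$r1_ohm)), 0.3)
})

test_that("identifiability floor and batch error routing hold", {
  p <- ref_params()
  tiny <- simulate_spectrum(p, frequencies = c(100, 50))
  expect_error(fit_spectrum(tiny), "10 points")
  narrow <- simulate_spectrum(p, frequencies = seq(100, 50, length.out = 12))
  expect_error(fit_spectrum(narrow), "decades")

  expect_equal(nrow(fit_eis_cohort(NULL)), 0)

  coh <- gen_eis_cohort(n_devices = 3, days = 14L, seed = 3)
  bad <- simulate_spectrum(p, frequencies = c(100, 50),
                           device_id = "device-bad", day = 14L)
  fits <- fit_eis_cohort(dplyr::bind_rows(coh$spectra, bad))
  expect_equal(nrow(fits), 4)
  expect_equal(sum(fits$converged), 3)
  expect_match(fits$error[fits$device_id == "device-bad"], "10 points")
  # order preserved
  expect_equal(fits$device_id,
               c("device-01", "device-02", "device-03", "device-bad"))
})

test_that("tidy and glance expose the fit in broom form", {
  fit <- fit_spectrum(simulate_spectrum(ref_params()))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("r1", "rb", "cp", "q", "alpha"))
  gl <- glance(fit)
  expect_equal(gl$n_points, 61)
  expect_true(gl$converged)
  expect_gte(gl$residual_norm, 0)
  expect_identical(gl$weighting, "modulus")
})

test_that("a barrier-free spectrum is flagged rb-at-zero, not hidden", {
  p <- circuit_params(r1 = 80, rb = 0, cp = 1e-6, q = 2e-4, alpha = 0.85)
  sp <- simulate_spectrum(p)
  fit <- fit_spectrum(sp, init = circuit_params(80, 1, 1e-6, 2e-4, 0.85))
  expect_true(fit$barrier_absent)
  expect_lt(fit$params$rb, 1e-3)
})
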