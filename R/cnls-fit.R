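# Complex non-linear least-squares (CNLS) estimation of circuit parameters
# from a measured impedance spectrum. Real and imaginary residuals are
# stacked and modulus-weighted (divided by |Z_data| per point) so that low-
# and high-impedance regions of a sweep spanning decades contribute evenly.

#' Default box bounds for CNLS fitting
#'
#' Brackets physiological transmembrane-device values with wide margins:
#' r1 in \[0.1, 1e4\] Ohm, rb in \[0, 1e4\] Ohm, cp in \[1e-9, 1e-2\] F,
#' q in \[1e-7, 10\] S.s^alpha, alpha in \[0.3, 1\].
#'
#' @return A list with numeric vectors `lower` and `upper`, named by
#'   parameter.
#' @export
default_fit_bounds <- function() {
  list(
    lower = c(r1 = 0.1, rb = 0,    cp = 1e-9, q = 1e-7, alpha = 0.3),
    upper = c(r1 = 1e4, rb = 1e4,  cp = 1e-2, q = 10,   alpha = 1)
  )
}

param_vec <- function(params) {
  unlist(params[c("r1", "rb", "cp", "q", "alpha")])
}

params_from_vec <- function(p) {
  circuit_params(r1 = p[["r1"]], rb = p[["rb"]], cp = max(p[["cp"]], 1e-300),
                 q = p[["q"]], alpha = p[["alpha"]])
}

clip_to_bounds <- function(p, bounds) {
  pmin(pmax(p, bounds$lower), bounds$upper)
}

#' Heuristic starting values for a CNLS fit
#'
#' Reads starting values off the spectrum itself: `r1` from |Z| at the
#' highest frequency (where both reactive branches vanish), `rb` from the
#' mid-frequency resistive plateau (|Z| at the grid point nearest 10 Hz,
#' minus `r1`, floored at 1 Ohm), `alpha = 0.8`, `q` from the low-frequency
#' CPE-dominated point (|Z| at the lowest frequency), and a generic
#' `cp = 1e-6` F. All values are clipped into the fitting bounds, so the
#' initialiser always returns a feasible vector.
#'
#' @param spectrum A tidy spectrum (see [simulate_spectrum()]).
#' @param bounds Box bounds as from [default_fit_bounds()].
#' @return A [circuit_params()] object.
#' @export
initialize_params <- function(spectrum, bounds = default_fit_bounds()) {
  validate_spectrum(spectrum)
  f <- spectrum$frequency_hz
  zmag <- Mod(spectrum_z(spectrum))
  r1 <- zmag[which.max(f)]
  i_plateau <- which.min(abs(log10(f) - log10(10)))
  rb <- max(zmag[i_plateau] - r1, 1)
  alpha <- 0.8
  i_low <- which.min(f)
  q <- 1 / (zmag[i_low] * (2 * pi * f[i_low])^alpha)
  p <- clip_to_bounds(
    c(r1 = r1, rb = rb, cp = 1e-6, q = q, alpha = alpha), bounds
  )
  params_from_vec(p)
}

cnls_residuals <- function(p, z_data, f) {
  z_model <- impedance(params_from_vec(p), f)
  w <- Mod(z_data)
  c(Re(z_model - z_data) / w, Im(z_model - z_data) / w)
}

# Forward-difference Jacobian of the stacked weighted residual vector,
# used only for standard errors at the optimum.
numeric_jacobian <- function(p, z_data, f, rel_step = 1e-6) {
  r0 <- cnls_residuals(p, z_data, f)
  J <- matrix(0, nrow = length(r0), ncol = length(p),
              dimnames = list(NULL, names(p)))
  for (k in seq_along(p)) {
    h <- max(abs(p[k]) * rel_step, 1e-12)
    pk <- p
    pk[k] <- pk[k] + h
    J[, k] <- (cnls_residuals(pk, z_data, f) - r0) / h
  }
  J
}

#' Fit the equivalent circuit to an impedance spectrum (CNLS)
#'
#' Estimates all five circuit parameters by complex non-linear least
#' squares: real and imaginary residuals are stacked and divided by the
#' per-point impedance modulus, and the weighted sum of squares is minimised
#' by bounded Levenberg--Marquardt ([minpack.lm::nls.lm()]) from the
#' heuristic initialiser (or a user-supplied start). On non-convergence an
#' optional seeded multistart perturbs the start log-normally and keeps the
#' best of the restarts; failures are reported in the result, never
#' silently.
#'
#' A spectrum must have at least 10 points spanning at least two decades of
#' frequency; below that the five-parameter model is not identifiable and
#' the fit is refused.
#'
#' @param spectrum A tidy spectrum for a single device/day.
#' @param init Optional [circuit_params()] starting values; default is
#'   [initialize_params()].
#' @param bounds Box bounds, default [default_fit_bounds()].
#' @param max_iter Maximum optimiser iterations (default 500).
#' @param ftol Relative cost-reduction convergence tolerance (default 1e-10).
#' @param multistart Number of additional randomised starts attempted if the
#'   first fit does not converge (default 5; 0 disables).
#' @param seed Seed for the multistart perturbations.
#'
#' @return An object of class `eis_fit`: fitted `params`, standard errors
#'   `se` (from the Jacobian at the optimum), `residual_norm` (weighted sum
#'   of squared residuals), `converged`, `n_iter`, the weighting label, a
#'   `barrier_absent` flag (rb pinned at the zero bound), and the data.
#'   Use [generics::tidy()] / [generics::glance()] for tibble summaries.
#' @export
fit_spectrum <- function(spectrum, init = NULL, bounds = default_fit_bounds(),
                         max_iter = 500, ftol = 1e-10,
                         multistart = 5, seed = 1L) {
  validate_spectrum(spectrum)
  f <- spectrum$frequency_hz
  if (length(f) < 10) {
    stop("spectrum has fewer than 10 points; circuit not identifiable",
         call. = FALSE)
  }
  if (log10(max(f) / min(f)) < 2) {
    stop("spectrum spans fewer than 2 decades; circuit not identifiable",
         call. = FALSE)
  }
  z_data <- spectrum_z(spectrum)
  if (is.null(init)) init <- initialize_params(spectrum, bounds)
  p0 <- clip_to_bounds(param_vec(init), bounds)

  run_lm <- function(start) {
    minpack.lm::nls.lm(
      par = start, lower = bounds$lower, upper = bounds$upper,
      fn = cnls_residuals, z_data = z_data, f = f,
      control = minpack.lm::nls.lm.control(
        ftol = ftol, ptol = 1e-12, maxiter = max_iter
      )
    )
  }
  lm_converged <- function(fit) fit$info %in% 1:4

  fit <- run_lm(p0)
  n_iter <- fit$niter
  if (!lm_converged(fit) && multistart > 0) {
    restarts <- withr::with_seed(seed, {
      lapply(seq_len(multistart), function(i) {
        jitter <- exp(stats::rnorm(length(p0), sd = 0.3))
        clip_to_bounds(p0 * jitter, bounds)
      })
    })
    for (start in restarts) {
      cand <- run_lm(start)
      n_iter <- n_iter + cand$niter
      better <- cand$deviance < fit$deviance
      if ((lm_converged(cand) && !lm_converged(fit)) ||
          (lm_converged(cand) == lm_converged(fit) && better)) {
        fit <- cand
      }
      if (lm_converged(fit)) break
    }
  }

  p_hat <- fit$par
  se <- rep(NA_real_, 5)
  names(se) <- names(p_hat)
  dof <- 2 * length(f) - length(p_hat)
  if (dof > 0) {
    J <- numeric_jacobian(p_hat, z_data, f)
    sigma2 <- fit$deviance / dof
    vc <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  }

  params <- params_from_vec(p_hat)
  z_fit <- impedance(params, f)
  structure(
    list(
      params = params,
      se = se,
      residual_norm = fit$deviance,
      converged = lm_converged(fit),
      n_iter = n_iter,
      weighting = "modulus",
      barrier_absent = p_hat[["rb"]] < 1e-3,
      message = fit$message,
      data = spectrum,
      fitted = tibble::tibble(
        frequency_hz = f, z_real_ohm = Re(z_fit), z_imag_ohm = Im(z_fit)
      )
    ),
    class = "eis_fit"
  )
}

#' @export
print.eis_fit <- function(x, ...) {
  cat("<eis_fit> CNLS fit,", x$weighting, "weighting\n")
  cat(sprintf("  converged: %s after %d iterations; weighted SSR = %.4g\n",
              x$converged, x$n_iter, x$residual_norm))
  est <- param_vec(x$params)
  for (nm in names(est)) {
    cat(sprintf("  %-5s = %.6g (se %.3g)\n", nm, est[[nm]], x$se[[nm]]))
  }
  if (isTRUE(x$barrier_absent)) cat("  note: rb at zero bound (barrier absent)\n")
  invisible(x)
}

#' Tidy a CNLS fit into a parameter table
#'
#' @param x An `eis_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per circuit parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy eis_fit
#' @export
tidy.eis_fit <- function(x, ...) {
  est <- param_vec(x$params)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$se[names(est)])
  )
}

#' One-row summary of a CNLS fit
#'
#' @param x An `eis_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `residual_norm`, `converged`, `n_iter`,
#'   `n_points`, `barrier_absent`, `weighting`.
#' @method glance eis_fit
#' @export
glance.eis_fit <- function(x, ...) {
  tibble::tibble(
    residual_norm = x$residual_norm,
    converged = x$converged,
    n_iter = x$n_iter,
    n_points = nrow(x$data),
    barrier_absent = x$barrier_absent,
    weighting = x$weighting
  )
}

#' Fit every spectrum of a cohort
#'
#' Splits a long spectrum table by `(device_id, day)` in order of first
#' appearance, fits each sweep with [fit_spectrum()], and returns one row
#' per sweep. A sweep whose fit is refused (for example too few points) is
#' reported in its row's `error` column with `NA` estimates; one bad device
#' never aborts the batch.
#'
#' @param spectra Long tidy table with columns `device_id`, `day`,
#'   `frequency_hz`, `z_real_ohm`, `z_imag_ohm`.
#' @param ... Passed on to [fit_spectrum()].
#' @return A tibble with columns `device_id`, `day`, `r1_ohm`, `rb_ohm`,
#'   `cp_farad`, `q_cpe`, `alpha`, `residual_norm`, `converged`,
#'   `barrier_absent`, `error`.
#' @export
fit_eis_cohort <- function(spectra, ...) {
  empty <- tibble::tibble(
    device_id = character(), day = integer(),
    r1_ohm = double(), rb_ohm = double(), cp_farad = double(),
    q_cpe = double(), alpha = double(), residual_norm = double(),
    converged = logical(), barrier_absent = logical(), error = character()
  )
  if (is.null(spectra) || nrow(spectra) == 0) return(empty)
  if (!all(c("device_id", "day") %in% names(spectra))) {
    stop("cohort spectra need `device_id` and `day` columns", call. = FALSE)
  }
  key <- paste(spectra$device_id, spectra$day, sep = "\r")
  groups <- split(seq_len(nrow(spectra)), factor(key, levels = unique(key)))
  rows <- purrr::map(groups, function(idx) {
    sp <- spectra[idx, , drop = FALSE]
    res <- tryCatch(fit_spectrum(sp, ...), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(
        device_id = sp$device_id[[1]], day = as.integer(sp$day[[1]]),
        r1_ohm = NA_real_, rb_ohm = NA_real_, cp_farad = NA_real_,
        q_cpe = NA_real_, alpha = NA_real_, residual_norm = NA_real_,
        converged = FALSE, barrier_absent = NA,
        error = conditionMessage(res)
      )
    } else {
      p <- param_vec(res$params)
      tibble::tibble(
        device_id = sp$device_id[[1]], day = as.integer(sp$day[[1]]),
        r1_ohm = p[["r1"]], rb_ohm = p[["rb"]], cp_farad = p[["cp"]],
        q_cpe = p[["q"]], alpha = p[["alpha"]],
        residual_norm = res$residual_norm, converged = res$converged,
        barrier_absent = res$barrier_absent, error = NA_character_
      )
    }
  })
  dplyr::bind_rows(rows)
}
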