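# Forward model of the e-transmembrane device impedance.
#
# Topology (single supported wiring): the electrolyte series resistance R1,
# in series with the epithelial barrier modelled as a parallel RC (Rb || Cp),
# in series with a constant phase element (CPE) representing the conducting
# scaffold / device:
#
#   Z(w) = R1 + Rb / (1 + j w Rb Cp) + 1 / (Q (j w)^alpha),   w = 2 pi f

#' Equivalent-circuit parameters for the barrier device model
#'
#' Bundles the five parameters of the series R1 -- (Rb || Cp) -- CPE circuit
#' used to model a scaffold-based transmembrane barrier device: the
#' electrolyte resistance `r1`, the epithelial barrier resistance `rb` and
#' capacitance `cp`, and the constant-phase-element magnitude `q` and
#' exponent `alpha` describing the porous scaffold electrode.
#'
#' @param r1 Electrolyte series resistance, Ohm (>= 0).
#' @param rb Barrier resistance, Ohm (>= 0; 0 means no epithelial barrier).
#' @param cp Barrier capacitance, Farad (> 0).
#' @param q CPE magnitude, S.s^alpha (> 0).
#' @param alpha CPE exponent, dimensionless, in (0, 1]; `alpha = 1` reduces
#'   the CPE to an ideal capacitor of value `q`.
#'
#' @return An object of class `circuit_params` (a named list).
#' @examples
#' p <- circuit_params(r1 = 60, rb = 25, cp = 5e-6, q = 2e-3, alpha = 0.85)
#' impedance(p, f = 100)
#' @export
circuit_params <- function(r1, rb, cp, q, alpha) {
  for (nm in c("r1", "rb", "cp", "q", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (r1 < 0) stop("`r1` must be >= 0", call. = FALSE)
  if (rb < 0) stop("`rb` must be >= 0", call. = FALSE)
  if (cp <= 0) stop("`cp` must be > 0", call. = FALSE)
  if (q <= 0) stop("`q` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  structure(
    list(r1 = r1, rb = rb, cp = cp, q = q, alpha = alpha),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>  R1 -- (Rb || Cp) -- CPE\n")
  cat(sprintf("  r1    = %.6g Ohm (electrolyte)\n", x$r1))
  cat(sprintf("  rb    = %.6g Ohm (barrier)\n", x$rb))
  cat(sprintf("  cp    = %.6g F   (barrier)\n", x$cp))
  cat(sprintf("  q     = %.6g S.s^alpha (CPE)\n", x$q))
  cat(sprintf("  alpha = %.6g (CPE exponent)\n", x$alpha))
  invisible(x)
}

#' Complex impedance of the barrier-device equivalent circuit
#'
#' Evaluates the series R1 -- (Rb || Cp) -- CPE model at one or more
#' frequencies. The CPE follows the dominant impedance-literature convention
#' `Z_CPE = 1 / (Q (j w)^alpha)` with `(j)^alpha = exp(j alpha pi / 2)`, so
#' the imaginary part is never positive (capacitive sign convention) and
#' `Z -> r1` as `f -> Inf`.
#'
#' @param params A [circuit_params()] object.
#' @param f Frequency in Hz; strictly positive, vectorised.
#'
#' @return A complex vector of impedances in Ohm, same length as `f`.
#' @export
impedance <- function(params, f) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(f) || length(f) < 1L || any(!is.finite(f)) || any(f <= 0)) {
    stop("`f` must contain finite, strictly positive frequencies (Hz)",
         call. = FALSE)
  }
  w <- 2 * pi * f
  z_barrier <- if (params$rb == 0) 0 + 0i else {
    params$rb / (1 + 1i * w * params$rb * params$cp)
  }
  # (j w)^alpha = w^alpha * exp(j alpha pi / 2)
  z_cpe <- exp(-1i * params$alpha * pi / 2) / (params$q * w^params$alpha)
  params$r1 + z_barrier + z_cpe
}

#' Logarithmic frequency grid for an impedance sweep
#'
#' Builds the descending log-spaced frequency grid of a potentiostat sweep.
#' Points sit at exact 1/`points_per_decade`-decade steps down from `f_max`;
#' `f_min` is always included as the final point. The default sweep
#' (10^5 Hz down to 0.1 Hz at 10 points per decade) has 61 points and
#' contains 100 Hz exactly.
#'
#' @param f_max Highest frequency, Hz.
#' @param f_min Lowest frequency, Hz. Must satisfy `f_max >= f_min > 0`.
#' @param points_per_decade Points per factor-of-10 span (>= 1).
#'
#' @return Numeric vector of frequencies in Hz, strictly descending.
#' @examples
#' f <- make_frequency_grid()
#' length(f)        # 61
#' 100 %in% f       # TRUE
#' @export
make_frequency_grid <- function(f_max = 1e5, f_min = 0.1,
                                points_per_decade = 10) {
  if (!is.numeric(f_max) || !is.numeric(f_min) || f_min <= 0 || f_max < f_min) {
    stop("need `f_max` >= `f_min` > 0", call. = FALSE)
  }
  if (!is.numeric(points_per_decade) || points_per_decade < 1) {
    stop("`points_per_decade` must be >= 1", call. = FALSE)
  }
  if (f_max == f_min) return(f_max)
  span <- log10(f_max) - log10(f_min)
  n_steps <- floor(span * points_per_decade + 1e-9)
  f <- 10^(log10(f_max) - seq(0, n_steps) / points_per_decade)
  if (f[length(f)] > f_min * (1 + 1e-12)) f <- c(f, f_min)
  f[length(f)] <- f_min  # exact endpoint
  f
}

#' Simulate a noiseless impedance spectrum from circuit parameters
#'
#' Vectorises [impedance()] over a frequency grid and returns the spectrum
#' in the package's tidy layout: one row per frequency with real and
#' imaginary impedance components in Ohm. Model-generated spectra always
#' satisfy `z_imag_ohm <= 0` (capacitive convention).
#'
#' @param params A [circuit_params()] object.
#' @param frequencies Frequencies in Hz, typically from
#'   [make_frequency_grid()].
#' @param device_id,day Identifier and integer culture day stamped on each
#'   row (the day is on the co-culture clock; see [coculture_to_total_day()]).
#' @param bias_v,ac_amplitude_v Acquisition metadata recorded with the sweep;
#'   the small-signal model itself is linear and does not use them.
#'
#' @return A tibble with columns `device_id`, `day`, `frequency_hz`,
#'   `z_real_ohm`, `z_imag_ohm`.
#' @export
simulate_spectrum <- function(params, frequencies = make_frequency_grid(),
                              device_id = "device-1", day = 0L,
                              bias_v = 0.1, ac_amplitude_v = 0.01) {
  z <- impedance(params, frequencies)
  out <- tibble::tibble(
    device_id = device_id,
    day = as.integer(day),
    frequency_hz = frequencies,
    z_real_ohm = Re(z),
    z_imag_ohm = Im(z)
  )
  attr(out, "bias_v") <- bias_v
  attr(out, "ac_amplitude_v") <- ac_amplitude_v
  out
}

#' Validate a tidy impedance-spectrum table
#'
#' Checks the column contract (`frequency_hz`, `z_real_ohm`, `z_imag_ohm`,
#' optionally `device_id`, `day`), positivity and finiteness of frequencies,
#' and finiteness of the impedance components.
#'
#' @param spectrum A spectrum tibble as produced by [simulate_spectrum()] or
#'   [read_spectra()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_spectrum <- function(spectrum) {
  req <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  missing_cols <- setdiff(req, names(spectrum))
  if (length(missing_cols)) {
    stop("spectrum is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  f <- spectrum$frequency_hz
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("spectrum frequencies must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(spectrum$z_real_ohm)) ||
      any(!is.finite(spectrum$z_imag_ohm))) {
    stop("spectrum impedance values must be finite", call. = FALSE)
  }
  invisible(spectrum)
}

#' Complex impedance column of a tidy spectrum
#'
#' @param spectrum A validated spectrum tibble.
#' @return Complex vector `z_real_ohm + 1i * z_imag_ohm`.
#' @export
spectrum_z <- function(spectrum) {
  validate_spectrum(spectrum)
  complex(real = spectrum$z_real_ohm, imaginary = spectrum$z_imag_ohm)
}

#' Convert between co-culture and total-culture day clocks
#'
#' Fibroblasts populate the scaffold for several days before the epithelial
#' cells are seeded; day 0 of the co-culture clock corresponds to total
#' culture day 6. Trajectory APIs in this package use the co-culture clock.
#'
#' @param day Integer day(s).
#' @param offset Days of fibroblast pre-culture (default 6).
#' @return Converted day(s).
#' @export
coculture_to_total_day <- function(day, offset = 6L) day + offset

#' @rdname coculture_to_total_day
#' @export
total_to_coculture_day <- function(day, offset = 6L) day - offset
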