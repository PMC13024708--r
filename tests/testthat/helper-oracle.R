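# Independent oracle for the forward model: evaluates the same circuit by a
# different algebraic route (admittance form for the parallel branch,
# direct complex exponentiation for the CPE) so agreement is a genuine
# cross-check, not a tautology.
z_oracle <- function(r1, rb, cp, q, alpha, f) {
  w <- 2 * pi * f
  zb <- if (rb == 0) 0 + 0i else 1 / (1 / rb + (1i * w) * cp)
  r1 + zb + 1 / (q * (1i * w)^alpha)
}

# Reference parameter set used across fitting tests.
ref_params <- function() circuit_params(r1 = 60, rb = 25, cp = 5e-6,
                                        q = 2e-3, alpha = 0.85)

# Proportional complex Gaussian noise, sd = noise_rel * |Z| per component.
add_prop_noise <- function(spectrum, noise_rel, seed) {
  withr::with_seed(seed, {
    zm <- Mod(complex(real = spectrum$z_real_ohm,
                      imaginary = spectrum$z_imag_ohm))
    spectrum$z_real_ohm <- spectrum$z_real_ohm +
      rnorm(nrow(spectrum), sd = noise_rel * zm)
    spectrum$z_imag_ohm <- spectrum$z_imag_ohm +
      rnorm(nrow(spectrum), sd = noise_rel * zm)
    spectrum
  })
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
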