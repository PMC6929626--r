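# Small phantom used across tests: coarse grid, few islets, noise-free by
# default so analytic recoveries are exact.
small_spec <- function(grid_shape = c(32, 32, 32), islet_count = 10,
                       noise_sigma_mr = 0, noise_sigma_pet = 0,
                       noise_sigma_section = 0, rng_seed = 11L, ...) {
  phantom_spec(grid_shape = grid_shape, islet_count = islet_count,
               pancreas_semiaxes_mm = c(3.6, 3.2, 3.0),
               insulinoma = list(center_mm = NULL, diameter_mm = 2),
               noise_sigma_mr = noise_sigma_mr,
               noise_sigma_pet = noise_sigma_pet,
               noise_sigma_section = noise_sigma_section,
               rng_seed = rng_seed, ...)
}

default_acq2 <- acquisition_params(flip_deg = c(4, 22))
default_acq3 <- acquisition_params(flip_deg = c(4, 14, 27))
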