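# Shared fixture builders: everything is generated in code at test time.

gaussian_spectrum <- function(center, sigma, amp = 1,
                              grid = seq(center - 5 * sigma,
                                         center + 5 * sigma, by = 1),
                              kind = "fluorescence") {
  spectrum(grid, amp * exp(-(grid - center)^2 / (2 * sigma^2)), kind = kind)
}

single_site_config <- function(ka, fa, temperature = 290, noise_sd = 0,
                               seed = 1L, ...) {
  synthetic_config(sites = tibble::tibble(ka = ka, fa = fa),
                   temperatures = temperature, ref_temperature = temperature,
                   noise_sd = noise_sd, seed = seed, ...)
}

single_site_series <- function(ka, fa, temperature = 290, noise_sd = 0,
                               seed = 1L, ...) {
  cfg <- single_site_config(ka, fa, temperature, noise_sd, seed, ...)
  generate_titration(cfg)[[1]]
}

hill_series <- function(kb, n, temperature = 310, noise_sd = 0, seed = 1L) {
  cfg <- synthetic_config(model = "hill", hill_kb = kb, hill_n = n,
                          temperatures = temperature,
                          ref_temperature = temperature,
                          noise_sd = noise_sd, seed = seed)
  generate_titration(cfg)[[1]]
}

# reference binding constants (M^-1) used across tests
ksv_ref <- c(`290` = 6.373e4, `300` = 5.415e4, `310` = 4.566e4)
kb_ref_by_t <- tibble::tibble(temperature = c(290, 300, 310),
                            k = c(0.5506, 1.3590, 1.7459) * 1e4)
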