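# Small shared fixtures for fast unit tests.

small_grid <- function() grid_config(width = 16, height = 16,
                                     vessel_spacing = 4)

# a noiseless, oscillation-free generator configuration
clean_synth_config <- function(group = "CTRL", cv = 0) {
  synth_config(group = group, subject_cv = cv, fs = 8,
               baseline_duration = 60, occlusion_duration = 120,
               post_duration = 300, noise_sd = 0,
               flowmotion = list(), biological_zero = 0)
}

# random valid circuit with a dominant shunt resistance
random_circuit <- function() {
  r123 <- exp(stats::runif(3, log(0.05), log(30)))
  suppressWarnings(circuit_params(
    r1 = r123[1], r2 = r123[2], r3 = r123[3],
    r4 = stats::runif(1, 150, 400),
    c1 = exp(stats::runif(1, log(1), log(150))),
    c2 = exp(stats::runif(1, log(1), log(150))),
    v0 = stats::runif(1, 40, 120)))
}
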