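# Shared fixture builders: everything is generated in code at test time.

# Noise-free uniform-attenuation pair.
clean_pair <- function(h = 64, w = 64, mu = 2, L = 1.5, illum = 200,
                       vignette = 0, seed = 1, sample_id = "fix",
                       condition = "synthetic") {
  generate_transmittance_pair(
    transmittance_phantom_spec(h, w, mu = mu, thickness_mm = L,
                               illumination = illum, vignette = vignette,
                               seed = seed),
    sample_id = sample_id, condition = condition)
}

# Noisy pair at the standard read-noise level (sd = 2% of illumination).
noisy_pair <- function(h = 256, w = 256, mu = 2, L = 1, illum = 200,
                       vignette = 0.15, seed = 1, sample_id = "fix",
                       condition = "synthetic") {
  generate_transmittance_pair(
    transmittance_phantom_spec(h, w, mu = mu, thickness_mm = L,
                               illumination = illum, vignette = vignette,
                               noise = noise_gaussian(0.02 * illum),
                               seed = seed),
    sample_id = sample_id, condition = condition)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
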