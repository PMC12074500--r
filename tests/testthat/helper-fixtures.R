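# Shared fixtures: everything is generated in code at test time.

# instrument-default optics on a small square frame for speed
cfg_small <- function(n = 128L) {
  optics_preset("ts2r-20x", sensor_shape = c(n, n))
}

# single microsphere centred in the field of view (the reference scene of
# the characterization experiments: 10 um PMMA sphere in glycerin-water)
sphere_phantom <- function(config, radius = 5, ri = 1.48, medium_ri = 1.43,
                           transmittance = 1) {
  fov <- field_of_view(config)
  add_sphere(phantom(medium_ri), x = fov[["width"]] / 2,
             y = fov[["height"]] / 2, radius = radius, ri = ri,
             transmittance = transmittance)
}

# noise-free multiplexed capture of an empty scene
flat_capture <- function(config, p_laser = 0.4, p_led = 30,
                         quantize = TRUE) {
  synthesize_multiplexed(phantom(), config,
                         illumination_setting(p_laser, p_led),
                         noise_off(), quantize = quantize)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
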