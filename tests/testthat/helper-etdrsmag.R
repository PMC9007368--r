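# Shared fixtures: small geometries and cohorts built in code.

# default-scale Spectralis raster, moderate column count for speed
test_geometry <- function(n_ascans = 256L, ...) {
  spectralis_geometry(n_ascans = n_ascans, ...)
}

test_eye <- function(al = 23.6, eye = "OD", id = "P1", snr = 30, ...) {
  eye_biometry(id, eye, axial_length = al, sphere = -1, cylinder = -0.5,
               snr = snr, ...)
}

# a cohort spec small enough for unit tests
test_spec <- function(n = 30, seed = 42L, ...) {
  cohort_spec(n, seed = seed, ...)
}

expect_all_lt <- function(x, bound) {
  expect_true(all(abs(x) < bound),
              label = sprintf("max |x| = %.4g < %.4g", max(abs(x)), bound))
}
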