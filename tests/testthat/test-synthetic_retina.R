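# Ground-truth pit model, the magnification-aware scanner, and cohorts.

test_that("pit thickness has the closed form at the origin and is symmetric", {
  m <- pit_model()
  expect_equal(pit_thickness(m, 0, 0),
               m$t_periphery + m$a_para * exp(-m$r_peak^2 / (2 * m$sigma_para^2)) -
                 m$a_pit)
  # point symmetry for the radially symmetric default
  set.seed(3)
  x <- runif(50, -3, 3)
  y <- runif(50, -3, 3)
  expect_equal(pit_thickness(m, x, y), pit_thickness(m, -x, -y))
  # nasal asymmetry breaks it in the expected direction
  ma <- pit_model(nasal_asymmetry = 1.2)
  expect_gt(pit_thickness(ma, 1, 0), pit_thickness(ma, -1, 0))
})

test_that("default surface is pit-shaped: global minimum at the fovea", {
  m <- pit_model()
  # brute-force grid search over the macular field
  xy <- expand.grid(x = seq(-3.5, 3.5, by = 0.05), y = seq(-3.5, 3.5, by = 0.05))
  tt <- pit_thickness(m, xy$x, xy$y)
  expect_true(all(tt > 0))
  k <- which.min(tt)
  expect_equal(abs(xy$x[k]), 0, tolerance = 1e-8)
  expect_equal(abs(xy$y[k]), 0, tolerance = 1e-8)
  # local maximum near r_peak
  r <- seq(0, 3.5, by = 0.01)
  tr <- pit_thickness(m, r, 0)
  expect_equal(r[which.max(tr)], m$r_peak, tolerance = 0.15)
  # degenerate shapes are refused
  expect_error(pit_model(a_pit = 0.1, a_para = 200, sigma_para = 3), "minimum")
  expect_error(pit_model(r_peak = 0.3), "r_peak")
})

test_that("simulated scans sample true positions but stamp default scales", {
  m <- pit_model()
  g <- test_geometry()
  # AL = assumed, no noise: samples equal the surface at nominal positions
  b0 <- test_eye(al = 24.385)
  sc0 <- simulate_scan(m, g, b0, noise_sd = 0)
  cx <- (g$n_ascans + 1) / 2
  cy <- (g$n_bscans + 1) / 2
  x <- (seq_len(g$n_ascans) - cx) * g$scale_x_default
  y <- (cy - seq_len(g$n_bscans)) * g$scale_y_default
  expected <- outer(y, x, function(Y, X) pit_thickness(m, X, Y))
  expect_equal(sc0$thickness, expected)

  # constant-thickness surface: every sample equals the baseline at any AL
  mc <- pit_model(a_para = 0, a_pit = 0)
  scc <- simulate_scan(mc, g, test_eye(al = 26.5), noise_sd = 0)
  expect_true(all(scc$thickness == mc$t_periphery))

  # field of view scales with axial length: the outermost sampled true
  # radius differs by the factor 26/22, visible in the edge-sample values
  s22 <- simulate_scan(m, g, test_eye(al = 22), noise_sd = 0)
  s26 <- simulate_scan(m, g, test_eye(al = 26), noise_sd = 0)
  r22 <- 22 / g$assumed_axial_length * (g$n_ascans - cx) * g$scale_x_default
  r26 <- r22 * 26 / 22
  expect_equal(s22$thickness[16, g$n_ascans], pit_thickness(m, r22, 0))
  expect_equal(s26$thickness[16, g$n_ascans], pit_thickness(m, r26, 0))
})

test_that("scan noise is reproducible per seed and leaves the caller's RNG alone", {
  m <- pit_model()
  g <- test_geometry(n_ascans = 64L)
  b <- test_eye()
  s1 <- simulate_scan(m, g, b, noise_sd = 3, seed = 99)
  set.seed(1234)
  before <- .Random.seed
  s2 <- simulate_scan(m, g, b, noise_sd = 3, seed = 99)
  expect_identical(before, .Random.seed)
  expect_identical(s1$thickness, s2$thickness)
  s3 <- simulate_scan(m, g, b, noise_sd = 3, seed = 100)
  expect_false(identical(s1$thickness, s3$thickness))
})

test_that("cohort draws are deterministic and respect degenerate settings", {
  sp <- test_spec(n = 5)
  c1 <- simulate_cohort(sp, geometry = test_geometry(n_ascans = 64L))
  c2 <- simulate_cohort(sp, geometry = test_geometry(n_ascans = 64L))
  expect_identical(c1$biometry, c2$biometry)
  expect_identical(c1$maps[[3]]$thickness, c2$maps[[3]]$thickness)
  expect_equal(nrow(c1$biometry), 10) # two eyes per participant

  sp0 <- test_spec(n = 4, al_sd = 0, interocular_al_correlation = 1)
  b0 <- simulate_cohort(sp0, keep_maps = FALSE)$biometry
  expect_true(all(b0$axial_length_mm == 23.6))
})

test_that("axial lengths are correlated between eyes and myope fraction hits target", {
  sp <- test_spec(n = 1500, seed = 202)
  bio <- simulate_cohort(sp, keep_maps = FALSE)$biometry
  od <- bio[bio$eye == "OD", ]
  os <- bio[bio$eye == "OS", ]
  expect_equal(stats::cor(od$axial_length_mm, os$axial_length_mm), 0.95,
               tolerance = 0.03)
  expect_equal(mean(od$axial_length_mm), 23.6, tolerance = 0.1)
  expect_equal(stats::sd(od$axial_length_mm), 0.9, tolerance = 0.07)
  grp <- classify_refractive_group(
    spherical_equivalent(bio$sphere_d, bio$cylinder_d))
  # realized myope fraction within 5 percentage points of the 23% target
  expect_lt(abs(mean(grp == "myope") - 0.23), 0.05)
  # myopes are the longer eyes under the emmetropization-failure map
  expect_gt(mean(bio$axial_length_mm[grp == "myope"]),
            mean(bio$axial_length_mm[grp == "non-myope"]) + 0.8)
})
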