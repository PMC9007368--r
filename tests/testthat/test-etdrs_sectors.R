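# ETDRS grid construction, sector averaging, and the raw/corrected pair.

test_that("corrected grid equals raw grid exactly at the assumed axial length", {
  g <- test_geometry()
  b <- test_eye(al = 24.385)
  ctr <- c(16, (g$n_ascans + 1) / 2)
  raw <- build_grid(g, b, ctr, corrected = FALSE)
  cor <- build_grid(g, b, ctr, corrected = TRUE)
  expect_identical(raw$labels, cor$labels)
  expect_identical(raw$codes, cor$codes)
  expect_identical(raw$scale_x, cor$scale_x)
})

test_that("short eyes get larger pixel radii under correction", {
  g <- test_geometry()
  b <- test_eye(al = 21.8)
  ctr <- c(16, (g$n_ascans + 1) / 2)
  raw <- build_grid(g, b, ctr, corrected = FALSE)
  cor <- build_grid(g, b, ctr, corrected = TRUE)
  # mm-per-pixel shrinks by AL/assumed, so each ring's pixel radius grows
  expect_equal(cor$scale_x / raw$scale_x, 21.8 / 24.385)
  # the central disc in pixels along the centre row: count columns labelled C
  n_raw <- sum(raw$labels[16, ] == "C")
  n_cor <- sum(cor$labels[16, ] == "C")
  expect_equal(n_cor / n_raw, 24.385 / 21.8, tolerance = 0.05)
  expect_gt(sum(cor$codes > 0), sum(raw$codes > 0))
})

test_that("grid masks match a brute-force point-in-region classification", {
  g <- spectralis_geometry(n_ascans = 512L)
  b <- test_eye(al = 23.1)
  ctr <- c(16, 256.5)
  for (corr in c(FALSE, TRUE)) {
    grid <- build_grid(g, b, ctr, corrected = corr)
    sx <- if (corr) corrected_transverse_scale(g$scale_x_default, 23.1) else g$scale_x_default
    sy <- if (corr) corrected_transverse_scale(g$scale_y_default, 23.1) else g$scale_y_default
    # independent per-pixel loop: radius bins and 45-degree diagonals
    expected <- matrix("outside", g$n_bscans, g$n_ascans)
    for (i in seq_len(g$n_bscans)) {
      for (j in seq_len(g$n_ascans)) {
        dx <- (j - ctr[2]) * sx
        dy <- (ctr[1] - i) * sy
        r <- sqrt(dx^2 + dy^2)
        if (r >= 3.0) next
        if (r < 0.5) {
          expected[i, j] <- "C"
          next
        }
        ring <- if (r < 1.5) "1" else "2"
        quad <- if (abs(dx) >= abs(dy)) {
          if (dx > 0) "N" else "T" # OD: nasal right
        } else {
          if (dy > 0) "S" else "I"
        }
        expected[i, j] <- paste0(quad, ring)
      }
    }
    expect_identical(grid$labels, expected)
  }
})

test_that("sector means behave on constant and symmetric maps", {
  g <- test_geometry()
  b <- test_eye(al = 23.0)
  const <- thickness_map(matrix(300, g$n_bscans, g$n_ascans), g, b)
  ee <- extract_eye(const, b, g)
  expect_true(all(ee$mean_um == 300)) # raw and corrected alike
  expect_true(all(ee$n_pixels > 0))

  # radially symmetric pit, no noise: opposite sectors agree within the
  # sampling tolerance of the anisotropic grid
  sc <- simulate_scan(pit_model(), g, b, noise_sd = 0)
  es <- extract_eye(sc)
  for (corr in c(FALSE, TRUE)) {
    v <- es$mean_um[es$corrected == corr]
    names(v) <- as.character(es$sector[es$corrected == corr])
    expect_equal(unname(v["N1"]), unname(v["T1"]), tolerance = 1e-8)
    expect_equal(unname(v["S1"]), unname(v["I1"]), tolerance = 1e-8)
    expect_equal(unname(v["N2"]), unname(v["T2"]), tolerance = 1e-8)
    expect_equal(unname(v["S2"]), unname(v["I2"]), tolerance = 1e-8)
    # horizontal vs vertical pairs differ only by sampling anisotropy
    expect_equal(unname(v["N1"]), unname(v["S1"]), tolerance = 0.005)
  }
})

test_that("corrected sector means agree with continuous quadrature on a dense grid", {
  # dense, near-isotropic resampling so that pixel averaging approximates
  # the continuous integral
  g <- scan_geometry(n_bscans = 361L, n_ascans = 361L,
                     scale_x_default = 7 / 360, scale_y_default = 7 / 360)
  m <- pit_model()
  al <- 23.0
  b <- test_eye(al = al)
  sc <- simulate_scan(m, g, b, noise_sd = 0)
  ee <- extract_eye(sc)
  for (corr in c(TRUE, FALSE)) {
    got <- ee$mean_um[ee$corrected == corr]
    want <- sector_truth(m, al, corrected = corr)
    expect_all_lt(got - want, 0.5)
  }
})

test_that("mirroring the map and toggling laterality preserves sector means", {
  m <- pit_model(nasal_asymmetry = 1.15) # nasally thicker retina
  g <- test_geometry()
  al <- 23.2
  od <- simulate_scan(m, g, test_eye(al = al, eye = "OD"), noise_sd = 0)
  os <- simulate_scan(m, g, test_eye(al = al, eye = "OS"), noise_sd = 0)
  # the OS scan of the same retina is the left-right mirror of the OD scan
  expect_equal(os$thickness, od$thickness[, rev(seq_len(g$n_ascans))])
  e_od <- extract_eye(od)
  e_os <- extract_eye(os)
  expect_equal(e_os$mean_um, e_od$mean_um, tolerance = 1e-10)
  # and the nasal sectors really are the thicker ones
  v <- e_od$mean_um[e_od$corrected]
  names(v) <- as.character(e_od$sector[e_od$corrected])
  expect_gt(v["N1"], v["T1"])
  expect_gt(v["N2"], v["T2"])
})

test_that("extract_eye pairs raw and corrected from one map and centre", {
  m <- pit_model()
  g <- test_geometry()
  # identity case
  e0 <- extract_eye(simulate_scan(m, g, test_eye(al = 24.385), noise_sd = 0))
  expect_equal(e0$mean_um[e0$corrected], e0$mean_um[!e0$corrected])
  # short eye: raw underestimates centrally, overestimates the outer ring
  e1 <- extract_eye(simulate_scan(m, g, test_eye(al = 22.5), noise_sd = 0))
  raw <- e1$mean_um[!e1$corrected]
  cor <- e1$mean_um[e1$corrected]
  names(raw) <- names(cor) <- as.character(e1$sector[!e1$corrected])
  expect_lt(raw["C"], cor["C"])
  expect_gt(raw["T2"], cor["T2"])
  expect_gt(raw["N2"], cor["N2"])
  # and the signs agree with the quadrature reference
  tr_raw <- sector_truth(m, 22.5, corrected = FALSE)
  tr_cor <- sector_truth(m, 22.5, corrected = TRUE)
  expect_lt(tr_raw["C"], tr_cor["C"])
  expect_gt(tr_raw["T2"], tr_cor["T2"])
})

test_that("empty sectors and out-of-grid centres are errors", {
  g <- test_geometry()
  b <- test_eye()
  expect_error(build_grid(g, b, c(200, 10), corrected = FALSE), "inside")
  # a map with a dead region covering the central disc
  sc <- simulate_scan(pit_model(), g, b, noise_sd = 0)
  sc$valid_mask[12:20, 108:149] <- FALSE
  ctr <- c(16, (g$n_ascans + 1) / 2)
  grid <- build_grid(g, b, ctr, corrected = FALSE)
  expect_error(sector_means(sc, grid), "C")
})
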