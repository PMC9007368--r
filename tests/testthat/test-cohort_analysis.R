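# Mixed-model stage: correction effect, axial-length interaction, group
# contrasts, Bonferroni adjustment.

# build a cohort table directly with known per-eye values
make_toy_table <- function(diff_by_eye, base = 300, al = NULL, group = NULL,
                           sector = "C") {
  n <- length(diff_by_eye)
  pid <- sprintf("P%03d", rep(seq_len(ceiling(n / 2)), each = 2)[1:n])
  eye <- rep(c("OD", "OS"), length.out = n)
  if (is.null(al)) al <- rep(23.6, n)
  se <- if (is.null(group)) rep(1, n) else ifelse(group == "myope", -2, 1)
  sector_df <- do.call(rbind, lapply(seq_len(n), function(k) {
    data.frame(participant_id = pid[k], eye = eye[k],
               corrected = c(FALSE, TRUE), sector = sector,
               mean_um = c(base, base + diff_by_eye[k]),
               n_pixels = 100L, truncation_fraction = 0)
  }))
  biometry <- data.frame(participant_id = pid, eye = eye,
                         axial_length_mm = al, sphere_d = se, cylinder_d = 0,
                         sex = rep(c("F", "M"), length.out = n),
                         ethnicity = "Caucasian")
  make_cohort_table(sector_df, biometry)
}

test_that("cohort table construction enforces the long paired layout", {
  tab <- make_toy_table(rnorm(6))
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 12)
  counts <- table(tab$participant_id, tab$eye)
  expect_true(all(counts[counts > 0] == 2)) # raw + corrected per eye/sector
  expect_equal(levels(tab$refractive_group), c("non-myope", "myope"))
})

test_that("correction effect is zero when corrected equals raw", {
  set.seed(21)
  tab <- make_toy_table(rep(0, 40))
  # add between-eye variation through the base, not the difference
  tab$thickness_um <- tab$thickness_um + rep(rnorm(40, 0, 8), each = 2)
  est <- fit_correction_effect(tab, "C")
  expect_lt(abs(est$estimate), 1e-8)
  expect_true(est$ci_lo <= 0 && est$ci_hi >= 0)
})

test_that("with no random-effect variance the estimate is the mean difference", {
  set.seed(22)
  d <- rnorm(60, 2.5, 0.6)
  tab <- make_toy_table(d)
  est <- fit_correction_effect(tab, "C")
  expect_equal(est$estimate, mean(d), tolerance = 1e-6)
  expect_equal(est$n_eyes, 60)
  expect_equal(est$n_participants, 30)
})

test_that("pooled correction estimate lies between disjoint half-cohort estimates", {
  set.seed(23)
  d1 <- rnorm(30, 1.0, 0.3)
  d2 <- rnorm(30, 3.0, 0.3)
  t1 <- make_toy_table(d1)
  t2 <- make_toy_table(d2)
  t2$participant_id <- sub("P0", "Q0", t2$participant_id)
  pooled <- rbind(t1, t2)
  class(pooled) <- class(t1)
  e1 <- fit_correction_effect(t1, "C")$estimate
  e2 <- fit_correction_effect(t2, "C")$estimate
  ep <- fit_correction_effect(pooled, "C")$estimate
  expect_true(ep > min(e1, e2) && ep < max(e1, e2))
})

test_that("group contrast recovers an injected myope thinning", {
  set.seed(24)
  n <- 120
  group <- rep(c("myope", "non-myope"), c(40, 80))
  base_eye <- 300 + rnorm(n, 0, 6) - ifelse(group == "myope", 3, 0)
  tab <- make_toy_table(rep(0, n), group = group)
  tab$thickness_um <- rep(base_eye, each = 2) + rnorm(2 * n, 0, 1)
  est <- fit_group_contrast(tab, "C", states = FALSE)
  expect_equal(est$estimate, -3, tolerance = 1.5)
  expect_true(est$ci_lo < -3 + 2 && est$ci_hi > -3 - 2)
  # identical distributions give a near-zero contrast
  tab0 <- make_toy_table(rep(0, n), group = group)
  tab0$thickness_um <- tab0$thickness_um + rnorm(2 * n, 0, 4)
  est0 <- fit_group_contrast(tab0, "C", states = FALSE)
  expect_lt(abs(est0$estimate / (est0$ci_hi - est0$ci_lo)), 1)
})

test_that("AL interaction matches the quadrature finite-difference oracle", {
  # noise-free synthetic mini-cohort through the full pipeline
  m <- pit_model()
  g <- test_geometry()
  set.seed(25)
  als <- runif(40, 22.2, 25.2)
  rows <- lapply(seq_along(als), function(k) {
    b <- eye_biometry(sprintf("P%03d", k), "OD", axial_length = als[k],
                      sphere = -1, snr = 30)
    extract_eye(simulate_scan(m, g, b, noise_sd = 0))
  })
  sector_df <- do.call(rbind, rows)
  biometry <- data.frame(participant_id = sprintf("P%03d", seq_along(als)),
                         eye = "OD", axial_length_mm = als,
                         sphere_d = -1, cylinder_d = 0,
                         sex = rep(c("F", "M"), 20), ethnicity = "Caucasian")
  tab <- make_cohort_table(sector_df, biometry)
  for (s in c("T2", "N1")) {
    est <- fit_al_interaction(tab, s)
    inter <- est$estimate[est$term == "al_x_correction"]
    oracle <- -magnification_slope_truth(m, mean(als))[s]
    # pipeline interaction sits near the oracle derivative
    expect_lt(est$ci_lo[est$term == "al_x_correction"], oracle + 0.35)
    expect_gt(est$ci_hi[est$term == "al_x_correction"], oracle - 0.35)
    expect_lt(abs(inter - oracle), 0.5)
  }
  # the outer-temporal interaction is strong and negative of the raw slope
  est_t2 <- fit_al_interaction(tab, "T2")
  expect_equal(est_t2$estimate[est_t2$term == "al_x_correction"],
               unname(-magnification_slope_truth(m, mean(als))["T2"]),
               tolerance = 0.15)
  est_c <- fit_al_interaction(tab, "C")
  expect_lt(est_c$estimate[est_c$term == "al_x_correction"], 0)
  # degenerate cohorts are refused
  tab_const <- make_toy_table(rep(0, 10))
  expect_error(fit_al_interaction(tab_const, "C"), "variance")
})

test_that("single-group cohorts skip the group family with a warning", {
  set.seed(26)
  tab <- make_toy_table(rnorm(20, 2, 0.5)) # everyone non-myopic
  expect_warning(eff <- analyze_cohort(tab, families = c("correction", "group"),
                                       sectors = "C"),
                 "refractive group")
  expect_equal(unique(eff$term), "correction")
  expect_error(suppressWarnings(analyze_cohort(tab, families = "group",
                                               sectors = "C")),
               "no effect family")
})

test_that("Bonferroni adjustment multiplies by family size and caps at one", {
  est <- data.frame(term = rep("correction", 9),
                    p_value = c(0.004, 0.2, rep(0.5, 7)),
                    p_adjusted = NA_real_)
  adj <- adjust_pvalues(est)
  expect_equal(adj$p_adjusted[1], 0.036)
  expect_equal(adj$p_adjusted[2], 1.0)
  expect_true(all(adj$p_adjusted >= adj$p_value))
  one <- adjust_pvalues(data.frame(term = "correction", p_value = 0.03,
                                   p_adjusted = NA_real_))
  expect_equal(one$p_adjusted, 0.03) # family of one is unchanged
})
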