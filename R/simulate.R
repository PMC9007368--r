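# Synthetic scans and two-eyed cohorts. The scanner model reproduces the
# transverse-magnification mechanism exactly as a real device does: the
# surface is sampled at the TRUE on-retina positions (scaled by the eye's
# axial length), but the output map is stamped with the device-default
# scales.

# run expr with a private RNG state derived from seed; the caller's global
# RNG stream is untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic sub-stream seeds below 2^31
.sub_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1103 * as.numeric(k)) %% 2147483629
}

#' Simulate one raster scan of a synthetic retina
#'
#' Samples the continuous thickness surface at the true retinal positions of
#' each pixel -- `(j - cx) * scale_x_default * AL / assumed` along the
#' B-scan, and likewise across B-scans -- adds i.i.d. Gaussian measurement
#' noise, and returns a map stamped with the *default* scales, exactly as a
#' scanner unaware of the eye's axial length would. Eyes longer than the
#' assumed axial length therefore cover a larger true retinal area within
#' the same pixel grid.
#'
#' @param model A [pit_model()].
#' @param geometry A [scan_geometry()].
#' @param biometry An [eye_biometry()] (axial length and laterality).
#' @param noise_sd Per-A-scan measurement noise (um).
#' @param seed Integer seed; the global RNG stream is left untouched.
#' @param fovea_offset True position `(x, y)` of the foveal centre relative
#'   to the scan centre, in image mm (x to the image right, y superior).
#' @param thickness_offset Additive offset (um) applied to the whole
#'   surface (used by the cohort generator for biological variation).
#' @return A [thickness_map()]. The generating truth (true fovea pixel
#'   position, offsets, seed) is attached as `attr(, "truth")`.
#' @export
simulate_scan <- function(model, geometry, biometry, noise_sd = 0,
                          seed = 1L, fovea_offset = c(0, 0),
                          thickness_offset = 0) {
  stopifnot(inherits(model, "pit_model"), inherits(geometry, "scan_geometry"),
            inherits(biometry, "eye_biometry"))
  al <- biometry$axial_length
  ratio <- al / geometry$assumed_axial_length
  sx_true <- geometry$scale_x_default * ratio
  sy_true <- geometry$scale_y_default * ratio
  cx0 <- (geometry$n_ascans + 1) / 2
  cy0 <- (geometry$n_bscans + 1) / 2

  x_img <- (seq_len(geometry$n_ascans) - cx0) * sx_true - fovea_offset[1]
  y_img <- (cy0 - seq_len(geometry$n_bscans)) * sy_true - fovea_offset[2]
  X <- matrix(x_img, geometry$n_bscans, geometry$n_ascans, byrow = TRUE)
  Y <- matrix(y_img, geometry$n_bscans, geometry$n_ascans)
  # nasal-positive retinal x: image right is nasal for OD, temporal for OS
  Xn <- if (identical(biometry$eye, "OD")) X else -X

  th <- pit_thickness(model, Xn, Y, axial_length = al) + thickness_offset
  if (noise_sd > 0) {
    th <- th + .with_seed(seed, matrix(
      stats::rnorm(length(th), 0, noise_sd), nrow(th)))
  }
  out <- thickness_map(th, geometry, biometry = biometry)
  attr(out, "truth") <- list(
    fovea_px = c(row = cy0 - fovea_offset[2] / sy_true,
                 col = cx0 + fovea_offset[1] / sx_true),
    fovea_offset = fovea_offset,
    thickness_offset = thickness_offset,
    axial_length = al,
    seed = seed
  )
  out
}

#' Cohort simulation settings
#'
#' Defaults mirror a community-based young-adult cohort: axial length
#' approximately N(23.6, 0.9^2) mm with high interocular correlation, about
#' 23 percent myopes (spherical equivalent of -0.50 D or less), and males'
#' retinas a few micrometres thicker than females'.
#'
#' The axial-length-to-refraction map is a deliberately crude
#' emmetropization-failure model: spherical equivalent falls linearly with
#' axial length (`se_from_al_slope`, D per mm) around a threshold placed so
#' that the expected myope fraction equals `myope_fraction_target`, plus
#' correlated-between-eyes Gaussian noise. It produces realistic refractive groups and
#' nothing more.
#'
#' @param n_participants Number of participants (two eyes each).
#' @param al_mean,al_sd Axial length distribution (mm).
#' @param interocular_al_correlation Correlation of the two eyes' axial
#'   lengths, implemented as a shared participant-level component plus an
#'   eye-level deviation.
#' @param myope_fraction_target Target fraction of myopic eyes.
#' @param se_from_al_slope Slope of spherical equivalent on axial length
#'   (D per mm, negative).
#' @param se_noise_participant_sd,se_noise_eye_sd Refraction noise (D),
#'   split into a participant-level component shared by both eyes and a
#'   small eye-level residual: refractive error, like axial length, is
#'   strongly correlated between a person's two eyes.
#' @param sex_effect Thickness offset of males relative to females (um).
#' @param participant_sd,eye_sd Biological thickness variation (um):
#'   participant-level and residual eye-level standard deviations, applied
#'   as uniform offsets to the whole surface. The defaults give a marginal
#'   between-eye SD of about 11 um and an interocular thickness correlation
#'   of 0.8.
#' @param myope_thinning True biological thinning (um) of myopic eyes, for
#'   parameter-recovery experiments; default 0.
#' @param noise_sd Per-A-scan measurement noise (um).
#' @param snr_mean,snr_sd Distribution of the device SNR score (a small
#'   fraction of scans falls below the quality threshold of 20).
#' @param ethnicity_probs Sampling probabilities for the ethnicity labels.
#' @param seed Integer master seed; every random draw flows from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        al_mean = 23.6, al_sd = 0.9,
                        interocular_al_correlation = 0.95,
                        myope_fraction_target = 0.23,
                        se_from_al_slope = -2.0,
                        se_noise_participant_sd = 0.45,
                        se_noise_eye_sd = 0.2,
                        sex_effect = 6,
                        participant_sd = 10, eye_sd = 5,
                        myope_thinning = 0,
                        noise_sd = 3,
                        snr_mean = 30, snr_sd = 5,
                        ethnicity_probs = c("Caucasian" = 0.86,
                                            "East Asian" = 0.02,
                                            "Other/mixed" = 0.12),
                        seed = 1L) {
  stopifnot(n_participants >= 1, al_sd >= 0,
            interocular_al_correlation >= 0, interocular_al_correlation <= 1,
            myope_fraction_target >= 0, myope_fraction_target <= 1,
            se_noise_participant_sd >= 0, se_noise_eye_sd >= 0,
            participant_sd >= 0, eye_sd >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# draw the biometry table (no scans) for a cohort_spec
.draw_biometry <- function(spec) {
  n <- spec$n_participants
  rho <- spec$interocular_al_correlation
  pid <- sprintf("P%04d", seq_len(n))

  shared <- stats::rnorm(n, spec$al_mean, spec$al_sd * sqrt(rho))
  dev <- matrix(stats::rnorm(2 * n, 0, spec$al_sd * sqrt(1 - rho)), n, 2)
  al <- pmin(pmax(shared + dev, .AL_RANGE[1]), .AL_RANGE[2])

  slope <- spec$se_from_al_slope
  se_noise_sd <- sqrt(spec$se_noise_participant_sd^2 + spec$se_noise_eye_sd^2)
  if (spec$myope_fraction_target > 0 &&
      spec$al_sd == 0 && se_noise_sd == 0) {
    warning("cohort_spec: myope_fraction_target unreachable with zero axial-length and refraction variance; proceeding",
            call. = FALSE)
  }
  # threshold axial length placed so P(SE <= -0.5) = target
  eff_sd <- sqrt(spec$al_sd^2 + (se_noise_sd / max(abs(slope), 1e-9))^2)
  al50 <- spec$al_mean + stats::qnorm(1 - spec$myope_fraction_target) * eff_sd
  se <- -0.5 + slope * (al - al50) +
    stats::rnorm(n, 0, spec$se_noise_participant_sd) +
    matrix(stats::rnorm(2 * n, 0, spec$se_noise_eye_sd), n, 2)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  ethnicity <- sample(names(spec$ethnicity_probs), n, replace = TRUE,
                      prob = spec$ethnicity_probs)
  p_off <- stats::rnorm(n, 0, spec$participant_sd)
  e_off <- matrix(stats::rnorm(2 * n, 0, spec$eye_sd), n, 2)
  cyl <- -abs(matrix(stats::rnorm(2 * n, 0, 0.4), n, 2))
  cr <- 7.8 + 0.1 * (al - spec$al_mean) +
    matrix(stats::rnorm(2 * n, 0, 0.2), n, 2)
  snr <- round(pmax(matrix(
    stats::rnorm(2 * n, spec$snr_mean, spec$snr_sd), n, 2), 5), 1)

  grp <- matrix(as.character(classify_refractive_group(as.numeric(se))), n, 2)
  offset <- p_off + e_off + ifelse(sex == "M", spec$sex_effect, 0) -
    ifelse(grp == "myope", spec$myope_thinning, 0)

  eyes <- c("OD", "OS")
  out <- do.call(rbind, lapply(1:2, function(k) {
    data.frame(
      participant_id = pid,
      eye = eyes[k],
      axial_length_mm = al[, k],
      corneal_radius_mm = round(cr[, k], 2),
      sphere_d = round(se[, k] - cyl[, k] / 2, 2),
      cylinder_d = round(cyl[, k], 2),
      snr = snr[, k],
      sex = sex,
      ethnicity = ethnicity,
      thickness_offset_um = offset[, k],
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$participant_id, out$eye), ]
  rownames(out) <- NULL
  out
}

#' Simulate a two-eyed cohort
#'
#' Draws participant- and eye-level biometry according to `spec` and,
#' unless `keep_maps = FALSE`, simulates one raster scan per eye. The
#' biometry table uses the same column schema the real-data path reads, so
#' synthetic and real inputs are interchangeable downstream; the column
#' `thickness_offset_um` carries the eye's true biological offset (synthetic
#' ground truth, absent from real data).
#'
#' @param spec A [cohort_spec()].
#' @param model A [pit_model()].
#' @param geometry A [scan_geometry()].
#' @param keep_maps Simulate and keep the per-eye scans (set `FALSE` for a
#'   biometry-only draw).
#' @return A list of class `oct_cohort` with `biometry` (data frame, one
#'   row per eye), `maps` (named list of [thickness_map()] or `NULL`),
#'   `spec`, `model`, `geometry`.
#' @export
simulate_cohort <- function(spec, model = pit_model(),
                            geometry = spectralis_geometry(),
                            keep_maps = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  biometry <- .with_seed(spec$seed, .draw_biometry(spec))
  maps <- NULL
  if (keep_maps) {
    maps <- lapply(seq_len(nrow(biometry)), function(k) {
      simulate_cohort_eye(spec, model, geometry, biometry[k, ], k)
    })
    names(maps) <- paste(biometry$participant_id, biometry$eye, sep = "_")
  }
  structure(list(biometry = biometry, maps = maps, spec = spec,
                 model = model, geometry = geometry),
            class = "oct_cohort")
}

#' Simulate the scan of a single cohort row
#'
#' Regenerates (deterministically, from the cohort seed and the row index)
#' the scan of one eye of a simulated cohort; used to stream large cohorts
#' through extraction without holding every map in memory.
#'
#' @inheritParams simulate_cohort
#' @param row One row of the cohort biometry table.
#' @param k Its row index (sub-stream selector).
#' @return A [thickness_map()].
#' @export
simulate_cohort_eye <- function(spec, model, geometry, row, k) {
  bio <- eye_biometry(row$participant_id, row$eye,
                      axial_length = row$axial_length_mm,
                      corneal_radius = row$corneal_radius_mm,
                      sphere = row$sphere_d, cylinder = row$cylinder_d,
                      snr = row$snr)
  simulate_scan(model, geometry, bio, noise_sd = spec$noise_sd,
                seed = .sub_seed(spec$seed, k),
                thickness_offset = row$thickness_offset_um)
}

#' Simulate a cohort and extract its sector table in one pass
#'
#' Streams eye by eye: simulate the scan, run the quality filter, locate the
#' fovea, average the raw and corrected ETDRS grids, discard the map. This
#' is the memory-light driver for cohort-scale experiments.
#'
#' @inheritParams simulate_cohort
#' @param min_snr Quality threshold passed to [quality_filter()].
#' @return A list with `table` (a cohort table, see [make_cohort_table()]),
#'   `biometry`, and `exclusions`.
#' @export
simulate_sector_table <- function(spec, model = pit_model(),
                                  geometry = spectralis_geometry(),
                                  min_snr = 20) {
  cohort <- simulate_cohort(spec, model, geometry, keep_maps = FALSE)
  bio <- cohort$biometry
  qf <- quality_filter(bio, min_snr = min_snr)
  idx <- match(paste(qf$retained$participant_id, qf$retained$eye),
               paste(bio$participant_id, bio$eye))
  n <- length(idx)
  means <- matrix(NA_real_, n, 18)
  npx <- matrix(NA_integer_, n, 18)
  trunc <- matrix(NA_real_, n, 18)
  for (i in seq_len(n)) {
    k <- idx[i]
    row <- bio[k, ]
    b <- eye_biometry(row$participant_id, row$eye,
                      axial_length = row$axial_length_mm,
                      sphere = row$sphere_d, cylinder = row$cylinder_d,
                      snr = row$snr)
    map <- simulate_scan(model, geometry, b, noise_sd = spec$noise_sd,
                         seed = .sub_seed(spec$seed, k),
                         thickness_offset = row$thickness_offset_um)
    st <- .eye_sector_stats(map, b, geometry)
    means[i, ] <- c(st$raw$mean, st$corrected$mean)
    npx[i, ] <- c(st$raw$n, st$corrected$n)
    trunc[i, ] <- c(st$raw$trunc, st$corrected$trunc)
  }
  sector_df <- data.frame(
    participant_id = rep(bio$participant_id[idx], each = 18),
    eye = rep(bio$eye[idx], each = 18),
    corrected = rep(rep(c(FALSE, TRUE), each = 9), n),
    sector = factor(rep(ETDRS_SECTORS, 2 * n), levels = ETDRS_SECTORS),
    mean_um = as.vector(t(means)),
    n_pixels = as.vector(t(npx)),
    truncation_fraction = as.vector(t(trunc)),
    stringsAsFactors = FALSE
  )
  list(
    table = make_cohort_table(sector_df, bio),
    biometry = bio,
    exclusions = qf$excluded
  )
}
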