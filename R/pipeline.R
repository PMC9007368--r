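# End-to-end drivers: simulate a dataset to disk, extract sector tables,
# analyse, and plot. These back the command-line interface in
# inst/cli/etdrsmag.R.

#' Run configuration
#'
#' Collects paths and parameters for the pipeline commands. Any field can
#' also be supplied through a YAML file ([read_run_config()]); a resolved
#' copy of the configuration (with the package version) is written into
#' every output directory.
#'
#' @param out_dir Output directory.
#' @param seed Master seed, recorded in every output.
#' @param n_participants Cohort size for [run_simulate()].
#' @param spec,model,geometry Optional [cohort_spec()], [pit_model()],
#'   [scan_geometry()]; defaults are built from `n_participants` and `seed`.
#' @param biometry_csv,scans_dir,geometry_json Input paths for
#'   [run_extract()]; default to the layout [run_simulate()] writes.
#' @param min_snr Quality threshold.
#' @param search_radius,smooth_mm Fovea-localisation parameters (mm).
#' @param nasal_side ETDRS orientation convention (see [build_grid()]).
#' @param write_truth Write the quadrature ground-truth sidecar for
#'   synthetic datasets.
#' @param figures Write forest-plot figures in [run_analyze()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_participants = 10L,
                       spec = NULL, model = NULL, geometry = NULL,
                       biometry_csv = file.path(out_dir, "biometry.csv"),
                       scans_dir = file.path(out_dir, "scans"),
                       geometry_json = file.path(out_dir, "geometry.json"),
                       min_snr = 20, search_radius = 1.5, smooth_mm = 0.25,
                       nasal_side = "auto", write_truth = TRUE,
                       figures = TRUE) {
  if (is.null(spec)) spec <- cohort_spec(n_participants, seed = seed)
  if (is.null(model)) model <- pit_model()
  if (is.null(geometry)) geometry <- spectralis_geometry()
  structure(as.list(environment()), class = "run_config")
}

#' Build a run configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments; the optional
#' blocks `spec`, `model`, `geometry` hold arguments for [cohort_spec()],
#' [pit_model()] and [scan_geometry()].
#'
#' @param path YAML file.
#' @param overrides Named list of fields that take precedence.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  n <- if (is.null(y$n_participants)) 10L else as.integer(y$n_participants)
  spec_args <- y$spec %||% list()
  if (is.null(spec_args$n_participants)) spec_args$n_participants <- n
  if (is.null(spec_args$seed)) spec_args$seed <- seed
  args <- y[setdiff(names(y), c("spec", "model", "geometry"))]
  args$seed <- seed
  args$n_participants <- n
  args$spec <- do.call(cohort_spec, spec_args)
  args$model <- do.call(pit_model, y$model %||% list())
  args$geometry <- if (is.null(y$geometry)) spectralis_geometry() else
    do.call(scan_geometry, y$geometry)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_resolved_config <- function(config, dir) {
  info <- list(
    seed = config$seed,
    n_participants = config$n_participants,
    min_snr = config$min_snr,
    search_radius = config$search_radius,
    smooth_mm = config$smooth_mm,
    nasal_side = config$nasal_side,
    assumed_axial_length = config$geometry$assumed_axial_length,
    package_version = as.character(utils::packageVersion("etdrsmag"))
  )
  jsonlite::write_json(info, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes `biometry.csv`, `geometry.json`, one thickness-map CSV per eye
#' under `scans/`, and (by default) `truth.json` holding each eye's true
#' corrected and raw sector means from the quadrature reference, its true
#' foveal position and thickness offset. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$scans_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config$spec, config$model, config$geometry,
                            keep_maps = FALSE)
  write_biometry_csv(cohort$biometry, config$biometry_csv)
  write_geometry_json(config$geometry, config$geometry_json)

  truth <- list()
  for (k in seq_len(nrow(cohort$biometry))) {
    row <- cohort$biometry[k, ]
    map <- simulate_cohort_eye(config$spec, config$model, config$geometry,
                               row, k)
    id <- paste(row$participant_id, row$eye, sep = "_")
    write_thickness_csv(map, file.path(config$scans_dir,
                                       paste0(id, ".csv")))
    if (config$write_truth) {
      tr <- attr(map, "truth")
      base <- config$model
      truth[[id]] <- list(
        axial_length_mm = row$axial_length_mm,
        thickness_offset_um = tr$thickness_offset,
        fovea_px = as.list(tr$fovea_px),
        sector_truth_corrected_um = as.list(
          sector_truth(base, row$axial_length_mm, corrected = TRUE,
                       assumed_axial_length = config$geometry$assumed_axial_length) +
            tr$thickness_offset),
        sector_truth_raw_um = as.list(
          sector_truth(base, row$axial_length_mm, corrected = FALSE,
                       assumed_axial_length = config$geometry$assumed_axial_length) +
            tr$thickness_offset)
      )
    }
  }
  if (config$write_truth) {
    jsonlite::write_json(truth, file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  .write_resolved_config(config, config$out_dir)
  invisible(config$out_dir)
}

#' Extract the tidy sector table from a dataset on disk
#'
#' Runs, for every eye surviving the quality filter: read the thickness
#' map, locate the fovea, build the raw and corrected ETDRS grids, average
#' per sector. Writes `sectors.csv`, `exclusions.csv` and a one-line-per-eye
#' `extract_log.csv`. Per-eye failures are logged and skipped; only an
#' empty survivor set is an error.
#'
#' @param config A [run_config()].
#' @return Invisibly, the sector data frame.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  biometry <- read_biometry_csv(config$biometry_csv)
  geometry <- read_geometry_json(config$geometry_json)
  qf <- quality_filter(biometry, min_snr = config$min_snr)
  exclusions <- qf$excluded
  rows <- list()
  log <- list()
  for (k in seq_len(nrow(qf$retained))) {
    row <- qf$retained[k, ]
    id <- paste(row$participant_id, row$eye, sep = "_")
    res <- tryCatch({
      bio <- eye_biometry(row$participant_id, row$eye,
                          axial_length = row$axial_length_mm,
                          corneal_radius = row$corneal_radius_mm,
                          sphere = row$sphere_d, cylinder = row$cylinder_d,
                          snr = row$snr)
      map <- read_thickness_csv(
        file.path(config$scans_dir, paste0(id, ".csv")), geometry, bio)
      extract_eye(map, search_radius = config$search_radius,
                  smooth_mm = config$smooth_mm,
                  nasal_side = config$nasal_side)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions <- rbind(exclusions, data.frame(
        participant_id = row$participant_id, eye = row$eye, snr = row$snr,
        reason = conditionMessage(res), stringsAsFactors = FALSE))
      next
    }
    fc <- attr(res, "fovea_centre")
    log[[id]] <- data.frame(
      participant_id = row$participant_id, eye = row$eye,
      fovea_row = fc[1], fovea_col = fc[2],
      max_truncation = max(res$truncation_fraction),
      stringsAsFactors = FALSE)
    rows[[id]] <- res
  }
  if (length(rows) == 0) {
    stop("run_extract: no eyes survived extraction", call. = FALSE)
  }
  sector_df <- do.call(rbind, rows)
  rownames(sector_df) <- NULL
  write_sector_csv(sector_df, file.path(config$out_dir, "sectors.csv"))
  utils::write.csv(exclusions, file.path(config$out_dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, log),
                   file.path(config$out_dir, "extract_log.csv"),
                   row.names = FALSE)
  invisible(sector_df)
}

#' Analyse an extracted dataset
#'
#' Joins the sector and biometry tables, fits the three effect families
#' across the nine sectors, writes `effects.csv`, a JSON run summary, and
#' (optionally) forest-plot figures per family.
#'
#' @param config A [run_config()].
#' @return Invisibly, the effect table.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sector_df <- read_sector_csv(file.path(config$out_dir, "sectors.csv"))
  biometry <- read_biometry_csv(config$biometry_csv)
  table <- make_cohort_table(sector_df, biometry)
  effects <- analyze_cohort(table)
  utils::write.csv(effects, file.path(config$out_dir, "effects.csv"),
                   row.names = FALSE)
  excl_path <- file.path(config$out_dir, "exclusions.csv")
  n_excl <- if (file.exists(excl_path)) nrow(utils::read.csv(excl_path)) else 0
  summary <- list(
    seed = config$seed,
    n_eyes = length(unique(paste(table$participant_id, table$eye))),
    n_participants = length(unique(table$participant_id)),
    n_excluded = n_excl,
    fallbacks = sum(effects$model %in%
                      c("intercept_only_fallback", "robust_lm_fallback")),
    package_version = as.character(utils::packageVersion("etdrsmag"))
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$figures)) {
    for (fam in c("correction", "al_x_correction", "group")) {
      sub <- switch(fam,
                    correction = effects[effects$term == "correction", ],
                    al_x_correction = effects[effects$term == "al_x_correction", ],
                    group = effects[effects$term %in%
                                      c("group_raw", "group_corrected"), ])
      if (nrow(sub) == 0) next
      p <- plot_effects(sub)
      ggplot2::ggsave(file.path(config$out_dir, paste0("forest_", fam, ".pdf")),
                      p, width = 6, height = 4)
    }
  }
  invisible(effects)
}

#' Run simulate, extract and analyse in sequence
#'
#' @param config A [run_config()].
#' @return Invisibly, the effect table.
#' @export
run_pipeline <- function(config) {
  run_simulate(config)
  run_extract(config)
  run_analyze(config)
}

#' Forest plot of per-sector effect estimates
#'
#' Estimates with 95 percent confidence intervals per ETDRS sector; solid
#' points mark Bonferroni-adjusted significance at 0.05.
#'
#' @param effects Effect rows from [analyze_cohort()].
#' @return A ggplot object.
#' @export
plot_effects <- function(effects) {
  effects$sector <- factor(effects$sector, levels = rev(ETDRS_SECTORS))
  effects$significant <- !is.na(effects$p_adjusted) & effects$p_adjusted < 0.05
  ggplot2::ggplot(effects, ggplot2::aes(
    x = .data$estimate, y = .data$sector, colour = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.25, position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant),
                        position = ggplot2::position_dodge(0.5)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "estimate (µm)", y = "ETDRS sector") +
    ggplot2::theme_minimal()
}
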