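# Plain-text on-disk formats: biometry CSV, geometry JSON sidecar,
# per-eye thickness-map CSV matrices, tidy sector CSV.

.BIOMETRY_COLS <- c("participant_id", "eye", "axial_length_mm",
                    "corneal_radius_mm", "sphere_d", "cylinder_d", "snr",
                    "sex", "ethnicity")

#' Read / write the biometry CSV
#'
#' Columns: `participant_id`, `eye`, `axial_length_mm`, `corneal_radius_mm`,
#' `sphere_d`, `cylinder_d`, `snr`, `sex`, `ethnicity` (extra columns are
#' preserved).
#'
#' @param path CSV file path.
#' @param biometry Data frame to write.
#' @return `read_biometry_csv` returns the data frame.
#' @export
read_biometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.BIOMETRY_COLS, names(df))
  if (length(missing)) {
    stop("biometry CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_biometry_csv
#' @export
write_biometry_csv <- function(biometry, path) {
  utils::write.csv(biometry, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a scan geometry JSON sidecar
#'
#' @param path JSON file path.
#' @param geometry A [scan_geometry()].
#' @return `read_geometry_json` returns a [scan_geometry()].
#' @export
read_geometry_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scan_geometry(j$n_bscans, j$n_ascans, j$scale_x_default, j$scale_y_default,
                axial_resolution = j$axial_resolution,
                assumed_axial_length = j$assumed_axial_length)
}

#' @rdname read_geometry_json
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a thickness map as a plain CSV matrix
#'
#' One row per B-scan, one column per A-scan, values in micrometres;
#' invalid pixels as `NA`. The geometry travels in its JSON sidecar.
#'
#' @param path CSV file path.
#' @param map A [thickness_map()].
#' @param geometry A [scan_geometry()] for reading.
#' @param biometry Optional [eye_biometry()] to attach on read.
#' @return `read_thickness_csv` returns a [thickness_map()].
#' @export
read_thickness_csv <- function(path, geometry, biometry = NULL) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  thickness_map(m, geometry, biometry = biometry)
}

#' @rdname read_thickness_csv
#' @export
write_thickness_csv <- function(map, path) {
  utils::write.table(map$thickness, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a long-format (bscan, ascan, value) thickness CSV
#'
#' Accepted for tiny fixtures; missing grid cells become invalid pixels.
#'
#' @inheritParams read_thickness_csv
#' @export
read_thickness_long_csv <- function(path, geometry, biometry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bscan", "ascan", "value") %in% names(df)))
  m <- matrix(NA_real_, geometry$n_bscans, geometry$n_ascans)
  m[cbind(df$bscan, df$ascan)] <- df$value
  thickness_map(m, geometry, biometry = biometry)
}

#' Read / write the tidy sector table CSV
#'
#' One row per eye x correction state x sector: `participant_id`, `eye`,
#' `corrected`, `sector`, `mean_um`, `n_pixels`, `truncation_fraction`.
#'
#' @param path CSV file path.
#' @param sector_df Data frame to write.
#' @export
read_sector_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sector <- factor(df$sector, levels = ETDRS_SECTORS)
  df$corrected <- as.logical(df$corrected)
  df
}

#' @rdname read_sector_csv
#' @export
write_sector_csv <- function(sector_df, path) {
  utils::write.csv(sector_df, path, row.names = FALSE)
  invisible(path)
}
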