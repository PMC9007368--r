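# Scan geometry, eye biometry, and the axial-length magnification correction.

#' Default axial length assumed by the Heidelberg Spectralis (mm)
#' @export
SPECTRALIS_AXIAL_LENGTH <- 24.385

# Device defaults documented for other instruments (see Discussion of the
# magnification literature): Cirrus 24.46 mm, Copernicus 24.00 mm.
#' Axial lengths assumed by common SD-OCT devices (mm)
#' @export
DEVICE_AXIAL_LENGTHS <- c(spectralis = 24.385, cirrus = 24.46, copernicus = 24.00)

.AL_RANGE <- c(15, 35) # plausibility gate, mm; a unit mistake fails loudly

#' Construct a raster scan geometry
#'
#' Describes the device-reported geometry of an OCT raster volume: the pixel
#' grid and the *default* transverse scales the scanner stamps on the image,
#' i.e. the mm-per-pixel values that are only true for an eye whose axial
#' length equals `assumed_axial_length`.
#'
#' @param n_bscans Number of B-scans (rows of the thickness map).
#' @param n_ascans Number of A-scans per B-scan (columns).
#' @param scale_x_default Device-reported transverse scale along a B-scan
#'   (mm per pixel, the "Scaling X" of the image metadata).
#' @param scale_y_default Spacing between adjacent B-scans (mm).
#' @param axial_resolution Axial sampling (micrometres per axial pixel).
#' @param assumed_axial_length Axial length (mm) the device calibration
#'   assumes; 24.385 mm for the Spectralis (see [DEVICE_AXIAL_LENGTHS]).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_bscans, n_ascans, scale_x_default, scale_y_default,
                          axial_resolution = 3.9,
                          assumed_axial_length = SPECTRALIS_AXIAL_LENGTH) {
  n_bscans <- as.integer(n_bscans)
  n_ascans <- as.integer(n_ascans)
  stopifnot(n_bscans >= 1, n_ascans >= 2)
  for (v in c(scale_x = scale_x_default, scale_y = scale_y_default,
              axial_resolution = axial_resolution,
              assumed_axial_length = assumed_axial_length)) {
    if (!is.finite(v) || v <= 0) {
      stop("scan_geometry: all scales must be finite and strictly positive, got ",
           format(v), call. = FALSE)
    }
  }
  g <- structure(list(
    n_bscans = n_bscans,
    n_ascans = n_ascans,
    scale_x_default = scale_x_default,
    scale_y_default = scale_y_default,
    axial_resolution = axial_resolution,
    assumed_axial_length = assumed_axial_length,
    nominal_extent_x = (n_ascans - 1) * scale_x_default,
    nominal_extent_y = (n_bscans - 1) * scale_y_default
  ), class = "scan_geometry")
  g
}

#' Spectralis 31-line macular raster geometry
#'
#' The scan protocol of the macular volume used throughout: a 31-line raster
#' covering 30 degrees horizontally by 25 degrees vertically, centred on the
#' fovea. At the assumed axial length of 24.385 mm the 30-degree field spans
#' about 8.6 mm on the retina. `n_ascans` defaults to 512; the device's
#' high-resolution mode records 1536 A-scans per line, but 512 columns sample
#' the slowly varying thickness surface amply and keep simulated cohorts
#' cheap.
#'
#' @param n_ascans A-scans per B-scan.
#' @param n_bscans Number of B-scans.
#' @param extent_x_mm,extent_y_mm Nominal field of view (mm) at the assumed
#'   axial length.
#' @inheritParams scan_geometry
#' @return A [scan_geometry()] object.
#' @export
spectralis_geometry <- function(n_ascans = 512L, n_bscans = 31L,
                                extent_x_mm = 8.6, extent_y_mm = 8.6 * 25 / 30,
                                axial_resolution = 3.9,
                                assumed_axial_length = SPECTRALIS_AXIAL_LENGTH) {
  scan_geometry(
    n_bscans = n_bscans, n_ascans = n_ascans,
    scale_x_default = extent_x_mm / (n_ascans - 1),
    scale_y_default = extent_y_mm / (n_bscans - 1),
    axial_resolution = axial_resolution,
    assumed_axial_length = assumed_axial_length
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: %d B-scans x %d A-scans, %.1f x %.1f mm nominal, assumed AL %.3f mm\n",
    x$n_bscans, x$n_ascans, x$nominal_extent_x, x$nominal_extent_y,
    x$assumed_axial_length))
  invisible(x)
}

.check_axial_length <- function(axial_length) {
  bad <- !is.finite(axial_length) | axial_length < .AL_RANGE[1] |
    axial_length > .AL_RANGE[2]
  if (any(bad)) {
    stop("axial length outside the plausible range [",
         .AL_RANGE[1], ", ", .AL_RANGE[2], "] mm: ",
         paste(format(axial_length[bad]), collapse = ", "),
         " (check units: axial length must be in mm)", call. = FALSE)
  }
  invisible(axial_length)
}

#' Axial-length correction of the transverse scale
#'
#' An OCT scan spans a fixed visual angle, so the retinal area imaged grows
#' with the eye's axial length. The device reports a transverse scale that is
#' only valid at its assumed axial length; the corrected scale for an
#' individual eye is
#' `scale_default * axial_length / assumed_axial_length`.
#'
#' @param scale_default Device-reported transverse scale (mm per pixel).
#' @param axial_length Measured axial length of the eye (mm).
#' @param assumed_axial_length Axial length assumed by the device (mm).
#' @return Corrected transverse scale (mm per pixel), same length as the
#'   longest input.
#' @examples
#' corrected_transverse_scale(6 / 512, 21.5)
#' @export
corrected_transverse_scale <- function(scale_default, axial_length,
                                       assumed_axial_length = SPECTRALIS_AXIAL_LENGTH) {
  if (any(!is.finite(scale_default) | scale_default <= 0)) {
    stop("scale_default must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(assumed_axial_length) | assumed_axial_length <= 0)) {
    stop("assumed_axial_length must be finite and strictly positive", call. = FALSE)
  }
  .check_axial_length(axial_length)
  scale_default * axial_length / assumed_axial_length
}

#' Actual on-retina extent of a nominal scan length
#'
#' Rescales a nominal scan extent (mm, as the device reports it) to the
#' physical extent imaged on an eye of the given axial length.
#'
#' @param nominal_extent Nominal extent (mm) at the assumed axial length.
#' @inheritParams corrected_transverse_scale
#' @return Actual scanned extent in mm.
#' @examples
#' actual_scan_extent(6, 21.5) # a "6 mm" scan on a short eye covers ~5.3 mm
#' @export
actual_scan_extent <- function(nominal_extent, axial_length,
                               assumed_axial_length = SPECTRALIS_AXIAL_LENGTH) {
  corrected_transverse_scale(nominal_extent, axial_length, assumed_axial_length)
}

#' Spherical equivalent refraction
#'
#' `sphere + cylinder / 2`, in dioptres. The value is invariant to whether
#' the prescription is written in minus- or plus-cylinder form, but
#' [as_minus_cylinder()] is provided to normalise stored records.
#'
#' @param sphere Spherical power (D).
#' @param cylinder Cylindrical power (D).
#' @return Spherical equivalent (D).
#' @export
spherical_equivalent <- function(sphere, cylinder) {
  if (any(!is.finite(sphere)) || any(!is.finite(cylinder))) {
    stop("sphere and cylinder must be finite", call. = FALSE)
  }
  sphere + cylinder / 2
}

#' Convert a plus-cylinder prescription to minus-cylinder form
#'
#' @param sphere,cylinder Prescription in plus-cylinder form.
#' @return A list with `sphere` and `cylinder` in minus-cylinder form.
#' @export
as_minus_cylinder <- function(sphere, cylinder) {
  list(sphere = sphere + cylinder, cylinder = -cylinder)
}

#' Classify an eye as myopic or non-myopic
#'
#' Myopia is defined as spherical equivalent of -0.50 D or less (the
#' boundary value -0.50 D counts as myopic).
#'
#' @param se Spherical equivalent (D), vectorised.
#' @return Factor with levels `non-myope`, `myope`.
#' @export
classify_refractive_group <- function(se) {
  if (any(!is.finite(se))) stop("spherical equivalent must be finite", call. = FALSE)
  factor(ifelse(se <= -0.50, "myope", "non-myope"),
         levels = c("non-myope", "myope"))
}

#' Eye biometry record
#'
#' @param participant_id Identifier of the participant.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param axial_length Axial length (mm); must lie in the plausibility range
#'   15--35 mm.
#' @param corneal_radius Mean corneal radius of curvature (mm); carried as
#'   metadata only (the device applies its own corneal-curvature handling).
#' @param sphere,cylinder Refraction (D), minus-cylinder convention. Set
#'   `plus_cylinder = TRUE` if the inputs use the plus-cylinder convention.
#' @param snr Device-reported signal-to-noise score of the scan.
#' @param plus_cylinder Convert from plus-cylinder input.
#' @return An object of class `eye_biometry`.
#' @export
eye_biometry <- function(participant_id, eye = c("OD", "OS"),
                         axial_length,
                         corneal_radius = NA_real_,
                         sphere = NA_real_, cylinder = 0,
                         snr = NA_real_,
                         plus_cylinder = FALSE) {
  eye <- match.arg(eye)
  .check_axial_length(axial_length)
  if (isTRUE(plus_cylinder)) {
    conv <- as_minus_cylinder(sphere, cylinder)
    sphere <- conv$sphere
    cylinder <- conv$cylinder
  }
  if (is.finite(cylinder) && cylinder > 0) {
    stop("cylinder must be <= 0 in the minus-cylinder convention; ",
         "pass plus_cylinder = TRUE to convert", call. = FALSE)
  }
  structure(list(
    participant_id = as.character(participant_id),
    eye = eye,
    axial_length = axial_length,
    corneal_radius = corneal_radius,
    sphere = sphere,
    cylinder = cylinder,
    snr = snr
  ), class = "eye_biometry")
}

#' @export
print.eye_biometry <- function(x, ...) {
  cat(sprintf("eye_biometry: %s %s, AL %.2f mm, SE %+.2f D, SNR %s\n",
              x$participant_id, x$eye, x$axial_length,
              spherical_equivalent(x$sphere, x$cylinder),
              format(x$snr)))
  invisible(x)
}

#' Scan-quality filter
#'
#' Retains scans with signal-to-noise ratio of at least `min_snr`; scans
#' below the threshold, or with a missing score, are excluded and logged.
#'
#' @param biometry Data frame with at least `participant_id`, `eye`, `snr`.
#' @param min_snr Minimum acceptable signal-to-noise score (default 20;
#'   scans with SNR below 20 are considered inadequate).
#' @return A list with `retained` (subset of `biometry`) and `excluded`
#'   (data frame of `participant_id`, `eye`, `snr`, `reason`).
#' @export
quality_filter <- function(biometry, min_snr = 20) {
  stopifnot(is.data.frame(biometry),
            all(c("participant_id", "eye", "snr") %in% names(biometry)))
  missing_snr <- !is.finite(biometry$snr)
  low <- !missing_snr & biometry$snr < min_snr
  keep <- !missing_snr & !low
  excluded <- data.frame(
    participant_id = biometry$participant_id[!keep],
    eye = biometry$eye[!keep],
    snr = biometry$snr[!keep],
    reason = ifelse(missing_snr[!keep], "missing_snr", "low_snr"),
    stringsAsFactors = FALSE
  )
  list(retained = biometry[keep, , drop = FALSE], excluded = excluded)
}
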