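# The 9-sector ETDRS grid in scan-pixel coordinates and per-sector means.

# sector areas in mm^2 for truncation accounting
.sector_area <- function() {
  r <- ETDRS_RADII
  c(C = pi * r[1]^2,
    rep(pi * (r[2]^2 - r[1]^2) / 4, 4),
    rep(pi * (r[3]^2 - r[2]^2) / 4, 4)) |>
    stats::setNames(ETDRS_SECTORS)
}

#' Build the ETDRS sector masks for a scan
#'
#' Assigns every pixel of the raster to one of the 9 ETDRS sectors (or
#' `outside`) by a pixel-centre point-in-region test. The physical offset of
#' pixel (i, j) from the foveal centre is `((j - cx) * sx, (cy - i) * sy)`
#' with image "up" (decreasing row) superior. With `corrected = FALSE` the
#' device-default scales are used; with `corrected = TRUE` both transverse
#' scales are rescaled by `axial_length / assumed_axial_length` (the
#' magnification acts on visual angle, hence isotropically in the transverse
#' plane), so the ring boundaries sit at the true 0.5/1.5/3.0 mm radii.
#'
#' Radial bins are half-open with the inner boundary inclusive:
#' `[0, 0.5)`, `[0.5, 1.5)`, `[1.5, 3.0)` mm. Quadrants are split along the
#' 45-degree diagonals by comparing `|dx|` and `|dy|`; pixels exactly on a
#' diagonal are assigned to the horizontal (nasal/temporal) quadrant, which
#' keeps sector membership exactly invariant under left-right mirroring with
#' an OD/OS toggle.
#'
#' The horizontal direction nearer the optic disc is nasal: image right for
#' a right eye (OD) and image left for a left eye (OS) under the default
#' orientation; override with `nasal_side` if the export orientation
#' differs.
#'
#' @param geometry A [scan_geometry()].
#' @param biometry An [eye_biometry()] (axial length and laterality).
#' @param centre Fractional `(row, col)` of the foveal centre.
#' @param corrected Use the axial-length-corrected transverse scales.
#' @param nasal_side `"auto"` (OD right, OS left), `"right"`, or `"left"`.
#' @param truncation_warn Warn if more than this fraction of any sector's
#'   area falls outside the scan.
#' @return An object of class `etdrs_sectors`: a `labels` character matrix plus
#'   the scales, centre, laterality and per-sector truncation fractions.
#' @export
build_grid <- function(geometry, biometry, centre, corrected = FALSE,
                       nasal_side = c("auto", "right", "left"),
                       truncation_warn = 0.20) {
  stopifnot(inherits(geometry, "scan_geometry"),
            inherits(biometry, "eye_biometry"),
            length(centre) == 2)
  nasal_side <- match.arg(nasal_side)
  if (centre[1] < 1 || centre[1] > geometry$n_bscans ||
      centre[2] < 1 || centre[2] > geometry$n_ascans) {
    stop("build_grid: centre must lie inside the scan grid", call. = FALSE)
  }
  if (corrected) {
    sx <- corrected_transverse_scale(geometry$scale_x_default,
                                     biometry$axial_length,
                                     geometry$assumed_axial_length)
    sy <- corrected_transverse_scale(geometry$scale_y_default,
                                     biometry$axial_length,
                                     geometry$assumed_axial_length)
  } else {
    sx <- geometry$scale_x_default
    sy <- geometry$scale_y_default
  }
  nasal_right <- switch(nasal_side,
                        auto = identical(biometry$eye, "OD"),
                        right = TRUE,
                        left = FALSE)

  nb <- geometry$n_bscans
  na <- geometry$n_ascans
  # only columns within the outer ring radius can carry a sector label
  jr <- ETDRS_RADII[3] / sx
  j0 <- max(1L, floor(centre[2] - jr))
  j1 <- min(na, ceiling(centre[2] + jr))
  cols <- j0:j1
  nc <- length(cols)
  dx <- (cols - centre[2]) * sx
  dy <- (centre[1] - seq_len(nb)) * sy # up = superior
  DX <- matrix(rep(dx, each = nb), nb, nc)
  DY <- matrix(dy, nb, nc)
  r2 <- DX * DX + DY * DY
  # rings by squared radius: 0 = central disc, 1 inner, 2 outer, 3 outside;
  # inner boundary inclusive, outer exclusive
  ring <- findInterval(r2, ETDRS_RADII^2)

  # quadrants along the 45-degree diagonals; diagonal ties (to within a
  # sub-nanometre epsilon, so that floating-point noise in the centre
  # estimate cannot split an exact tie) go to the horizontal
  # (nasal/temporal) quadrant so that mirroring plus an OD/OS toggle leaves
  # membership unchanged. N = 0, S = 1, T = 2, I = 3.
  horiz <- abs(DX) >= abs(DY) - 1e-9
  qi <- integer(length(r2))
  qi[!horiz & DY > 0] <- 1L
  qi[!horiz & DY <= 0] <- 3L
  if (nasal_right) qi[horiz & DX <= 0] <- 2L else qi[horiz & DX > 0] <- 2L

  # sector codes 1..9 in ETDRS_SECTORS order, 0 = outside
  sub <- integer(length(r2))
  sub[ring == 0L] <- 1L
  inner <- ring == 1L | ring == 2L
  sub[inner] <- 2L + (ring[inner] - 1L) * 4L + qi[inner]
  code <- matrix(0L, nb, na)
  code[, cols] <- sub
  labels <- matrix(c("outside", ETDRS_SECTORS)[code + 1L], nb, na)

  px_area <- sx * sy
  counts <- tabulate(code, nbins = 9L)
  trunc_frac <- pmax(0, 1 - counts * px_area / .sector_area())
  names(trunc_frac) <- ETDRS_SECTORS
  over <- trunc_frac > truncation_warn
  if (any(over)) {
    warning("build_grid: sector(s) ",
            paste(names(trunc_frac)[over], collapse = ", "),
            " truncated by the scan bounds by more than ",
            round(100 * truncation_warn), "%", call. = FALSE)
  }

  structure(list(
    labels = labels,
    codes = code,
    radii = ETDRS_RADII,
    centre = centre,
    scale_x = sx,
    scale_y = sy,
    laterality = biometry$eye,
    corrected = corrected,
    truncation_fraction = trunc_frac
  ), class = "etdrs_sectors")
}

#' @export
print.etdrs_sectors <- function(x, ...) {
  cat(sprintf(
    "etdrs_sectors (%s, %s): centre (%.1f, %.1f), scales %.4f x %.4f mm/px\n",
    x$laterality, if (x$corrected) "corrected" else "raw",
    x$centre[1], x$centre[2], x$scale_x, x$scale_y))
  invisible(x)
}

#' Per-sector mean thickness
#'
#' Unweighted mean of the valid pixels in each of the 9 ETDRS sectors.
#'
#' @param map A [thickness_map()].
#' @param sectors An [build_grid()] result on the same grid.
#' @return Data frame with one row per sector: `sector`, `mean_um`,
#'   `n_pixels`, `truncation_fraction`, `corrected`.
#' @export
sector_means <- function(map, sectors) {
  stopifnot(inherits(map, "thickness_map"), inherits(sectors, "etdrs_sectors"),
            all(dim(map$thickness) == dim(sectors$labels)))
  ok <- map$valid_mask & sectors$codes > 0L
  cd <- sectors$codes[ok]
  ns <- tabulate(cd, nbins = 9L)
  empty <- ns == 0
  if (any(empty)) {
    stop("sector_means: no valid pixels in sector(s) ",
         paste(ETDRS_SECTORS[empty], collapse = ", "), call. = FALSE)
  }
  sums <- numeric(9)
  rs <- rowsum(map$thickness[ok], cd)
  sums[as.integer(rownames(rs))] <- rs
  data.frame(
    sector = factor(ETDRS_SECTORS, levels = ETDRS_SECTORS),
    mean_um = sums / ns,
    n_pixels = as.integer(ns),
    truncation_fraction = as.numeric(sectors$truncation_fraction),
    corrected = sectors$corrected,
    row.names = NULL
  )
}

# fast path: per-eye raw+corrected sector statistics as plain vectors
.eye_sector_stats <- function(map, biometry, geometry,
                              search_radius = 1.5, smooth_mm = 0.25, ...) {
  centre <- map$fovea_centre
  if (is.null(centre)) {
    centre <- locate_fovea(map, search_radius = search_radius,
                           smooth_mm = smooth_mm)
  }
  out <- list(centre = centre)
  for (corr in c(FALSE, TRUE)) {
    grid <- build_grid(geometry, biometry, centre, corrected = corr, ...)
    ok <- map$valid_mask & grid$codes > 0L
    cd <- grid$codes[ok]
    ns <- tabulate(cd, nbins = 9L)
    if (any(ns == 0)) {
      stop("sector_means: no valid pixels in sector(s) ",
           paste(ETDRS_SECTORS[ns == 0], collapse = ", "), call. = FALSE)
    }
    sums <- numeric(9)
    rs <- rowsum(map$thickness[ok], cd)
    sums[as.integer(rownames(rs))] <- rs
    key <- if (corr) "corrected" else "raw"
    out[[key]] <- list(mean = sums / ns, n = ns,
                       trunc = as.numeric(grid$truncation_fraction))
  }
  out
}

#' Raw and corrected sector means for one eye
#'
#' Composes the per-eye pipeline: locate the fovea once, build the raw
#' (device-default scale) and corrected (axial-length-rescaled) ETDRS grids
#' at that same centre, and average the same thickness map under both.
#' The two variants differ only in where the sector boundaries fall.
#'
#' @param map A [thickness_map()] (with `biometry` attached, or supplied).
#' @param biometry An [eye_biometry()]; defaults to the one on the map.
#' @param geometry Override the map's geometry (rarely needed).
#' @param ... Passed to [build_grid()] (e.g. `nasal_side`).
#' @param search_radius,smooth_mm Passed to [locate_fovea()].
#' @return Data frame with 18 rows (9 sectors x raw/corrected):
#'   `participant_id`, `eye`, `corrected`, `sector`, `mean_um`, `n_pixels`,
#'   `truncation_fraction`; the fovea estimate is in `attr(, "fovea_centre")`.
#' @export
extract_eye <- function(map, biometry = map$biometry, geometry = map$geometry,
                        search_radius = 1.5, smooth_mm = 0.25, ...) {
  stopifnot(inherits(map, "thickness_map"), inherits(biometry, "eye_biometry"))
  st <- .eye_sector_stats(map, biometry, geometry,
                          search_radius = search_radius,
                          smooth_mm = smooth_mm, ...)
  out <- data.frame(
    participant_id = biometry$participant_id,
    eye = biometry$eye,
    corrected = rep(c(FALSE, TRUE), each = 9),
    sector = factor(rep(ETDRS_SECTORS, 2), levels = ETDRS_SECTORS),
    mean_um = c(st$raw$mean, st$corrected$mean),
    n_pixels = c(st$raw$n, st$corrected$n),
    truncation_fraction = c(st$raw$trunc, st$corrected$trunc),
    stringsAsFactors = FALSE
  )
  attr(out, "fovea_centre") <- st$centre
  out
}
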