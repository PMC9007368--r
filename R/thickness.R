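# From segmented surfaces to a per-A-scan thickness map, and foveal-centre
# localisation.

#' Thickness map container
#'
#' Full retinal thickness on the raster grid (rows = B-scans, columns =
#' A-scans), in micrometres, together with the geometry the device stamped
#' on the scan and, optionally, the eye's biometry.
#'
#' @param thickness Numeric matrix (`n_bscans` x `n_ascans`), um.
#' @param geometry A [scan_geometry()] matching the matrix dimensions.
#' @param biometry Optional [eye_biometry()].
#' @param valid_mask Logical matrix of per-pixel validity; defaults to
#'   finite, positive thickness.
#' @param fovea_centre Optional fractional `(row, col)` of the foveal centre.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(thickness, geometry, biometry = NULL,
                          valid_mask = NULL, fovea_centre = NULL) {
  stopifnot(is.matrix(thickness),
            inherits(geometry, "scan_geometry"),
            nrow(thickness) == geometry$n_bscans,
            ncol(thickness) == geometry$n_ascans)
  if (is.null(valid_mask)) {
    valid_mask <- is.finite(thickness) & thickness > 0
  }
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(thickness)))
  structure(list(
    thickness = thickness,
    geometry = geometry,
    biometry = biometry,
    valid_mask = valid_mask,
    fovea_centre = fovea_centre
  ), class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("thickness_map: %d x %d, %.0f%% valid, mean %.1f um\n",
              nrow(x$thickness), ncol(x$thickness),
              100 * mean(x$valid_mask),
              mean(x$thickness[x$valid_mask])))
  invisible(x)
}

#' Segmented ILM/RPE surface pair
#'
#' Axial positions of the inner limiting membrane and retinal pigment
#' epithelium per (B-scan, A-scan), either in axial pixels or in
#' micrometres. Positions increase with depth, so the RPE value exceeds the
#' ILM value wherever segmentation succeeded.
#'
#' @param ilm,rpe Numeric matrices of equal dimension.
#' @param geometry A [scan_geometry()].
#' @param unit `"px"` (axial pixels; converted via
#'   `geometry$axial_resolution`) or `"um"`.
#' @return An object of class `segmented_surfaces`.
#' @export
segmented_surfaces <- function(ilm, rpe, geometry, unit = c("px", "um")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(ilm), is.matrix(rpe), all(dim(ilm) == dim(rpe)),
            inherits(geometry, "scan_geometry"),
            nrow(ilm) == geometry$n_bscans, ncol(ilm) == geometry$n_ascans)
  structure(list(ilm = ilm, rpe = rpe, geometry = geometry, unit = unit),
            class = "segmented_surfaces")
}

#' Full retinal thickness from segmented surfaces
#'
#' Thickness is the axial distance RPE minus ILM along each A-scan,
#' converted to micrometres when the surfaces are in axial pixels. No
#' transverse smoothing is applied. A-scans where the surfaces cross or are
#' missing are flagged invalid; if more than `max_invalid_fraction` of the
#' grid is invalid the segmentation is considered failed and an error is
#' raised.
#'
#' @param surfaces A [segmented_surfaces()].
#' @param biometry Optional [eye_biometry()] to attach.
#' @param max_invalid_fraction Invalid-pixel fraction above which to abort.
#' @return A [thickness_map()]; the number of invalid A-scans is available
#'   as `attr(, "n_invalid")`.
#' @export
surfaces_to_thickness <- function(surfaces, biometry = NULL,
                                  max_invalid_fraction = 0.10) {
  stopifnot(inherits(surfaces, "segmented_surfaces"))
  diff_ <- surfaces$rpe - surfaces$ilm
  th <- if (surfaces$unit == "px") {
    diff_ * surfaces$geometry$axial_resolution
  } else {
    diff_
  }
  valid <- is.finite(th) & th > 0
  n_invalid <- sum(!valid)
  frac <- n_invalid / length(th)
  if (frac > max_invalid_fraction) {
    stop(sprintf(
      "surfaces_to_thickness: %.1f%% of A-scans invalid (RPE <= ILM or missing); segmentation failure",
      100 * frac), call. = FALSE)
  }
  th[!valid] <- NA_real_
  out <- thickness_map(th, surfaces$geometry, biometry = biometry,
                       valid_mask = valid)
  attr(out, "n_invalid") <- n_invalid
  out
}

# running box sums along rows / columns via cumulative sums; windows are
# clipped at the matrix edges
.box_sum_rows <- function(m, k) {
  h <- (k - 1L) %/% 2L
  na <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  hi <- pmin(na, seq_len(na) + h)
  lo <- pmax(0L, seq_len(na) - h - 1L)
  cs[, hi + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE]
}

.box_sum_cols <- function(m, k) {
  h <- (k - 1L) %/% 2L
  nb <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(nb, seq_len(nb) + h)
  lo <- pmax(0L, seq_len(nb) - h - 1L)
  cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
}

# validity-aware separable box smoothing; invalid cells contribute neither
# to the sum nor the count, and edge windows are partial
.box_smooth <- function(values, valid, kx, ky) {
  v <- values
  v[!valid] <- 0
  cnt <- matrix(as.numeric(valid), nrow(values))
  if (kx > 1) {
    v <- .box_sum_rows(v, kx)
    cnt <- .box_sum_rows(cnt, kx)
  }
  if (ky > 1) {
    v <- .box_sum_cols(v, ky)
    cnt <- .box_sum_cols(cnt, ky)
  }
  out <- v / cnt
  out[!is.finite(out)] <- NA_real_
  out
}

.odd_kernel <- function(width_mm, scale_mm) {
  k <- max(1L, round(width_mm / scale_mm))
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

#' Locate the foveal centre on a thickness map
#'
#' The fovea is the minimum of a lightly smoothed thickness surface within
#' `search_radius` of the scan centre (the protocol centres scans on the
#' fovea, so a wider search only invites ectopic minima). Smoothing is a
#' validity-aware moving average of about `smooth_mm` in each transverse
#' direction, measured with the device-default scales; for the 31-line
#' raster the B-scan spacing exceeds the kernel so smoothing acts along the
#' B-scans only. Ties are broken toward the scan centre, and the discrete
#' minimum is refined to sub-pixel precision by one-dimensional quadratic
#' interpolation in each axis.
#'
#' @param map A [thickness_map()].
#' @param search_radius Search radius around the scan centre (mm).
#' @param smooth_mm Smoothing kernel width (mm).
#' @return Fractional `c(row, col)` of the foveal centre.
#' @export
locate_fovea <- function(map, search_radius = 1.5, smooth_mm = 0.25) {
  stopifnot(inherits(map, "thickness_map"))
  g <- map$geometry
  kx <- .odd_kernel(smooth_mm, g$scale_x_default)
  ky <- .odd_kernel(smooth_mm, g$scale_y_default)

  cy0 <- (g$n_bscans + 1) / 2
  cx0 <- (g$n_ascans + 1) / 2
  # work on the search window plus the kernel margin only
  mi <- search_radius / g$scale_y_default + ky
  mj <- search_radius / g$scale_x_default + kx
  i0 <- max(1L, floor(cy0 - mi))
  i1 <- min(g$n_bscans, ceiling(cy0 + mi))
  j0 <- max(1L, floor(cx0 - mj))
  j1 <- min(g$n_ascans, ceiling(cx0 + mj))
  sub <- map$thickness[i0:i1, j0:j1, drop = FALSE]
  subv <- map$valid_mask[i0:i1, j0:j1, drop = FALSE]
  sm <- .box_smooth(sub, subv, kx, ky)

  dy <- (i0:i1 - cy0) * g$scale_y_default
  dx <- (j0:j1 - cx0) * g$scale_x_default
  dist2 <- outer(dy^2, dx^2, `+`)
  in_window <- dist2 <= search_radius^2
  cand <- which(in_window & is.finite(sm))
  if (length(cand) == 0L) {
    stop("locate_fovea: no valid pixels within the search window", call. = FALSE)
  }
  vals <- sm[cand]
  best <- cand[vals <= min(vals) + 1e-12]
  if (length(best) > 1L) best <- best[which.min(dist2[best])]
  ij <- arrayInd(best, dim(sm))
  i <- ij[1]
  j <- ij[2]

  refine <- function(vm1, v0, vp1) {
    if (!is.finite(vm1) || !is.finite(vp1)) return(0)
    denom <- vm1 - 2 * v0 + vp1
    if (denom <= 0) return(0)
    off <- 0.5 * (vm1 - vp1) / denom
    max(-0.5, min(0.5, off))
  }
  di <- if (i > 1 && i < nrow(sm)) refine(sm[i - 1, j], sm[i, j], sm[i + 1, j]) else 0
  dj <- if (j > 1 && j < ncol(sm)) refine(sm[i, j - 1], sm[i, j], sm[i, j + 1]) else 0
  c(row = i0 - 1L + i + di, col = j0 - 1L + j + dj)
}
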