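# Continuous-domain reference values: ETDRS sector means of a pit_model by
# 2D Gauss-Legendre quadrature in polar coordinates. These are the ground
# truth that the pixel-based extraction is validated against, and the
# generator's "truth" sidecar for synthetic eyes.

#' ETDRS sector labels
#'
#' Central disc `C`, inner ring (`N1`, `S1`, `T1`, `I1`) and outer ring
#' (`N2`, `S2`, `T2`, `I2`); N/S/T/I = nasal, superior, temporal, inferior.
#' @export
ETDRS_SECTORS <- c("C", "N1", "S1", "T1", "I1", "N2", "S2", "T2", "I2")

#' ETDRS ring radii (mm): central disc 0.5, inner ring to 1.5, outer to 3.0
#' @export
ETDRS_RADII <- c(0.5, 1.5, 3.0)

# angular span of each quadrant in retinal coordinates (nasal = 0 rad,
# superior = pi/2); diagonals at +-45 degrees
.quadrant_theta <- list(
  N = c(-pi / 4, pi / 4),
  S = c(pi / 4, 3 * pi / 4),
  T = c(3 * pi / 4, 5 * pi / 4),
  I = c(5 * pi / 4, 7 * pi / 4)
)

#' True ETDRS sector means of a continuous thickness surface
#'
#' Averages `pit_thickness` over the exact annular-sector boundaries by
#' tensor Gauss-Legendre quadrature in polar coordinates, i.e.
#' `mean = (integral of T r dr dtheta) / (integral of r dr dtheta)`.
#'
#' With `corrected = TRUE` the boundaries are the nominal ETDRS radii in
#' true retinal mm: the value an ideal, magnification-corrected extraction
#' should report. With `corrected = FALSE` the boundaries are scaled by
#' `axial_length / assumed_axial_length`: the region a grid drawn with the
#' device-default scale actually covers on this eye, i.e. the expectation of
#' the raw (uncorrected) sector mean.
#'
#' @param model A [pit_model()].
#' @param axial_length Axial length of the eye (mm).
#' @param corrected Logical; see Details.
#' @param assumed_axial_length Device-assumed axial length (mm).
#' @param fovea_offset Offset (mm, retinal nasal/superior coordinates) of
#'   the grid centre from the true foveal centre; default none.
#' @param n_nodes Gauss-Legendre nodes per dimension and sector.
#' @return Named numeric vector of the 9 sector means (um), in
#'   [ETDRS_SECTORS] order.
#' @export
sector_truth <- function(model, axial_length,
                         corrected = TRUE,
                         assumed_axial_length = SPECTRALIS_AXIAL_LENGTH,
                         fovea_offset = c(0, 0),
                         n_nodes = 48) {
  .check_axial_length(axial_length)
  f <- if (corrected) 1 else axial_length / assumed_axial_length
  radii <- ETDRS_RADII * f

  mean_polar <- function(r1, r2, th1, th2) {
    gr <- pracma::gaussLegendre(n_nodes, r1, r2)
    gt <- pracma::gaussLegendre(n_nodes, th1, th2)
    r <- gr$x
    th <- gt$x
    X <- outer(r, cos(th)) + fovea_offset[1]
    Y <- outer(r, sin(th)) + fovea_offset[2]
    tt <- pit_thickness(model, X, Y, axial_length)
    w <- outer(gr$w * r, gt$w) # polar Jacobian r
    sum(w * tt) / sum(w)
  }

  out <- c(C = mean_polar(0, radii[1], 0, 2 * pi))
  for (ring in 1:2) {
    for (q in names(.quadrant_theta)) {
      th <- .quadrant_theta[[q]]
      out[paste0(q, ring)] <- mean_polar(radii[ring], radii[ring + 1],
                                         th[1], th[2])
    }
  }
  out[ETDRS_SECTORS]
}

#' Finite-difference magnification slope of the raw sector mean
#'
#' Derivative with respect to axial length of the expected *raw* sector mean
#' (device-default grid on an eye of the given axial length), from central
#' differences on [sector_truth()]. Since the corrected sector mean of a
#' surface without biological axial-length terms does not depend on axial
#' length, this is also the expected `d(raw - corrected)/dAL`: the per-mm
#' over- (positive) or under-estimation (negative) by raw measurements.
#'
#' @inheritParams sector_truth
#' @param h Step size (mm) for the central difference.
#' @return Named numeric vector (um per mm of axial length).
#' @export
magnification_slope_truth <- function(model, axial_length,
                                      assumed_axial_length = SPECTRALIS_AXIAL_LENGTH,
                                      h = 0.05, n_nodes = 48) {
  up <- sector_truth(model, axial_length + h, corrected = FALSE,
                     assumed_axial_length = assumed_axial_length,
                     n_nodes = n_nodes)
  lo <- sector_truth(model, axial_length - h, corrected = FALSE,
                     assumed_axial_length = assumed_axial_length,
                     n_nodes = n_nodes)
  (up - lo) / (2 * h)
}
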