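# Continuous ground-truth model of the macular thickness surface.

#' Foveal-pit thickness model
#'
#' A smooth parametric model of full retinal thickness around the fovea:
#' a peripheral baseline, a Gaussian parafoveal annular bump peaking at
#' `r_peak`, and a Gaussian foveal pit centred on the fovea,
#'
#' \deqn{T(r) = t_p + a_{para} e^{-(r - r_{peak})^2 / 2\sigma_{para}^2}
#'            - a_{pit} e^{-r^2 / 2\sigma_{pit}^2},}
#'
#' which is thinnest at the fovea, thickest in the parafovea, and declines
#' gently toward the periphery. Coordinates are retinal millimetres with the
#' nasal direction at positive x.
#'
#' Defaults were chosen once to give anatomically plausible ETDRS sector
#' means (fovea around 240 um, inner ring around 330 um, outer ring around
#' 300 um); they are configuration, not normative values.
#'
#' @param t_periphery Baseline thickness far from the fovea (um).
#' @param a_para Amplitude of the parafoveal bump (um).
#' @param r_peak Radius of the parafoveal maximum (mm); must lie in
#'   (0.5, 2.5).
#' @param sigma_para Width of the parafoveal bump (mm).
#' @param a_pit Depth amplitude of the foveal pit (um).
#' @param sigma_pit Width of the foveal pit (mm).
#' @param nasal_asymmetry Multiplier applied smoothly to the parafoveal bump
#'   on the nasal half-plane (1 = radially symmetric).
#' @param nasal_transition Width (mm) of the smooth nasal/temporal blend.
#' @param al_slope_central,al_slope_peripheral Biological axial-length
#'   thinning effects (um per mm of axial length above
#'   `assumed_axial_length`), blended from the central value at the fovea to
#'   the peripheral value outside the pit. Default 0 (magnification-only
#'   surfaces).
#' @param assumed_axial_length Reference axial length (mm) at which the
#'   biological terms vanish.
#' @return An object of class `pit_model`.
#' @export
pit_model <- function(t_periphery = 270, a_para = 70, r_peak = 0.95,
                      sigma_para = 1.0, a_pit = 75, sigma_pit = 0.35,
                      nasal_asymmetry = 1, nasal_transition = 0.25,
                      al_slope_central = 0, al_slope_peripheral = 0,
                      assumed_axial_length = SPECTRALIS_AXIAL_LENGTH) {
  stopifnot(t_periphery > 0, a_para >= 0, sigma_para > 0, a_pit >= 0,
            sigma_pit > 0, nasal_asymmetry > 0, nasal_transition > 0)
  if (r_peak <= 0.5 || r_peak >= 2.5) {
    stop("r_peak must lie in (0.5, 2.5) mm for a pit-shaped profile",
         call. = FALSE)
  }
  m <- structure(as.list(environment()), class = "pit_model")
  # pit-shaped by construction: verify on a radial grid
  r <- seq(0, 3.5, by = 0.01)
  tt <- pit_thickness(m, r, 0)
  if (any(tt <= 0)) stop("pit_model: thickness must be positive on [0, 3.5] mm",
                         call. = FALSE)
  if (which.min(tt) != 1L) {
    stop("pit_model: thickness minimum must be at the fovea (r = 0); ",
         "chosen amplitudes do not produce a pit", call. = FALSE)
  }
  m
}

#' Evaluate the continuous thickness surface
#'
#' @param model A [pit_model()].
#' @param x,y Retinal coordinates (mm) relative to the foveal centre; x is
#'   positive toward the nasal side. Vectorised.
#' @param axial_length Axial length (mm) of the eye, used only by the
#'   biological thinning terms.
#' @return Thickness in micrometres.
#' @export
pit_thickness <- function(model, x, y, axial_length = model$assumed_axial_length) {
  r2 <- x^2 + y^2
  r <- sqrt(r2)
  bump <- model$a_para * exp(-(r - model$r_peak)^2 / (2 * model$sigma_para^2))
  if (model$nasal_asymmetry != 1) {
    w <- stats::plogis(x / model$nasal_transition)
    bump <- bump * (1 + (model$nasal_asymmetry - 1) * w)
  }
  pit_w <- exp(-r2 / (2 * model$sigma_pit^2))
  out <- model$t_periphery + bump - model$a_pit * pit_w
  dal <- axial_length - model$assumed_axial_length
  if (any(dal != 0) &&
      (model$al_slope_central != 0 || model$al_slope_peripheral != 0)) {
    slope <- model$al_slope_peripheral +
      (model$al_slope_central - model$al_slope_peripheral) * pit_w
    out <- out + dal * slope
  }
  out
}

#' @export
print.pit_model <- function(x, ...) {
  cat(sprintf(
    "pit_model: baseline %.0f um, bump %.0f um @ %.2f mm, pit %.0f um (sigma %.2f mm)\n",
    x$t_periphery, x$a_para, x$r_peak, x$a_pit, x$sigma_pit))
  invisible(x)
}
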