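#' Estimate vesicle capacitance and pore conductance from an admittance step
#'
#' Inverts the from-closed forward model: given a phase-corrected admittance
#' step (`dRe`, `dIm`) at carrier `omega`,
#' \deqn{\hat C_v = \frac{\Delta Re^2 + \Delta Im^2}{\Delta Im\ \omega},
#'   \qquad \hat G_p = \frac{\Delta Re^2 + \Delta Im^2}{\Delta Re}.}
#' The estimators assume the event is an opening from a fully closed pore.
#' Steps with `|dRe|` at or below the resolution floor `epsilon_re` are
#' reported as fully open (`cv = dIm/omega`, no finite `Gp`) — the case I
#' semantics, where the Re projection is indistinguishable from recording
#' noise. Decremental steps (`dRe < -epsilon_re`) violate the from-closed
#' assumption (they require a conducting pre-fused pore); for these the
#' estimators are evaluated on `|dRe|` so the magnitudes remain comparable
#' across cases, but the estimate is flagged `applicable = FALSE` with
#' provenance `"two-state"`.
#'
#' @param delta an [admittance_delta()] with `d_im > 0`; a nonpositive `d_im`
#'   is not an on-step and is an error.
#' @param epsilon_re resolution floor on `|dRe|` in siemens (>= 0). Default 0
#'   (noiseless); pipelines set it from the calibration-segment noise.
#' @return An object of class `pore_estimate`: fields `cv_hat` (farad),
#'   `gp_hat` (siemens, `Inf` when fully open), `fully_open`, `applicable`,
#'   `provenance` (`"from-closed"` or `"two-state"`), and the source `delta`.
#' @examples
#' d <- admittance_from_closed(fF(0.5), pS(30))
#' estimate_cv_gp(d)   # recovers 0.5 fF, 30 pS
#' @export
estimate_cv_gp <- function(delta, epsilon_re = 0) {
  stopifnot(inherits(delta, "admittance_delta"),
            is.numeric(epsilon_re), length(epsilon_re) == 1L, epsilon_re >= 0)
  if (delta$d_im <= 0) {
    stop("estimate_cv_gp(): d_im must be > 0 (not an exocytic on-step)")
  }
  dre <- delta$d_re
  dim <- delta$d_im
  w <- delta$omega
  if (abs(dre) <= epsilon_re) {
    est <- list(cv_hat = dim / w, gp_hat = Inf, fully_open = TRUE,
                applicable = TRUE, provenance = "from-closed", delta = delta)
  } else {
    mag2 <- dre^2 + dim^2
    est <- list(
      cv_hat = mag2 / (dim * w),
      gp_hat = mag2 / abs(dre),
      fully_open = FALSE,
      applicable = dre > 0,
      provenance = if (dre > 0) "from-closed" else "two-state",
      delta = delta
    )
    if (dre < 0) {
      warning("negative dRe: from-closed inversion applied to |dRe|; ",
              "estimate flagged not applicable (two-state event)")
    }
  }
  structure(est, class = "pore_estimate")
}

#' @export
print.pore_estimate <- function(x, ...) {
  gp <- if (x$fully_open) "fully open" else sprintf("%.4g pS", as_pS(x$gp_hat))
  cat(sprintf("pore_estimate: Cv = %.4g fF, Gp = %s [%s%s]\n",
              as_fF(x$cv_hat), gp, x$provenance,
              if (x$applicable) "" else ", not applicable"))
  invisible(x)
}

#' Fusion-pore diameter from its conductance
#'
#' Models the open pore as a cylindrical conductor of length `pore_length`
#' filled with electrolyte of resistivity `resistivity`:
#' `Gp = pi d^2 / (4 rho lambda)`, hence `d = sqrt(4 Gp rho lambda / pi)`.
#' The geometry constants are deliberately arguments, not constants: reported
#' diameters depend on the assumed pore length and luminal resistivity, and
#' published values for both vary.
#'
#' @param gp pore conductance in siemens (>= 0, vectorised).
#' @param pore_length pore (membrane) length in metres (> 0); default 15 nm,
#'   the thickness of two apposed bilayers plus a short neck.
#' @param resistivity electrolyte resistivity in ohm metres (> 0); default
#'   1.0, physiological saline.
#' @return pore diameter in metres.
#' @examples
#' pore_diameter(pS(5)) * 1e9   # ~ 0.31 nm
#' @export
pore_diameter <- function(gp, pore_length = 15e-9, resistivity = 1.0) {
  stopifnot(is.numeric(gp), all(gp >= 0),
            is.numeric(pore_length), pore_length > 0,
            is.numeric(resistivity), resistivity > 0)
  sqrt(4 * gp * resistivity * pore_length / pi)
}

#' @param diameter pore diameter in metres (>= 0, vectorised).
#' @rdname pore_diameter
#' @return `conductance_from_diameter`: pore conductance in siemens.
#' @export
conductance_from_diameter <- function(diameter, pore_length = 15e-9,
                                      resistivity = 1.0) {
  stopifnot(is.numeric(diameter), all(diameter >= 0),
            is.numeric(pore_length), pore_length > 0,
            is.numeric(resistivity), resistivity > 0)
  pi * diameter^2 / (4 * resistivity * pore_length)
}
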