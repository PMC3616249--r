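#' Patch equivalent-circuit parameters
#'
#' The cell-attached patch is modelled as the pipette access resistance
#' `R_A` in series with the patch membrane (whole-cell capacitance `C_m` in
#' parallel with membrane conductance `G_M`). A vesicle fused to the patch
#' adds its own capacitance `Cv` behind a fusion-pore conductance `Gp`, in
#' parallel with the membrane. At the lock-in carrier frequency the circuit
#' attenuates and rotates the vesicle's admittance contribution by the
#' complex factor
#' \deqn{T^2(\omega) = 1 / (1 + R_A G_M + i \omega C_m R_A)^2}
#' whose phase is removed experimentally by adjusting the lock-in phase so
#' that pure capacitance changes project only on the imaginary channel.
#' The default parameters (`R_A = 0`) therefore give `T^2 = 1` exactly, the
#' phase-corrected, unity-gain setting in which amplitudes are analysed;
#' nonzero circuit constants are used to simulate uncorrected recordings.
#'
#' @param access_resistance access resistance `R_A` in ohm (>= 0).
#' @param membrane_conductance membrane conductance `G_M` in siemens (>= 0).
#' @param membrane_capacitance whole-cell capacitance `C_m` in farad (>= 0).
#' @param carrier_frequency lock-in carrier frequency in Hz (> 0); the
#'   recordings emulated here use 1591 or 6400 Hz.
#' @return An object of class `circuit_params` with fields `access_resistance`,
#'   `membrane_conductance`, `membrane_capacitance`, `carrier_frequency`, and
#'   derived `omega` (rad/s), `t_squared` (complex) and `theta` (its phase,
#'   rad).
#' @examples
#' circuit_params()                      # phase-corrected ideal: T^2 = 1
#' circuit_params(10e6, 1e-9, 5e-12)     # attenuated, rotated
#' @export
circuit_params <- function(access_resistance = 0,
                           membrane_conductance = 0,
                           membrane_capacitance = 0,
                           carrier_frequency = 1591) {
  stopifnot(
    is.numeric(access_resistance), length(access_resistance) == 1L,
    access_resistance >= 0,
    is.numeric(membrane_conductance), length(membrane_conductance) == 1L,
    membrane_conductance >= 0,
    is.numeric(membrane_capacitance), length(membrane_capacitance) == 1L,
    membrane_capacitance >= 0,
    is.numeric(carrier_frequency), length(carrier_frequency) == 1L,
    carrier_frequency > 0
  )
  p <- list(
    access_resistance = access_resistance,
    membrane_conductance = membrane_conductance,
    membrane_capacitance = membrane_capacitance,
    carrier_frequency = carrier_frequency,
    omega = 2 * pi * carrier_frequency
  )
  p$t_squared <- 1 / (1 + access_resistance * membrane_conductance +
                        1i * p$omega * membrane_capacitance * access_resistance)^2
  p$theta <- Arg(p$t_squared)
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Patch equivalent-circuit parameters\n")
  cat(sprintf("  R_A = %g ohm, G_M = %g S, C_m = %g F\n",
              x$access_resistance, x$membrane_conductance,
              x$membrane_capacitance))
  cat(sprintf("  carrier %g Hz (omega = %g rad/s)\n",
              x$carrier_frequency, x$omega))
  cat(sprintf("  T^2 = %.6g %+.6gi (|T|^2 = %.6g, theta = %.6g rad)\n",
              Re(x$t_squared), Im(x$t_squared), Mod(x$t_squared), x$theta))
  invisible(x)
}

#' Complex circuit factor T^2(omega)
#'
#' Evaluates `T^2(omega) = 1 / (1 + R_A G_M + i omega C_m R_A)^2`, the
#' attenuation/rotation applied by the patch circuit to the fused vesicle's
#' admittance contribution. With `R_A = 0` it is exactly 1.
#'
#' @param params a [circuit_params()] object.
#' @return a length-1 complex number.
#' @export
t_squared <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  params$t_squared
}

#' Fusion-pore state of a fused vesicle
#'
#' Describes a vesicle of capacitance `Cv` whose fusion pore switches between
#' a pre-fused conductance (`gp_pre`, possibly 0 for a fully closed pore, or
#' small and nonzero for a "nearly closed" pore) and an open conductance
#' (`gp_open`, or fully open, i.e. unbounded). The fully open limit is an
#' explicit flag rather than a large sentinel so the vanishing-Re limit is
#' exact rather than an overflow-prone approximation.
#'
#' @param vesicle_capacitance vesicle capacitance `Cv` in farad (> 0).
#' @param gp_pre pre-fused pore conductance in siemens (>= 0).
#' @param gp_open open pore conductance in siemens, or `NULL` with
#'   `fully_open = TRUE` for the unbounded limit.
#' @param fully_open logical; if `TRUE` the open state is the fully open
#'   (infinite conductance) limit and `gp_open` is ignored.
#' @return An object of class `pore_state`.
#' @examples
#' pore_state(fF(0.5), gp_pre = pS(5), gp_open = pS(30))
#' pore_state(fF(0.9), fully_open = TRUE)   # from closed to fully open
#' @export
pore_state <- function(vesicle_capacitance, gp_pre = 0, gp_open = NULL,
                       fully_open = is.null(gp_open)) {
  stopifnot(
    is.numeric(vesicle_capacitance), length(vesicle_capacitance) == 1L,
    vesicle_capacitance > 0,
    is.numeric(gp_pre), length(gp_pre) == 1L, gp_pre >= 0,
    is.logical(fully_open), length(fully_open) == 1L
  )
  if (!fully_open) {
    stopifnot(is.numeric(gp_open), length(gp_open) == 1L, gp_open >= 0)
  } else {
    gp_open <- Inf
  }
  structure(
    list(vesicle_capacitance = vesicle_capacitance,
         gp_pre = gp_pre, gp_open = gp_open, fully_open = fully_open),
    class = "pore_state"
  )
}

#' @export
print.pore_state <- function(x, ...) {
  open <- if (x$fully_open) "fully open" else sprintf("%.4g pS", as_pS(x$gp_open))
  cat(sprintf("pore_state: Cv = %.4g fF, Gp %s -> %s\n",
              as_fF(x$vesicle_capacitance),
              sprintf("%.4g pS", as_pS(x$gp_pre)), open))
  invisible(x)
}

#' Admittance step (delta Re, delta Im)
#'
#' A measured or modelled change in the demodulated admittance accompanying a
#' fusion event: `d_re` on the real (conductance) channel and `d_im` on the
#' imaginary (capacitance) channel, both in siemens, at carrier `omega`.
#' `d_re` may be negative (decremental, case III, two-state steps); for an
#' opening from a fully closed pore both components are nonnegative.
#'
#' @param d_re real-part step in siemens.
#' @param d_im imaginary-part step in siemens.
#' @param omega carrier angular frequency in rad/s (> 0).
#' @return An object of class `admittance_delta` with accessors via
#'   [as.data.frame.admittance_delta()] reporting pS and `d_im/omega` in fF.
#' @export
admittance_delta <- function(d_re, d_im, omega) {
  stopifnot(
    is.numeric(d_re), length(d_re) == 1L, is.finite(d_re),
    is.numeric(d_im), length(d_im) == 1L, is.finite(d_im),
    is.numeric(omega), length(omega) == 1L, omega > 0
  )
  structure(list(d_re = d_re, d_im = d_im, omega = omega),
            class = "admittance_delta")
}

#' @export
print.admittance_delta <- function(x, ...) {
  cat(sprintf("admittance_delta: dRe = %.4g pS, dIm = %.4g pS (dIm/omega = %.4g fF)\n",
              as_pS(x$d_re), as_pS(x$d_im), as_fF(x$d_im / x$omega)))
  invisible(x)
}

#' @param x an `admittance_delta`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @rdname admittance_delta
#' @export
as.data.frame.admittance_delta <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(d_re_pS = as_pS(x$d_re), d_im_pS = as_pS(x$d_im),
             d_im_fF = as_fF(x$d_im / x$omega), omega = x$omega)
}

# Vectorised from-closed admittance change (T^2 applied), a = omega * Cv.
# Gp = 0 handled by analytic continuation (the limit is 0 + 0i), Gp = Inf by
# the fully open limit i * a.
.delta_from_closed <- function(a, gp, t2) {
  base <- complex(length.out = length(gp))
  open <- is.infinite(gp)
  pos <- !open & gp > 0
  if (any(open)) base[open] <- 1i * a
  if (any(pos)) {
    g <- gp[pos]
    denom <- 1 + (a / g)^2
    base[pos] <- complex(real = a^2 / g / denom, imaginary = a / denom)
  }
  t2 * base
}

#' Admittance change of a pore opening from the closed state
#'
#' Forward model for the admittance step produced when a vesicle of
#' capacitance `Cv`, initially with a fully closed pore, opens to conductance
#' `Gp`:
#' \deqn{\Delta Y = T^2(\omega)\left(\frac{(\omega C_v)^2/G_p}{1 + (\omega
#'   C_v/G_p)^2} + \frac{i\,\omega C_v}{1 + (\omega C_v/G_p)^2}\right)}
#' With `T^2 = 1` this is `dRe = (w Cv)^2 Gp / (Gp^2 + (w Cv)^2)` and
#' `dIm = w Cv Gp^2 / (Gp^2 + (w Cv)^2)`. In the fully open limit
#' (`Gp -> Inf`) the real part vanishes and `dY = i T^2 w Cv`; for `Gp = 0`
#' the limit `(0, 0)` is returned analytically, never by numeric division.
#'
#' @param vesicle_capacitance vesicle capacitance in farad (> 0).
#' @param gp pore conductance in siemens (>= 0); ignored when
#'   `fully_open = TRUE`.
#' @param params a [circuit_params()] object (default: phase-corrected,
#'   `T^2 = 1`).
#' @param fully_open logical; evaluate the `Gp -> Inf` limit.
#' @return an [admittance_delta()].
#' @examples
#' # fully open 0.5 fF vesicle at 1591 Hz: dRe = 0, dIm = w Cv ~ 5 pS
#' admittance_from_closed(fF(0.5), fully_open = TRUE)
#' # incompletely open pore: both components finite
#' admittance_from_closed(fF(0.5), pS(30))
#' @export
admittance_from_closed <- function(vesicle_capacitance, gp = NULL,
                                   params = circuit_params(),
                                   fully_open = is.null(gp)) {
  stopifnot(inherits(params, "circuit_params"),
            is.numeric(vesicle_capacitance),
            length(vesicle_capacitance) == 1L, vesicle_capacitance > 0)
  gp <- if (fully_open) Inf else gp
  stopifnot(is.numeric(gp), length(gp) == 1L, gp >= 0)
  a <- params$omega * vesicle_capacitance
  y <- .delta_from_closed(a, gp, params$t_squared)
  admittance_delta(Re(y), Im(y), params$omega)
}

#' Admittance step between two pore states
#'
#' Difference of the from-closed admittance change evaluated at the open and
#' pre-fused conductances of a [pore_state()]. With `T^2 = 1` the sign of the
#' real part equals the sign of `(w Cv)^2 - gp_pre * gp_open`: a small vesicle
#' opening from a nearly closed pore yields a decremental Re projection
#' (case III), while the same conductance change on a large vesicle yields an
#' incremental one (case II). A decremental Re step is only possible when the
#' pre-fused pore is nearly closed (conducting), never from a fully closed
#' pore.
#'
#' @param pore a [pore_state()]; `gp_pre` and the open state must not both be
#'   fully open limits unless they are equal.
#' @param params a [circuit_params()] object.
#' @return an [admittance_delta()].
#' @examples
#' p <- pore_state(fF(0.5), gp_pre = pS(5), gp_open = pS(30))
#' step_between_states(p)   # dRe < 0, dIm > 0: case III signature
#' @export
step_between_states <- function(pore, params = circuit_params()) {
  stopifnot(inherits(pore, "pore_state"), inherits(params, "circuit_params"))
  a <- params$omega * pore$vesicle_capacitance
  y <- .delta_from_closed(a, pore$gp_open, params$t_squared) -
    .delta_from_closed(a, pore$gp_pre, params$t_squared)
  admittance_delta(Re(y), Im(y), params$omega)
}

#' Pore conductance maximising the real-part step
#'
#' For a from-closed opening the real part `dRe(Gp) = a^2 Gp / (Gp^2 + a^2)`
#' (with `a = w Cv`, `T^2` a constant scale) is maximal exactly at
#' `Gp* = w Cv`: small vesicles peak at lower pore conductances than large
#' ones, which is why an incomplete opening from a shared nearly closed state
#' sits on the falling limb for a small vesicle (decremental step) and the
#' rising limb for a large one (incremental step).
#'
#' @param vesicle_capacitance vesicle capacitance in farad (> 0).
#' @param params a [circuit_params()] object (only the carrier enters).
#' @return the maximising conductance in siemens.
#' @examples
#' as_pS(re_argmax_conductance(fF(0.5)))   # ~ 5 pS at 1591 Hz
#' @export
re_argmax_conductance <- function(vesicle_capacitance,
                                  params = circuit_params()) {
  stopifnot(inherits(params, "circuit_params"),
            is.numeric(vesicle_capacitance),
            length(vesicle_capacitance) == 1L, vesicle_capacitance > 0)
  params$omega * vesicle_capacitance
}

#' Tabulate the forward model over a pore-conductance grid
#'
#' Evaluates the from-closed admittance change over a grid of pore
#' conductances for one or more vesicle sizes, for plotting or CSV export of
#' the dRe(Gp)/dIm(Gp) curves.
#'
#' @param vesicle_capacitance vector of vesicle capacitances in farad.
#' @param gp vector of pore conductances in siemens (default: 400-point grid
#'   over 0.5--100 pS).
#' @param params a [circuit_params()] object.
#' @param file optional path; when given the table is also written as CSV.
#' @return a data.frame with columns `cv_fF`, `gp_pS`, `d_re_pS`, `d_im_pS`.
#' @examples
#' head(admittance_curve(fF(c(0.5, 4))))
#' @export
admittance_curve <- function(vesicle_capacitance,
                             gp = pS(seq(0.5, 100, length.out = 400)),
                             params = circuit_params(), file = NULL) {
  stopifnot(inherits(params, "circuit_params"),
            all(vesicle_capacitance > 0), all(gp >= 0))
  out <- do.call(rbind, lapply(vesicle_capacitance, function(cv) {
    y <- .delta_from_closed(params$omega * cv, gp, params$t_squared)
    data.frame(cv_fF = as_fF(cv), gp_pS = as_pS(gp),
               d_re_pS = as_pS(Re(y)), d_im_pS = as_pS(Im(y)))
  }))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
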