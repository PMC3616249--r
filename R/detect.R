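# Phase recovery from calibration pulses and on/off step detection on the
# demodulated channels.

#' Step-detection parameters
#'
#' @param window sliding-window half-width in samples (>= 2). The change
#'   statistic is the difference of the means of `window` samples on either
#'   side of a candidate edge.
#' @param threshold_k detection threshold in multiples of the noise SD of
#'   that mean difference (> 0).
#' @param min_event_duration minimum on/off separation in seconds.
#' @param pairing_tolerance maximum relative mismatch between on and off
#'   amplitudes for pairing, in (0, 1).
#' @param epsilon_re resolution floor on `|dRe|` in siemens, or `"auto"`
#'   (default) to use 3x the standard error of the plateau-difference
#'   amplitude estimate, propagated from the Re-channel baseline noise.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(window = 20, threshold_k = 5,
                             min_event_duration = 0.1,
                             pairing_tolerance = 0.25,
                             epsilon_re = "auto") {
  stopifnot(window >= 2, threshold_k > 0, min_event_duration > 0,
            pairing_tolerance > 0, pairing_tolerance < 1)
  if (!identical(epsilon_re, "auto")) {
    stopifnot(is.numeric(epsilon_re), epsilon_re >= 0)
  }
  structure(list(window = as.integer(window), threshold_k = threshold_k,
                 min_event_duration = min_event_duration,
                 pairing_tolerance = pairing_tolerance,
                 epsilon_re = epsilon_re),
            class = "detection_params")
}

# Robust per-sample noise SD: MAD of first differences / sqrt(2). Immune to
# the step offsets that contaminate a plain SD.
.noise_sd <- function(x) {
  if (length(x) < 3) return(NA_real_)
  stats::mad(diff(x)) / sqrt(2)
}

# Logical mask of samples inside calibration epochs (with margin, seconds).
.calib_mask <- function(trace, margin) {
  ct <- calib_times(trace$config)
  masked <- rep(FALSE, length(trace$time))
  for (tc in ct) {
    masked <- masked | (trace$time >= tc - margin &
                          trace$time < tc + trace$config$calib_width + margin)
  }
  masked
}

#' Recover the lock-in phase from calibration pulses
#'
#' A calibration pulse is a pure capacitance step, so after correct phase
#' setting it projects only on the Im channel. This routine measures the
#' complex step of every calibration pulse on the schedule recorded in the
#' trace config (plateau means just before vs during the pulse) and returns
#' the angle `theta` by which the recorded signal is rotated away from pure
#' Im, estimated in least squares as the argument of the summed complex
#' steps. Rotating the trace by `-theta` (see [rotate_trace()]) nullifies
#' the calibration pulses' Re projection. Per-channel noise SDs are
#' estimated from calibration-free samples via the median absolute
#' deviation of first differences.
#'
#' @param trace a `lockin_trace` containing at least one calibration pulse.
#' @param calib_capacitance calibration pulse size in farad; defaults to the
#'   trace config's value.
#' @return list with `theta` (rad, in (-pi, pi]), `noise_sd_re`,
#'   `noise_sd_im` (siemens), `n_pulses`, and `steps` (per-pulse complex
#'   step amplitudes).
#' @export
estimate_phase <- function(trace, calib_capacitance = NULL) {
  stopifnot(inherits(trace, "lockin_trace"))
  cfg <- trace$config
  if (is.null(calib_capacitance)) calib_capacitance <- cfg$calib_capacitance
  ct <- calib_times(cfg)
  if (!length(ct)) {
    stop("estimate_phase(): trace contains no calibration pulses")
  }
  fs <- cfg$sampling_rate
  m <- 2 / fs  # trim 2 samples at each plateau edge
  pw <- cfg$calib_width
  steps <- complex(0)
  for (tc in ct) {
    pre <- trace$time >= tc - pw + m & trace$time < tc - m
    dur <- trace$time >= tc + m & trace$time < tc + pw - m
    if (sum(pre) < 2 || sum(dur) < 2) {
      stop("estimate_phase(): calibration pulse at t = ", tc,
           " has too few clean samples (clipped or mis-scheduled)")
    }
    steps <- c(steps, complex(
      real = mean(trace$re[dur]) - mean(trace$re[pre]),
      imaginary = mean(trace$im[dur]) - mean(trace$im[pre])))
  }
  expected <- 1i * 2 * pi * cfg$carrier_frequency * calib_capacitance
  if (any(Mod(steps) < 0.1 * Mod(expected))) {
    stop("estimate_phase(): calibration pulse amplitude far below ",
         "omega * C_cal; pulse clipped or absent")
  }
  theta <- Arg(sum(steps)) - pi / 2
  theta <- Arg(exp(1i * theta))  # wrap to (-pi, pi]
  masked <- .calib_mask(trace, margin = m)
  list(theta = theta,
       noise_sd_re = .noise_sd(trace$re[!masked]),
       noise_sd_im = .noise_sd(trace$im[!masked]),
       n_pulses = length(ct),
       steps = steps)
}

#' Rotate a trace's complex admittance signal
#'
#' Multiplies `re + i im` by `exp(-i theta)`, undoing a lock-in phase error
#' of `theta` as estimated by [estimate_phase()].
#'
#' @param trace a `lockin_trace`.
#' @param theta rotation angle in rad.
#' @return the phase-corrected `lockin_trace`.
#' @export
rotate_trace <- function(trace, theta) {
  stopifnot(inherits(trace, "lockin_trace"), is.numeric(theta),
            length(theta) == 1L)
  y <- complex(real = trace$re, imaginary = trace$im) * exp(-1i * theta)
  trace$re <- Re(y)
  trace$im <- Im(y)
  trace$config$phase_error <- trace$config$phase_error - theta
  trace
}

# Plateau mean of channel x over sample indices (lo, hi], excluding masked
# samples and trimming `g` samples at each end (reduced when the segment is
# short, keeping at least a third of it).
.plateau_mean <- function(x, masked, lo, hi, g) {
  idx <- seq.int(lo + 1L, hi)
  len <- length(idx)
  g_eff <- min(g, max(0L, (len - 2L) %/% 3L))
  if (len > 2L * g_eff) {
    idx <- idx[seq.int(g_eff + 1L, len - g_eff)]
  }
  idx <- idx[!masked[idx]]
  if (!length(idx)) return(NA_real_)
  mean(x[idx])
}

#' Detect and pair capacitance steps in a lock-in trace
#'
#' Change points are found on the Im (capacitance) channel: the statistic is
#' the difference of adjacent `window`-sample means, flagged where its
#' magnitude exceeds `threshold_k` times its noise SD, with contiguous
#' same-sign excursions collapsed to the location of their extremum.
#' Calibration-pulse epochs are masked out of detection and of all plateau
#' averages. On-steps (Im up) are paired with the next off-step (Im down)
#' when the amplitudes agree within `pairing_tolerance` and the separation
#' is at least `min_event_duration`; unpaired on-steps are returned in the
#' `unpaired` attribute, never silently dropped. Step amplitudes on both
#' channels are differences of plateau means around the on edge, excluding
#' half a window next to each edge — the Re amplitude is measured passively
#' at the epochs defined by the Im channel, mirroring how an event is
#' defined by its capacitance step while its Re projection may be zero.
#'
#' @param trace a phase-corrected `lockin_trace`.
#' @param params a [detection_params()].
#' @return a data.frame of class `detected_steps` with columns `t_on`,
#'   `t_off`, `d_re`, `d_im` (siemens), `d_re_pS`, `d_im_pS`; attributes
#'   `noise_sd_re`, `noise_sd_im`, `epsilon_re` (the resolved floor, S) and
#'   `unpaired` (data.frame of unmatched on-steps).
#' @export
detect_steps <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "lockin_trace"),
            inherits(params, "detection_params"))
  w <- params$window
  fs <- trace$config$sampling_rate
  im <- trace$im
  re <- trace$re
  n <- length(im)
  masked <- .calib_mask(trace, margin = w / fs)

  empty <- data.frame(t_on = numeric(0), t_off = numeric(0),
                      d_re = numeric(0), d_im = numeric(0),
                      d_re_pS = numeric(0), d_im_pS = numeric(0))
  sd_im <- .noise_sd(im[!masked])
  sd_re <- .noise_sd(re[!masked])
  # SE of a difference of two window means; floor guards the noiseless case
  se_diff <- function(s) s * sqrt(2 / w)
  eps <- if (identical(params$epsilon_re, "auto")) {
    3 * se_diff(sd_re)
  } else {
    params$epsilon_re
  }
  finish <- function(df, unpaired) {
    structure(df, class = c("detected_steps", "data.frame"),
              noise_sd_re = sd_re, noise_sd_im = sd_im, epsilon_re = eps,
              unpaired = unpaired)
  }
  if (n < 2 * w + 2) return(finish(empty, empty))

  # d[c] = mean(im[(c+1):(c+w)]) - mean(im[(c-w+1):c]) via cumulative sums
  cs <- c(0, cumsum(im))
  cpos <- seq.int(w, n - w)
  d <- (cs[cpos + w + 1] - cs[cpos + 1]) / w - (cs[cpos + 1] - cs[cpos - w + 1]) / w
  thr <- max(params$threshold_k * se_diff(sd_im),
             1e-9 * max(abs(im), na.rm = TRUE),
             .Machine$double.xmin)
  # positions whose windows touch masked samples are unusable
  cm <- c(0, cumsum(masked))
  touches <- (cm[cpos + w + 1] - cm[cpos - w + 1]) > 0
  cand <- which(abs(d) > thr & !touches)

  if (!length(cand)) return(finish(empty, empty))

  # collapse contiguous same-sign runs to the extremum position
  runs <- split(cand, cumsum(c(TRUE, diff(cand) > 1 |
                                 sign(d[cand])[-1] != sign(d[cand])[-length(cand)])))
  cp <- vapply(runs, function(r) cpos[r[which.max(abs(d[r]))]], numeric(1))
  cp <- sort(unname(cp))

  # plateau-mean amplitudes at each change point
  g <- as.integer(ceiling(w / 2))
  bounds <- c(0L, as.integer(cp), n)
  k_n <- length(cp)
  amp_im <- amp_re <- numeric(k_n)
  for (k in seq_len(k_n)) {
    pre_im <- .plateau_mean(im, masked, bounds[k], bounds[k + 1], g)
    post_im <- .plateau_mean(im, masked, bounds[k + 1], bounds[k + 2], g)
    pre_re <- .plateau_mean(re, masked, bounds[k], bounds[k + 1], g)
    post_re <- .plateau_mean(re, masked, bounds[k + 1], bounds[k + 2], g)
    amp_im[k] <- post_im - pre_im
    amp_re[k] <- post_re - pre_re
  }

  keep <- is.finite(amp_im)
  cp <- cp[keep]; amp_im <- amp_im[keep]; amp_re <- amp_re[keep]

  # pair on-steps with the following off-step
  events <- empty
  unpaired <- empty
  k <- 1L
  while (k <= length(cp)) {
    if (amp_im[k] > 0) {
      paired <- FALSE
      if (k < length(cp) && amp_im[k + 1] < 0) {
        sep <- (cp[k + 1] - cp[k]) / fs
        if (sep >= params$min_event_duration &&
            abs(amp_im[k] + amp_im[k + 1]) <=
              params$pairing_tolerance * abs(amp_im[k])) {
          events <- rbind(events, data.frame(
            t_on = trace$time[cp[k] + 1L], t_off = trace$time[cp[k + 1] + 1L],
            d_re = amp_re[k], d_im = amp_im[k],
            d_re_pS = as_pS(amp_re[k]), d_im_pS = as_pS(amp_im[k])))
          paired <- TRUE
          k <- k + 2L
        }
      }
      if (!paired) {
        unpaired <- rbind(unpaired, data.frame(
          t_on = trace$time[cp[k] + 1L], t_off = NA_real_,
          d_re = amp_re[k], d_im = amp_im[k],
          d_re_pS = as_pS(amp_re[k]), d_im_pS = as_pS(amp_im[k])))
        k <- k + 1L
      }
    } else {
      k <- k + 1L  # off-step without a preceding on-step
    }
  }
  finish(events, unpaired)
}
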