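# Synthetic lock-in trace generation: the stand-in for cell-attached
# recordings, with ground truth for every downstream stage.

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration for a synthetic lock-in trace
#'
#' Describes a demodulated cell-attached recording: the lock-in carrier, the
#' sampling of the demodulated Re/Im channels, per-channel additive Gaussian
#' noise, an optional uncorrected lock-in phase error, and the periodic
#' capacitance calibration pulses used to set (and later recover) the phase.
#' Simulation operates at the demodulated (Re, Im) level: the analysis
#' consumes lock-in outputs, so synthesising the raw carrier-frequency
#' current would add nothing testable. The 111 mV sine stimulus of the
#' emulated recordings exists only upstream of this representation.
#'
#' @param duration trace length in seconds (> 0).
#' @param sampling_rate demodulated-channel sampling rate in Hz (default 100,
#'   typical for lock-in capacitance traces).
#' @param carrier_frequency lock-in carrier in Hz (default 1591; recordings
#'   of this kind use 1591 or 6400 Hz).
#' @param noise_sd_re,noise_sd_im additive white Gaussian noise SD per
#'   channel, in siemens (>= 0).
#' @param phase_error uncorrected lock-in phase error in rad (default 0); the
#'   whole (Re + i Im) signal is rotated by this angle.
#' @param calib_capacitance calibration pulse size in farad (default 10 fF).
#' @param calib_period seconds between calibration pulses (default 10).
#' @param calib_width calibration pulse width in seconds (default 0.5).
#' @param seed integer RNG seed; identical configs give identical traces.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration,
                       sampling_rate = 100,
                       carrier_frequency = 1591,
                       noise_sd_re = 0,
                       noise_sd_im = 0,
                       phase_error = 0,
                       calib_capacitance = fF(10),
                       calib_period = 10,
                       calib_width = 0.5,
                       seed = 1L) {
  stopifnot(duration > 0, sampling_rate > 0, carrier_frequency > 0,
            noise_sd_re >= 0, noise_sd_im >= 0,
            calib_capacitance >= 0, calib_period > calib_width,
            calib_width > 0)
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         carrier_frequency = carrier_frequency,
         noise_sd_re = noise_sd_re, noise_sd_im = noise_sd_im,
         phase_error = phase_error,
         calib_capacitance = calib_capacitance,
         calib_period = calib_period, calib_width = calib_width,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %g s @ %g Hz, carrier %g Hz\n",
    "  noise SD (Re, Im) = (%g, %g) pS, phase error %g rad\n",
    "  calibration %g fF every %g s (width %g s), seed %d\n"),
    x$duration, x$sampling_rate, x$carrier_frequency,
    as_pS(x$noise_sd_re), as_pS(x$noise_sd_im), x$phase_error,
    as_fF(x$calib_capacitance), x$calib_period, x$calib_width, x$seed))
  invisible(x)
}

# Calibration pulse onset times for a config.
calib_times <- function(config) {
  if (config$calib_period > config$duration) return(numeric(0))
  t <- seq(config$calib_period, config$duration, by = config$calib_period)
  t[t + config$calib_width <= config$duration]
}

#' A single transient exocytic event specification
#'
#' One reversible fusion event: an on-step at `t_on`, a plateau of `duration`
#' seconds, and an off-step of equal magnitude, with the vesicle/pore
#' parameters of `pore` determining the (Re, Im) plateau offset via the
#' equivalent-circuit forward model.
#'
#' @param t_on onset time in seconds (>= 0).
#' @param duration open duration in seconds (> 0).
#' @param pore a [pore_state()].
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(t_on, duration, pore) {
  stopifnot(t_on >= 0, duration > 0, inherits(pore, "pore_state"))
  structure(list(t_on = t_on, duration = duration, pore = pore),
            class = "event_spec")
}

#' Cell-type profile for event sampling
#'
#' Distributional defaults for synthetic event ensembles, anchored on
#' representative recordings: lactotrophs carry larger secretory vesicles
#' (representative unitary events of 0.9, 4.0 and 1.2 fF) and astrocytes
#' smaller ones (0.3, 1.6, 0.6 fF); decremental-Re (case III) events are
#' considerably more frequent in astrocytes. Vesicle capacitance is drawn
#' log-normally. The nearly closed pre-fused conductance range is centred on
#' ~5 pS (lactotroph) / ~2 pS (astrocyte) and the incompletely open range on
#' 20--60 pS, below the fully open regime.
#'
#' @param name `"lactotroph"`, `"astrocyte"`, or `"custom"`.
#' @param cv_median median vesicle capacitance in farad.
#' @param cv_sigma log-normal sigma (SD of log Cv).
#' @param case_mix length-3 probability vector for intended cases I, II, III
#'   (must sum to 1).
#' @param gp_pre_range length-2 range (siemens) for nearly closed pre-fused
#'   conductances.
#' @param gp_open_range length-2 range (siemens) for incompletely open
#'   conductances.
#' @return An object of class `cell_profile`.
#' @examples
#' cell_profile("astrocyte")
#' @export
cell_profile <- function(name = c("lactotroph", "astrocyte", "custom"),
                         cv_median = NULL, cv_sigma = 0.6,
                         case_mix = NULL,
                         gp_pre_range = NULL,
                         gp_open_range = pS(c(20, 60))) {
  name <- match.arg(name)
  defaults <- switch(name,
    lactotroph = list(cv_median = fF(1.2), case_mix = c(0.45, 0.40, 0.15),
                      gp_pre_range = pS(c(2, 8))),
    astrocyte  = list(cv_median = fF(0.6), case_mix = c(0.30, 0.25, 0.45),
                      gp_pre_range = pS(c(1, 4))),
    custom     = list(cv_median = fF(1.0), case_mix = c(1, 1, 1) / 3,
                      gp_pre_range = pS(c(2, 8)))
  )
  cv_median <- if (is.null(cv_median)) defaults$cv_median else cv_median
  case_mix <- if (is.null(case_mix)) defaults$case_mix else case_mix
  gp_pre_range <- if (is.null(gp_pre_range)) defaults$gp_pre_range else gp_pre_range
  stopifnot(cv_median > 0, cv_sigma >= 0,
            length(case_mix) == 3, all(case_mix >= 0),
            abs(sum(case_mix) - 1) < 1e-9,
            length(gp_pre_range) == 2, all(gp_pre_range > 0),
            diff(gp_pre_range) >= 0,
            length(gp_open_range) == 2, all(gp_open_range > 0),
            diff(gp_open_range) >= 0)
  structure(list(name = name, cv_median = cv_median, cv_sigma = cv_sigma,
                 case_mix = stats::setNames(case_mix, c("I", "II", "III")),
                 gp_pre_range = gp_pre_range,
                 gp_open_range = gp_open_range),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "cell_profile '%s': Cv ~ lognormal(median %.3g fF, sigma %.2g)\n",
    "  case mix I/II/III = %.2f/%.2f/%.2f\n",
    "  Gp pre %s pS, open %s pS\n"),
    x$name, as_fF(x$cv_median), x$cv_sigma,
    x$case_mix[1], x$case_mix[2], x$case_mix[3],
    paste(as_pS(x$gp_pre_range), collapse = "-"),
    paste(as_pS(x$gp_open_range), collapse = "-")))
  invisible(x)
}

# Draw one pore_state realising the intended case's dRe sign at carrier
# omega. Case I is a fully closed -> fully open transition (dRe exactly 0);
# case II requires (w Cv)^2 > gp_pre * gp_open, case III the reverse
# (possible only from a conducting, nearly closed pre-fused pore).
# Resamples until the sign boundary is satisfied.
.draw_pore <- function(case, profile, omega, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    cv <- stats::rlnorm(1, meanlog = log(profile$cv_median),
                        sdlog = profile$cv_sigma)
    if (case == "I") return(pore_state(cv, gp_pre = 0, fully_open = TRUE))
    pre <- if (case == "II" && stats::runif(1) < 0.5) 0 else
      stats::runif(1, profile$gp_pre_range[1], profile$gp_pre_range[2])
    open <- stats::runif(1, profile$gp_open_range[1], profile$gp_open_range[2])
    a2 <- (omega * cv)^2
    ok <- if (case == "II") a2 > pre * open else a2 < pre * open
    if (ok) return(pore_state(cv, gp_pre = pre, gp_open = open))
  }
  stop("could not realise a case ", case, " event within ", max_tries,
       " draws; profile and carrier are incompatible")
}

#' Sample a synthetic event ensemble for a cell type
#'
#' Draws `n` non-overlapping transient exocytic events: vesicle capacitance
#' from the profile's log-normal, the intended case from its case mix, and
#' pre/open pore conductances resampled until the intended case's Re-step
#' sign is realised (checked against the analytic sign boundary
#' `(w Cv)^2` vs `gp_pre * gp_open`). Event durations are uniform on
#' 0.2--5 s; onsets are placed uniformly, keeping `margin` seconds of clear
#' baseline around every event and avoiding calibration-pulse epochs when a
#' config is supplied.
#'
#' @param profile a [cell_profile()].
#' @param n number of events (>= 0).
#' @param duration trace duration the events must fit in, seconds.
#' @param seed integer RNG seed (deterministic output).
#' @param config optional [sim_config()]; its calibration schedule is
#'   avoided and its carrier sets the sign boundary (default carrier
#'   1591 Hz otherwise).
#' @param margin clear baseline kept around each event and calibration
#'   pulse, seconds.
#' @param duration_range range of event open durations, seconds.
#' @return list of [event_spec()], sorted by onset. Each carries the
#'   intended case as attribute `"case"`.
#' @export
sample_cell_events <- function(profile, n, duration, seed = 1L,
                               config = NULL, margin = 0.5,
                               duration_range = c(0.2, 5)) {
  stopifnot(inherits(profile, "cell_profile"), n >= 0, duration > 0,
            length(duration_range) == 2, all(duration_range > 0))
  if (n == 0) return(list())
  omega <- 2 * pi * if (is.null(config)) 1591 else config$carrier_frequency
  forbidden <- if (is.null(config)) {
    matrix(numeric(0), ncol = 2)
  } else {
    ct <- calib_times(config)
    cbind(ct - margin, ct + config$calib_width + margin)
  }
  .with_seed(seed, {
    events <- list()
    occupied <- forbidden
    for (k in seq_len(n)) {
      dur <- stats::runif(1, duration_range[1], duration_range[2])
      placed <- FALSE
      for (try in 1:2000) {
        t_on <- stats::runif(1, margin, duration - dur - margin)
        lo <- t_on - margin
        hi <- t_on + dur + margin
        if (!any(lo < occupied[, 2] & hi > occupied[, 1])) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n, " events of mean duration ",
             mean(duration_range), " s in ", duration,
             " s; trace too short or too crowded")
      }
      case <- sample(c("I", "II", "III"), 1, prob = profile$case_mix)
      ev <- event_spec(t_on, dur, .draw_pore(case, profile, omega))
      attr(ev, "case") <- case
      events[[k]] <- ev
      occupied <- rbind(occupied, c(lo, hi))
    }
    events[order(vapply(events, `[[`, numeric(1), "t_on"))]
  })
}

#' Sample pore states for an ensemble study
#'
#' Draws `n` vesicle/pore parameter sets from a cell profile without placing
#' them on a time axis — the input for forward-model ensemble studies such
#' as per-case dIm-vs-dRe correlation analyses. Cases are drawn from the
#' profile's mix unless `case` fixes one; the intended case's Re-step sign
#' is always realised (resampled against the analytic sign boundary).
#'
#' @param profile a [cell_profile()].
#' @param n number of draws (>= 0).
#' @param seed integer RNG seed.
#' @param case optional `"I"`, `"II"` or `"III"` to force every draw.
#' @param carrier_frequency carrier in Hz defining the sign boundary.
#' @return list of [pore_state()], each with the case as attribute `"case"`.
#' @examples
#' ps <- sample_pore_states(cell_profile("astrocyte"), 5, seed = 1,
#'                          case = "III")
#' @export
sample_pore_states <- function(profile, n, seed = 1L, case = NULL,
                               carrier_frequency = 1591) {
  stopifnot(inherits(profile, "cell_profile"), n >= 0)
  if (!is.null(case)) stopifnot(case %in% c("I", "II", "III"))
  omega <- 2 * pi * carrier_frequency
  .with_seed(seed, {
    lapply(seq_len(n), function(k) {
      cs <- if (is.null(case)) {
        sample(c("I", "II", "III"), 1, prob = profile$case_mix)
      } else {
        case
      }
      p <- .draw_pore(cs, profile, omega)
      attr(p, "case") <- cs
      p
    })
  })
}

#' Generate a synthetic demodulated lock-in trace
#'
#' Builds the (Re, Im) channels of a cell-attached recording: zero baseline;
#' for each event a plateau offset equal to the equivalent-circuit two-state
#' step for its pore (phase-corrected, `T^2 = 1`); calibration pulses adding
#' a pure capacitance step (`dRe = 0`, `dIm = omega * calib_capacitance`) on
#' schedule; the whole complex signal rotated by the config's `phase_error`;
#' then additive white Gaussian noise per channel. Step edges are
#' instantaneous (single-sample transitions). Identical configs and events
#' give identical traces.
#'
#' @param config a [sim_config()].
#' @param events list of [event_spec()]; must fit within the duration and
#'   must not overlap each other or a calibration pulse.
#' @return An object of class `lockin_trace`: fields `time`, `re`, `im`
#'   (equal-length numeric vectors, siemens), `config`, and `ground_truth`
#'   (a data.frame of the true event times, amplitudes and case labels).
#' @examples
#' cfg <- sim_config(duration = 30, seed = 7)
#' ev <- list(event_spec(3, 2, pore_state(fF(0.5), pS(5), pS(30))))
#' tr <- generate_trace(cfg, ev)
#' @export
generate_trace <- function(config, events = list()) {
  stopifnot(inherits(config, "sim_config"))
  lapply(events, function(e) stopifnot(inherits(e, "event_spec")))
  fs <- config$sampling_rate
  n <- floor(config$duration * fs)
  time <- (seq_len(n) - 1) / fs
  params <- circuit_params(carrier_frequency = config$carrier_frequency)
  omega <- params$omega

  # event intervals, sorted; check containment and overlaps
  if (length(events)) {
    t_on <- vapply(events, `[[`, numeric(1), "t_on")
    events <- events[order(t_on)]
    ivl <- t(vapply(events, function(e) c(e$t_on, e$t_on + e$duration),
                    numeric(2)))
    if (any(ivl[, 2] > config$duration)) {
      stop("events extend beyond the trace duration")
    }
    if (nrow(ivl) > 1 && any(ivl[-1, 1] < ivl[-nrow(ivl), 2])) {
      stop("events overlap")
    }
  }

  ct <- calib_times(config)
  if (length(events) && length(ct)) {
    for (k in seq_along(ct)) {
      if (any(ivl[, 1] < ct[k] + config$calib_width & ivl[, 2] > ct[k])) {
        stop("an event collides with the calibration pulse at t = ", ct[k])
      }
    }
  }

  rot <- exp(1i * config$phase_error)
  y <- complex(length.out = n)

  for (k in seq_along(ct)) {
    idx <- time >= ct[k] & time < ct[k] + config$calib_width
    y[idx] <- y[idx] + rot * 1i * omega * config$calib_capacitance
  }

  gt <- data.frame(t_on = numeric(0), t_off = numeric(0),
                   cv_fF = numeric(0), gp_pre_pS = numeric(0),
                   gp_open_pS = numeric(0), d_re_pS = numeric(0),
                   d_im_pS = numeric(0), case = character(0))
  for (e in events) {
    d <- step_between_states(e$pore, params)
    idx <- time >= e$t_on & time < e$t_on + e$duration
    y[idx] <- y[idx] + rot * complex(real = d$d_re, imaginary = d$d_im)
    case <- attr(e, "case")
    if (is.null(case)) case <- .classify(d$d_re, d$d_im, 0)
    gt <- rbind(gt, data.frame(
      t_on = e$t_on, t_off = e$t_on + e$duration,
      cv_fF = as_fF(e$pore$vesicle_capacitance),
      gp_pre_pS = as_pS(e$pore$gp_pre),
      gp_open_pS = as_pS(e$pore$gp_open),
      d_re_pS = as_pS(d$d_re), d_im_pS = as_pS(d$d_im), case = case))
  }

  re <- Re(y)
  im <- Im(y)
  if (config$noise_sd_re > 0 || config$noise_sd_im > 0) {
    noise <- .with_seed(config$seed, list(
      re = stats::rnorm(n, 0, config$noise_sd_re),
      im = stats::rnorm(n, 0, config$noise_sd_im)))
    re <- re + noise$re
    im <- im + noise$im
  }

  structure(list(time = time, re = re, im = im, config = config,
                 ground_truth = gt),
            class = "lockin_trace")
}

#' @export
print.lockin_trace <- function(x, ...) {
  cat(sprintf(
    "lockin_trace: %d samples @ %g Hz (%g s), carrier %g Hz, %d ground-truth event(s)\n",
    length(x$time), x$config$sampling_rate, x$config$duration,
    x$config$carrier_frequency, nrow(x$ground_truth)))
  invisible(x)
}

#' Plot a lock-in trace
#'
#' Stacked Im (capacitance) and Re (conductance) channels in pS against
#' time, with ground-truth event onsets marked when present.
#'
#' @param x a `lockin_trace`.
#' @param ... passed to [plot()].
#' @export
plot.lockin_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, as_pS(x$im), type = "l", xlab = "",
                 ylab = "Im (pS)", ...)
  if (nrow(x$ground_truth)) {
    graphics::abline(v = x$ground_truth$t_on, col = "grey70", lty = 3)
  }
  graphics::plot(x$time, as_pS(x$re), type = "l", xlab = "time (s)",
                 ylab = "Re (pS)", ...)
  if (nrow(x$ground_truth)) {
    graphics::abline(v = x$ground_truth$t_on, col = "grey70", lty = 3)
  }
  invisible(x)
}

#' Write / read a lock-in trace as CSV plus JSON sidecar
#'
#' The trace samples go to a three-column CSV (`time`, `re`, `im`, SI units);
#' the configuration and ground-truth events go to `<file>.json`. The pair
#' round-trips exactly at full double precision.
#'
#' @param trace a `lockin_trace`.
#' @param file path of the CSV file; the sidecar is `<file>.json`.
#' @return `write_trace`: `file`, invisibly. `read_trace`: a `lockin_trace`.
#' @export
write_trace <- function(trace, file) {
  stopifnot(inherits(trace, "lockin_trace"))
  df <- data.frame(time = trace$time, re = trace$re, im = trace$im)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   file, row.names = FALSE, quote = FALSE)
  gt_out <- trace$ground_truth
  if (nrow(gt_out)) {
    # JSON has no Inf; fully open conductances travel as strings
    gt_out$gp_open_pS <- as.character(gt_out$gp_open_pS)
  }
  side <- list(config = unclass(trace$config), ground_truth = gt_out)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  df <- utils::read.csv(file)
  side_path <- paste0(file, ".json")
  if (!file.exists(side_path)) {
    stop("sidecar not found: ", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, side$config[setdiff(names(side$config), "seed")])
  cfg$seed <- as.integer(side$config$seed)
  gt <- side$ground_truth
  if (is.null(gt) || length(gt) == 0) {
    gt <- data.frame(t_on = numeric(0), t_off = numeric(0),
                     cv_fF = numeric(0), gp_pre_pS = numeric(0),
                     gp_open_pS = numeric(0), d_re_pS = numeric(0),
                     d_im_pS = numeric(0), case = character(0))
  }
  if (nrow(gt)) gt$gp_open_pS <- as.numeric(gt$gp_open_pS)  # "Inf" strings
  structure(list(time = df$time, re = df$re, im = df$im, config = cfg,
                 ground_truth = gt),
            class = "lockin_trace")
}
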