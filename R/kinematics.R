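#' Eyelid kinematics parameters for the synthetic trace generator
#'
#' Describes per-trial eyelid-closure kinetics in camera pixel units. The
#' unconditioned response (UR) is a linear rise over `ur_rise_ms` to
#' `ur_amplitude_px` followed by exponential decay with time constant
#' `decay_tau_ms`. A conditioned response (CR), present with probability
#' `cr_probability`, rises linearly from a Gaussian-sampled onset
#' (`cr_onset_mean_ms`, `cr_onset_sd_ms` after CS onset) over `cr_rise_ms`
#' to `cr_amplitude_frac` of the UR amplitude, then decays with the same
#' time constant. Spontaneous blinks are Poisson events with UR-like shape.
#'
#' @param cr_probability probability a trial contains a CR, in `[0, 1]`.
#' @param cr_onset_mean_ms,cr_onset_sd_ms CR onset distribution (ms after CS).
#' @param cr_rise_ms CR rise time; the CR peaks at onset + rise (ms).
#' @param cr_amplitude_frac CR peak as a fraction of the UR amplitude.
#' @param ur_amplitude_px UR peak above baseline, in pixels.
#' @param ur_rise_ms,decay_tau_ms UR rise time and shared decay constant (ms).
#' @param baseline_px open-eye baseline white-pixel count.
#' @param noise_sd_px additive Gaussian pixel noise SD.
#' @param spontaneous_blink_rate_hz rate of UR-like spontaneous blinks.
#' @return a `blink_params` list, validated.
#' @export
blink_params <- function(cr_probability = 0.5,
                         cr_onset_mean_ms = 150, cr_onset_sd_ms = 20,
                         cr_rise_ms = 100, cr_amplitude_frac = 0.6,
                         ur_amplitude_px = 400, ur_rise_ms = 40,
                         decay_tau_ms = 250, baseline_px = 40,
                         noise_sd_px = 8, spontaneous_blink_rate_hz = 0.05) {
  p <- list(
    cr_probability = check_scalar(cr_probability, "cr_probability", 0, 1),
    cr_onset_mean_ms = check_scalar(cr_onset_mean_ms, "cr_onset_mean_ms", 0),
    cr_onset_sd_ms = check_scalar(cr_onset_sd_ms, "cr_onset_sd_ms", 0),
    cr_rise_ms = check_scalar(cr_rise_ms, "cr_rise_ms", 0),
    cr_amplitude_frac = check_scalar(cr_amplitude_frac, "cr_amplitude_frac", 0, 1),
    ur_amplitude_px = check_scalar(ur_amplitude_px, "ur_amplitude_px", 0),
    ur_rise_ms = check_scalar(ur_rise_ms, "ur_rise_ms", 0),
    decay_tau_ms = check_scalar(decay_tau_ms, "decay_tau_ms", 0),
    baseline_px = check_scalar(baseline_px, "baseline_px", 0),
    noise_sd_px = check_scalar(noise_sd_px, "noise_sd_px", 0),
    spontaneous_blink_rate_hz =
      check_scalar(spontaneous_blink_rate_hz, "spontaneous_blink_rate_hz", 0)
  )
  class(p) <- "blink_params"
  p
}

#' Construct an eyelid-closure trace
#'
#' @param time_ms sample times in ms relative to CS onset (CS onset = 0).
#' @param value_px nonnegative white-pixel counts, one per sample.
#' @param frame_rate_hz nominal frame rate.
#' @return an `eyelid_trace` data frame with columns `time_ms`, `value_px`.
#' @export
eyelid_trace <- function(time_ms, value_px, frame_rate_hz) {
  if (length(time_ms) != length(value_px)) {
    stop_invalid("`time_ms` and `value_px` must have equal length")
  }
  if (any(diff(time_ms) <= 0)) stop_invalid("`time_ms` must be strictly increasing")
  if (any(value_px < 0)) stop_invalid("`value_px` must be nonnegative")
  tr <- data.frame(time_ms = as.numeric(time_ms), value_px = as.numeric(value_px))
  attr(tr, "frame_rate_hz") <- frame_rate_hz
  class(tr) <- c("eyelid_trace", "data.frame")
  tr
}

# piecewise blink waveform: linear rise then exponential decay
blink_shape <- function(t, onset_ms, amplitude, rise_ms, tau_ms) {
  dtm <- t - onset_ms
  out <- numeric(length(t))
  rising <- dtm >= 0 & dtm < rise_ms
  falling <- dtm >= rise_ms
  if (rise_ms > 0) out[rising] <- amplitude * dtm[rising] / rise_ms else out[rising] <- amplitude
  out[falling] <- amplitude * exp(-(dtm[falling] - rise_ms) / tau_ms)
  out
}

#' Generate a synthetic eyelid trace for one trial
#'
#' Produces a seeded eyelid-closure trace spanning `window_pre_ms` before CS
#' onset to `window_post_ms` after US onset (after CS offset on CS-only
#' trials). Paired trials always contain a UR starting at US onset; a CR is
#' drawn with probability `cr_probability`; spontaneous blinks and Gaussian
#' pixel noise are added on top of the baseline, and the result is clamped
#' at zero. The ground truth (CR presence, onset, peak time) is stored as
#' attributes so recovery can be verified downstream.
#'
#' @param trial one row of a [generate_schedule()] schedule, or any list with
#'   `trial_type` and (for paired trials) `us_onset_ms`.
#' @param params a [blink_params()] object.
#' @param frame_rate_hz camera frame rate; default 200 Hz (5 ms resolution).
#' @param seed integer seed.
#' @param window_pre_ms,window_post_ms recording window relative to CS onset /
#'   US onset (CS offset when unpaired); must cover at least 500 ms before the
#'   CS and 1500 ms after the US for the scoring windows to exist.
#' @param cs_duration_ms CS duration used to place the CS-only window end.
#' @return an [eyelid_trace()] with ground-truth attributes `cr_present`,
#'   `cr_onset_ms`, `cr_peak_ms`, `trial_type`, `us_onset_ms`.
#' @export
generate_trace <- function(trial, params = blink_params(), frame_rate_hz = 200,
                           seed = 1L, window_pre_ms = 500, window_post_ms = 1500,
                           cs_duration_ms = 280) {
  stopifnot(inherits(params, "blink_params"))
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    stop_invalid("`frame_rate_hz` must be positive")
  }
  if (window_pre_ms < 500 || window_post_ms < 1500) {
    stop_invalid("recording window must span at least [-500, US + 1500] ms")
  }
  type <- as.character(trial$trial_type)
  paired <- identical(type, "paired")
  us_onset <- if (paired) as.numeric(trial$us_onset_ms) else NA_real_
  anchor_end <- if (paired) us_onset else cs_duration_ms
  dt <- 1000 / frame_rate_hz
  times <- seq(-window_pre_ms, anchor_end + window_post_ms, by = dt)

  withr::with_seed(as.integer(seed), {
    v <- rep(params$baseline_px, length(times))
    cr_present <- runif(1) < params$cr_probability
    cr_onset <- max(1, rnorm(1, params$cr_onset_mean_ms, params$cr_onset_sd_ms))
    if (cr_present) {
      v <- v + blink_shape(times, cr_onset,
                           params$cr_amplitude_frac * params$ur_amplitude_px,
                           params$cr_rise_ms, params$decay_tau_ms)
    }
    if (paired) {
      v <- v + blink_shape(times, us_onset, params$ur_amplitude_px,
                           params$ur_rise_ms, params$decay_tau_ms)
    }
    span_s <- (max(times) - min(times)) / 1000
    n_spont <- rpois(1, params$spontaneous_blink_rate_hz * span_s)
    if (n_spont > 0) {
      onsets <- runif(n_spont, min(times), max(times))
      amps <- params$ur_amplitude_px * runif(n_spont, 0.7, 1)
      for (k in seq_len(n_spont)) {
        v <- v + blink_shape(times, onsets[k], amps[k],
                             params$ur_rise_ms, params$decay_tau_ms)
      }
    }
    if (params$noise_sd_px > 0) v <- v + rnorm(length(v), 0, params$noise_sd_px)
    v <- pmax(v, 0)
    tr <- eyelid_trace(times, v, frame_rate_hz)
    attr(tr, "cr_present") <- cr_present
    attr(tr, "cr_onset_ms") <- if (cr_present) cr_onset else NA_real_
    attr(tr, "cr_peak_ms") <- if (cr_present) cr_onset + params$cr_rise_ms else NA_real_
    attr(tr, "trial_type") <- type
    attr(tr, "us_onset_ms") <- us_onset
    tr
  })
}
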