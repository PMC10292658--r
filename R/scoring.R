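#' Normalise a paired (US-CS) trial trace
#'
#' Restricts the trace to the window within `window_ms` of US onset and maps
#' it affinely so that the signal minimum during the 280 ms after CS onset
#' becomes 0 and the signal maximum during the 500 ms after US onset becomes
#' 1. A flat trace (maximum equal to minimum) cannot be normalised and marks
#' the trial excluded with reason `"degenerate_normalization"`.
#'
#' @param raw an [eyelid_trace()] with time relative to CS onset.
#' @param us_onset_ms US onset in ms after CS onset (default 250: a 30 ms US
#'   co-terminating with a 280 ms CS).
#' @param cs_anchor_ms length of the CS-minimum anchor window (ms).
#' @param us_anchor_ms length of the US-maximum anchor window (ms).
#' @param window_ms half-width of the analysis window around US onset.
#' @return list with `time_ms`, `normalized`, anchors `cs_min` and `us_max`,
#'   `ur_amplitude` (`us_max - cs_min`), logical `excluded`, and `reason`.
#' @export
normalize_paired <- function(raw, us_onset_ms = 250, cs_anchor_ms = 280,
                             us_anchor_ms = 500, window_ms = 1500) {
  stopifnot(inherits(raw, "eyelid_trace"))
  t <- raw$time_ms; v <- raw$value_px
  in_cs <- t > 0 & t <= cs_anchor_ms
  in_us <- t > us_onset_ms & t <= us_onset_ms + us_anchor_ms
  if (!any(in_cs) || !any(in_us)) {
    stop("trace does not cover the CS and US anchor windows")
  }
  cs_min <- min(v[in_cs])
  us_max <- max(v[in_us])
  keep <- abs(t - us_onset_ms) <= window_ms
  out <- list(time_ms = t[keep], cs_min = cs_min, us_max = us_max,
              ur_amplitude = us_max - cs_min)
  if (us_max == cs_min) {
    out$normalized <- rep(NA_real_, sum(keep))
    out$excluded <- TRUE
    out$reason <- "degenerate_normalization"
  } else {
    out$normalized <- (v[keep] - cs_min) / (us_max - cs_min)
    out$excluded <- FALSE
    out$reason <- NA_character_
  }
  out
}

#' Classify a normalised paired trial
#'
#' A trial is excluded if the normalised signal exceeds `threshold` at any
#' sample in the pre-CR window `[0, 100)` ms after CS onset (eyelid already
#' moving before a CR could begin). Otherwise it is a CR if any sample in
#' the CR window `[100, 250]` ms exceeds `threshold`, else no_CR. Window
#' edges are half-open on the left bound of the exclusion window and closed
#' on the CR window, and a single supra-threshold sample suffices.
#'
#' @param normalized normalised signal values.
#' @param time_ms sample times (ms after CS onset), aligned with `normalized`.
#' @param threshold CR detection threshold on the normalised scale.
#' @param cr_window `c(lo, hi)` CR detection window (ms), closed.
#' @param exclusion_window `c(lo, hi)` pre-CR window (ms), `[lo, hi)`.
#' @return one of `"CR"`, `"no_CR"`, `"excluded"`.
#' @export
classify_paired <- function(normalized, time_ms, threshold = 0.15,
                            cr_window = c(100, 250),
                            exclusion_window = c(0, 100)) {
  stopifnot(length(normalized) == length(time_ms))
  if (anyNA(normalized)) return("excluded")
  pre <- time_ms >= exclusion_window[1] & time_ms < exclusion_window[2]
  win <- time_ms >= cr_window[1] & time_ms <= cr_window[2]
  if (!any(win)) stop("no samples in the CR window")
  if (any(normalized[pre] > threshold)) return("excluded")
  if (any(normalized[win] > threshold)) return("CR")
  "no_CR"
}

#' Normalise and classify a CS-only (unpaired) trial
#'
#' CS-only trials have no US, so the trace is normalised to the mean UR
#' amplitude (`us_max - cs_min`) of the preceding paired trials (up to 9,
#' fewer at the start of a session), after subtracting the trial's own
#' baseline (mean of the pre-CS samples; if none, the minimum over the
#' 280 ms after CS onset). A CR is present iff the normalised signal
#' exceeds `threshold` somewhere in `[100, 400]` ms after CS onset *and*
#' stays below `baseline_threshold` throughout `[0, 99]` ms.
#'
#' @param raw an [eyelid_trace()] with time relative to CS onset.
#' @param prev_ur_amplitudes UR amplitudes of the preceding paired trials
#'   (most recent up to 9 are used).
#' @param threshold,cr_window CR criterion on the normalised scale.
#' @param baseline_threshold,baseline_window early-quiescence criterion.
#' @param cs_anchor_ms fallback baseline window length (ms after CS onset).
#' @return list with `classification` (`"CR"`, `"no_CR"`, or `"excluded"`),
#'   `normalized`, `time_ms`, `reason`.
#' @export
normalize_and_classify_cs_only <- function(raw, prev_ur_amplitudes,
                                           threshold = 0.15,
                                           cr_window = c(100, 400),
                                           baseline_threshold = 0.05,
                                           baseline_window = c(0, 99),
                                           cs_anchor_ms = 280) {
  stopifnot(inherits(raw, "eyelid_trace"))
  amps <- prev_ur_amplitudes[!is.na(prev_ur_amplitudes) & prev_ur_amplitudes > 0]
  if (length(amps) == 0) {
    return(list(classification = "excluded", normalized = NULL,
                time_ms = NULL, reason = "no_reference_ur"))
  }
  amps <- tail(amps, 9L)
  t <- raw$time_ms; v <- raw$value_px
  pre <- t < 0
  baseline <- if (any(pre)) mean(v[pre]) else min(v[t > 0 & t <= cs_anchor_ms])
  norm <- (v - baseline) / mean(amps)
  win <- t >= cr_window[1] & t <= cr_window[2]
  base <- t >= baseline_window[1] & t <= baseline_window[2]
  if (!any(win)) stop("no samples in the CS-only CR window")
  is_cr <- any(norm[win] > threshold) && all(norm[base] < baseline_threshold)
  list(classification = if (is_cr) "CR" else "no_CR",
       normalized = norm, time_ms = t, reason = NA_character_)
}

#' Score every trial of one animal-session
#'
#' Walks the trials in presentation order: paired trials are normalised
#' against their own CS/US anchors and classified; each CS-only trial is
#' normalised against the UR amplitudes of the paired trials that preceded
#' it (up to 9; degenerate paired trials contribute no reference). The
#' normalised curves of CS-only trials are kept for peak-time analysis.
#'
#' @param traces list of [eyelid_trace()] objects, one per trial, in
#'   presentation order.
#' @param schedule the matching [generate_schedule()] session (or any data
#'   frame with `trial_type`, `us_onset_ms`, `trial_index`).
#' @param threshold CR threshold on the normalised scale.
#' @param paired_cr_window,cs_only_cr_window detection windows (ms).
#' @return a `scored_session` list: `trials`, a data frame with one row per
#'   trial (`trial_index`, `trial_type`, `classification`, `reason`,
#'   `cs_min`, `us_max`, `ur_amplitude`), and `cs_only_curves`, a list of
#'   normalised curves for CS-only trials.
#' @export
score_session <- function(traces, schedule, threshold = 0.15,
                          paired_cr_window = c(100, 250),
                          cs_only_cr_window = c(100, 400)) {
  stopifnot(length(traces) == nrow(schedule))
  n <- nrow(schedule)
  res <- data.frame(trial_index = schedule$trial_index,
                    trial_type = schedule$trial_type,
                    classification = NA_character_,
                    reason = NA_character_,
                    cs_min = NA_real_, us_max = NA_real_,
                    ur_amplitude = NA_real_)
  ur_amps <- numeric(0)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    if (schedule$trial_type[i] == "paired") {
      nz <- normalize_paired(traces[[i]], us_onset_ms = schedule$us_onset_ms[i])
      res$cs_min[i] <- nz$cs_min
      res$us_max[i] <- nz$us_max
      if (nz$excluded) {
        res$classification[i] <- "excluded"
        res$reason[i] <- nz$reason
      } else {
        res$classification[i] <-
          classify_paired(nz$normalized, nz$time_ms, threshold = threshold,
                          cr_window = paired_cr_window)
        res$ur_amplitude[i] <- nz$ur_amplitude
        ur_amps <- c(ur_amps, nz$ur_amplitude)
      }
    } else {
      cz <- normalize_and_classify_cs_only(traces[[i]], ur_amps,
                                           threshold = threshold,
                                           cr_window = cs_only_cr_window)
      res$classification[i] <- cz$classification
      res$reason[i] <- cz$reason
      if (!is.null(cz$normalized)) {
        curves[[i]] <- list(time_ms = cz$time_ms, normalized = cz$normalized,
                            classification = cz$classification)
      }
    }
  }
  structure(list(trials = res, cs_only_curves = curves), class = "scored_session")
}

#' Peak time of a smoothed CS-only curve
#'
#' Smooths the normalised CS-only curve with a centred moving average and
#' returns the time of its maximum within the search window, in ms after CS
#' onset.
#'
#' @param time_ms,normalized the CS-only curve.
#' @param smooth_ms moving-average window (ms); default 25.
#' @param search_window window over which the argmax is taken (ms).
#' @return peak time in ms.
#' @export
trial_peak_time <- function(time_ms, normalized, smooth_ms = 25,
                            search_window = c(0, 500)) {
  dt <- stats::median(diff(time_ms))
  k <- max(1L, round(smooth_ms / dt))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(normalized, rep(1 / k, k), sides = 2))
  ok <- !is.na(sm) & time_ms >= search_window[1] & time_ms <= search_window[2]
  if (!any(ok)) stop("no smoothed samples inside the search window")
  time_ms[ok][which.max(sm[ok])]
}

#' Per-animal CS-only peak time over the final training sessions
#'
#' For each CS-only trial classified as a CR in the final sessions, the peak
#' time of the smoothed normalised curve is computed; the animal's peak time
#' is the mean over those trials. Animals without any qualifying trial get
#' `NA` (the metric is absent, not zero).
#'
#' @param sessions named list of `scored_session` objects; names (or the
#'   `session_index` argument) give the session indices.
#' @param session_index integer vector of session indices aligned with
#'   `sessions`; defaults to `as.integer(names(sessions))`.
#' @param final_sessions sessions entering the average (default 10:12).
#' @param smooth_ms,search_window passed to [trial_peak_time()].
#' @return scalar mean peak time (ms), or `NA_real_`.
#' @export
peak_time <- function(sessions, session_index = NULL, final_sessions = 10:12,
                      smooth_ms = 25, search_window = c(0, 500)) {
  if (is.null(session_index)) session_index <- as.integer(names(sessions))
  stopifnot(length(session_index) == length(sessions))
  peaks <- numeric(0)
  for (j in seq_along(sessions)) {
    if (!(session_index[j] %in% final_sessions)) next
    for (cv in sessions[[j]]$cs_only_curves) {
      if (is.null(cv) || cv$classification != "CR") next
      peaks <- c(peaks, trial_peak_time(cv$time_ms, cv$normalized,
                                        smooth_ms, search_window))
    }
  }
  if (length(peaks) == 0) NA_real_ else mean(peaks)
}
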