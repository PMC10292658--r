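#' Summarise one animal-session into percent-CR performance
#'
#' Counted trials are the non-excluded paired trials; percent CR is the
#' percentage of counted trials carrying a CR. CS-only trials are tallied
#' separately and never enter the paired percent-CR. With no counted trials
#' the percentage is absent (`NA`), not zero.
#'
#' @param trials data frame with `trial_type` and `classification` columns
#'   (as produced by [score_session()]`$trials`), all from one
#'   animal-session.
#' @param animal_id,strain,sex,session_index identifiers carried into the
#'   summary row.
#' @return one-row data frame with `animal_id`, `strain`, `sex`, `session`,
#'   `n_counted`, `n_cr`, `percent_cr`, `n_excluded`, `n_cs_only`,
#'   `n_cs_only_cr`.
#' @export
summarize_session <- function(trials, animal_id = NA, strain = NA, sex = NA,
                              session_index = NA) {
  if (inherits(trials, "scored_session")) trials <- trials$trials
  paired <- trials[trials$trial_type == "paired", , drop = FALSE]
  cs <- trials[trials$trial_type == "cs_only", , drop = FALSE]
  counted <- paired$classification != "excluded"
  n_counted <- sum(counted)
  n_cr <- sum(paired$classification == "CR")
  data.frame(
    animal_id = animal_id, strain = strain, sex = sex,
    session = session_index,
    n_counted = n_counted, n_cr = n_cr,
    percent_cr = if (n_counted > 0) 100 * n_cr / n_counted else NA_real_,
    n_excluded = sum(!counted),
    n_cs_only = nrow(cs),
    n_cs_only_cr = sum(cs$classification == "CR")
  )
}

#' Terminal conditioned-response performance
#'
#' Mean percent-CR over the last three training sessions (10-12 of the
#' 12-session protocol).
#'
#' @param summaries data frame of session summaries for one animal, with
#'   `session` and `percent_cr` columns.
#' @param terminal_sessions sessions entering the mean; default 10:12.
#' @return mean percent-CR over the terminal sessions.
#' @export
terminal_performance <- function(summaries, terminal_sessions = 10:12) {
  missing <- setdiff(terminal_sessions, summaries$session)
  if (length(missing) > 0) {
    stop("missing terminal session(s): ", paste(missing, collapse = ", "))
  }
  mean(summaries$percent_cr[summaries$session %in% terminal_sessions])
}

#' Group learning curves (mean and SEM of percent-CR per session)
#'
#' @param summaries data frame of per-animal session summaries with
#'   `strain`, `sex`, `session`, `percent_cr`.
#' @return data frame with `strain`, `sex`, `session`, `n`, `mean_percent_cr`,
#'   `sem` (`NA` for single-animal cells).
#' @export
learning_curve <- function(summaries) {
  sp <- split(summaries,
              list(summaries$strain, summaries$sex, summaries$session),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- sum(!is.na(d$percent_cr))
    data.frame(strain = d$strain[1], sex = d$sex[1], session = d$session[1],
               n = n,
               mean_percent_cr = mean(d$percent_cr, na.rm = TRUE),
               sem = if (n > 1) sd(d$percent_cr, na.rm = TRUE) / sqrt(n)
                     else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$strain, out$sex, out$session), , drop = FALSE]
}

#' Per-animal per-day mean rotarod latency
#'
#' The accelerating-rotarod trial ends at 5 min at the latest, so latencies
#' above 300 s are a data error.
#'
#' @param trials data frame with `animal_id`, `day`, `latency_s` (optionally
#'   `strain`, `sex`, carried through).
#' @param max_latency_s trial ceiling in seconds (default 300).
#' @return data frame with one row per animal-day and `mean_latency_s`.
#' @export
rotarod_latencies <- function(trials, max_latency_s = 300) {
  if (any(trials$latency_s > max_latency_s)) {
    stop("latency exceeds the ", max_latency_s, " s trial ceiling")
  }
  if (any(trials$latency_s < 0)) stop("negative latency")
  keep <- intersect(c("strain", "sex"), names(trials))
  sp <- split(trials, list(trials$animal_id, trials$day), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    row <- data.frame(animal_id = d$animal_id[1], day = d$day[1],
                      n_trials = nrow(d), mean_latency_s = mean(d$latency_s))
    for (k in keep) row[[k]] <- d[[k]][1]
    row
  }))
  rownames(out) <- NULL
  out[order(out$animal_id, out$day), , drop = FALSE]
}
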