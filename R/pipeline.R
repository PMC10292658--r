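#' Simulate and score one animal-session
#'
#' Generates a trace for every trial of the schedule and scores the session.
#' With `use_video = TRUE` each trace is first rendered to a synthetic eye
#' video and re-extracted with [extract_trace()], exercising the full
#' camera-to-classification path; otherwise the generator traces are scored
#' directly. All randomness derives from `seed` via per-trial sub-seeds, so
#' the result is reproducible and independent of execution order.
#'
#' @param schedule one session from [generate_schedule()].
#' @param params a [blink_params()] object.
#' @param frame_rate_hz camera frame rate.
#' @param seed integer seed.
#' @param use_video render + extract instead of scoring generator traces.
#' @param geometry an [eye_geometry()] used when rendering.
#' @return a [score_session()] result; the generator's ground-truth CR flags
#'   are attached as attribute `cr_truth`.
#' @export
simulate_scored_session <- function(schedule, params = blink_params(),
                                    frame_rate_hz = 200, seed = 1L,
                                    use_video = FALSE,
                                    geometry = eye_geometry()) {
  n <- nrow(schedule)
  seeds <- derive_seeds(seed, 2L * n)
  truth <- logical(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- generate_trace(schedule[i, ], params, frame_rate_hz,
                         seed = seeds[2L * i - 1L])
    truth[i] <- isTRUE(attr(tr, "cr_present"))
    if (use_video) {
      stack <- render_video(tr, geometry, seed = seeds[2L * i])
      tr <- extract_trace(stack, cs_onset_ms = 0)
    }
    traces[[i]] <- tr
  }
  out <- score_session(traces, schedule)
  attr(out, "cr_truth") <- truth
  out
}

#' Simulate and score a two-group cohort end to end
#'
#' For each animal of each strain, simulates the requested training
#' sessions at that strain's CR probability, scores every trial (optionally
#' through the video render/extract path), and aggregates session
#' summaries.
#'
#' @param n_per_group animals per strain.
#' @param cr_probabilities named per-strain CR probabilities, e.g.
#'   `c(C57 = 0.7, BTBR = 0.3)`.
#' @param sessions session indices to simulate (default 10:12, the terminal
#'   sessions).
#' @param params baseline [blink_params()]; each strain's `cr_probability`
#'   is substituted in.
#' @param frame_rate_hz,use_video,geometry passed to
#'   [simulate_scored_session()].
#' @param seed integer master seed.
#' @param sex sex label carried into the summaries.
#' @return list with `summaries` (one row per animal-session, see
#'   [summarize_session()]) and `scored` (nested list of scored sessions,
#'   `scored[[animal_id]][[as.character(session)]]`).
#' @export
simulate_scored_cohort <- function(n_per_group = 8L,
                                   cr_probabilities = c(C57 = 0.7, BTBR = 0.3),
                                   sessions = 10:12,
                                   params = blink_params(),
                                   frame_rate_hz = 60,
                                   use_video = TRUE,
                                   geometry = eye_geometry(),
                                   seed = 1L, sex = "M") {
  strains <- names(cr_probabilities)
  stopifnot(length(strains) >= 1, !is.null(strains))
  n_units <- length(strains) * n_per_group * length(sessions)
  seeds <- derive_seeds(seed, n_units)
  # one schedule set per animal so trial orders differ across animals
  sched_seeds <- derive_seeds(seed + 1L, length(strains) * n_per_group)
  summaries <- list()
  scored <- list()
  u <- 0L; a <- 0L
  for (st in strains) {
    p <- params
    p$cr_probability <- unname(cr_probabilities[[st]])
    for (k in seq_len(n_per_group)) {
      a <- a + 1L
      id <- sprintf("%s_%02d", st, k)
      scheds <- generate_schedule(length(sessions), seed = sched_seeds[a])
      scored[[id]] <- list()
      for (j in seq_along(sessions)) {
        u <- u + 1L
        ss <- simulate_scored_session(scheds[[j]], p, frame_rate_hz,
                                      seed = seeds[u], use_video = use_video,
                                      geometry = geometry)
        scored[[id]][[as.character(sessions[j])]] <- ss
        summaries[[length(summaries) + 1L]] <-
          summarize_session(ss$trials, animal_id = id, strain = st, sex = sex,
                            session_index = sessions[j])
      }
    }
  }
  list(summaries = do.call(rbind, summaries), scored = scored)
}

#' Per-strain terminal performance means
#'
#' @param summaries per-animal session summaries.
#' @param terminal_sessions sessions entering each animal's terminal mean.
#' @return data frame `strain`, `n_animals`, `mean_terminal_percent_cr`,
#'   `sem`.
#' @export
terminal_group_means <- function(summaries, terminal_sessions = 10:12) {
  per_animal <- do.call(rbind, lapply(split(summaries, summaries$animal_id),
    function(d) data.frame(animal_id = d$animal_id[1], strain = d$strain[1],
                           terminal = terminal_performance(d, terminal_sessions))))
  out <- do.call(rbind, lapply(split(per_animal, per_animal$strain),
    function(d) data.frame(strain = d$strain[1], n_animals = nrow(d),
                           mean_terminal_percent_cr = mean(d$terminal),
                           sem = sd(d$terminal) / sqrt(nrow(d)))))
  rownames(out) <- NULL
  out
}
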