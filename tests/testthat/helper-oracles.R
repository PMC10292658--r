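# Independent oracles: deliberately naive implementations that scan every
# sample / densely resample geometry, kept free of the production code paths.

# literal sample-by-sample paired-trial rule: walk the samples in time order;
# any early supra-threshold sample excludes the trial before the CR window is
# ever consulted
oracle_classify_paired <- function(normalized, time_ms, threshold = 0.15) {
  ord <- order(time_ms)
  for (i in ord) {
    if (time_ms[i] >= 0 && time_ms[i] < 100) {
      if (normalized[i] > threshold) return("excluded")
    }
  }
  for (i in ord) {
    if (time_ms[i] >= 100 && time_ms[i] <= 250) {
      if (normalized[i] > threshold) return("CR")
    }
  }
  "no_CR"
}

# literal CS-only rule: must exceed 0.15 somewhere in [100, 400] ms and stay
# below 0.05 throughout [0, 99] ms
oracle_classify_cs_only <- function(normalized, time_ms) {
  quiet <- TRUE
  hit <- FALSE
  for (i in seq_along(time_ms)) {
    t <- time_ms[i]
    if (t >= 0 && t <= 99 && normalized[i] >= 0.05) quiet <- FALSE
    if (t >= 100 && t <= 400 && normalized[i] > 0.15) hit <- TRUE
  }
  if (hit && quiet) "CR" else "no_CR"
}

# Sholl by dense resampling: every edge sampled at `step` um; crossings are
# in/out flips between consecutive samples within an edge
oracle_sholl_counts <- function(morph, radii, step = 0.01) {
  nodes <- morph$nodes
  cx <- morph$soma_center[1]; cy <- morph$soma_center[2]
  child <- nodes[nodes$parent != -1, , drop = FALSE]
  d_all <- list(); id_all <- list()
  for (k in seq_len(nrow(child))) {
    j <- match(child$parent[k], nodes$id)
    x0 <- nodes$x[j]; y0 <- nodes$y[j]
    x1 <- child$x[k]; y1 <- child$y[k]
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    if (len == 0) next
    tt <- seq(0, 1, by = step / len)
    if (tt[length(tt)] < 1) tt <- c(tt, 1)
    d_all[[k]] <- sqrt((x0 + tt * (x1 - x0) - cx)^2 +
                       (y0 + tt * (y1 - y0) - cy)^2)
    id_all[[k]] <- rep(k, length(tt))
  }
  d <- unlist(d_all); eid <- unlist(id_all)
  same <- eid[-length(eid)] == eid[-1]
  vapply(radii, function(r) {
    ins <- d <= r
    sum(ins[-length(ins)][same] != ins[-1][same])
  }, integer(1))
}

# random blink parameter set spanning all classifier branches (high
# spontaneous-blink rates provoke exclusions, low amplitudes provoke no_CR)
random_blink_params <- function() {
  blink_params(
    cr_probability = runif(1),
    cr_onset_mean_ms = runif(1, 80, 220),
    cr_onset_sd_ms = runif(1, 0, 40),
    cr_rise_ms = runif(1, 50, 150),
    cr_amplitude_frac = runif(1, 0.1, 1),
    ur_amplitude_px = runif(1, 150, 600),
    ur_rise_ms = runif(1, 20, 60),
    decay_tau_ms = runif(1, 120, 400),
    baseline_px = runif(1, 10, 80),
    noise_sd_px = runif(1, 0, 15),
    spontaneous_blink_rate_hz = runif(1, 0, 0.5)
  )
}

# straight radial branch of given length, used by the analytic Sholl cases
straight_branch_morphology <- function(length_um = 41, angle = pi / 2,
                                       n_nodes = 1L) {
  xs <- length_um * cos(angle) * seq_len(n_nodes) / n_nodes
  ys <- length_um * sin(angle) * seq_len(n_nodes) / n_nodes
  nodes <- data.frame(id = 1:(n_nodes + 1L), type = c(1L, rep(3L, n_nodes)),
                      x = c(0, xs), y = c(0, ys), z = 0, radius = c(5, rep(0.5, n_nodes)),
                      parent = c(-1L, 1:n_nodes))
  neuron_morphology(nodes)
}

paired_trial_row <- function(us_onset_ms = 250) {
  data.frame(trial_type = "paired", cs_onset_ms = 0, us_onset_ms = us_onset_ms)
}

cs_only_trial_row <- function() {
  data.frame(trial_type = "cs_only", cs_onset_ms = 0, us_onset_ms = NA_real_)
}
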