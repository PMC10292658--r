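make_trace <- function(time_ms, value_px) eyelid_trace(time_ms, value_px, 200)

test_that("paired normalization maps the anchor range onto [0, 1]", {
  t <- seq(-500, 1750, by = 5)
  v <- rep(10, length(t))
  v[t > 250 & t <= 750] <- 110              # UR window maximum 110
  v[t == 150] <- 60                         # mid-range sample
  nz <- normalize_paired(make_trace(t, v), us_onset_ms = 250)
  expect_equal(nz$cs_min, 10)
  expect_equal(nz$us_max, 110)
  expect_equal(nz$normalized[nz$time_ms == 150], 0.5)
  expect_equal(max(nz$normalized), 1)
  expect_equal(min(nz$normalized), 0)
  expect_true(all(abs(nz$time_ms - 250) <= 1500))
})

test_that("normalization and classification are affine invariant", {
  tr <- generate_trace(paired_trial_row(), blink_params(cr_probability = 1),
                       200, seed = 3)
  nz1 <- normalize_paired(tr, 250)
  tr2 <- make_trace(tr$time_ms, 3.7 * tr$value_px + 55)
  nz2 <- normalize_paired(tr2, 250)
  expect_equal(nz1$normalized, nz2$normalized)
  expect_identical(classify_paired(nz1$normalized, nz1$time_ms),
                   classify_paired(nz2$normalized, nz2$time_ms))
})

test_that("flat paired traces are excluded as degenerate, not NaN", {
  t <- seq(-500, 1750, by = 5)
  nz <- normalize_paired(make_trace(t, rep(42, length(t))), 250)
  expect_true(nz$excluded)
  expect_equal(nz$reason, "degenerate_normalization")
  expect_identical(classify_paired(nz$normalized, nz$time_ms), "excluded")
})

test_that("paired classification follows the threshold-crossing rule", {
  t <- seq(-250, 1750, by = 5)
  base <- numeric(length(t))
  # UR after 250 ms only -> no CR
  late <- base; late[t > 255 & t < 600] <- 1
  expect_identical(classify_paired(late, t), "no_CR")
  # single crossing to 0.2 at 150 ms -> CR
  cr <- late; cr[t == 150] <- 0.2
  expect_identical(classify_paired(cr, t), "CR")
  # crossing at 50 ms -> excluded regardless of later samples
  early <- cr; early[t == 50] <- 0.2
  expect_identical(classify_paired(early, t), "excluded")
  # boundary conventions: 100 ms belongs to the CR window, not exclusion
  at100 <- late; at100[t == 100] <- 0.2
  expect_identical(classify_paired(at100, t), "CR")
  at250 <- late; at250[t == 250] <- 0.2
  expect_identical(classify_paired(at250, t), "CR")
})

test_that("CS-only classification applies both clauses of the rule", {
  t <- seq(-500, 1780, by = 5)
  flat <- make_trace(t, rep(0, length(t)) + 50)
  res <- normalize_and_classify_cs_only(flat, prev_ur_amplitudes = rep(100, 9))
  expect_identical(res$classification, "no_CR")
  ramp <- rep(50, length(t)); ramp[t >= 250 & t <= 350] <- 80  # 0.3 normalized
  res <- normalize_and_classify_cs_only(make_trace(t, ramp), rep(100, 9))
  expect_identical(res$classification, "CR")
  # 0.06 at 50 ms violates the early-quiescence clause
  bad <- ramp; bad[t == 50] <- 56
  res <- normalize_and_classify_cs_only(make_trace(t, bad), rep(100, 9))
  expect_identical(res$classification, "no_CR")
  # no usable reference UR -> excluded with reason
  res <- normalize_and_classify_cs_only(make_trace(t, ramp), numeric(0))
  expect_identical(res$classification, "excluded")
  expect_identical(res$reason, "no_reference_ur")
})

test_that("CS-only normalization uses at most the last nine UR amplitudes", {
  t <- seq(-500, 1780, by = 5)
  ramp <- rep(50, length(t)); ramp[t >= 250 & t <= 350] <- 80
  # older large amplitudes must be ignored: mean of last 9 is 100 -> CR
  amps <- c(1e6, rep(100, 9))
  res <- normalize_and_classify_cs_only(make_trace(t, ramp), amps)
  expect_identical(res$classification, "CR")
  # with a huge reference the 30 px deflection is negligible -> no_CR
  res <- normalize_and_classify_cs_only(make_trace(t, ramp), rep(1e6, 9))
  expect_identical(res$classification, "no_CR")
})

test_that("production classifier matches the literal-rule oracle", {
  n_ok <- 0L
  for (s in 1:400) {
    p <- withr::with_seed(s, random_blink_params())
    tr <- generate_trace(paired_trial_row(), p, 100, seed = s + 1000L)
    nz <- normalize_paired(tr, 250)
    got <- classify_paired(nz$normalized, nz$time_ms)
    want <- if (nz$excluded) "excluded" else
      oracle_classify_paired(nz$normalized, nz$time_ms)
    if (identical(got, want)) n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 400L)
})

test_that("no trial is both excluded and CR (exclusion precedence)", {
  for (s in 1:200) {
    p <- withr::with_seed(s, random_blink_params())
    tr <- generate_trace(paired_trial_row(), p, 100, seed = s)
    nz <- normalize_paired(tr, 250)
    cls <- classify_paired(nz$normalized, nz$time_ms)
    expect_true(cls %in% c("CR", "no_CR", "excluded"))
    if (cls == "excluded" && !nz$excluded) {
      pre <- nz$time_ms >= 0 & nz$time_ms < 100
      expect_true(any(nz$normalized[pre] > 0.15))
    }
  }
})

test_that("peak time lands on the smoothed CS-only maximum", {
  # noiseless CR peaking at 250 ms: smoothed argmax within one frame interval
  tr <- generate_trace(cs_only_trial_row(),
                       blink_params(cr_probability = 1, cr_onset_mean_ms = 150,
                                    cr_onset_sd_ms = 0, cr_rise_ms = 100,
                                    noise_sd_px = 0,
                                    spontaneous_blink_rate_hz = 0),
                       200, seed = 2)
  res <- normalize_and_classify_cs_only(tr, rep(400, 9))
  pt <- trial_peak_time(res$time_ms, res$normalized)
  expect_lte(abs(pt - 250), 5)
})

test_that("peak-time recovery on a jittered synthetic cohort", {
  # onset ~ N(160, 30), rise 100 -> true peak ~ N(260, 30); 30 trials
  p <- blink_params(cr_probability = 1, cr_onset_mean_ms = 160,
                    cr_onset_sd_ms = 30, cr_rise_ms = 100, noise_sd_px = 2,
                    spontaneous_blink_rate_hz = 0)
  peaks <- vapply(1:30, function(s) {
    tr <- generate_trace(cs_only_trial_row(), p, 200, seed = s)
    res <- normalize_and_classify_cs_only(tr, rep(400, 9))
    trial_peak_time(res$time_ms, res$normalized)
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 260), 3 * 30 / sqrt(30) + 6)  # + smoothing bias
})

test_that("per-animal peak time averages CS-only CRs of the final sessions", {
  p <- blink_params(cr_probability = 1, cr_onset_mean_ms = 150,
                    cr_onset_sd_ms = 10, noise_sd_px = 2,
                    spontaneous_blink_rate_hz = 0)
  sch <- generate_schedule(3, seed = 5)
  scored <- lapply(1:3, function(j) {
    simulate_scored_session(sch[[j]], p, 100, seed = j)
  })
  names(scored) <- c("10", "11", "12")
  pt <- peak_time(scored)
  expect_true(is.finite(pt))
  expect_gt(pt, 150); expect_lt(pt, 400)
  # metric absent (NA), not zero, without qualifying trials
  empty <- scored["10"]
  names(empty) <- "3"
  expect_true(is.na(peak_time(empty)))
})
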