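test_that("null model: no components, no noise, no gaps gives a flat trace", {
  cfg <- tiny_config(seed = 4, null = TRUE, noise = FALSE, gaps = FALSE)
  set.seed(4)
  part <- make_participant(cfg, "15mo", "p1")
  tr <- generate_trial_trace(cfg, part, "15mo", "novel")
  expect_equal(nrow(tr), 960)
  b <- round(part$baseline_mm, 6)
  expect_true(all(tr$left_pupil_mm == b))
  expect_true(all(tr$right_pupil_mm == b))
  expect_true(all(tr$left_valid & tr$right_valid))
  # pre-sound 1000-ms window mean equals the participant baseline exactly
  win <- tr$t_ms >= 2680 & tr$t_ms < 3680
  expect_equal(mean(tr$left_pupil_mm[win]), b)
})

test_that("condition differences are exactly the component kernels", {
  cfg <- tiny_config(seed = 11, noise = FALSE, gaps = FALSE)
  set.seed(11)
  part <- make_participant(cfg, "15mo", "p1")
  novel <- generate_trial_trace(cfg, part, "15mo", "novel")
  familiar <- generate_trial_trace(cfg, part, "15mo", "familiar")
  switched <- generate_trial_trace(cfg, part, "15mo", "switched")

  comps <- cfg$age_groups[["15mo"]]$components
  rel_t <- novel$t_ms - cfg$trial_timeline$sound_onset_ms
  perc <- gamma_kernel(rel_t, comps$perceptual_novelty$onset_latency_ms,
                       comps$perceptual_novelty$rise_time_ms,
                       part$amplitudes[["perceptual_novelty"]])
  assoc <- gamma_kernel(rel_t, comps$association_novelty$onset_latency_ms,
                        comps$association_novelty$rise_time_ms,
                        part$amplitudes[["association_novelty"]])
  expect_equal(novel$left_pupil_mm - familiar$left_pupil_mm, perc,
               tolerance = 1e-5)
  expect_equal(switched$left_pupil_mm - familiar$left_pupil_mm, assoc,
               tolerance = 1e-5)
})

test_that("kernel is nonnegative, zero before onset, peaks at the rise time", {
  t <- seq(0, 4300, by = 1)
  k <- gamma_kernel(t, 1300, 800, 0.14)
  expect_true(all(k >= 0))
  expect_true(all(k[t <= 1300] == 0))
  expect_equal(t[which.max(k)], 1300 + 800)
  expect_equal(max(k), 0.14)
})

test_that("configured onsets are recoverable from noise-free differences", {
  for (onset in c(1300, 2000, 3950)) {
    comp <- default_components("15mo")["perceptual_novelty"]
    comp$perceptual_novelty$onset_latency_ms <- onset
    cfg <- tiny_config(seed = 21, noise = FALSE, gaps = FALSE)
    cfg$age_groups[["15mo"]]$components <- comp
    set.seed(21)
    part <- make_participant(cfg, "15mo", "p1")
    novel <- generate_trial_trace(cfg, part, "15mo", "novel")
    familiar <- generate_trial_trace(cfg, part, "15mo", "familiar")
    d <- novel$left_pupil_mm - familiar$left_pupil_mm
    rel_t <- novel$t_ms - cfg$trial_timeline$sound_onset_ms
    post <- rel_t >= 0
    bins <- bin_series(c(d[post], numeric(520))[1:520])
    first_nonzero_bin_end <- 50 * which(abs(bins) > 1e-9)[1]
    expect_lte(abs(first_nonzero_bin_end - onset), 50)
  }
})

test_that("noisy novel-minus-familiar differences appear only after onset", {
  # Monte-Carlo check against the configured 15mo perceptual onset (1300 ms):
  # across 200 simulated trial pairs the per-bin one-sided test fires after
  # the onset but not before it.
  cfg <- tiny_config(seed = 31, gaps = FALSE)
  set.seed(31)
  part <- make_participant(cfg, "15mo", "p1")
  n_pairs <- 200
  diffs <- matrix(NA_real_, n_pairs, 86)
  for (r in seq_len(n_pairs)) {
    nv <- generate_trial_trace(cfg, part, "15mo", "novel")
    fm <- generate_trial_trace(cfg, part, "15mo", "familiar")
    rel_t <- nv$t_ms - cfg$trial_timeline$sound_onset_ms
    idx <- switchpupil:::post_onset_window(nv$t_ms, 3680)
    diffs[r, ] <- bin_series(nv$left_pupil_mm[idx] - fm$left_pupil_mm[idx])
  }
  tt <- colMeans(diffs) / (apply(diffs, 2, sd) / sqrt(n_pairs))
  p <- pt(tt, n_pairs - 1, lower.tail = FALSE)
  bin_end <- seq(50, by = 50, length.out = 86)
  expect_true(all(p[bin_end < 1300] > 1e-4))
  expect_true(all(p[bin_end >= 1600 & bin_end <= 3000] < 1e-4))
})

test_that("gap-length sampler matches its exponential law", {
  set.seed(99)
  lens <- sample_gap_lengths(10000, 37.4)
  expect_lt(abs(mean(lens) - 37.4) / 37.4, 0.02)
  set.seed(100)
  lens2 <- sample_gap_lengths(10000, 37.4, long_gap_prob = 0.01,
                              long_gap_length_ms = 600)
  expect_gte(mean(lens2 < 500), 0.98)
})

test_that("inject_missingness honours its contracts", {
  tr <- clean_test_trial(seed = 5)
  gp <- list(enabled = TRUE, gap_rate_per_s = 0, long_gap_prob = 0,
             long_gap_length_ms = 600, both_eyes_prob = 1)
  out <- inject_missingness(data.table::copy(tr), gp, 37.4)
  expect_identical(as.data.frame(out), as.data.frame(tr))

  # injecting into an already-gapped trial is a contract violation
  gp$gap_rate_per_s <- 2
  set.seed(1)
  gapped <- inject_missingness(data.table::copy(tr), gp, 37.4)
  expect_error(inject_missingness(gapped, gp, 37.4), "no prior gaps")

  # a dropout trial exceeds the 40% inclusion criterion downstream
  set.seed(2)
  dropped <- inject_missingness(clean_test_trial(seed = 5),
                                list(enabled = FALSE), 37.4, dropout = TRUE,
                                dropout_missing_range = c(0.45, 0.45))
  mr <- compute_missing_rate(dropped)
  expect_gte(mr, 0.40)
  expect_false(preprocess_trial(dropped)$included)
})

test_that("generate_dataset is deterministic and matches the design", {
  cfg <- tiny_config(seed = 77, n = 2)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))

  des <- design_table(d1)
  per_part <- des[, .(fam = sum(phase == "familiarization"),
                      test = sum(phase == "test")), by = participant_id]
  expect_true(all(per_part$fam == 16))  # 4 blocks x 4 trials
  expect_true(all(per_part$test == 5))  # 2 familiar + 2 switched + 1 novel
  tc <- des[phase == "test", table(condition)]
  expect_equal(as.integer(tc[c("familiar", "switched", "novel")]), c(4L, 4L, 2L))

  # byte-identical exports under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_gaze_table(d1, f1); write_gaze_table(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("n = 0 participants gives an empty but valid dataset", {
  cfg <- tiny_config(seed = 1, n = 0)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds), 0)
  f <- tempfile()
  write_gaze_table(ds, f)
  back <- read_gaze_table(f)
  expect_equal(nrow(back), 0)
})

test_that("unknown condition or age group errors", {
  cfg <- tiny_config(seed = 1)
  expect_error(generate_trial_trace(cfg, "p1", "15mo", "weird"),
               "unknown test condition")
  expect_error(generate_trial_trace(cfg, "p1", "99mo", "novel"),
               "unknown age_group")
})
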