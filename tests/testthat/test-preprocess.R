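test_that("missing rate counts samples lacking both eyes, against the nominal count", {
  tr <- clean_test_trial(seed = 2)
  expect_equal(compute_missing_rate(tr), 0.0)

  # 384 fully missing of 960 expected -> exactly 0.40, excluded (strict <)
  tr2 <- data.table::copy(tr)
  tr2[1:384, `:=`(left_valid = FALSE, right_valid = FALSE,
                  left_pupil_mm = NA_real_, right_pupil_mm = NA_real_)]
  expect_equal(compute_missing_rate(tr2), 0.40)
  expect_false(preprocess_trial(tr2)$included)

  # one-eye samples still count as present
  tr3 <- data.table::copy(tr)
  tr3[1:100, `:=`(left_valid = FALSE, right_valid = FALSE,
                  left_pupil_mm = NA_real_, right_pupil_mm = NA_real_)]
  tr3[101:150, `:=`(left_valid = FALSE, left_pupil_mm = NA_real_)]
  expect_equal(compute_missing_rate(tr3), 100 / 960)

  expect_error(compute_missing_rate(tr, duration_ms = 0), "zero-duration")
})

test_that("trial selection drops participants missing a condition", {
  ts <- data.table::CJ(participant_id = c("a", "b", "c"),
                       condition = c("familiar", "switched", "novel"))
  ts[, age_group := "15mo"]
  ts[, missing_rate := 0.05]
  # participant b loses their only novel trial
  ts[participant_id == "b" & condition == "novel", missing_rate := 0.6]
  sel <- select_trials(ts)
  expect_setequal(sel$participants, c("a", "c"))
  expect_false(any(sel$trials[participant_id == "b", retained]))
  expect_equal(sel$report$n_retained_participants, 2L)

  clean <- data.table::copy(ts)[, missing_rate := 0]
  expect_equal(sort(select_trials(clean)$participants), c("a", "b", "c"))
})

test_that("linear interpolation is exact where it should be", {
  r <- interpolate_gaps(c(3.0, NA, NA, 3.3))
  expect_equal(r$series, c(3.0, 3.1, 3.2, 3.3))
  expect_equal(r$gap_lengths_ms, 2 * 1000 / 120)

  x <- c(2, 2.5, 3, 3.5)
  expect_equal(interpolate_gaps(x)$series, x)
  expect_equal(interpolate_gaps(x)$gap_lengths_ms, numeric(0))

  # any interior gap pattern on a linear ramp is reconstructed exactly
  set.seed(42)
  for (rep in 1:20) {
    ramp <- seq(3, 4, length.out = 100)
    holes <- sample(2:99, sample(1:40, 1))
    gapped <- ramp
    gapped[holes] <- NA
    expect_equal(interpolate_gaps(gapped)$series, ramp, tolerance = 1e-12)
  }

  # leading/trailing gaps are nearest-value holds
  r2 <- interpolate_gaps(c(NA, NA, 5, 6, NA))
  expect_equal(r2$series, c(5, 5, 5, 6, 6))

  r3 <- interpolate_gaps(rep(NA_real_, 10))
  expect_false(r3$usable)
})

test_that("the low-pass filter matches its transfer-function oracle", {
  # DC gain exactly 1
  expect_equal(lowpass_4hz(rep(3.5, 100), 120), rep(3.5, 100))

  t <- (0:959) / 120
  core <- 150:810  # away from edges
  # 10-Hz sine attenuated by >= 90%, amplitude matching the analytic gain
  g10 <- butter2_filtfilt_gain(10, 4, 120)
  out10 <- lowpass_4hz(sin(2 * pi * 10 * t), 120)
  expect_lt(max(abs(out10[core])), 0.1)
  expect_equal(max(abs(out10[core])), g10, tolerance = 0.01)

  # 0.5-Hz sine attenuated by <= 5%
  out05 <- lowpass_4hz(sin(2 * pi * 0.5 * t), 120)
  expect_gt(max(abs(out05[core])), 0.95)

  # mixture: output approximately the scaled 0.5-Hz component
  g05 <- butter2_filtfilt_gain(0.5, 4, 120)
  mix <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 15 * t)
  outmix <- lowpass_4hz(mix, 120)
  target <- g05 * sin(2 * pi * 0.5 * t)
  rms_err <- sqrt(mean((outmix[core] - target[core])^2))
  expect_lt(rms_err, 0.1)

  expect_error(lowpass_4hz(rnorm(5), 120), "too short")
  # vectorised recursion equals the reference loop
  co <- butter2_lowpass(4, 120)
  set.seed(7)
  x <- rnorm(300) + 4
  expect_equal(switchpupil:::iir_filter(co$b, co$a, x),
               iir_filter_loop(co$b, co$a, x), tolerance = 1e-12)
})

test_that("eye averaging passes single eyes through", {
  expect_equal(average_eyes(c(3, 3), c(3, 3)), c(3, 3))
  expect_equal(average_eyes(3.0, 3.4), 3.2)
  expect_equal(average_eyes(c(3.0, NA), c(3.4, 2.0)), c(3.2, 2.0))
  expect_equal(average_eyes(NULL, c(1, 2)), c(1, 2))
  expect_error(average_eyes(NULL, NULL), "unusable")
})

test_that("baseline correction zeroes the pre-onset window and is shift-invariant", {
  t_ms <- (0:959) * 1000 / 120
  const <- rep(4.2, 960)
  bc <- baseline_correct(const, t_ms, 3680)
  expect_true(all(bc$rel == 0))

  step <- ifelse(t_ms < 3680, 4.0, 4.2)
  bc2 <- baseline_correct(step, t_ms, 3680)
  expect_true(all(abs(bc2$rel[t_ms >= 3680] - 0.2) < 1e-12))

  set.seed(3)
  x <- 4 + cumsum(rnorm(960, 0, 0.01))
  expect_equal(baseline_correct(x + 1.23, t_ms, 3680)$rel,
               baseline_correct(x, t_ms, 3680)$rel, tolerance = 1e-12)
})

test_that("binning produces 86 bins of 6 samples, discarding the last 4", {
  expect_equal(bin_series(rep(0.3, 520)), rep(0.3, 86))
  # rel_series = 0..519 -> bin k (0-based) mean = 6k + 2.5
  b <- bin_series(0:519)
  expect_equal(b, 6 * (0:85) + 2.5)
  expect_equal(length(b), 86)
  expect_error(bin_series(numeric(519)), "520")
  # samples 516-519 do not influence any bin
  x <- c(numeric(516), 99, 99, 99, 99)
  expect_equal(bin_series(x), rep(0, 86))
})

test_that("condition aggregation averages a participant's trials", {
  b1 <- rnorm(86)
  b2 <- rnorm(86)
  expect_equal(aggregate_condition(list(b1)), b1)
  expect_equal(aggregate_condition(list(b1, b1)), b1)
  expect_equal(aggregate_condition(list(b1, b2)), (b1 + b2) / 2)
})

test_that("corrected trials have a zero-mean baseline window", {
  cfg <- tiny_config(seed = 13, n = 2)
  ds <- generate_dataset(cfg, phases = "test")
  test <- ds[phase == "test"]
  for (k in unique(test$trial_idx)[1:3]) {
    tr <- test[participant_id == "15mo_p01" & trial_idx == k]
    res <- preprocess_trial(tr)
    if (!res$included) next
    win <- tr$t_ms >= 2680 & tr$t_ms < 3680
    expect_lt(abs(mean(res$rel_full[win])), 1e-9)
  }
})

test_that("end-to-end noise-free differences recover the binned kernel", {
  cfg <- tiny_config(seed = 17, noise = FALSE, gaps = FALSE)
  set.seed(17)
  part <- make_participant(cfg, "15mo", "p1")
  novel <- preprocess_trial(generate_trial_trace(cfg, part, "15mo", "novel"))
  familiar <- preprocess_trial(generate_trial_trace(cfg, part, "15mo", "familiar"))
  d_bins <- novel$bins - familiar$bins

  comps <- cfg$age_groups[["15mo"]]$components$perceptual_novelty
  tr <- generate_trial_trace(cfg, part, "15mo", "novel")
  idx <- switchpupil:::post_onset_window(tr$t_ms, 3680)
  kernel <- gamma_kernel(tr$t_ms[idx] - 3680, comps$onset_latency_ms,
                         comps$rise_time_ms,
                         part$amplitudes[["perceptual_novelty"]])
  k_bins <- bin_series(kernel)

  amp <- part$amplitudes[["perceptual_novelty"]]
  onset_bin <- ceiling(comps$onset_latency_ms / 50)
  away <- setdiff(seq_len(86), (onset_bin - 4):(onset_bin + 4))
  rms <- sqrt(mean((d_bins[away] - k_bins[away])^2))
  expect_lt(rms, 0.02 * amp)
})

test_that("preprocess_dataset assembles complete per-group arrays", {
  cfg <- tiny_config(seed = 23, n = 3)
  ds <- generate_dataset(cfg, phases = "test")
  tc <- preprocess_dataset(ds)
  g <- tc$age_groups[["15mo"]]
  expect_equal(dim(g$array)[2:3], c(3L, 86L))
  expect_false(anyNA(g$array))
  expect_true(all(g$trial_counts > 0))
  expect_equal(tc$bin_times_ms[86], 4300)
  # QC gap stats present
  expect_true(tc$qc[["15mo"]]$n_gaps > 0)
  expect_gte(tc$qc[["15mo"]]$frac_below_500ms, 0.9)
})
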