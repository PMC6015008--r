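# Preprocessing: inclusion -> interpolation -> filter -> eye average ->
# baseline correction -> 50-ms binning ------------------------------------

CONDITIONS <- c("familiar", "switched", "novel")
N_BINS <- 86L
SAMPLES_PER_BIN <- 6L
POST_ONSET_SAMPLES <- 520L

#' Missing rate of a trial
#'
#' Fraction of the trial's *expected* samples (nominal duration times
#' sampling rate) that lack a valid measurement in both eyes. A sample with
#' at least one valid eye counts as present; rows absent from the export
#' count as missing. Computed before any interpolation.
#'
#' @param trial One trial's sample `data.table`.
#' @param duration_ms Nominal trial duration; default 8000 ms for test
#'   trials, 9000 ms for familiarization trials.
#' @param rate Sampling rate (Hz).
#' @return Fraction in \[0, 1\].
#' @export
compute_missing_rate <- function(trial, duration_ms = NULL, rate = 120) {
  if (is.null(duration_ms)) {
    duration_ms <- if (identical(unique(trial$phase), "familiarization")) 9000 else 8000
  }
  if (duration_ms <= 0) stop("zero-duration trial", call. = FALSE)
  expected <- ceiling(duration_ms * rate / 1000)
  present <- sum(trial$left_valid | trial$right_valid)
  (expected - present) / expected
}

#' Linear interpolation of per-eye gaps
#'
#' Interior `NA` runs are connected linearly between the last sample before
#' and the first sample after each gap. Leading/trailing gaps have no
#' flanking sample on one side and are filled by nearest-value hold (they
#' still counted as missing for the inclusion criterion). All gap lengths
#' are recorded.
#'
#' @param series Numeric vector with `NA` gaps.
#' @param dt_ms Sample period (ms), used only to express gap lengths in ms.
#' @return List: `series` (gap-free, or `NULL` if the whole eye is missing),
#'   `gap_lengths_ms`, `usable`.
#' @export
interpolate_gaps <- function(series, dt_ms = 1000 / 120) {
  na <- is.na(series)
  runs <- rle(na)
  gap_lengths <- runs$lengths[runs$values] * dt_ms
  if (all(na)) {
    return(list(series = NULL, gap_lengths_ms = gap_lengths, usable = FALSE))
  }
  if (!any(na)) {
    return(list(series = series, gap_lengths_ms = numeric(0), usable = TRUE))
  }
  idx <- which(!na)
  filled <- approx(x = idx, y = series[idx], xout = seq_along(series),
                   method = "linear", rule = 2)$y
  list(series = filled, gap_lengths_ms = gap_lengths, usable = TRUE)
}

#' Average the two eyes
#'
#' Per-sample mean of whichever eyes are available; samples with a single
#' eye pass that eye through unchanged.
#'
#' @param left,right Numeric vectors (either may be `NULL` for an unusable
#'   eye, or contain `NA`s).
#' @return Numeric vector.
#' @export
average_eyes <- function(left, right) {
  if (is.null(left) && is.null(right)) {
    stop("both eyes unusable; trial should have been excluded upstream",
         call. = FALSE)
  }
  if (is.null(left)) return(right)
  if (is.null(right)) return(left)
  out <- rowMeans(cbind(left, right), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Pre-stimulus baseline correction
#'
#' Subtracts the mean over the `window_ms` window immediately before sound
#' onset from the whole series, expressing pupil size as relative change
#' (mm). Correcting per trial removes individual and slow-state differences
#' in absolute pupil size.
#'
#' @param series Gap-free series (mm).
#' @param t_ms Sample times (ms since trial onset).
#' @param sound_onset_ms Sound onset (ms).
#' @param window_ms Baseline window length (ms), default 1000.
#' @return List: `rel` (corrected series, full length), `baseline_mm`,
#'   `baseline_idx` (indices of the window).
#' @export
baseline_correct <- function(series, t_ms, sound_onset_ms, window_ms = 1000) {
  stopifnot(length(series) == length(t_ms))
  win <- which(t_ms >= sound_onset_ms - window_ms & t_ms < sound_onset_ms)
  if (!length(win)) {
    stop("no samples in the baseline window", call. = FALSE)
  }
  baseline <- mean(series[win])
  list(rel = series - baseline, baseline_mm = baseline, baseline_idx = win)
}

# Indices of the post-onset analysis window. The trial timeline implies
# 8000 - 3680 = 4320 ms of post-onset data; at exactly 120 Hz only 518
# sample instants fall at or after onset, so to honour the documented count
# of 520 samples the window is allowed to start up to `n_required - available`
# samples (~17 ms) before onset. Returns NULL when the trial is too short.
post_onset_window <- function(t_ms, sound_onset_ms,
                              n_required = POST_ONSET_SAMPLES) {
  n <- length(t_ms)
  first <- which(t_ms >= sound_onset_ms)[1]
  if (is.na(first)) return(NULL)
  avail <- n - first + 1L
  if (avail < n_required) {
    first <- first - (n_required - avail)
    if (first < 1L) return(NULL)
  }
  seq.int(first, first + n_required - 1L)
}

#' Average a corrected series into 50-ms bins
#'
#' Takes the 520-sample post-onset series, averages every 6 consecutive
#' samples into one 50-ms bin, and discards the 4 samples left over at the
#' end of the trial: exactly 86 bins, the last ending 4300 ms after onset.
#'
#' @param rel_series Corrected post-onset series, >= 520 samples (truncated
#'   to 520 if longer).
#' @return Numeric vector of 86 bin means.
#' @export
#' @examples
#' bin_series(rep(0.2, 520))[1:3]
bin_series <- function(rel_series) {
  if (length(rel_series) < POST_ONSET_SAMPLES) {
    stop(sprintf("need %d post-onset samples to form %d bins, got %d; trial excluded",
                 POST_ONSET_SAMPLES, N_BINS, length(rel_series)), call. = FALSE)
  }
  rel_series <- rel_series[seq_len(POST_ONSET_SAMPLES)]
  used <- rel_series[seq_len(N_BINS * SAMPLES_PER_BIN)]
  colMeans(matrix(used, nrow = SAMPLES_PER_BIN))
}

#' Preprocess a single test trial
#'
#' Applies the pipeline in its fixed order: missing-rate inclusion check,
#' per-eye linear interpolation, per-eye zero-phase 4-Hz low-pass (over the
#' full trial, so baseline statistics see the same smoothing), binocular
#' averaging, baseline correction over the 1000 ms before sound onset, and
#' 50-ms binning of the post-onset window.
#'
#' @param trial One trial's sample `data.table`.
#' @param sound_onset_ms Sound onset (ms).
#' @param rate Sampling rate (Hz).
#' @param missing_threshold Trials at or above this missing rate are
#'   excluded (strict `<` test).
#' @param min_baseline_fraction Minimum fraction of the baseline window that
#'   must be present (pre-interpolation) for the trial to be usable.
#' @return List: `missing_rate`, `included`, `reason`, and for included
#'   trials `bins` (86 values), `rel_series` (corrected post-onset window),
#'   `baseline_mm`, `gap_lengths_ms`.
#' @export
preprocess_trial <- function(trial, sound_onset_ms = 3680, rate = 120,
                             missing_threshold = 0.40,
                             min_baseline_fraction = 0.5) {
  mr <- compute_missing_rate(trial, rate = rate)
  out <- list(missing_rate = mr, included = mr < missing_threshold,
              reason = NA_character_, bins = NULL, rel_series = NULL,
              baseline_mm = NA_real_, gap_lengths_ms = numeric(0))
  if (!out$included) {
    out$reason <- "missing_rate"
    return(out)
  }

  dt_ms <- 1000 / rate
  left <- ifelse(trial$left_valid, trial$left_pupil_mm, NA_real_)
  right <- ifelse(trial$right_valid, trial$right_pupil_mm, NA_real_)

  li <- interpolate_gaps(left, dt_ms)
  ri <- interpolate_gaps(right, dt_ms)
  out$gap_lengths_ms <- c(li$gap_lengths_ms, ri$gap_lengths_ms)
  lf <- if (li$usable) lowpass_4hz(li$series, rate) else NULL
  rf <- if (ri$usable) lowpass_4hz(ri$series, rate) else NULL
  if (is.null(lf) && is.null(rf)) {
    out$included <- FALSE
    out$reason <- "no_usable_eye"
    return(out)
  }
  avg <- average_eyes(lf, rf)

  # baseline window must be mostly present (before interpolation)
  win <- which(trial$t_ms >= sound_onset_ms - 1000 & trial$t_ms < sound_onset_ms)
  present_frac <- if (length(win)) {
    mean(trial$left_valid[win] | trial$right_valid[win])
  } else 0
  if (present_frac < min_baseline_fraction) {
    out$included <- FALSE
    out$reason <- "baseline_missing"
    return(out)
  }

  bc <- baseline_correct(avg, trial$t_ms, sound_onset_ms)
  out$baseline_mm <- bc$baseline_mm
  idx <- post_onset_window(trial$t_ms, sound_onset_ms)
  if (is.null(idx)) {
    out$included <- FALSE
    out$reason <- "too_short"
    return(out)
  }
  out$rel_series <- bc$rel[idx]
  out$rel_full <- bc$rel
  out$bins <- bin_series(out$rel_series)
  out
}

#' Trial selection and participant retention
#'
#' Keeps test trials whose missing rate is strictly below the threshold and
#' drops entirely any participant lacking at least one included trial in
#' each of the three conditions.
#'
#' @param trial_summary `data.table` with columns `participant_id`,
#'   `age_group`, `condition`, `missing_rate`, `included`.
#' @param missing_threshold Inclusion threshold (default 0.40).
#' @return List: `trials` (the summary with a final `retained` flag),
#'   `participants` (retained ids), `report` (per-age-group counts).
#' @export
select_trials <- function(trial_summary, missing_threshold = 0.40) {
  ts <- data.table::copy(data.table::as.data.table(trial_summary))
  if (!"included" %in% names(ts)) {
    ts[, included := missing_rate < missing_threshold]
  }
  cover <- ts[included == TRUE,
              .(n_cond = data.table::uniqueN(condition)),
              by = .(participant_id, age_group)]
  keep <- cover[n_cond == length(CONDITIONS), participant_id]
  ts[, retained := included & participant_id %in% keep]
  report <- ts[, .(
    n_trials = .N,
    n_included = sum(included),
    n_participants = data.table::uniqueN(participant_id),
    n_retained_participants = data.table::uniqueN(participant_id[retained])
  ), by = age_group]
  list(trials = ts, participants = keep, report = report)
}

#' Average a participant's included trials per condition
#'
#' @param bins_list List of 86-bin vectors (one per included trial of one
#'   participant x condition cell).
#' @return The element-wise mean, an 86-bin vector.
#' @export
aggregate_condition <- function(bins_list) {
  stopifnot(length(bins_list) >= 1)
  m <- do.call(rbind, bins_list)
  stopifnot(ncol(m) == N_BINS)
  colMeans(m)
}

#' Preprocess a dataset into per-condition time courses
#'
#' Runs [preprocess_trial()] on every test trial, applies the selection
#' rules, aggregates each retained participant's included trials per
#' condition, and assembles, per age group, the participant x condition x
#' bin array that feeds the per-bin tests.
#'
#' @param dataset A `gaze_dataset` (long sample table).
#' @param sound_onset_ms,rate,missing_threshold See [preprocess_trial()].
#' @return List of class `sp_timecourse`: `age_groups` (per group: `array`
#'   \[participant x 3 conditions x 86 bins\], `trial_counts`), `trials`
#'   (per-trial QC table), `selection` (from [select_trials()]), `qc`
#'   (gap-length statistics per age group), `bin_times_ms` (nominal bin end
#'   times after sound onset).
#' @export
preprocess_dataset <- function(dataset, sound_onset_ms = 3680, rate = NULL,
                               missing_threshold = 0.40) {
  rate <- rate %||% (attr(dataset, "sampling_rate") %||% 120)
  test <- data.table::as.data.table(dataset)[phase == "test"]
  if (!nrow(test)) stop("no test-phase trials in dataset", call. = FALSE)

  keys <- c("participant_id", "age_group", "trial_idx", "condition")
  trial_ids <- unique(test[, keys, with = FALSE])

  results <- vector("list", nrow(trial_ids))
  for (i in seq_len(nrow(trial_ids))) {
    tr <- test[trial_ids[i], on = keys]
    results[[i]] <- preprocess_trial(tr, sound_onset_ms, rate,
                                     missing_threshold)
  }
  summary_dt <- data.table::data.table(
    trial_ids,
    missing_rate = vapply(results, `[[`, numeric(1), "missing_rate"),
    included = vapply(results, `[[`, logical(1), "included"),
    reason = vapply(results, `[[`, character(1), "reason")
  )
  sel <- select_trials(summary_dt, missing_threshold)

  groups <- list()
  for (ag in unique(trial_ids$age_group)) {
    pids <- sort(intersect(sel$participants,
                           unique(trial_ids[age_group == ag, participant_id])))
    if (!length(pids)) next
    arr <- array(NA_real_, dim = c(length(pids), length(CONDITIONS), N_BINS),
                 dimnames = list(pids, CONDITIONS, NULL))
    counts <- matrix(0L, length(pids), length(CONDITIONS),
                     dimnames = list(pids, CONDITIONS))
    for (pi in seq_along(pids)) {
      for (ci in seq_along(CONDITIONS)) {
        sel_rows <- which(trial_ids$participant_id == pids[pi] &
                            trial_ids$condition == CONDITIONS[ci] &
                            summary_dt$included)
        bl <- lapply(results[sel_rows], `[[`, "bins")
        bl <- Filter(Negate(is.null), bl)
        counts[pi, ci] <- length(bl)
        if (length(bl)) arr[pi, ci, ] <- aggregate_condition(bl)
      }
    }
    complete <- apply(counts > 0, 1, all)
    groups[[ag]] <- list(array = arr[complete, , , drop = FALSE],
                         trial_counts = counts[complete, , drop = FALSE])
  }

  qc <- list()
  for (ag in unique(trial_ids$age_group)) {
    rows <- which(trial_ids$age_group == ag & summary_dt$included)
    gaps <- unlist(lapply(results[rows], `[[`, "gap_lengths_ms"))
    qc[[ag]] <- gap_qc(gaps)
  }

  structure(list(
    age_groups = groups,
    trials = summary_dt,
    selection = sel,
    qc = qc,
    bin_times_ms = seq(50, by = 50, length.out = N_BINS),
    sound_onset_ms = sound_onset_ms,
    rate = rate
  ), class = "sp_timecourse")
}

# Exponential-fit summary of interpolated gap lengths: MLE mean with a
# normal-approximation 95% CI, and the fraction of gaps under 500 ms.
gap_qc <- function(gap_lengths_ms) {
  n <- length(gap_lengths_ms)
  if (n == 0) {
    return(list(n_gaps = 0L, mean_ms = NA_real_, ci95 = c(NA_real_, NA_real_),
                frac_below_500ms = NA_real_))
  }
  m <- mean(gap_lengths_ms)
  se <- m / sqrt(n)
  list(n_gaps = n, mean_ms = m, ci95 = c(m - 1.96 * se, m + 1.96 * se),
       frac_below_500ms = mean(gap_lengths_ms < 500))
}
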