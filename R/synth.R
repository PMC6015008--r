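# Synthetic switch-paradigm session generator ----------------------------

#' Gamma-shaped pupil dilation kernel
#'
#' Smooth, causal, unimodal dilation curve used as the impulse response of a
#' novelty component. The kernel is a rescaled gamma density: zero at and
#' before `onset_latency_ms`, rising to its peak `amplitude_mm` exactly
#' `rise_time_ms` after onset, then decaying.
#'
#' @param t_ms Times after sound onset (ms), vector.
#' @param onset_latency_ms Component onset after sound onset (ms).
#' @param rise_time_ms Time from onset to peak (ms).
#' @param amplitude_mm Peak dilation (mm).
#' @param shape Gamma shape parameter (> 1); larger values give a more
#'   symmetric bump.
#' @return Numeric vector of dilations (mm), nonnegative, zero before onset.
#' @export
#' @examples
#' k <- gamma_kernel(seq(0, 3000, by = 50), 1300, 600, 0.11)
#' max(k)  # 0.11, at 1900 ms
gamma_kernel <- function(t_ms, onset_latency_ms, rise_time_ms, amplitude_mm,
                         shape = 3) {
  stopifnot(shape > 1, rise_time_ms > 0, amplitude_mm >= 0)
  x <- t_ms - onset_latency_ms
  y <- numeric(length(x))
  pos <- x > 0
  scale <- rise_time_ms / (shape - 1)
  y[pos] <- amplitude_mm * (x[pos] / rise_time_ms)^(shape - 1) *
    exp(-(x[pos] - rise_time_ms) / scale)
  y
}

#' Sample interpolation-gap lengths
#'
#' Gap lengths are exponential with the configured mean, mixed with rare long
#' gaps (also exponential, with a much larger mean) representing sustained
#' tracking loss. Under the defaults the expected fraction of gaps shorter
#' than 500 ms exceeds 0.98.
#'
#' @param n Number of gaps.
#' @param gap_length_mean_ms Mean of the short-gap exponential (ms).
#' @param long_gap_prob Mixture weight of the long-gap component.
#' @param long_gap_length_ms Mean of the long-gap exponential (ms).
#' @return Numeric vector of gap lengths (ms).
#' @export
sample_gap_lengths <- function(n, gap_length_mean_ms, long_gap_prob = 0,
                               long_gap_length_ms = 600) {
  stopifnot(gap_length_mean_ms > 0, long_gap_prob >= 0, long_gap_prob <= 1)
  if (n == 0) return(numeric(0))
  is_long <- runif(n) < long_gap_prob
  len <- rexp(n, rate = 1 / gap_length_mean_ms)
  if (any(is_long)) {
    len[is_long] <- rexp(sum(is_long), rate = 1 / long_gap_length_ms)
  }
  len
}

# Two-state looking/away Markov chain realised by alternating geometric
# dwell times; p is the stationary looking probability, r the per-sample
# switching "granularity".
markov_onscreen <- function(n, p, r) {
  if (n == 0L) return(logical(0))
  p <- min(max(p, 1e-6), 1 - 1e-6)
  out <- logical(n)
  state <- runif(1) < p
  i <- 1L
  while (i <= n) {
    leave_prob <- if (state) r * (1 - p) else r * p
    len <- if (leave_prob <= 0) n else rgeom(1, leave_prob) + 1L
    j <- min(n, i + len - 1L)
    out[i:j] <- state
    state <- !state
    i <- j + 1L
  }
  out
}

#' Draw participant-level parameters
#'
#' Baseline pupil size, per-component response amplitudes (lognormal around
#' the configured mean, so amplitudes are guaranteed nonnegative), and the
#' participant's looking-disposition effects on the logit scale.
#'
#' @param config A [sim_config()].
#' @param age_group Age-group label present in `config`.
#' @param id Participant identifier.
#' @return List of participant parameters.
#' @export
make_participant <- function(config, age_group, id) {
  grp <- config$age_groups[[age_group]]
  if (is.null(grp)) stop("unknown age_group: ", age_group, call. = FALSE)
  amps <- vapply(grp$components, function(cmp) {
    cv <- cmp$amplitude_cv %||% 0
    if (cv > 0) {
      cmp$amplitude_mm * exp(rnorm(1, 0, cv) - cv^2 / 2)
    } else {
      cmp$amplitude_mm
    }
  }, numeric(1))
  list(
    id = id,
    age_group = age_group,
    baseline_mm = rnorm(1, config$baseline_pupil_mm[["mean"]],
                        config$baseline_pupil_mm[["sd"]]),
    amplitudes = amps,
    looking_u = rnorm(1, 0, config$looking$participant_sd),
    looking_slope = rnorm(1, 0, config$looking$habituation_slope_sd)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one trial's binocular trace
#'
#' Both eyes share the same underlying signal — participant baseline, a slow
#' random-walk drift, and the dilation kernels of every component affecting
#' the trial's condition, time-locked to sound onset — and differ only by
#' independent per-sample Gaussian noise. Familiarization trials carry no
#' dilation components (only their looking flags are analysed downstream).
#'
#' Sampling uses the session RNG; call [set.seed()] (or use
#' [generate_dataset()], which seeds from the config) for reproducibility.
#'
#' @param config A [sim_config()].
#' @param participant A list from [make_participant()], or a character id (in
#'   which case participant parameters are drawn first).
#' @param age_group Age-group label; must exist in `config`.
#' @param condition `"familiar"`, `"switched"` or `"novel"` for test trials;
#'   a pair label (e.g. `"A1-S1"`) for familiarization trials.
#' @param phase `"test"` or `"familiarization"`.
#' @param block Familiarization block index (1-based), `NA` for test trials.
#' @param trial_idx Trial index within the phase.
#' @param dropout If `TRUE`, a long contiguous both-eye gap is injected so
#'   the trial's missing rate lands in `config$dropout_missing_range`.
#' @return A `data.table` with the canonical gaze columns (one row per
#'   sample).
#' @export
generate_trial_trace <- function(config, participant, age_group, condition,
                                 phase = c("test", "familiarization"),
                                 block = NA_integer_, trial_idx = 1L,
                                 dropout = FALSE) {
  phase <- match.arg(phase)
  grp <- config$age_groups[[age_group]]
  if (is.null(grp)) stop("unknown age_group: ", age_group, call. = FALSE)
  if (phase == "test" && !condition %in% c("familiar", "switched", "novel")) {
    stop("unknown test condition: ", condition, call. = FALSE)
  }
  if (is.character(participant)) {
    participant <- make_participant(config, age_group, participant)
  }

  tl <- config$trial_timeline
  duration <- if (phase == "test") tl$test_duration_ms else tl$familiarization_duration_ms
  rate <- config$sampling_rate
  dt <- 1000 / rate
  n <- ceiling(duration * rate / 1000)
  t_ms <- round((seq_len(n) - 1) * dt, 3)

  signal <- rep(participant$baseline_mm, n) +
    cumsum(rnorm(n, 0, config$drift_sd_mm))
  if (phase == "test") {
    rel_t <- t_ms - tl$sound_onset_ms
    for (nm in names(grp$components)) {
      cmp <- grp$components[[nm]]
      if (condition %in% cmp$conditions_affected) {
        signal <- signal + gamma_kernel(rel_t, cmp$onset_latency_ms,
                                        cmp$rise_time_ms,
                                        participant$amplitudes[[nm]],
                                        cmp$shape %||% 3)
      }
    }
  }
  # 1e-6 mm quantisation keeps the TSV round-trip exactly lossless
  left <- round(signal + rnorm(n, 0, config$noise_sd_mm), 6)
  right <- round(signal + rnorm(n, 0, config$noise_sd_mm), 6)

  on_screen <- generate_onscreen(config, participant, phase, condition, block, n)

  trial <- data.table::data.table(
    participant_id = participant$id,
    age_group = age_group,
    phase = phase,
    block = as.integer(block),
    trial_idx = as.integer(trial_idx),
    condition = condition,
    t_ms = t_ms,
    left_pupil_mm = left,
    right_pupil_mm = right,
    left_valid = TRUE,
    right_valid = TRUE,
    on_screen = on_screen
  )

  if (config$gap_process$enabled || dropout) {
    trial <- inject_missingness(
      trial, config$gap_process,
      gap_length_mean_ms = grp$gap_length_mean_ms,
      dropout = dropout,
      dropout_missing_range = config$dropout_missing_range
    )
  }
  trial
}

# Looking target probability on the logit scale, then a two-state Markov
# realisation with that stationary probability.
generate_onscreen <- function(config, participant, phase, condition, block, n) {
  lk <- config$looking
  ag <- participant$age_group
  m <- if (phase == "test") {
    tc <- lk$test_condition_means[[ag]]
    if (condition %in% names(tc)) tc[[condition]] else mean(tc)
  } else {
    bm <- lk$fam_block_means[[ag]]
    b <- if (is.na(block)) 1L else min(block, length(bm))
    bm[[b]]
  }
  eta <- qlogis(m) + participant$looking_u + rnorm(1, 0, lk$trial_sd)
  if (phase == "familiarization" && !is.na(block)) {
    eta <- eta + participant$looking_slope * (block - 2.5)
  }
  markov_onscreen(n, plogis(eta), lk$switch_rate_per_sample)
}

#' Inject blink/dropout gaps into a clean trial
#'
#' Gap onsets arrive as a Poisson process along the trial; lengths follow the
#' short/long exponential mixture of [sample_gap_lengths()]. Each gap hits
#' both eyes with probability `gap_process$both_eyes_prob`, otherwise one
#' randomly chosen eye. Samples inside a gap get their validity flag cleared
#' and their diameter removed. Optionally one long contiguous "distraction"
#' dropout is added so the trial exceeds the inclusion threshold downstream.
#'
#' @param trial A trial `data.table` with no prior gaps (all samples valid).
#' @param gap_process The `gap_process` list of a [sim_config()].
#' @param gap_length_mean_ms Mean short-gap length (ms).
#' @param dropout Add the long distraction dropout?
#' @param dropout_missing_range Range of the intended missing fraction for
#'   dropout trials.
#' @return The trial with gaps applied.
#' @export
inject_missingness <- function(trial, gap_process, gap_length_mean_ms,
                               dropout = FALSE,
                               dropout_missing_range = c(0.45, 0.70)) {
  if (!all(trial$left_valid) || !all(trial$right_valid)) {
    stop("inject_missingness() expects a trial with no prior gaps",
         call. = FALSE)
  }
  n <- nrow(trial)
  duration_ms <- n * 1000 / infer_rate(trial$t_ms)
  left_gap <- logical(n)
  right_gap <- logical(n)

  if (isTRUE(gap_process$enabled) && gap_process$gap_rate_per_s > 0) {
    n_gaps <- rpois(1, gap_process$gap_rate_per_s * duration_ms / 1000)
    if (n_gaps > 0) {
      starts <- runif(n_gaps, 0, duration_ms)
      lens <- sample_gap_lengths(n_gaps, gap_length_mean_ms,
                                 gap_process$long_gap_prob,
                                 gap_process$long_gap_length_ms)
      both <- runif(n_gaps) < gap_process$both_eyes_prob
      left_eye <- both | (runif(n_gaps) < 0.5)
      right_eye <- both | !left_eye
      for (g in seq_len(n_gaps)) {
        hit <- trial$t_ms >= starts[g] & trial$t_ms < starts[g] + lens[g]
        if (left_eye[g]) left_gap <- left_gap | hit
        if (right_eye[g]) right_gap <- right_gap | hit
      }
    }
  }

  if (isTRUE(dropout)) {
    frac <- runif(1, dropout_missing_range[1], dropout_missing_range[2])
    len <- frac * duration_ms
    start <- runif(1, 0, duration_ms - len)
    hit <- trial$t_ms >= start & trial$t_ms < start + len
    left_gap <- left_gap | hit
    right_gap <- right_gap | hit
  }

  if (any(left_gap)) {
    trial[left_gap, `:=`(left_valid = FALSE, left_pupil_mm = NA_real_)]
  }
  if (any(right_gap)) {
    trial[right_gap, `:=`(right_valid = FALSE, right_pupil_mm = NA_real_)]
  }
  trial
}

infer_rate <- function(t_ms) {
  if (length(t_ms) < 2) return(120)
  round(1000 / stats::median(diff(t_ms)))
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from `config$seed` and generates, in a fixed order, every
#' participant of every configured age group: 4 familiarization blocks x 4
#' trials (two audio-visual pairs, two screen sides), then the test phase
#' (default 2 familiar, 2 switched, 1 novel trial). A configured fraction of
#' test trials receives a distraction dropout pushing it over the
#' missing-rate threshold. Identical seed and config give identical output.
#'
#' @param config A [sim_config()].
#' @param phases Which phases to generate; structure-recovery simulations can
#'   skip familiarization for speed.
#' @return A `gaze_dataset`: a long `data.table` (one row per sample) with
#'   attributes `seed`, `config_hash` and `sampling_rate`.
#' @export
#' @examples
#' ds <- generate_dataset(sim_config(seed = 7, age_groups = "15mo",
#'                                   n_participants = c("15mo" = 2)))
#' nrow(ds)
generate_dataset <- function(config,
                             phases = c("familiarization", "test")) {
  validate_config(config)
  phases <- match.arg(phases, several.ok = TRUE)
  set.seed(config$seed)

  fam_pairs <- c("A1-S1", "A2-S2")
  trials <- list()
  for (ag in names(config$age_groups)) {
    grp <- config$age_groups[[ag]]
    for (i in seq_len(grp$n_participants)) {
      pid <- sprintf("%s_p%02d", ag, i)
      part <- make_participant(config, ag, pid)

      if ("familiarization" %in% phases) {
        idx <- 0L
        for (b in seq_len(config$n_familiarization_blocks)) {
          conds <- rep(fam_pairs,
                       length.out = config$familiarization_trials_per_block)
          for (cond in sample(conds)) {
            idx <- idx + 1L
            trials[[length(trials) + 1L]] <- generate_trial_trace(
              config, part, ag, cond,
              phase = "familiarization", block = b, trial_idx = idx
            )
          }
        }
      }

      if ("test" %in% phases) {
        test_conds <- c(
          rep("familiar", config$n_test_trials[["familiar"]]),
          rep("switched", config$n_test_trials[["switched"]])
        )
        # familiar/switched order counterbalanced, novel always last
        test_conds <- c(sample(test_conds), rep("novel", config$n_test_trials[["novel"]]))
        for (k in seq_along(test_conds)) {
          drop_trial <- runif(1) < grp$exclusion_target
          trials[[length(trials) + 1L]] <- generate_trial_trace(
            config, part, ag, test_conds[k],
            phase = "test", block = NA_integer_, trial_idx = k,
            dropout = drop_trial
          )
        }
      }
    }
  }

  ds <- if (length(trials)) {
    data.table::rbindlist(trials)
  } else {
    empty_gaze_table()
  }
  as_gaze_dataset(ds, seed = config$seed, config_hash = config_hash(config),
                  sampling_rate = config$sampling_rate)
}

#' Design table of a dataset
#'
#' One row per trial with its metadata and sample count.
#'
#' @param dataset A `gaze_dataset` (long sample table).
#' @return A `data.table` keyed by participant, phase and trial index.
#' @export
design_table <- function(dataset) {
  dataset[, .(n_samples = .N, duration_ms = max(t_ms) + 1000 / infer_rate(t_ms)),
          by = .(participant_id, age_group, phase, block, trial_idx, condition)]
}
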