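# Simulation configuration -----------------------------------------------

#' Default response components for an age-group profile
#'
#' Two dilation components are modelled: a fast *perceptual-novelty*
#' component, present only in the novel condition, and a slow
#' *association-novelty* component, present only in the switched condition.
#' The younger profile carries no association component: infants of that age
#' are assumed not to have formed the audio-visual pairing.
#'
#' Onset latencies are times after sound onset (ms); `rise_time_ms` is the
#' kernel's time to peak; `amplitude_mm` the peak dilation in mm;
#' `amplitude_cv` the lognormal coefficient of variation of the amplitude
#' across participants.
#'
#' @param age_group `"10mo"` or `"15mo"`.
#' @return Named list of component parameter lists.
#' @export
default_components <- function(age_group = c("15mo", "10mo")) {
  age_group <- match.arg(age_group)
  perceptual <- list(
    name = "perceptual_novelty",
    onset_latency_ms = if (age_group == "15mo") 1300 else 2000,
    rise_time_ms = if (age_group == "15mo") 800 else 750,
    amplitude_mm = if (age_group == "15mo") 0.14 else 0.10,
    amplitude_cv = if (age_group == "15mo") 0.65 else 0.70,
    shape = 3,
    conditions_affected = "novel"
  )
  if (age_group == "10mo") {
    return(list(perceptual_novelty = perceptual))
  }
  association <- list(
    name = "association_novelty",
    onset_latency_ms = 3950,
    rise_time_ms = 500,
    amplitude_mm = 0.10,
    amplitude_cv = 0.5,
    shape = 3,
    conditions_affected = "switched"
  )
  list(perceptual_novelty = perceptual, association_novelty = association)
}

#' Build a simulation configuration
#'
#' Returns the full parameterisation of a synthetic cohort. Defaults describe
#' a two-age-group switch-paradigm session: a familiarization phase of 4
#' blocks x 4 nine-second trials, followed by five 8-second test trials
#' (2 familiar, 2 switched, 1 novel), recorded binocularly at 120 Hz with the
#' test-trial sound starting at 3680 ms. Blink/dropout gaps arrive as a
#' Poisson process with approximately exponential lengths; a configurable
#' fraction of test trials additionally receives a long "distraction" dropout
#' so that they exceed the 40% missing-rate inclusion threshold downstream.
#'
#' @param seed Integer seed; the same seed and config give byte-identical
#'   datasets.
#' @param age_groups Character subset of `c("10mo", "15mo")`.
#' @param n_participants Named integer vector per age group; `NULL` for the
#'   defaults (18 ten-month-olds, 16 fifteen-month-olds).
#' @param exclusion_target Named numeric vector per age group: fraction of
#'   test trials pushed over the missing-rate threshold (`NULL` for defaults
#'   0.20 / 0.25).
#' @param components `NULL` for age-appropriate defaults (see
#'   [default_components()]), or a named list (one entry per age group) of
#'   component lists. Use `list("15mo" = list())` etc. for a null
#'   (no-dilation) cohort.
#' @param noise_sd_mm Per-eye, per-sample Gaussian measurement noise (mm).
#' @param drift_sd_mm Per-sample standard deviation of the shared slow
#'   random-walk drift (mm).
#' @param gaps Logical; `FALSE` disables the gap process entirely.
#' @param gap_rate_per_s Poisson rate of gap onsets per second per trial.
#' @param long_gap_prob Mixture probability of a long (e.g. look-away) gap.
#' @param long_gap_length_ms Mean length of long gaps (exponential).
#' @param sampling_rate Samples per second (Hz).
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 42, age_groups = "15mo")
#' cfg$trial_timeline$sound_onset_ms
sim_config <- function(seed = 1L,
                       age_groups = c("10mo", "15mo"),
                       n_participants = NULL,
                       exclusion_target = NULL,
                       components = NULL,
                       noise_sd_mm = 0.08,
                       drift_sd_mm = 0.002,
                       gaps = TRUE,
                       gap_rate_per_s = 2,
                       long_gap_prob = 0.01,
                       long_gap_length_ms = 600,
                       sampling_rate = 120) {
  age_groups <- match.arg(age_groups, c("10mo", "15mo"), several.ok = TRUE)
  def_n <- c("10mo" = 18L, "15mo" = 16L)
  def_excl <- c("10mo" = 0.20, "15mo" = 0.25)
  def_gapmean <- c("10mo" = 32.3, "15mo" = 37.4)

  groups <- list()
  for (ag in age_groups) {
    n <- if (!is.null(n_participants) && ag %in% names(n_participants)) {
      as.integer(n_participants[[ag]])
    } else {
      def_n[[ag]]
    }
    ex <- if (!is.null(exclusion_target) && ag %in% names(exclusion_target)) {
      exclusion_target[[ag]]
    } else {
      def_excl[[ag]]
    }
    comp <- if (!is.null(components) && ag %in% names(components)) {
      components[[ag]]
    } else {
      default_components(ag)
    }
    groups[[ag]] <- list(
      n_participants = n,
      exclusion_target = ex,
      gap_length_mean_ms = def_gapmean[[ag]],
      components = comp
    )
  }

  cfg <- list(
    seed = as.integer(seed),
    sampling_rate = sampling_rate,
    trial_timeline = list(
      test_duration_ms = 8000,
      sound_onset_ms = 3680,
      familiarization_duration_ms = 9000
    ),
    n_test_trials = c(familiar = 2L, switched = 2L, novel = 1L),
    n_familiarization_blocks = 4L,
    familiarization_trials_per_block = 4L,
    baseline_pupil_mm = c(mean = 4.5, sd = 0.4),
    noise_sd_mm = noise_sd_mm,
    drift_sd_mm = drift_sd_mm,
    gap_process = list(
      enabled = isTRUE(gaps),
      gap_rate_per_s = gap_rate_per_s,
      long_gap_prob = long_gap_prob,
      long_gap_length_ms = long_gap_length_ms,
      both_eyes_prob = 0.8
    ),
    dropout_missing_range = c(0.45, 0.70),
    age_groups = groups,
    looking = list(
      switch_rate_per_sample = 0.02,
      participant_sd = 0.6,     # logit scale, shared across a participant
      trial_sd = 0.7,           # logit scale, per trial
      habituation_slope_sd = 0.3,
      fam_block_means = list(
        "10mo" = c(0.919, 0.873, 0.865, 0.800),
        "15mo" = c(0.913, 0.899, 0.847, 0.782)
      ),
      test_condition_means = list(
        "10mo" = c(familiar = 0.895, switched = 0.920, novel = 0.952),
        "15mo" = c(familiar = 0.839, switched = 0.895, novel = 0.961)
      )
    )
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants (positive durations, sound onset inside
#' the trial, nonnegative amplitudes, probabilities in \[0, 1\]) and errors
#' with an informative message on the first violation.
#'
#' @param config A `sim_config` list.
#' @return The config, invisibly.
#' @export
validate_config <- function(config) {
  tl <- config$trial_timeline
  stopifnot(is.list(tl))
  if (!all(unlist(tl) > 0)) {
    stop("all trial durations must be > 0", call. = FALSE)
  }
  if (tl$sound_onset_ms >= tl$test_duration_ms) {
    stop("sound_onset_ms must be < test_duration_ms", call. = FALSE)
  }
  if (config$sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (config$noise_sd_mm < 0 || config$drift_sd_mm < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  gp <- config$gap_process
  if (gp$gap_rate_per_s < 0) stop("gap_rate_per_s must be >= 0", call. = FALSE)
  if (gp$long_gap_prob < 0 || gp$long_gap_prob > 1) {
    stop("long_gap_prob must lie in [0, 1]", call. = FALSE)
  }
  for (ag in names(config$age_groups)) {
    grp <- config$age_groups[[ag]]
    if (grp$n_participants < 0) stop("n_participants must be >= 0", call. = FALSE)
    if (grp$exclusion_target < 0 || grp$exclusion_target > 1) {
      stop("exclusion_target must lie in [0, 1]", call. = FALSE)
    }
    if (grp$gap_length_mean_ms <= 0) {
      stop("gap_length_mean_ms must be > 0", call. = FALSE)
    }
    for (cmp in grp$components) {
      if (cmp$amplitude_mm < 0) stop("component amplitudes must be >= 0", call. = FALSE)
      if (cmp$onset_latency_ms < 0 || cmp$rise_time_ms <= 0) {
        stop("component latencies must be >= 0 and rise times > 0", call. = FALSE)
      }
      if (!all(cmp$conditions_affected %in% c("familiar", "switched", "novel"))) {
        stop("conditions_affected must be a subset of familiar/switched/novel",
             call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Read / write a run configuration as JSON
#'
#' @param path File path.
#' @param config A `sim_config`.
#' @return `read_config` returns a validated `sim_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # read_json simplifies the per-age component lists; re-nest scalars
  cfg$n_test_trials <- unlist(cfg$n_test_trials)
  cfg$baseline_pupil_mm <- unlist(cfg$baseline_pupil_mm)
  cfg$dropout_missing_range <- unlist(cfg$dropout_missing_range)
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; recorded in output file headers
#' so that a dataset can be traced to the exact configuration that produced
#' it.
#'
#' @param config A `sim_config`.
#' @return Character MD5 hex digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
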