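# Proportion-of-looking-time measures -------------------------------------

#' Proportion of looking time in a trial
#'
#' Sum of on-screen sample time divided by the nominal trial duration
#' (whole-screen area of interest: any on-screen-flagged sample counts as
#' looking). Time-weighted, so the proportion is invariant to the sampling
#' rate.
#'
#' @param trial One trial's sample `data.table`.
#' @param duration_ms Nominal duration (defaults by phase as in
#'   [compute_missing_rate()]).
#' @param rate Sampling rate (Hz).
#' @return Fraction in \[0, 1\].
#' @export
proportion_looking <- function(trial, duration_ms = NULL, rate = 120) {
  if (is.null(duration_ms)) {
    duration_ms <- if (identical(unique(trial$phase), "familiarization")) 9000 else 8000
  }
  looking_ms <- sum(trial$on_screen) * 1000 / rate
  min(1, looking_ms / duration_ms)
}

#' Per-trial looking records for a dataset
#'
#' @param dataset A `gaze_dataset` (long sample table).
#' @param rate Sampling rate; taken from the dataset attribute by default.
#' @return `data.table`: one row per trial with `looking_ms` and
#'   `proportion`.
#' @export
looking_records <- function(dataset, rate = NULL) {
  rate <- rate %||% (attr(dataset, "sampling_rate") %||% 120)
  dt <- data.table::as.data.table(dataset)
  rec <- dt[, .(
    looking_ms = sum(on_screen) * 1000 / rate,
    duration_ms = ifelse(phase[1] == "familiarization", 9000, 8000)
  ), by = .(participant_id, age_group, phase, block, trial_idx, condition)]
  rec[, proportion := pmin(1, looking_ms / duration_ms)]
  rec[]
}

#' Familiarization-phase block summary and habituation test
#'
#' Per-participant block means of the looking proportion (4 trials per
#' block), group mean and SE per block, and the block-1 versus block-4
#' paired t-test (two-tailed) with Hedges' g_av — the check that looking
#' declined over familiarization. Participants missing a block are dropped
#' from the test with a warning. A zero-variance block difference is
#' flagged degenerate.
#'
#' @param records Looking records (one age group's familiarization trials),
#'   as from [looking_records()].
#' @return List: `block_means` (per participant), `group_summary` (mean/SE
#'   per block), `block1_vs_4` (t, df, p, g_av, degenerate), `n`.
#' @export
familiarization_block_summary <- function(records) {
  rec <- data.table::as.data.table(records)[phase == "familiarization"]
  if (!nrow(rec)) stop("no familiarization trials in records", call. = FALSE)
  bm <- rec[, .(proportion = mean(proportion)), by = .(participant_id, block)]
  n_blocks <- max(bm$block)
  complete <- bm[, .N, by = participant_id][N == n_blocks, participant_id]
  dropped <- setdiff(unique(bm$participant_id), complete)
  if (length(dropped)) {
    warning(sprintf("dropping %d participant(s) missing a block: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    bm <- bm[participant_id %in% complete]
  }
  group <- bm[, .(mean = mean(proportion), se = sd(proportion) / sqrt(.N)),
              keyby = block]
  wide <- data.table::dcast(bm, participant_id ~ block, value.var = "proportion")
  b1 <- wide[["1"]]
  b4 <- wide[[as.character(n_blocks)]]
  test <- posthoc_paired_t(b1, b4, n_comparisons = 1)
  list(block_means = bm, group_summary = group,
       block1_vs_4 = test, n = length(b1))
}

#' Compare the familiarization decline between two age groups
#'
#' The per-participant reduction (block 1 minus block 4) is compared across
#' groups with an independent-samples t-test (pooled variance) and Hedges'
#' g_s.
#'
#' @param summary1,summary2 Results of [familiarization_block_summary()] for
#'   the two groups.
#' @return List: `t`, `df`, `p`, `g_s`.
#' @export
familiarization_group_comparison <- function(summary1, summary2) {
  red <- function(s) {
    wide <- data.table::dcast(s$block_means, participant_id ~ block,
                              value.var = "proportion")
    nb <- ncol(wide) - 1
    wide[[2]] - wide[[nb + 1]]
  }
  r1 <- red(summary1); r2 <- red(summary2)
  tt <- stats::t.test(r1, r2, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, g_s = hedges_g_s(r1, r2))
}

#' Test-phase looking-time comparisons
#'
#' Per-participant condition means feed a one-way repeated-measures ANOVA
#' over the three conditions, followed by the planned one-tailed paired
#' comparisons novel > familiar and switched > familiar (uncorrected: the
#' directional predictions are made in advance) with Hedges' g_av.
#'
#' @param records Looking records for one age group's test phase.
#' @return List: `condition_means` (per participant), `group_summary`,
#'   `anova` (F, df, p, eta_p2), `novel_vs_familiar`,
#'   `switched_vs_familiar` (each: t, df, p one-tailed, g_av, degenerate),
#'   `n`.
#' @export
test_phase_comparisons <- function(records) {
  rec <- data.table::as.data.table(records)[phase == "test"]
  if (!nrow(rec)) stop("no test trials in records", call. = FALSE)
  cm <- rec[, .(proportion = mean(proportion)),
            by = .(participant_id, condition)]
  complete <- cm[, .N, by = participant_id][N == length(CONDITIONS),
                                            participant_id]
  cm <- cm[participant_id %in% complete]
  wide <- data.table::dcast(cm, participant_id ~ condition,
                            value.var = "proportion")
  m <- as.matrix(wide[, CONDITIONS, with = FALSE])
  rownames(m) <- wide$participant_id

  anova <- rm_anova_bin(m)
  group <- cm[, .(mean = mean(proportion), se = sd(proportion) / sqrt(.N)),
              keyby = condition]
  list(
    condition_means = cm,
    group_summary = group,
    anova = anova,
    novel_vs_familiar = posthoc_paired_t(m[, "novel"], m[, "familiar"],
                                         n_comparisons = 1,
                                         alternative = "greater"),
    switched_vs_familiar = posthoc_paired_t(m[, "switched"], m[, "familiar"],
                                            n_comparisons = 1,
                                            alternative = "greater"),
    n = nrow(m)
  )
}
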