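# End-to-end orchestration ------------------------------------------------

#' Per-bin analysis of a condition time course
#'
#' For one age group's participant x condition x bin array: per-bin one-way
#' repeated-measures ANOVA (F, p, partial eta-squared), the consecutive-bin
#' significance rule, per-bin Bonferroni-corrected post-hoc paired t-tests
#' with Hedges' g_av for the three pairwise contrasts, and cluster-based
#' Monte-Carlo permutation p-values for the omnibus test and each pairwise
#' contrast.
#'
#' @param Y Array `[n, 3, 86]` with condition dimnames.
#' @param n_perm Permutations per contrast.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param bin_times_ms Nominal bin end times (ms after sound onset).
#' @return List of class `sp_analysis`: `bins` (per-bin table), `posthoc`
#'   (per contrast: per-bin t, p_bonf, g_av), `clusters` (per contrast,
#'   `sp_clusters`), `df`, `n`.
#' @export
analyze_timecourse <- function(Y, n_perm = 1000, alpha = 0.05, seed,
                               bin_times_ms = seq(50, by = 50,
                                                  length.out = dim(Y)[3])) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(length(dim(Y)) == 3)
  n <- dim(Y)[1]
  an <- rm_anova_bins(Y)
  Fv <- ifelse(is.na(an$F), 0, an$F)
  pv <- ifelse(is.na(an$p), 1, an$p)
  bins <- data.table::data.table(
    bin = seq_len(dim(Y)[3]),
    time_ms = bin_times_ms,
    F = Fv, p = pv,
    eta_p2 = ifelse(is.na(an$eta_p2), 0, an$eta_p2),
    significant_raw = pv < alpha,
    significant_rule = consecutive_rule(pv, alpha)
  )

  pairs <- list(c("novel", "familiar"), c("novel", "switched"),
                c("switched", "familiar"))
  posthoc <- list()
  for (pr in pairs) {
    lab <- paste(pr, collapse = "-")
    x1 <- matrix(Y[, pr[1], ], n)
    x2 <- matrix(Y[, pr[2], ], n)
    res <- lapply(seq_len(ncol(x1)), function(b) {
      posthoc_paired_t(x1[, b], x2[, b], n_comparisons = length(pairs))
    })
    posthoc[[lab]] <- data.table::data.table(
      bin = seq_len(ncol(x1)),
      time_ms = bin_times_ms,
      t = vapply(res, `[[`, numeric(1), "t"),
      p_bonf = vapply(res, `[[`, numeric(1), "p_bonf"),
      g_av = vapply(res, function(r) r$g_av$value, numeric(1)),
      degenerate = vapply(res, `[[`, logical(1), "degenerate")
    )
  }

  clusters <- list(
    omnibus = cluster_permutation(Y, "omnibus", n_perm, alpha, seed = seed)
  )
  for (i in seq_along(pairs)) {
    lab <- paste(pairs[[i]], collapse = "-")
    clusters[[lab]] <- cluster_permutation(Y, pairs[[i]], n_perm, alpha,
                                           seed = seed + i)
  }

  structure(list(bins = bins, posthoc = posthoc, clusters = clusters,
                 df = an$df, n = n, alpha = alpha),
            class = "sp_analysis")
}

#' Run the whole pipeline on a configuration
#'
#' simulate -> write/read the gaze export -> preprocess -> looking-time
#' summaries -> per-bin statistics and cluster permutation tests, with all
#' outputs and a run manifest written under `out_dir`. Deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_perm Permutations per contrast.
#' @param alpha Significance level.
#' @param make_plots Also write time-course and F/eta figures (PNG).
#' @return List of class `sp_run`: `manifest`, `timecourse`
#'   (`sp_timecourse`), `looking`, `analysis` (per age group), `paths`.
#' @export
run_pipeline <- function(config, out_dir, n_perm = 1000, alpha = 0.05,
                         make_plots = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    gaze = file.path(out_dir, "gaze.tsv"),
    timecourse = file.path(out_dir, "timecourse.tsv"),
    looking = file.path(out_dir, "looking_summary.tsv"),
    results = file.path(out_dir, "results.json"),
    qc = file.path(out_dir, "qc.json"),
    manifest = file.path(out_dir, "manifest.json")
  )

  stage <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                              format(Sys.time(), "%H:%M:%S"), ...))

  stage("simulate: seed %d", config$seed)
  ds <- generate_dataset(config)
  write_gaze_table(ds, paths$gaze)
  ds <- read_gaze_table(paths$gaze)
  stage("simulate: %d samples, %d trials", nrow(ds), nrow(design_table(ds)))

  tc <- preprocess_dataset(ds)
  for (ag in names(tc$qc)) {
    q <- tc$qc[[ag]]
    stage("preprocess %s: %d gaps interpolated, %.1f%% < 500 ms, mean %.1f ms",
          ag, q$n_gaps, 100 * (q$frac_below_500ms %||% NA), q$mean_ms %||% NA)
  }
  print_report <- tc$selection$report
  for (i in seq_len(nrow(print_report))) {
    with(print_report[i], stage(
      "include %s: %d/%d trials, %d/%d participants retained",
      age_group, n_included, n_trials, n_retained_participants, n_participants))
  }

  rec <- looking_records(ds)
  looking <- list()
  for (ag in unique(rec$age_group)) {
    r <- rec[age_group == ag]
    looking[[ag]] <- list(
      familiarization = if (any(r$phase == "familiarization")) {
        familiarization_block_summary(r)
      },
      test = test_phase_comparisons(r)
    )
  }
  if (length(looking) == 2 &&
      !any(vapply(looking, function(l) is.null(l$familiarization), logical(1)))) {
    looking$group_comparison <- familiarization_group_comparison(
      looking[[1]]$familiarization, looking[[2]]$familiarization)
  }

  analysis <- list()
  for (i in seq_along(tc$age_groups)) {
    ag <- names(tc$age_groups)[i]
    Y <- tc$age_groups[[ag]]$array
    stage("analyze %s: n = %d, df = (2, %d)", ag, dim(Y)[1], 2 * (dim(Y)[1] - 1))
    analysis[[ag]] <- analyze_timecourse(
      Y, n_perm = n_perm, alpha = alpha,
      seed = config$seed + 7919L * i, bin_times_ms = tc$bin_times_ms)
  }

  write_timecourse_tsv(tc, paths$timecourse)
  write_looking_tsv(looking, paths$looking)
  jsonlite::write_json(serialize_results(analysis, looking), paths$results,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  jsonlite::write_json(serialize_qc(tc), paths$qc, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  if (make_plots) {
    for (ag in names(tc$age_groups)) {
      paths[[paste0("fig_timecourse_", ag)]] <-
        plot_timecourse(tc, ag, file.path(out_dir, sprintf("timecourse_%s.png", ag)))
      paths[[paste0("fig_stats_", ag)]] <-
        plot_bin_stats(analysis[[ag]], file.path(out_dir, sprintf("binstats_%s.png", ag)))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("switchpupil")),
    config_hash = config_hash(config),
    seed = config$seed,
    n_perm = n_perm,
    counts = list(
      samples = nrow(ds),
      trials = nrow(design_table(ds)),
      test_trials = nrow(tc$trials),
      included_test_trials = sum(tc$trials$included),
      retained_participants = vapply(tc$age_groups,
                                     function(g) dim(g$array)[1], integer(1))
    ),
    outputs = lapply(paths[!vapply(paths, is.null, logical(1))], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  structure(list(manifest = manifest, timecourse = tc, looking = looking,
                 analysis = analysis, paths = paths), class = "sp_run")
}

write_timecourse_tsv <- function(tc, path) {
  rows <- list()
  for (ag in names(tc$age_groups)) {
    Y <- tc$age_groups[[ag]]$array
    dn <- dimnames(Y)
    for (ci in seq_len(dim(Y)[2])) {
      m <- matrix(Y[, ci, ], dim(Y)[1])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        age_group = ag,
        participant_id = rep(dn[[1]], times = ncol(m)),
        condition = dn[[2]][ci],
        bin = rep(seq_len(ncol(m)), each = nrow(m)),
        time_ms = rep(tc$bin_times_ms, each = nrow(m)),
        rel_pupil_mm = as.vector(m)
      )
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, age_group, participant_id, condition, bin)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

write_looking_tsv <- function(looking, path) {
  rows <- list()
  for (ag in setdiff(names(looking), "group_comparison")) {
    fam <- looking[[ag]]$familiarization
    if (!is.null(fam)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        age_group = ag, section = "familiarization_block",
        level = as.character(fam$group_summary$block),
        mean = fam$group_summary$mean, se = fam$group_summary$se)
    }
    tst <- looking[[ag]]$test
    rows[[length(rows) + 1L]] <- data.table::data.table(
      age_group = ag, section = "test_condition",
      level = as.character(tst$group_summary$condition),
      mean = tst$group_summary$mean, se = tst$group_summary$se)
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

serialize_results <- function(analysis, looking) {
  ser_test <- function(t) {
    if (is.null(t)) return(NULL)
    out <- t[setdiff(names(t), "g_av")]
    if (!is.null(t$g_av)) out$g_av <- t$g_av$value
    if (!is.null(t$g_s)) out$g_s <- t$g_s$value
    out
  }
  list(
    pupil = lapply(analysis, function(a) list(
      n = a$n, df = a$df,
      bins = a$bins,
      posthoc = a$posthoc,
      clusters = lapply(a$clusters, function(cl) list(
        contrast = cl$contrast, threshold = cl$threshold,
        n_perm = cl$n_perm, seed = cl$seed, exhaustive = cl$exhaustive,
        clusters = cl$clusters))
    )),
    looking = lapply(looking, function(l) {
      if (!is.null(l[["t"]])) return(ser_test(l))  # group comparison entry
      list(
        familiarization = if (!is.null(l$familiarization)) list(
          n = l$familiarization$n,
          group_summary = l$familiarization$group_summary,
          block1_vs_4 = ser_test(l$familiarization$block1_vs_4)),
        test = list(
          n = l$test$n,
          group_summary = l$test$group_summary,
          anova = l$test$anova[c("F", "df", "p", "eta_p2")],
          novel_vs_familiar = ser_test(l$test$novel_vs_familiar),
          switched_vs_familiar = ser_test(l$test$switched_vs_familiar))
      )
    })
  )
}

serialize_qc <- function(tc) {
  list(
    trials = tc$trials,
    report = tc$selection$report,
    gaps = tc$qc
  )
}
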