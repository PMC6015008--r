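# Per-bin repeated-measures ANOVA, effect sizes, consecutive-bin rule,
# and the cluster-based Monte-Carlo permutation correction ---------------

#' One-way repeated-measures ANOVA for one time bin
#'
#' Classical within-subject decomposition of a complete participants x
#' conditions matrix: `SS_total = SS_subjects + SS_conditions + SS_error`,
#' `F = (SS_cond/df1) / (SS_error/df2)` with `df1 = k - 1`,
#' `df2 = (k - 1)(n - 1)`, and partial eta-squared
#' `SS_cond / (SS_cond + SS_error)`.
#'
#' A bin where both `SS_cond` and `SS_error` vanish has an undefined F; it
#' is reported as `F = 0` (non-significant) with a warning.
#'
#' @param data Numeric matrix, participants in rows, conditions in columns,
#'   complete cases only.
#' @return List: `F`, `df` (length 2), `p`, `eta_p2`, `ss` (the three SS
#'   terms).
#' @export
#' @examples
#' m <- cbind(familiar = c(0.1, 0.2, 0.15), switched = c(0.12, 0.25, 0.2),
#'            novel = c(0.3, 0.4, 0.35))
#' rm_anova_bin(m)$F
rm_anova_bin <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("rm_anova_bin() requires complete rows", call. = FALSE)
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  r <- rm_anova_bins(array(data, dim = c(n, k, 1)))
  if (is.na(r$F[1])) {
    warning("zero within- and between-condition variance: F undefined, reported as 0")
  }
  list(F = ifelse(is.na(r$F[1]), 0, r$F[1]), df = r$df,
       p = ifelse(is.na(r$p[1]), 1, r$p[1]),
       eta_p2 = ifelse(is.na(r$eta_p2[1]), 0, r$eta_p2[1]),
       ss = list(cond = r$ss_cond[1], subj = r$ss_subj[1], error = r$ss_error[1]))
}

#' Vectorised per-bin repeated-measures ANOVA
#'
#' Same decomposition as [rm_anova_bin()], computed for all bins of a
#' participants x conditions x bins array at once.
#'
#' @param Y Numeric array `[n, k, B]`, complete.
#' @return List of per-bin vectors `F`, `p`, `eta_p2`, `ss_*`, plus `df`.
#'   Degenerate bins (no variance at all) carry `NA`.
#' @export
rm_anova_bins <- function(Y) {
  stopifnot(length(dim(Y)) == 3)
  n <- dim(Y)[1]; k <- dim(Y)[2]; B <- dim(Y)[3]
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)

  flat <- matrix(Y, n * k, B)                       # (i,c) stacked by condition
  grand <- colMeans(flat)
  ss_tot <- colSums(sweep(flat, 2, grand)^2)

  cond_means <- matrix(NA_real_, k, B)
  for (c in seq_len(k)) cond_means[c, ] <- colMeans(matrix(Y[, c, ], n, B))
  ss_cond <- n * colSums(sweep(cond_means, 2, grand)^2)

  subj_means <- matrix(0, n, B)
  for (c in seq_len(k)) subj_means <- subj_means + matrix(Y[, c, ], n, B)
  subj_means <- subj_means / k
  ss_subj <- k * colSums(sweep(subj_means, 2, grand)^2)

  ss_err <- pmax(ss_tot - ss_cond - ss_subj, 0)

  Fv <- (ss_cond / df1) / (ss_err / df2)
  eta <- ss_cond / (ss_cond + ss_err)
  degen <- ss_err < .Machine$double.eps^0.75
  Fv[degen & ss_cond < .Machine$double.eps^0.75] <- NA_real_
  eta[ss_cond + ss_err < .Machine$double.eps^0.75] <- NA_real_
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, eta_p2 = eta, df = c(df1, df2),
       ss_cond = ss_cond, ss_subj = ss_subj, ss_error = ss_err)
}

#' Consecutive-bin significance rule
#'
#' A bin counts as significant only when its own p-value and those of both
#' immediate neighbours fall below `alpha`, i.e. it sits inside a run of at
#' least three successive significant bins (150 ms at 50-ms bins). The first
#' and last bins can never be flagged.
#'
#' @param p_values Ordered per-bin p-values.
#' @param alpha Per-bin significance level.
#' @return Logical mask, same length.
#' @export
consecutive_rule <- function(p_values, alpha = 0.05) {
  sig <- !is.na(p_values) & p_values < alpha
  B <- length(sig)
  if (B < 3) return(rep(FALSE, B))
  out <- logical(B)
  core <- 2:(B - 1)
  out[core] <- sig[core] & sig[core - 1] & sig[core + 1]
  out
}

#' Hedges' g for paired (within-participant) designs, average-SD variant
#'
#' `d_av = (mean1 - mean2) / ((SD1 + SD2)/2)`, multiplied by the small-sample
#' bias correction `J = 1 - 3 / (4(n - 1) - 1)`. At `n = 2`, `J = 0`, so
#' `g_av = 0` regardless of the raw difference — a documented degeneracy of
#' the correction, not a bug.
#'
#' @param x1,x2 Paired numeric vectors.
#' @return List of class `sp_effect_size`: `kind`, `value`, `components`.
#' @export
#' @examples
#' hedges_g_av(c(2, 4, 6), c(1, 3, 5))$value  # 0.5 * 4/7
hedges_g_av <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  n <- length(x1)
  s1 <- sd(x1); s2 <- sd(x2)
  if (s1 == 0 && s2 == 0) {
    stop("both SDs are zero: g_av undefined", call. = FALSE)
  }
  J <- 1 - 3 / (4 * (n - 1) - 1)
  d_av <- (mean(x1) - mean(x2)) / ((s1 + s2) / 2)
  structure(list(kind = "g_av", value = d_av * J,
                 components = list(mean1 = mean(x1), mean2 = mean(x2),
                                   sd1 = s1, sd2 = s2, n = n, J = J,
                                   d = d_av)),
            class = "sp_effect_size")
}

#' Hedges' g for independent groups (pooled-SD variant)
#'
#' `d_s = (mean1 - mean2) / SD_pooled` with `df = n1 + n2 - 2`, corrected by
#' `J = 1 - 3 / (4 df - 1)`.
#'
#' @param group1,group2 Independent numeric vectors (n >= 2 each).
#' @return List of class `sp_effect_size`.
#' @export
hedges_g_s <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  pooled <- sqrt(((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) / df)
  if (pooled == 0) stop("pooled SD is zero: g_s undefined", call. = FALSE)
  J <- 1 - 3 / (4 * df - 1)
  d_s <- (mean(group1) - mean(group2)) / pooled
  structure(list(kind = "g_s", value = d_s * J,
                 components = list(mean1 = mean(group1), mean2 = mean(group2),
                                   sd_pooled = pooled, n1 = n1, n2 = n2,
                                   J = J, d = d_s)),
            class = "sp_effect_size")
}

#' Paired t-test with Bonferroni correction and Hedges' g_av
#'
#' Standard paired t on the differences; the Bonferroni-corrected p is
#' `min(1, p * n_comparisons)`. Zero-variance differences are flagged
#' degenerate: with a zero mean the statistic is 0, otherwise the test is
#' reported as infinitely extreme (every pair moved identically).
#'
#' @param x1,x2 Paired numeric vectors.
#' @param n_comparisons Number of comparisons in the family (3 for the three
#'   pairwise condition contrasts).
#' @param alternative `"two.sided"`, or `"greater"`/`"less"` for the planned
#'   one-tailed comparisons (`p_one = p_two / 2` when the sample effect lies
#'   in the predicted direction, `1 - p_two / 2` otherwise).
#' @return List: `t`, `df`, `p` (by `alternative`), `p_bonf`, `g_av`,
#'   `degenerate`.
#' @export
posthoc_paired_t <- function(x1, x2, n_comparisons = 3,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  n <- length(x1)
  d <- x1 - x2
  degenerate <- sd(d) == 0
  if (degenerate) {
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    tval <- mean(d) / (sd(d) / sqrt(n))
  }
  df <- n - 1
  p_two <- 2 * pt(-abs(tval), df)
  p <- switch(alternative,
              two.sided = p_two,
              greater = if (mean(d) >= 0) p_two / 2 else 1 - p_two / 2,
              less = if (mean(d) <= 0) p_two / 2 else 1 - p_two / 2)
  g <- tryCatch(hedges_g_av(x1, x2),
                error = function(e) structure(
                  list(kind = "g_av", value = NA_real_, components = NULL),
                  class = "sp_effect_size"))
  list(t = tval, df = df, p = p, p_bonf = min(1, p * n_comparisons),
       g_av = g, degenerate = degenerate)
}

# Vectorised paired t over bins: D is an n x B matrix of differences.
# Zero-variance bins contribute statistic 0 by design.
paired_t_bins <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tval <- ifelse(v > 0, m / sqrt(v / n), 0)
  list(t = tval, df = n - 1, p = 2 * pt(-abs(tval), n - 1))
}

#' Contiguous supra-threshold clusters of a per-bin statistic
#'
#' For unsigned statistics (F), a cluster is a maximal run of bins with
#' `stat > threshold` and its mass is the sum of the statistic. For signed
#' statistics (t), positive and negative excursions form separate clusters
#' and the mass keeps its sign.
#'
#' @param stat Per-bin statistic.
#' @param threshold Cluster-forming threshold (applied to `abs(stat)` when
#'   `signed`).
#' @param signed Treat the statistic as signed?
#' @return `data.table` with `start`, `end`, `mass` (empty when nothing
#'   exceeds the threshold).
#' @export
find_clusters <- function(stat, threshold, signed = FALSE) {
  lab <- if (signed) sign(stat) * (abs(stat) > threshold) else as.numeric(stat > threshold)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  data.table::data.table(
    start = starts[keep],
    end = ends[keep],
    mass = vapply(which(keep), function(j) sum(stat[starts[j]:ends[j]]),
                  numeric(1))
  )
}

max_cluster_mass <- function(stat, threshold, signed = FALSE) {
  cl <- find_clusters(stat, threshold, signed)
  if (!nrow(cl)) 0 else max(abs(cl$mass))
}

#' Cluster-based Monte-Carlo permutation test over time bins
#'
#' Tests whether the conditions of a participant x condition x bin array are
#' drawn from the same distribution, while controlling the family-wise error
#' over the 86 bins. The procedure is the max-cluster-mass permutation
#' scheme standard for EEG/MEG time series:
#'
#' 1. compute the per-bin statistic (omnibus repeated-measures F, or paired
#'    t for a pairwise contrast);
#' 2. form clusters of contiguous bins exceeding the parametric threshold at
#'    `alpha` (two-sided for t);
#' 3. the cluster mass is the statistic summed over the cluster;
#' 4. for each permutation, exchange condition labels independently within
#'    each participant (for pairwise contrasts: swap the pair with
#'    probability 1/2; when `2^n <= n_perm` all sign assignments are
#'    enumerated instead), recompute, and record the maximum cluster mass;
#' 5. the Monte-Carlo p of each observed cluster is
#'    `(1 + #permutations with max mass >= observed) / (1 + n_perm)`
#'    (exact `#/2^n` under full enumeration).
#'
#' @param Y Array `[n, k, B]` (use the per-age-group array of
#'   [preprocess_dataset()]).
#' @param contrast `"omnibus"` or a length-2 character vector of condition
#'   names (requires dimnames on `Y`), e.g. `c("novel", "familiar")`.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param alpha Cluster-forming level.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List of class `sp_clusters`: `contrast`, `clusters` (`start`,
#'   `end`, `mass`, `p_mc`), `stat` (observed per-bin statistic),
#'   `threshold`, `df`, `n_perm` (effective), `seed`, `exhaustive`,
#'   `null_max_mass`.
#' @export
cluster_permutation <- function(Y, contrast = "omnibus", n_perm = 1000,
                                alpha = 0.05, seed) {
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: Monte-Carlo p resolution is poor")
  stopifnot(length(dim(Y)) == 3)
  set.seed(seed)
  n <- dim(Y)[1]; k <- dim(Y)[2]; B <- dim(Y)[3]

  if (identical(contrast, "omnibus")) {
    res <- omnibus_permutation(Y, n_perm, alpha)
  } else {
    stopifnot(length(contrast) == 2)
    conds <- dimnames(Y)[[2]]
    if (is.null(conds) || !all(contrast %in% conds)) {
      stop("contrast conditions not found in the array's dimnames", call. = FALSE)
    }
    D <- matrix(Y[, contrast[1], ] - Y[, contrast[2], ], n, B)
    res <- pairwise_permutation(D, n_perm, alpha)
  }
  res$contrast <- if (identical(contrast, "omnibus")) "omnibus" else paste(contrast, collapse = "-")
  res$seed <- seed
  class(res) <- "sp_clusters"
  res
}

omnibus_permutation <- function(Y, n_perm, alpha) {
  n <- dim(Y)[1]; k <- dim(Y)[2]; B <- dim(Y)[3]
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  thr <- qf(1 - alpha, df1, df2)

  A <- lapply(seq_len(k), function(c) matrix(Y[, c, ], n, B))
  obs <- rm_anova_bins(Y)
  Fobs <- ifelse(is.na(obs$F), 0, obs$F)
  clusters <- find_clusters(Fobs, thr, signed = FALSE)

  # SS_total and SS_subjects are invariant under within-participant label
  # permutation; only the condition means move.
  grand <- Reduce(`+`, lapply(A, colMeans)) / k
  C <- obs$ss_cond + obs$ss_error   # SS_cond + SS_err is permutation-invariant
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    sig <- t(vapply(seq_len(n), function(i) sample.int(k), integer(k)))
    ss_cond <- numeric(B)
    for (c in seq_len(k)) {
      acc <- numeric(B)
      for (j in seq_len(k)) {
        idx <- which(sig[, c] == j)
        if (length(idx)) acc <- acc + colSums(A[[j]][idx, , drop = FALSE])
      }
      ss_cond <- ss_cond + (acc / n - grand)^2
    }
    ss_cond <- n * ss_cond
    ss_err <- pmax(C - ss_cond, 0)
    Fp <- ifelse(ss_err > 0, (ss_cond / df1) / (ss_err / df2), 0)
    null_max[p] <- max_cluster_mass(Fp, thr)
  }

  p_mc <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (1 + n_perm)
  }, numeric(1))
  clusters$p_mc <- p_mc
  list(clusters = clusters, stat = Fobs, p_param = obs$p, eta_p2 = obs$eta_p2,
       threshold = thr, df = c(df1, df2), n_perm = n_perm,
       exhaustive = FALSE, null_max_mass = null_max)
}

pairwise_permutation <- function(D, n_perm, alpha) {
  n <- nrow(D); B <- ncol(D)
  thr <- qt(1 - alpha / 2, n - 1)
  obs <- paired_t_bins(D)
  clusters <- find_clusters(obs$t, thr, signed = TRUE)

  exhaustive <- 2^n <= n_perm
  S <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
  }
  P <- nrow(S)
  M <- (S %*% D) / n
  css <- matrix(colSums(D^2), P, B, byrow = TRUE)
  V <- (css - n * M^2) / (n - 1)
  V[V < 0] <- 0
  Tm <- ifelse(V > 0, M / sqrt(V / n), 0)
  null_max <- vapply(seq_len(P), function(p) max_cluster_mass(Tm[p, ], thr, TRUE),
                     numeric(1))

  p_mc <- vapply(clusters$mass, function(m) {
    if (exhaustive) sum(null_max >= abs(m)) / P
    else (1 + sum(null_max >= abs(m))) / (1 + P)
  }, numeric(1))
  clusters$p_mc <- p_mc
  list(clusters = clusters, stat = obs$t, p_param = obs$p,
       threshold = thr, df = n - 1, n_perm = P, exhaustive = exhaustive,
       null_max_mass = null_max)
}

#' @export
print.sp_clusters <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %s (n_perm = %d%s, threshold = %.3f)\n",
              x$contrast, x$n_perm,
              if (isTRUE(x$exhaustive)) ", exhaustive" else "", x$threshold))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' @export
print.sp_effect_size <- function(x, ...) {
  cat(sprintf("Hedges' %s = %.4f\n", x$kind, x$value))
  invisible(x)
}
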