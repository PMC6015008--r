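# Independent oracles and small fixture builders used across the suite.

# Brute-force one-way repeated-measures ANOVA by explicit loops over the
# sum-of-squares decomposition; deliberately naive and independent of
# rm_anova_bin().
brute_force_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(m[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, eta_p2 = ss_cond / (ss_cond + ss_err), df = c(df1, df2),
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Reference direct-form IIR loop (oracle for the vectorised implementation).
iir_filter_loop <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  x1 <- x[1]; x2 <- x[1]; y1 <- x[1]; y2 <- x[1]
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + b[2] * x1 + b[3] * x2 - a[2] * y1 - a[3] * y2
    x2 <- x1; x1 <- x[i]
    y2 <- y1; y1 <- yi
    y[i] <- yi
  }
  y
}

# Consecutive-run oracle: position flagged iff it sits strictly inside a run
# of >= 3 significant bins (i.e. has significant neighbours on both sides).
consecutive_rule_oracle <- function(sig) {
  B <- length(sig)
  out <- logical(B)
  for (b in seq_len(B)) {
    if (b == 1 || b == B) next
    out[b] <- sig[b] && sig[b - 1] && sig[b + 1]
  }
  out
}

# A small, fast cohort configuration. `null` drops all dilation components.
tiny_config <- function(seed = 1, ag = "15mo", n = 3, null = FALSE,
                        exclusion = 0, noise = TRUE, gaps = TRUE, ...) {
  comps <- if (null) {
    stats::setNames(list(list()), ag)
  } else {
    NULL
  }
  sim_config(seed = seed, age_groups = ag,
             n_participants = stats::setNames(n, ag),
             exclusion_target = stats::setNames(exclusion, ag),
             components = comps,
             noise_sd_mm = if (noise) 0.08 else 0,
             drift_sd_mm = if (noise) 0.002 else 0,
             gaps = gaps, ...)
}

# One clean synthetic test trial data.table (all samples valid).
clean_test_trial <- function(seed = 1, condition = "familiar", noise = FALSE) {
  cfg <- tiny_config(seed, noise = noise, gaps = FALSE)
  set.seed(seed)
  part <- make_participant(cfg, "15mo", "p1")
  generate_trial_trace(cfg, part, "15mo", condition)
}
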