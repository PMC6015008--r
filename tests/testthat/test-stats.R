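test_that("rm_anova_bin matches the brute-force sum-of-squares oracle", {
  m <- matrix(c(1, 2, 3, 2, 3, 4, 1, 3, 5, 2, 2, 2), ncol = 3, byrow = TRUE)
  got <- rm_anova_bin(m)
  want <- brute_force_rm_anova(m)
  expect_equal(got$F, want$F, tolerance = 1e-12)
  expect_equal(got$eta_p2, want$eta_p2, tolerance = 1e-12)
  expect_equal(got$df, want$df)

  # property: random 3-8 participant matrices, relative tolerance 1e-10
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * 3, mean = 4, sd = 0.5), n, 3)
    got <- rm_anova_bin(m)
    want <- brute_force_rm_anova(m)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$eta_p2, want$eta_p2, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # eta recomputed from (F, df) equals eta from SS terms
    eta_from_F <- got$F * got$df[1] / (got$F * got$df[1] + got$df[2])
    expect_equal(eta_from_F, got$eta_p2, tolerance = 1e-10)
  }
})

test_that("rm_anova_bin handles degenerate input", {
  m <- matrix(2.5, 4, 3)
  expect_warning(r <- rm_anova_bin(m), "undefined")
  expect_equal(r$F, 0)
  expect_equal(r$eta_p2, 0)
  expect_error(rm_anova_bin(matrix(1:3, 1, 3)), "at least 2")
})

test_that("vectorised per-bin ANOVA agrees with the single-bin version", {
  set.seed(55)
  n <- 6; B <- 12
  Y <- array(rnorm(n * 3 * B), dim = c(n, 3, B))
  v <- rm_anova_bins(Y)
  for (b in seq_len(B)) {
    s <- rm_anova_bin(Y[, , b])
    expect_equal(v$F[b], s$F, tolerance = 1e-12)
    expect_equal(v$eta_p2[b], s$eta_p2, tolerance = 1e-12)
  }
})

test_that("consecutive-bin rule matches exhaustive enumeration", {
  expect_equal(consecutive_rule(c(0.5, 0.01, 0.5, 0.5)), rep(FALSE, 4))
  p3 <- c(0.5, 0.01, 0.01, 0.01, 0.5)
  expect_equal(consecutive_rule(p3), c(FALSE, FALSE, TRUE, FALSE, FALSE))
  p4 <- c(0.01, 0.01, 0.01, 0.01, 0.5)
  expect_equal(consecutive_rule(p4), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  alt <- rep(c(0.01, 0.5), 5)
  expect_equal(consecutive_rule(alt), rep(FALSE, 10))

  # all 2^10 significance patterns against the run-membership oracle
  for (code in 0:1023) {
    sig <- as.logical(bitwAnd(code, 2^(0:9)))
    p <- ifelse(sig, 0.01, 0.5)
    expect_equal(consecutive_rule(p), consecutive_rule_oracle(sig))
  }
})

test_that("post-hoc paired t matches hand computation and Bonferroni clips", {
  r <- posthoc_paired_t(c(1, 2, 3, 4), c(2, 4, 3, 6))
  d <- c(-1, -2, 0, -2)
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$p_bonf, min(1, r$p * 3))

  ident <- posthoc_paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(ident$degenerate)
  expect_equal(ident$t, 0)
  expect_equal(ident$p_bonf, 1)
  expect_equal(ident$g_av$value, 0)

  # Bonferroni p is monotone in raw p and never below it
  set.seed(9)
  for (rep in 1:10) {
    x1 <- rnorm(6); x2 <- rnorm(6)
    r <- posthoc_paired_t(x1, x2)
    expect_gte(r$p_bonf, r$p)
    expect_equal(r$p_bonf, min(1, 3 * r$p))
  }
})

test_that("Hedges' g closed forms reproduce exactly", {
  expect_equal(hedges_g_av(c(1, 2, 3), c(1, 2, 3))$value, 0)
  g <- hedges_g_av(c(2, 4, 6), c(1, 3, 5))
  expect_equal(g$value, 0.5 * (1 - 3 / 7), tolerance = 1e-12)
  expect_equal(g$components$J, 4 / 7)
  # n = 2 -> J = 0 -> g_av = 0 regardless of d
  g2 <- hedges_g_av(c(10, 20), c(1, 2))
  expect_equal(g2$value, 0)
  expect_error(hedges_g_av(c(1, 1, 1), c(2, 2, 2)), "undefined")

  gs <- hedges_g_s(c(0, 2), c(1, 3))
  expect_equal(gs$value, -(1 / sqrt(2)) * (1 - 3 / 7), tolerance = 1e-10)
  flip <- hedges_g_s(c(1, 3), c(0, 2))
  expect_equal(flip$value, -gs$value, tolerance = 1e-12)
  expect_equal(hedges_g_s(c(1, 2, 3), c(2, 3, 1))$value, 0)
  expect_error(hedges_g_s(c(1, 1), c(1, 1)), "undefined")
})

test_that("find_clusters segments supra-threshold runs correctly", {
  s <- c(0, 5, 6, 0, 7, 0, 0)
  cl <- find_clusters(s, threshold = 4)
  expect_equal(cl$start, c(2, 5))
  expect_equal(cl$end, c(3, 5))
  expect_equal(cl$mass, c(11, 7))
  expect_equal(nrow(find_clusters(rep(0, 5), 4)), 0)

  st <- c(3, 3, -3, -4, 0.5)
  cls <- find_clusters(st, threshold = 2, signed = TRUE)
  expect_equal(cls$mass, c(6, -7))
})

test_that("cluster permutation p-values respect their resolution bound", {
  set.seed(77)
  Y <- array(rnorm(10 * 3 * 40), dim = c(10, 3, 40),
             dimnames = list(NULL, c("familiar", "switched", "novel"), NULL))
  r <- cluster_permutation(Y, "omnibus", n_perm = 200, seed = 5)
  if (nrow(r$clusters)) expect_true(all(r$clusters$p_mc >= 1 / 201))
  rp <- cluster_permutation(Y, c("novel", "familiar"), n_perm = 200, seed = 5)
  if (nrow(rp$clusters)) expect_true(all(rp$clusters$p_mc >= 1 / 201))
  expect_false(rp$exhaustive)  # 2^10 > 200: random sign flips, not enumeration
})

test_that("permutation results are invariant to participant-level offsets and relabeling", {
  set.seed(31)
  n <- 8; B <- 30
  Y <- array(rnorm(n * 3 * B), dim = c(n, 3, B),
             dimnames = list(NULL, c("familiar", "switched", "novel"), NULL))
  Y[, "novel", 10:18] <- Y[, "novel", 10:18] + 1  # plant a cluster

  r1 <- cluster_permutation(Y, "omnibus", n_perm = 300, seed = 9)
  Y2 <- Y + array(rep(rnorm(n, 0, 5), 3 * B), dim = dim(Y))  # per-participant shift
  r2 <- cluster_permutation(Y2, "omnibus", n_perm = 300, seed = 9)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-8)
  expect_equal(r1$clusters$p_mc, r2$clusters$p_mc)

  # swapping the roles of the two conditions flips the t but not the p
  ra <- cluster_permutation(Y, c("novel", "familiar"), n_perm = 300, seed = 9)
  rb <- cluster_permutation(Y, c("familiar", "novel"), n_perm = 300, seed = 9)
  expect_equal(ra$stat, -rb$stat, tolerance = 1e-12)
  expect_equal(sort(ra$clusters$p_mc), sort(rb$clusters$p_mc))

  # relabeling conditions leaves the omnibus statistic unchanged and the
  # Monte-Carlo p within sampling resolution (the realised permutation draws
  # attach to different labels)
  Yr <- Y[, c("switched", "novel", "familiar"), ]
  dimnames(Yr)[[2]] <- c("familiar", "switched", "novel")
  rr <- cluster_permutation(Yr, "omnibus", n_perm = 300, seed = 9)
  expect_equal(rr$stat, r1$stat, tolerance = 1e-8)
  expect_true(all(abs(rr$clusters$p_mc - r1$clusters$p_mc) <= 0.05))
})

test_that("a planted cluster is detected with a small Monte-Carlo p", {
  set.seed(13)
  n <- 12; B <- 40
  Y <- array(rnorm(n * 3 * B, sd = 0.5), dim = c(n, 3, B),
             dimnames = list(NULL, c("familiar", "switched", "novel"), NULL))
  Y[, "novel", 15:25] <- Y[, "novel", 15:25] + 1.2
  r <- cluster_permutation(Y, "omnibus", n_perm = 500, seed = 3)
  expect_gt(nrow(r$clusters), 0)
  main <- r$clusters[which.max(abs(r$clusters$mass))]
  expect_lt(main$p_mc, 0.01)
  expect_true(main$start <= 16 && main$end >= 24)

  expect_warning(cluster_permutation(Y, "omnibus", n_perm = 50, seed = 1),
                 "n_perm")
  expect_error(cluster_permutation(Y, "omnibus", n_perm = 200), "seed")
})
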