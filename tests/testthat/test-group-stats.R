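test_that("permutation T-test handles extremes and identical samples", {
  set.seed(18)
  x <- rnorm(30)
  y <- rnorm(30) + 10
  res <- permutation_t_test(x, y, n_perm = 999, seed = 1)
  expect_equal(res$p, 1 / 1000)   # add-one formula, no permutation exceeds
  expect_lt(res$T, 0)

  z <- rnorm(12)
  res2 <- permutation_t_test(z, z, n_perm = 499, seed = 2)
  expect_equal(res2$T, 0)
  expect_equal(res2$p, 1)

  res3 <- permutation_t_test(rep(1, 5), rep(1, 7), n_perm = 199)
  expect_equal(res3$T, 0)
  expect_equal(res3$p, 1)

  expect_error(permutation_t_test(1, rnorm(5)), "n >= 2")
  # determinism under seed
  y2 <- rnorm(20)
  a <- permutation_t_test(x, y2, n_perm = 499, seed = 7)
  b <- permutation_t_test(x, y2, n_perm = 499, seed = 7)
  expect_identical(a, b)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(19)
  n_sim <- 300
  p <- vapply(seq_len(n_sim), function(i) {
    permutation_t_test(rnorm(12), rnorm(12), n_perm = 199, seed = i)$p
  }, numeric(1))
  for (alpha in c(0.05, 0.1)) {
    expect_lte(mean(p <= alpha), alpha + 2.5 * sqrt(alpha / n_sim) + 0.01)
  }
})

test_that("Cohen's d matches the pooled-SD oracle and is antisymmetric", {
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -2 / sqrt(2))  # = -1.414214
  set.seed(20)
  x <- rnorm(15); y <- rnorm(20)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_equal(cohens_d(x, x), 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero pooled")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.9)),
               c(0.004, 0.02, 0.08 / 3, 0.9))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  set.seed(21)
  p <- runif(50)
  expect_equal(bh_fdr(p), bh_oracle(p))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
})

test_that("family correction never mixes p-values across families", {
  res <- data.frame(
    p_uncorrected = c(0.001, 0.01, 0.02, 0.9, 0.04),
    family = c("a", "a", "a", "a", "b"))
  out <- apply_family_correction(res)
  expect_equal(out$p_fdr[out$family == "a"],
               bh_oracle(res$p_uncorrected[res$family == "a"]))
  # sentinel singleton family is untouched by the other family's values
  expect_equal(out$p_fdr[out$family == "b"], 0.04)
  res$family[2] <- NA
  expect_error(apply_family_correction(res), "orphan")
})

test_that("age residualisation is an exact least-squares projection", {
  age <- c(20, 30, 40, 50, 60, 70)
  expect_lt(max(abs(age_residuals(2 * age + 5, age))), 1e-10)
  set.seed(22)
  v <- rnorm(50); a <- rnorm(50, 40, 10)
  r <- age_residuals(v, a)
  expect_lt(abs(cor(r, a)), 1e-8)
  v2 <- rnorm(30)  # independent of age: residuals ~ centered values
  r2 <- age_residuals(v2, seq(20, 49))
  expect_lt(max(abs(r2 - (v2 - mean(v2)) +
                      cov(v2, 20:49) / var(20:49) * (20:49 - mean(20:49)))),
            1e-8)
  expect_error(age_residuals(v2, rep(30, 30)), "constant")
})

test_that("Kruskal-Wallis and Dunn match brute-force rank computation", {
  expect_equal(kruskal_wallis(list(1:3, 4:6, 7:9))$chisq, 7.2)
  # identical groups: H = 0 after tie correction, p = 1
  g0 <- list(1:10, 1:10, 1:10)
  kw0 <- kruskal_wallis(g0)
  expect_equal(kw0$chisq, 0)
  expect_equal(kw0$p, 1)
  # rank invariance to monotone transforms
  g <- list(c(1, 5, 2), c(7, 3, 8), c(4, 9, 6))
  expect_equal(kruskal_wallis(g)$chisq,
               kruskal_wallis(lapply(g, exp))$chisq)

  # exhaustive small-sample oracle (integer datasets, total n <= 9)
  grid <- expand.grid(rep(list(1:3), 6))
  for (i in seq(1, nrow(grid), by = 7)) {
    vals <- as.numeric(grid[i, ])
    gs <- list(vals[1:2], vals[3:4], vals[5:6])
    if (length(unique(vals)) == 1) next
    expect_equal(kruskal_wallis(gs)$chisq, kw_oracle(gs), tolerance = 1e-12)
    dn <- dunns_posthoc(gs)
    expect_equal(dn$Z[1], dunn_z_oracle(gs, 1, 2), tolerance = 1e-12)
    expect_equal(dn$Z[3], dunn_z_oracle(gs, 2, 3), tolerance = 1e-12)
  }
})

test_that("Dunn's post-hoc flags the shifted group and is antisymmetric", {
  set.seed(23)
  gs <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30) + 3)
  dn <- dunns_posthoc(gs)
  sig <- dn$p_fdr < 0.05
  expect_true(all(sig[dn$group_a == "c" | dn$group_b == "c"]))
  expect_false(sig[dn$group_a == "a" & dn$group_b == "b"])
  # sign convention under group order swap
  dn2 <- dunns_posthoc(list(b = gs$b, a = gs$a, c = gs$c))
  zab <- dn$Z[dn$group_a == "a" & dn$group_b == "b"]
  zba <- dn2$Z[dn2$group_a == "b" & dn2$group_b == "a"]
  expect_equal(zab, -zba)
  # identical groups: Z ~ 0, corrected p ~ 1
  dn0 <- dunns_posthoc(list(1:10, 1:10, 1:10))
  expect_true(all(abs(dn0$Z) < 1e-12))
  expect_true(all(dn0$p_fdr > 0.99))
  # omnibus gate policy
  expect_error(dunns_posthoc(gs, omnibus_p = 0.2, require_omnibus = TRUE),
               "gated")
})

test_that("Spearman partial correlation recovers planted dependence", {
  x <- 1:10; cov_ind <- rnorm(10)
  expect_equal(spearman_partial(x, x, cov_ind)$rho, 1)
  expect_equal(spearman_partial(x, -x, cov_ind)$rho, -1)

  # jointly normal with partial correlation 0.5 given z
  set.seed(24)
  n <- 5000
  z <- rnorm(n); u <- rnorm(n); v <- rnorm(n)
  rho <- 0.5
  xx <- z + u
  yy <- z + rho * u + sqrt(1 - rho^2) * v
  est <- spearman_partial(xx, yy, z)
  expect_lt(abs(est$rho - 0.5), 0.05)
  expect_lt(est$p, 1e-10)
  expect_error(spearman_partial(rep(1, 10), rnorm(10), rnorm(10)),
               "zero variance")
})

test_that("the FC-clinical correlation stage builds state-domain families", {
  set.seed(25)
  n_pat <- 12; k <- 3; npair <- 10
  med <- array(rnorm(n_pat * k * npair), dim = c(n_pat, k, npair))
  med[1, 2, ] <- NA   # patient 1 never visits state 2
  doms <- data.frame(fatigue = rnorm(n_pat), motor = rnorm(n_pat))
  doms$motor[2] <- NA
  age <- rnorm(n_pat, 40, 10)
  res <- correlate_fc_clinical(med, doms, age)
  expect_equal(nrow(res), k * 2 * npair)
  expect_equal(length(unique(res$family)), k * 2)
  expect_true(all(table(res$family) == npair))
  expect_true(all(res$p_fdr >= res$p_uncorrected - 1e-15))
  # pairwise deletion: state-2 families exclude patient 1
  expect_equal(unique(res$n[res$state == 2 & res$domain == "fatigue"]),
               n_pat - 1)
  expect_equal(unique(res$n[res$state == 2 & res$domain == "motor"]),
               n_pat - 2)
})
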