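test_that("state sequences follow the Markov kernel", {
  # absorbing chain: identity transition matrix stays in the start state
  cfg <- state_process_config(diag(3), replicate(3, diag(4), simplify = FALSE))
  expect_equal(generate_state_sequence(cfg, 10, seed = 1, start = 1),
               rep(1L, 10))

  # deterministic cycle 1 -> 2 -> 3 -> 1
  P <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  cfg <- state_process_config(P, replicate(3, diag(4), simplify = FALSE))
  expect_equal(generate_state_sequence(cfg, 6, seed = 1, start = 1),
               c(1L, 2L, 3L, 1L, 2L, 3L))

  # symmetric 2-state chain: long-run fraction time near the stationary 0.5
  cfg <- state_process_config(matrix(0.5, 2, 2),
                              replicate(2, diag(4), simplify = FALSE))
  s <- generate_state_sequence(cfg, 10000, seed = 2)
  expect_lt(abs(mean(s == 1) - 0.5), 0.02)

  # same seed gives an identical sequence
  expect_identical(generate_state_sequence(cfg, 500, seed = 9),
                   generate_state_sequence(cfg, 500, seed = 9))
})

test_that("non-stochastic transition rows are rejected", {
  P <- rbind(c(0.5, 0.4), c(0.5, 0.5))
  expect_error(state_process_config(P, replicate(2, diag(3), simplify = FALSE)),
               "non-stochastic")
})

test_that("long-run occupancy matches the stationary distribution", {
  P <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1), c(0.2, 0.2, 0.6))
  cfg <- state_process_config(P, replicate(3, diag(3), simplify = FALSE))
  pi_hat <- Re(eigen(t(P))$vectors[, 1]); pi_hat <- pi_hat / sum(pi_hat)
  s <- generate_state_sequence(cfg, 100000, seed = 4)
  expect_lt(max(abs(tabulate(s, 3) / 100000 - pi_hat)), 0.02)
})

test_that("sampled time-courses reproduce the planted state correlations", {
  n_comp <- 6
  R <- diag(n_comp); R[1, 2] <- R[2, 1] <- 0.6
  cfg <- state_process_config(matrix(1), list(R), seed = 1)
  cohort <- cohort_config(n_hc = 1, n_mild = 1, n_nodis = 1,
                          n_components = n_comp, n_timepoints = 20000)
  g <- generate_timecourses(cfg, cohort, participant_seed = 3)
  S <- cor(t(g$timecourses$values))
  expect_lt(abs(S[1, 2] - 0.6), 0.03)
  off <- S[lower.tri(S)]
  off <- off[-1]  # drop the planted pair (lower-tri position 1 = (2,1))
  expect_lt(max(abs(off)), 0.03)
})

test_that("time-course generation is reproducible under a fixed seed", {
  cfg <- default_state_process()
  cohort <- cohort_config(n_timepoints = 60)
  a <- generate_timecourses(cfg, cohort, participant_seed = 7)
  b <- generate_timecourses(cfg, cohort, participant_seed = 7)
  expect_identical(a$timecourses$values, b$timecourses$values)
  expect_identical(a$state_labels, b$state_labels)
})

test_that("PSD repair yields valid correlation matrices", {
  R <- matrix(0.9, 4, 4); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.9   # indefinite
  cfg <- state_process_config(matrix(1), list(R))
  R2 <- cfg$centroid_correlations[[1]]
  expect_true(all(eigen(R2, symmetric = TRUE)$values >= -1e-10))
  expect_equal(diag(R2), rep(1, 4))
})

test_that("clinical cohort plants the configured subgroup effects", {
  # null effects: subgroup difference of every domain near zero
  cc0 <- cohort_config(n_hc = 2, n_mild = 150, n_nodis = 150,
                       clinical_effect_sizes = c(
                         vision = 0, motor = 0, fatigue = 0, depression = 0,
                         cognition = 0, brain_volume = 0, lesion_load = 0),
                       missingness_rate = 0)
  clin <- generate_clinical_cohort(cc0, seed = 21)
  pat <- clin$group == "MS"
  dom <- domain_composite(clin[pat, default_domain_map()$test])
  grp <- edss_split(clin$EDSS[pat])$subgroup
  for (d in names(dom)) {
    diff <- mean(dom[[d]][grp == "mild_moderate"], na.rm = TRUE) -
      mean(dom[[d]][grp == "no_disability"], na.rm = TRUE)
    expect_lt(abs(diff), 3 / sqrt(150))
  }

  # planted fatigue effect of 1.0 recovered within Monte-Carlo tolerance
  cc1 <- cohort_config(n_hc = 2, n_mild = 200, n_nodis = 200,
                       clinical_effect_sizes = c(fatigue = 1.0),
                       missingness_rate = 0)
  clin1 <- generate_clinical_cohort(cc1, seed = 22)
  pat1 <- clin1$group == "MS"
  dom1 <- domain_composite(clin1[pat1, default_domain_map()$test])
  grp1 <- edss_split(clin1$EDSS[pat1])$subgroup
  d_hat <- cohens_d(dom1$fatigue[grp1 == "mild_moderate"],
                    dom1$fatigue[grp1 == "no_disability"])
  expect_lt(abs(d_hat - 1.0), 0.25)

  # zero missingness leaves no missing cells in the patient battery
  expect_false(anyNA(clin1[pat1, default_domain_map()$test]))
})

test_that("cohort generation is deterministic and structured", {
  cc <- cohort_config(n_hc = 3, n_mild = 3, n_nodis = 3, n_timepoints = 50)
  a <- simulate_cohort(cc, seed = 5)
  b <- simulate_cohort(cc, seed = 5)
  expect_identical(a$clinical, b$clinical)
  expect_identical(lapply(a$timecourses, `[[`, "values"),
                   lapply(b$timecourses, `[[`, "values"))
  # age runs older in the mild-moderate subgroup at scale
  big <- generate_clinical_cohort(cohort_config(n_hc = 2, n_mild = 300,
                                                n_nodis = 300), seed = 6)
  expect_gt(mean(big$age[big$subgroup_truth == "mild_moderate"]),
            mean(big$age[big$subgroup_truth == "no_disability"]))
})

test_that("window truth labels are a majority vote over the window", {
  tr <- c(rep(1L, 30), rep(2L, 30))
  wl <- window_truth_labels(tr, w = 22)
  expect_length(wl, 39)
  expect_equal(wl[1], 1L)     # pure state-1 window
  expect_equal(wl[39], 2L)    # pure state-2 window
  # window starting at TR 20 covers TRs 20..41: 11 ones, 11 twos -> tie,
  # broken in favour of the state occurring first in the window
  expect_equal(wl[20], 1L)
  expect_equal(wl[21], 2L)    # 10 ones vs 12 twos
})
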