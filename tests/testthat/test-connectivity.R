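test_that("fisher_z matches arctanh, clips at the boundary, is monotone", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "out of range")
  set.seed(1)
  r <- sort(runif(200, -0.999, 0.999))
  expect_true(all(diff(fisher_z(r)) > 0))
})

test_that("lower-triangle vectorization round-trips and counts pairs", {
  expect_length(vectorize_lower_triangle(diag(47)), 1081)
  expect_length(vectorize_lower_triangle(diag(3)), 3)
  set.seed(2)
  M <- matrix(rnorm(36), 6); M <- M + t(M)
  v <- vectorize_lower_triangle(M)
  M2 <- devectorize_lower_triangle(v)
  expect_identical(M2[lower.tri(M2)], M[lower.tri(M)])
  expect_identical(t(M2)[lower.tri(M2)], M[lower.tri(M)])
  A <- M; A[1, 2] <- A[1, 2] + 1
  expect_error(vectorize_lower_triangle(A), "symmetric")
  # documented ordering: (2,1), (3,1), ..., i.e. j varies slowest
  pi3 <- pair_index(3)
  expect_equal(unname(pi3[, "i"]), c(2L, 3L, 3L))
  expect_equal(unname(pi3[, "j"]), c(1L, 1L, 2L))
})

test_that("static FC handles perfect correlation and zero variance", {
  set.seed(3)
  base <- rnorm(50)
  X <- rbind(base, base, -base + 0, rnorm(50))
  ts <- component_timecourses(X, component_ids = paste0("c", 1:4))
  v <- static_fc(ts)
  idx <- pair_index(4)
  expect_equal(v[idx[, "i"] == 2 & idx[, "j"] == 1], atanh(1 - 1e-7))
  expect_equal(v[idx[, "i"] == 3 & idx[, "j"] == 1], -atanh(1 - 1e-7))
  X2 <- X; X2[4, ] <- 5
  expect_error(static_fc(component_timecourses(X2,
                                               component_ids = paste0("c", 1:4))),
               "zero-variance component.*c4")
})

test_that("sliding windows enumerate starts and agree with static FC", {
  set.seed(4)
  X <- matrix(rnorm(5 * 255), 5)
  ts <- component_timecourses(X)
  w <- sliding_window_fc(ts, w = 22, s = 1)
  expect_equal(nrow(w$values), 234)
  expect_equal(w$window_start_TR[1], 0)
  expect_equal(w$window_start_TR[234], 233)

  # every window equals static FC of the corresponding slice (no taper)
  for (m in c(1, 100, 234)) {
    slice <- X[, (m:(m + 21)), drop = FALSE]
    expect_equal(w$values[m, ], unclass(static_fc(slice)),
                 ignore_attr = TRUE)
  }

  # degenerate window: T == w gives exactly the static FC
  Xs <- X[, 1:22]
  w1 <- sliding_window_fc(component_timecourses(Xs), w = 22)
  expect_equal(nrow(w1$values), 1)
  expect_equal(w1$values[1, ], unclass(static_fc(Xs)), ignore_attr = TRUE)

  expect_error(sliding_window_fc(component_timecourses(Xs), w = 23),
               "exceeds")
})

test_that("windowed FC means track static FC on stationary data", {
  set.seed(5)
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.5
  cfg <- state_process_config(matrix(1), list(R))
  g <- generate_timecourses(cfg, cohort_config(n_components = 4,
                                               n_timepoints = 2000),
                            participant_seed = 6)
  sfc <- static_fc(g$timecourses)
  wfc <- sliding_window_fc(g$timecourses, w = 22)
  expect_lt(max(abs(colMeans(wfc$values) - sfc)), 0.15)
})

test_that("component permutation permutes pairs consistently", {
  set.seed(6)
  X <- matrix(rnorm(6 * 60), 6)
  perm <- c(3, 1, 6, 2, 5, 4)
  v1 <- static_fc(X)
  v2 <- static_fc(X[perm, ])
  M1 <- devectorize_lower_triangle(v1)
  M2 <- devectorize_lower_triangle(v2)
  expect_equal(M2, M1[perm, perm])
})

test_that("gaussian taper downweights window edges but stays close", {
  set.seed(7)
  X <- matrix(rnorm(4 * 100), 4)
  wt <- sliding_window_fc(component_timecourses(X), w = 22,
                          taper = "gaussian")
  wr <- sliding_window_fc(component_timecourses(X), w = 22)
  expect_equal(dim(wt$values), dim(wr$values))
  expect_false(isTRUE(all.equal(wt$values, wr$values)))
  expect_lt(max(abs(wt$values - wr$values)), 1.5)
})
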