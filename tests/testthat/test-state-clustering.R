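planted_blobs <- function(n_per = 20, k = 3, d = 6, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, d)
  for (c in seq_len(k)) {
    centers[c, ((c - 1) %% d) + 1] <- sep * ifelse(c > d, -1, 1)
  }
  X <- do.call(rbind, lapply(seq_len(k), function(c) {
    sweep(matrix(rnorm(n_per * d), n_per), 2, centers[c, ], "+")
  }))
  list(X = X, truth = rep(seq_len(k), each = n_per))
}

test_that("L1 k-means recovers well-separated planted blobs exactly", {
  pb <- planted_blobs()
  fit <- kmeans_cityblock(pb$X, 3, seed = 2)
  expect_equal(length(unique(fit$labels)), 3)
  tab <- table(pb$truth, fit$labels)
  expect_equal(sum(apply(tab, 1, max)), nrow(pb$X))  # perfect up to relabel
})

test_that("k = 1 centroid is the coordinate-wise median", {
  set.seed(3)
  X <- matrix(rnorm(45), 9, 5)
  fit <- kmeans_cityblock(X, 1, seed = 1)
  expect_equal(as.vector(fit$centroids), apply(X, 2, median))
  expect_equal(fit$cost, sum(abs(sweep(X, 2, apply(X, 2, median)))))
})

test_that("converged cost equals the exhaustive-partition optimum", {
  set.seed(4)
  for (rep in 1:5) {
    X <- matrix(rnorm(12), 6, 2)
    fit <- kmeans_cityblock(X, 2, n_init = 30, seed = rep)
    expect_equal(fit$cost, brute_l1_optimum(X, 2), tolerance = 1e-10)
  }
  X8 <- matrix(rnorm(16), 8, 2)
  fit8 <- kmeans_cityblock(X8, 2, n_init = 50, seed = 9)
  expect_equal(fit8$cost, brute_l1_optimum(X8, 2), tolerance = 1e-10)
})

test_that("clustering is invariant to row order up to relabelling", {
  pb <- planted_blobs(n_per = 15, seed = 5)
  set.seed(11)
  perm <- sample(nrow(pb$X))
  f1 <- kmeans_cityblock(pb$X, 3, seed = 7)
  f2 <- kmeans_cityblock(pb$X[perm, ], 3, seed = 7)
  # same partition of the same points, modulo label names
  g1 <- f1$labels[perm]
  tab <- table(g1, f2$labels)
  expect_equal(sum(apply(tab, 1, max)), nrow(pb$X))
})

test_that("Dunn's index matches hand computations and degenerate rules", {
  # two clusters separated by 10, each of diameter 1
  X <- rbind(c(0, 0), c(1, 0), c(11, 0), c(12, 0))
  expect_equal(dunns_index(X, c(1, 1, 2, 2)), 10)
  # coincident points in 2 clusters: zero diameter everywhere -> Inf
  Xc <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  expect_equal(dunns_index(Xc, c(1, 1, 2, 2)), Inf)
  expect_error(dunns_index(X, c(1, 1, 1, 1)), "2 non-empty")
})

test_that("merging planted clusters never increases Dunn's index", {
  pb <- planted_blobs(n_per = 4, k = 3, d = 2, sep = 8, seed = 6)
  d3 <- dunns_index(pb$X, pb$truth)
  merged <- pb$truth
  merged[merged == 3] <- 2
  expect_lte(dunns_index(pb$X, merged), d3)
})

test_that("select_k finds planted k and flags divergence on noise", {
  pb <- planted_blobs(n_per = 25, k = 2, d = 8, sep = 12, seed = 7)
  sel <- select_k(pb$X, k_range = 2:6, seed = 3)
  expect_equal(sel$k, 2L)
  expect_false(sel$divergence)

  expect_error(select_k(pb$X, k_range = 2:3, seed = 1), "at least 3")

  # isotropic noise: no stable convergence between the two criteria
  set.seed(8)
  noise <- matrix(rnorm(150 * 10), 150)
  div <- vapply(1:4, function(s) {
    suppressMessages(select_k(noise, k_range = 2:8, seed = s)$divergence)
  }, logical(1))
  expect_true(any(div))
})

test_that("occupancy relabelling sorts states and breaks ties by id", {
  model <- structure(list(
    k = 3L,
    centroids = matrix(1:9, 3, 3),
    labels = data.frame(participant = "a",
                        window = 1:600,
                        window_start_TR = 0:599,
                        state = rep(c(1L, 2L, 3L), c(100, 300, 200))),
    occupancy = c(100L, 300L, 200L), relabel_map = 1:3, cost = 0),
    class = "state_model")
  out <- relabel_by_occupancy(model)
  expect_equal(out$relabel_map, c(3L, 1L, 2L))   # b->1, c->2, a->3
  expect_equal(out$occupancy, c(300L, 200L, 100L))
  expect_equal(out$centroids[1, ], c(2, 5, 8))   # old state 2 leads

  # already sorted: identity map
  model$labels$state <- rep(c(1L, 2L, 3L), c(300, 200, 100))
  out2 <- relabel_by_occupancy(model)
  expect_equal(out2$relabel_map, 1:3)

  # equal occupancies: lower original id gets the lower final id
  model$labels$state <- rep(c(1L, 2L, 3L), c(200, 200, 200))
  out3 <- relabel_by_occupancy(model)
  expect_equal(out3$relabel_map, 1:3)
})

test_that("participant state medians follow the even/odd median rules", {
  V <- rbind(c(0.1, 1), c(0.2, 2), c(0.9, 3))
  med <- participant_state_medians(V, labels = c(2L, 2L, 2L), k = 3)
  expect_equal(med[2, ], c(0.2, 2))
  expect_true(all(is.na(med[c(1, 3), ])))
  expect_equal(attr(med, "visited"), c(FALSE, TRUE, FALSE))

  V2 <- rbind(c(0.1, 0), c(0.3, 1))
  med2 <- participant_state_medians(V2, labels = c(1L, 1L), k = 1)
  expect_equal(med2[1, ], c(0.2, 0.5))
})

test_that("planted states are recovered from pooled windows", {
  # long-dwell process (mean segment length 100 TR >= 2 windows), per the
  # recovery premise that segments span at least two window lengths
  cfg <- state_process_config(default_transition_matrix(5, rep(0.99, 5)),
                              default_state_centroids(), seed = 1)
  cohort <- cohort_config(n_hc = 8, n_mild = 1, n_nodis = 1)
  tcs <- list(); truth <- list()
  for (i in 1:8) {
    g <- generate_timecourses(cfg, cohort, participant_seed = 100 + i,
                              participant_id = paste0("p", i))
    tcs[[paste0("p", i)]] <- g$timecourses
    truth[[paste0("p", i)]] <- g$state_labels
  }
  wfc <- lapply(tcs, sliding_window_fc, w = 22)
  model <- cluster_states(wfc, k = 5, seed = 3)
  truth <- unlist(lapply(truth, window_truth_labels, w = 22))
  tab <- table(truth, model$labels$state)
  agreement <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(agreement, 0.9)
  # occupancy is sorted descending after relabelling
  expect_true(all(diff(model$occupancy) <= 0))
  # fraction of all windows in each state sums to 1
  expect_equal(sum(model$occupancy), nrow(model$labels))
})
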