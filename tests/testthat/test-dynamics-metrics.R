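test_that("temporal metrics match hand enumerations", {
  lab <- c(1L, 1L, 2L, 2L, 2L, 1L)
  expect_equal(fraction_time(lab, 2), c(0.5, 0.5))
  expect_equal(mean_dwell_time(lab, 2), c(1.5, 3))
  expect_equal(stickiness(lab, 2), c(1L, 2L))

  tc <- transition_counts(c(1L, 2L, 1L, 3L), 3)
  expect_equal(tc$ordered[1, 2], 1L)
  expect_equal(tc$ordered[2, 1], 1L)
  expect_equal(tc$ordered[1, 3], 1L)
  expect_equal(sum(tc$ordered), 3L)
  expect_equal(tc$pairs$count[tc$pairs$state_a == 1 & tc$pairs$state_b == 2], 2L)
  expect_equal(tc$pairs$count[tc$pairs$state_a == 1 & tc$pairs$state_b == 3], 1L)

  # constant sequence: single run, maximal stickiness, no transitions
  const <- rep(3L, 234)
  expect_equal(fraction_time(const, 5), c(0, 0, 1, 0, 0))
  expect_equal(mean_dwell_time(const, 5)[3], 234)
  expect_true(all(is.na(mean_dwell_time(const, 5)[-3])))
  expect_equal(stickiness(const, 5)[3], 233L)
  expect_equal(sum(transition_counts(const, 5)$ordered), 0L)

  # strictly alternating: zero stickiness
  expect_equal(stickiness(c(1L, 2L, 1L, 2L), 2), c(0L, 0L))
})

test_that("stay/switch conservation holds on random label sequences", {
  set.seed(10)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    lab <- sample.int(k, 200, replace = TRUE)
    st <- stickiness(lab, k)
    tr <- transition_counts(lab, k)
    expect_equal(sum(st) + sum(tr$ordered), 199L)
    expect_equal(sum(fraction_time(lab, k)), 1)
    # fraction_time identity via runs
    runs <- rle(lab)
    n_runs <- tabulate(runs$values, k)
    expect_equal(fraction_time(lab, k), (st + n_runs) / 200)
  }
})

test_that("state average connectivity averages windows within states", {
  V <- rbind(rep(0.2, 4), rep(0.4, 4), rep(1, 4))
  lab <- c(1L, 1L, 2L)
  expect_equal(state_average_connectivity(V, lab, 3), c(0.3, 1, NA))
  # all windows identical: every visited state equals the matrix mean
  Vc <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(state_average_connectivity(Vc, c(1L, 2L), 2), c(2, 2))
})

test_that("ASOC reduces to hand averages on a 4-component example", {
  # 2 networks x 2 components; pair order (2,1),(3,1),(4,1),(3,2),(4,2),(4,3)
  assignment <- data.frame(component_id = paste0("c", 1:4),
                           network = c("A", "A", "B", "B"))
  v <- c(0.6, 0.1, 0.2, 0.3, 0.4, 0.8)
  V <- rbind(v, v)
  attr(V, "pair_index") <- pair_index(4)
  a <- asoc(V, assignment)
  expect_equal(a$grand, mean(v))
  expect_equal(unname(a$intra["A"]), 0.6)
  expect_equal(unname(a$intra["B"]), 0.8)
  expect_equal(unname(a$inter["A"]), mean(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(unname(a$inter["B"]), mean(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(a$pairwise$value[a$pairwise$network_a == "A"],
               mean(c(0.1, 0.2, 0.3, 0.4)))

  # uniform values: grand = intra = inter
  Vu <- matrix(0.25, 3, 6)
  attr(Vu, "pair_index") <- pair_index(4)
  au <- asoc(Vu, assignment)
  expect_equal(au$grand, 0.25)
  expect_true(all(au$intra == 0.25))
  expect_true(all(au$inter == 0.25))
})

test_that("default assignment yields 7 intra and 8 inter ASOC values", {
  set.seed(11)
  V <- matrix(rnorm(3 * 1081), 3)
  attr(V, "pair_index") <- pair_index(47)
  a <- asoc(V, default_network_assignment())
  expect_length(a$intra, 7)       # BG has one component: no intra value
  expect_length(a$inter, 8)
  expect_false("BG" %in% names(a$intra))
  expect_true("BG" %in% names(a$inter))
})

test_that("static overall connectivity equals single-window ASOC", {
  set.seed(12)
  X <- matrix(rnorm(47 * 60), 47)
  fc <- static_fc(X)
  soc <- static_overall_connectivity(fc, default_network_assignment())
  V <- matrix(fc, 1); attr(V, "pair_index") <- attr(fc, "pair_index")
  a1 <- asoc(V, default_network_assignment())
  expect_equal(soc$grand, a1$grand)
  expect_equal(soc$intra, a1$intra)
  expect_equal(soc$inter, a1$inter)
  expect_equal(soc$grand, mean(fc))
})

test_that("grand ASOC is the occupancy-weighted mean of state connectivity", {
  sc <- small_cohort(n = 2, seed = 9, n_timepoints = 150)
  wfc <- sliding_window_fc(sc$tcs[[1]], w = 22)
  lab <- window_truth_labels(sc$truth[[1]], w = 22)
  a <- asoc(wfc, default_network_assignment())
  avg <- state_average_connectivity(wfc, lab, 5)
  ft <- fraction_time(lab, 5)
  expect_equal(a$grand, sum(ft * avg, na.rm = TRUE), tolerance = 1e-12)
})
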