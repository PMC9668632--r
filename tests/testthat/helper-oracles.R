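# Independent brute-force oracles used to freeze expected values.

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  parts <- list()
  rgs <- integer(n)
  recurse <- function(i, maxc) {
    if (i > n) {
      parts[[length(parts) + 1]] <<- rgs[1:n]
      return(invisible())
    }
    for (c in 1:(maxc + 1)) {
      rgs[i] <<- c
      recurse(i + 1, max(maxc, c))
    }
  }
  rgs[1] <- 1
  recurse(2, 1)
  if (n == 1) parts <- list(1L)
  parts
}

# modularity of a partition on a signed graph, straight from the
# definition (positive part weighted 1/v+, negative part 1/(v+ + v-))
modularity_oracle <- function(W, part, gamma = 1) {
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  same <- outer(part, part, "==")
  qp <- if (vp > 0) sum((Wp - gamma * outer(sp, sp) / vp)[same]) / vp else 0
  qn <- if (vn > 0) {
    sum((Wn - gamma * outer(sn, sn) / vn)[same]) / (vp + vn)
  } else 0
  qp - qn
}

# exhaustive-partition maximum modularity for small graphs
max_modularity_oracle <- function(W, gamma = 1) {
  n <- nrow(W)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- modularity_oracle(W, p, gamma)
    if (q > best) best <- q
  }
  best
}

# total within-cluster L1 cost of a labelled partition (median centers)
l1_cost_oracle <- function(X, labels) {
  cost <- 0
  for (c in unique(labels)) {
    sub <- X[labels == c, , drop = FALSE]
    med <- apply(sub, 2, median)
    cost <- cost + sum(abs(sweep(sub, 2, med)))
  }
  cost
}

# exhaustive minimum L1 cost over all partitions into exactly k clusters
brute_l1_optimum <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  for (p in all_partitions(n)) {
    if (length(unique(p)) != k) next
    best <- min(best, l1_cost_oracle(X, p))
  }
  best
}

# Kruskal-Wallis H with tie correction, from the textbook formula
kw_oracle <- function(groups) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn's pairwise Z from pooled ranks with tie correction
dunn_z_oracle <- function(groups, a, b) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (mean(r[g == a]) - mean(r[g == b])) /
    sqrt(s2 * (1 / sum(g == a) + 1 / sum(g == b)))
}

# hand step-up BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# small synthetic cohort shared by clustering-oriented tests
small_cohort <- function(n = 8, seed = 5, n_timepoints = 255) {
  cc <- cohort_config(n_hc = n, n_mild = 1, n_nodis = 1,
                      n_timepoints = n_timepoints)
  sim <- simulate_cohort(cc, seed = seed)
  keep <- sim$clinical$group == "HC"
  list(tcs = sim$timecourses[keep],
       truth = sim$truth_tr_labels[keep],
       sim = sim)
}
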