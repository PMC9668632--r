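#' Louvain community detection and modularity on signed weighted graphs
#'
#' Community Louvain on a weighted, possibly signed, undirected graph.
#' Negative weights are handled by the selected rule:
#' \describe{
#'   \item{`"asym"`}{asymmetric signed treatment (default): positive and
#'     negative subnetworks contribute to the quality function with weights
#'     `1/v+` and `1/(v+ + v-)` respectively, where `v+`/`v-` are the total
#'     positive/negative strengths. Appropriate for signed Fisher-Z FC.}
#'   \item{`"abs"`}{absolute values of the weights.}
#'   \item{`"zero"`}{negative weights set to zero.}
#' }
#' The algorithm greedily maximises the partition quality by local node
#' moves followed by graph aggregation, repeated until stable; the best of
#' `n_restart` seeded node-order shuffles is returned.
#'
#' @param fc Either a Fisher-Z FC vector (lower-triangle order) or a
#'   symmetric weight matrix; the diagonal is ignored.
#' @param gamma Resolution parameter (default 1).
#' @param negative_weight_rule One of `"asym"`, `"abs"`, `"zero"`.
#' @param seed Integer seed for the node-order shuffles.
#' @param n_restart Number of restarts (default 10).
#' @return List with `Q` (modularity of the final partition) and
#'   `partition` (integer community id per node).
#' @export
modularity_louvain <- function(fc, gamma = 1,
                               negative_weight_rule = c("asym", "abs", "zero"),
                               seed = 1L, n_restart = 10L) {
  rule <- match.arg(negative_weight_rule)
  W <- if (is.matrix(fc)) fc else devectorize_lower_triangle(fc)
  if (max(abs(W - t(W))) > 1e-10) stop("weight matrix must be symmetric")
  diag(W) <- 0
  if (rule == "abs") W <- abs(W)
  if (rule == "zero") W[W < 0] <- 0
  if (all(W == 0)) stop("all-zero weight matrix")
  B <- signed_modularity_matrix(W, gamma)
  n <- nrow(B)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restart)) {
    ord <- sample.int(n)
    if (r %% 2 == 1) {
      part <- louvain_partition(B, ord)
    } else {
      # restart from a random coarse partition to escape the greedy basin
      init <- sample.int(max(2L, min(n, ceiling(sqrt(n)) + 1L)), n,
                         replace = TRUE)
      lm <- local_moves(B, init, ord)
      part <- as.integer(factor(lm$comm, levels = unique(lm$comm)))
    }
    q <- sum(B[outer(part, part, "==")])
    if (is.null(best) || q > best$Q + 1e-15) {
      best <- list(Q = q, partition = part)
    }
  }
  best$partition <- as.integer(factor(best$partition,
                                      levels = unique(best$partition)))
  best
}

#' Modularity of a given partition on a signed graph
#'
#' @param W Symmetric weight matrix (diagonal ignored).
#' @param partition Integer community ids per node.
#' @param gamma Resolution parameter.
#' @param negative_weight_rule See [modularity_louvain()].
#' @return Scalar Q.
#' @export
modularity_q <- function(W, partition, gamma = 1,
                         negative_weight_rule = c("asym", "abs", "zero")) {
  rule <- match.arg(negative_weight_rule)
  diag(W) <- 0
  if (rule == "abs") W <- abs(W)
  if (rule == "zero") W[W < 0] <- 0
  B <- signed_modularity_matrix(W, gamma)
  sum(B[outer(partition, partition, "==")])
}

# B such that Q(partition) = sum of B over within-community (i, j) pairs,
# including i == j; combines the positive and negative null models with the
# asymmetric 1/v+ and 1/(v+ + v-) weighting
signed_modularity_matrix <- function(W, gamma) {
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) B <- B + (Wp - gamma * tcrossprod(sp) / vp) / vp
  if (vn > 0) B <- B - (Wn - gamma * tcrossprod(sn) / vn) / (vp + vn)
  (B + t(B)) / 2
}

# greedy local node moves on quality matrix B, starting from `comm`
local_moves <- function(B, comm, order) {
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order) {
      ci <- comm[i]
      # quality links of node i to each community (excluding self-term)
      row <- B[i, ]
      row[i] <- 0
      link <- tapply(row, comm, sum)
      stay <- link[[as.character(ci)]]
      bestc <- ci
      bestg <- stay
      for (cn in names(link)) {
        if (link[[cn]] > bestg + 1e-15) {
          bestg <- link[[cn]]; bestc <- as.integer(cn)
        }
      }
      # leaving into a fresh singleton community is also a candidate move
      if (0 > bestg + 1e-15) {
        bestg <- 0; bestc <- max(comm) + 1L
      }
      if (bestc != ci) {
        comm[i] <- bestc
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(comm = comm, moved = moved_any)
}

# one full Louvain run (local moves + aggregation, then a node-level
# refinement of the final partition) on quality matrix B
louvain_partition <- function(B, ord) {
  n <- nrow(B)
  node_comm <- seq_len(n)   # community of each original node
  Bc <- B                   # current (aggregated) quality matrix
  level_order <- ord
  repeat {
    m <- nrow(Bc)
    lm <- local_moves(Bc, seq_len(m), level_order)
    comm <- as.integer(factor(lm$comm, levels = unique(lm$comm)))
    node_comm <- comm[node_comm]
    if (!lm$moved || max(comm) == m) break
    # aggregate
    agg <- rowsum(t(rowsum(Bc, comm)), comm)
    Bc <- (agg + t(agg)) / 2
    level_order <- seq_len(nrow(Bc))
  }
  # refinement: single-node moves between final communities
  ref <- local_moves(B, node_comm, ord)
  as.integer(factor(ref$comm, levels = unique(ref$comm)))
}
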