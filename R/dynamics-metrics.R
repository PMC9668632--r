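#' Fraction time (fractional occupancy) per state
#'
#' Proportion of windows spent in each state; never-visited states get 0.
#'
#' @param labels Integer per-window state labels.
#' @param k Number of states.
#' @return Numeric vector of length `k` summing to 1.
#' @export
fraction_time <- function(labels, k = max(labels)) {
  if (length(labels) < 1) stop("need at least 1 window")
  tabulate(labels, nbins = k) / length(labels)
}

# run-length encoding of the label sequence
state_runs <- function(labels) {
  r <- rle(as.integer(labels))
  data.frame(state = r$values, length = r$lengths)
}

#' Mean dwell time per state
#'
#' Mean number of consecutive windows spent in a state upon entering it
#' (mean maximal run length); unvisited states are `NA`.
#'
#' @inheritParams fraction_time
#' @return Numeric vector of length `k` (windows).
#' @export
mean_dwell_time <- function(labels, k = max(labels)) {
  if (length(labels) < 1) stop("need at least 1 window")
  runs <- state_runs(labels)
  out <- rep(NA_real_, k)
  agg <- tapply(runs$length, runs$state, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' State stickiness
#'
#' Number of adjacent window pairs in which the participant remains in the
#' same state, attributed to that state. Equivalently, (windows in state)
#' minus (number of runs of that state).
#'
#' @inheritParams fraction_time
#' @return Integer vector of length `k`.
#' @export
stickiness <- function(labels, k = max(labels)) {
  if (length(labels) < 2) stop("need at least 2 windows")
  n <- length(labels)
  same <- labels[-n] == labels[-1]
  out <- integer(k)
  stay <- labels[-n][same]
  if (length(stay)) {
    tab <- tabulate(stay, nbins = k)
    out <- tab
  }
  out
}

#' Transition counts between states
#'
#' Ordered counts `a -> b` of adjacent windows with different states, plus
#' unordered pair totals. Self-pairs (stays) are excluded; see
#' [stickiness()].
#'
#' @inheritParams fraction_time
#' @return List with `ordered` (k x k matrix, zero diagonal) and `pairs`
#'   (data frame: `state_a < state_b`, `count`).
#' @export
transition_counts <- function(labels, k = max(labels)) {
  if (length(labels) < 2) stop("need at least 2 windows")
  n <- length(labels)
  M <- matrix(0L, k, k)
  from <- labels[-n]; to <- labels[-1]
  sw <- from != to
  for (t in which(sw)) M[from[t], to[t]] <- M[from[t], to[t]] + 1L
  pairs <- expand.grid(state_a = seq_len(k), state_b = seq_len(k))
  pairs <- pairs[pairs$state_a < pairs$state_b, ]
  pairs$count <- M[cbind(pairs$state_a, pairs$state_b)] +
    M[cbind(pairs$state_b, pairs$state_a)]
  rownames(pairs) <- NULL
  list(ordered = M, pairs = pairs)
}

#' State-wise average connectivity
#'
#' Global mean Fisher-Z connectivity strength over all of a participant's
#' windows spent in each state (mean over windows and pairs); unvisited
#' states are `NA`.
#'
#' @param wfc A `windowed_fc` object (or windows x pairs matrix).
#' @param labels Integer state labels per window.
#' @param k Number of states.
#' @return Numeric vector of length `k`.
#' @export
state_average_connectivity <- function(wfc, labels, k = max(labels)) {
  V <- if (inherits(wfc, "windowed_fc")) wfc$values else as.matrix(wfc)
  if (nrow(V) != length(labels)) stop("labels do not align with windows")
  out <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    idx <- which(labels == s)
    if (length(idx)) out[s] <- mean(V[idx, ])
  }
  out
}

#' Temporal dynamics metrics for one participant
#'
#' @param labels Integer per-window state labels.
#' @param k Number of states.
#' @return Data frame with one row per state: `state`, `fraction_time`,
#'   `mean_dwell_time`, `stickiness`, `n_runs`.
#' @export
dynamic_metrics <- function(labels, k = max(labels)) {
  runs <- state_runs(labels)
  n_runs <- tabulate(runs$state, nbins = k)
  data.frame(state = seq_len(k),
             fraction_time = fraction_time(labels, k),
             mean_dwell_time = mean_dwell_time(labels, k),
             stickiness = stickiness(labels, k),
             n_runs = n_runs)
}

#' Across-state overall connectivity (ASOC)
#'
#' Averages a participant's windowed Fisher-Z FC over all windows,
#' irrespective of state: one grand-average value over all pairs, one
#' intra-network value per network with at least two components, and one
#' inter-network value per network (pairs with exactly one component in the
#' network, i.e. the network's overall connectivity with the rest of the
#' brain). Pairwise network-to-network averages are also returned.
#'
#' @param wfc A `windowed_fc` object (or windows x pairs matrix with a
#'   `pair_index` attribute/entry).
#' @param assignment Data frame `component_id`/`network` covering every
#'   component (see [default_network_assignment()]).
#' @return Object of class `asoc`: list with `grand` (scalar), `intra`
#'   (named vector over multi-component networks), `inter` (named vector
#'   over all networks), and `pairwise` (data frame `network_a`,
#'   `network_b`, `value`).
#' @export
asoc <- function(wfc, assignment) {
  if (inherits(wfc, "windowed_fc")) {
    V <- wfc$values
    pidx <- wfc$pair_index
  } else {
    V <- as.matrix(wfc)
    pidx <- attr(wfc, "pair_index")
    if (is.null(pidx)) {
      n <- (1 + sqrt(1 + 8 * ncol(V))) / 2
      pidx <- pair_index(as.integer(round(n)))
    }
  }
  nets <- assignment$network
  n_comp <- nrow(assignment)
  if (max(pidx) > n_comp) stop("assignment does not cover all components")
  counts <- table(nets)
  if (any(counts == 0)) stop("network with zero components")
  pair_means <- colMeans(V)
  net_i <- nets[pidx[, "i"]]
  net_j <- nets[pidx[, "j"]]
  net_names <- unique(nets)
  intra <- vapply(net_names, function(nm) {
    sel <- net_i == nm & net_j == nm
    if (!any(sel)) NA_real_ else mean(pair_means[sel])
  }, numeric(1))
  intra <- intra[!is.na(intra)]   # only networks with >= 2 components
  inter <- vapply(net_names, function(nm) {
    sel <- xor(net_i == nm, net_j == nm)
    mean(pair_means[sel])
  }, numeric(1))
  combs <- utils::combn(net_names, 2)
  pairwise <- data.frame(network_a = combs[1, ], network_b = combs[2, ],
                         value = apply(combs, 2, function(p) {
                           sel <- (net_i == p[1] & net_j == p[2]) |
                             (net_i == p[2] & net_j == p[1])
                           mean(pair_means[sel])
                         }),
                         stringsAsFactors = FALSE)
  structure(list(grand = mean(pair_means), intra = intra, inter = inter,
                 pairwise = pairwise),
            class = "asoc")
}

#' @export
print.asoc <- function(x, ...) {
  cat(sprintf("asoc: grand = %.4f; %d intra-network, %d inter-network values\n",
              x$grand, length(x$intra), length(x$inter)))
  invisible(x)
}

#' Overall connectivity from static FC
#'
#' Same table shape as [asoc()], computed from a single static FC vector
#' (equivalently, ASOC of a one-window series equal to that vector).
#'
#' @param fc Fisher-Z FC vector (with `pair_index` attribute, as returned
#'   by [static_fc()]).
#' @param assignment Component-to-network table.
#' @return An `asoc` object.
#' @export
static_overall_connectivity <- function(fc, assignment) {
  V <- matrix(fc, nrow = 1)
  attr(V, "pair_index") <- attr(fc, "pair_index")
  asoc(V, assignment)
}
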