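#' Pool windowed FC across participants
#'
#' Stacks the window x pair matrices of a cohort into one matrix for joint
#' clustering, keeping a row index back to participants and windows.
#'
#' @param wfc_list Named list of `windowed_fc` objects (one per participant).
#' @return List with `X` (pooled windows x n_pairs matrix) and `index`
#'   (data frame: `participant`, `window` (1-based), `window_start_TR`).
#' @export
pool_windows <- function(wfc_list) {
  if (is.null(names(wfc_list))) {
    names(wfc_list) <- paste0("sub", seq_along(wfc_list))
  }
  X <- do.call(rbind, lapply(wfc_list, `[[`, "values"))
  idx <- do.call(rbind, lapply(names(wfc_list), function(id) {
    wf <- wfc_list[[id]]
    data.frame(participant = id,
               window = seq_len(nrow(wf$values)),
               window_start_TR = wf$window_start_TR,
               stringsAsFactors = FALSE)
  }))
  rownames(X) <- NULL
  list(X = X, index = idx)
}

#' City-block k-means with median centroid updates
#'
#' Lloyd-style alternation under the L1 metric: points are assigned to the
#' nearest centroid in city-block distance and centroids are updated to the
#' coordinate-wise median of their members (the true L1 minimiser). Empty
#' clusters are re-seeded at the point farthest from its current centroid.
#' The best of `n_init` k-means++-style restarts (by total within-cluster L1
#' cost) is returned; results are deterministic under `seed`.
#'
#' @param X Numeric matrix, points x features.
#' @param k Number of clusters (>= 1).
#' @param n_init Number of random restarts (default 20).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param seed Integer seed.
#' @param init_centroids Optional k x ncol(X) matrix of starting centroids;
#'   when given, a single run from these centroids is performed.
#' @return Object of class `l1_kmeans`: list with `labels` (1..k per row),
#'   `centroids` (k x features), `cost` (total within-cluster L1),
#'   `iterations`, `best_init`, `n_reseeds`, `k`.
#' @export
kmeans_cityblock <- function(X, k, n_init = 20L, max_iter = 300L, seed = 1L,
                             init_centroids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric")
  if (k < 1) stop("k must be >= 1")
  if (nrow(X) < k) stop("need at least k rows")
  if (!is.null(seed)) set.seed(seed)
  res <- .kmeans_l1_cpp(X, as.integer(k), as.integer(n_init),
                        as.integer(max_iter), init_centroids)
  res$k <- as.integer(k)
  class(res) <- "l1_kmeans"
  res
}

#' @export
print.l1_kmeans <- function(x, ...) {
  cat(sprintf("l1_kmeans: k = %d, cost = %.4g, %d iterations (restart %d)\n",
              x$k, x$cost, x$iterations, x$best_init))
  invisible(x)
}

#' Dunn's cluster-validity index (city-block distances)
#'
#' Minimum between-cluster separation (smallest pairwise point distance
#' between two clusters) divided by the maximum within-cluster diameter
#' (largest pairwise distance inside any cluster). Degenerate
#' configurations in which every cluster has zero diameter return `Inf`.
#'
#' @param X Points x features matrix (ignored when `D` is supplied).
#' @param labels Cluster labels per row.
#' @param D Optional precomputed pairwise distance matrix.
#' @return Scalar index (larger = better separated).
#' @export
dunns_index <- function(X, labels, D = NULL) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 non-empty clusters")
  if (is.null(D)) D <- .pairwise_l1_cpp(t(as.matrix(X)))
  if (length(labels) != nrow(D)) stop("labels do not match points")
  ks <- sort(unique(labels))
  max_diam <- 0
  for (c in ks) {
    idx <- which(labels == c)
    if (length(idx) > 1) {
      max_diam <- max(max_diam, max(D[idx, idx]))
    }
  }
  min_sep <- Inf
  for (a in seq_along(ks)) {
    for (b in seq_along(ks)) {
      if (b <= a) next
      ia <- which(labels == ks[a]); ib <- which(labels == ks[b])
      min_sep <- min(min_sep, min(D[ia, ib]))
    }
  }
  if (max_diam == 0) return(Inf)
  min_sep / max_diam
}

#' Select the number of connectivity states
#'
#' Scans `k_range`, clustering (city-block k-means) at each k, and combines
#' two criteria: the elbow candidate is the k whose total within-cluster
#' cost (normalised by the single-cluster cost, which anchors the curve at
#' k = 1) lies farthest below the chord joining the endpoints of the cost
#' curve (L-method); the Dunn candidate is the k maximising Dunn's index. When the
#' two agree, that k is returned with `divergence = FALSE`; otherwise the
#' elbow k is returned with a divergence flag. For large inputs the scan
#' runs on an exemplar subset of at most `max_points` evenly spaced rows
#' (pairwise distances for Dunn's index are computed once and reused).
#'
#' @param X Points x features matrix (e.g. pooled windowed FC).
#' @param k_range Candidate state counts (default 2:10; at least 3 values,
#'   otherwise the elbow is undefined).
#' @param seed Integer seed.
#' @param n_init Restarts per k during the scan (default 20).
#' @param max_iter Maximum iterations (default 100).
#' @param max_points Exemplar-subset size cap (default 2000).
#' @param rows Optional row indices of the exemplar subset; when pooled
#'   windows overlap (slide < window length), pass non-overlapping windows
#'   here, otherwise adjacent near-duplicate windows at state boundaries
#'   degrade both criteria.
#' @return List with `k`, `elbow_k`, `dunn_k`, `divergence`, `diagnostics`
#'   (data frame: k, cost, normalised cost, Dunn's index), and
#'   `exemplar_rows` (row indices used).
#' @export
select_k <- function(X, k_range = 2:10, seed = 1L, n_init = 20L,
                     max_iter = 100L, max_points = 2000L, rows = NULL) {
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3) {
    stop("k_range must contain at least 3 values for the elbow criterion")
  }
  if (max(k_range) > nrow(X)) stop("k_range exceeds the number of points")
  n <- nrow(X)
  if (is.null(rows)) {
    rows <- if (n > max_points) {
      unique(round(seq(1, n, length.out = max_points)))
    } else seq_len(n)
  } else if (length(rows) > max_points) {
    rows <- rows[unique(round(seq(1, length(rows), length.out = max_points)))]
  }
  Xs <- X[rows, , drop = FALSE]
  D <- .pairwise_l1_cpp(t(Xs))
  cost <- dunn <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- kmeans_cityblock(Xs, k_range[i], n_init = n_init,
                            max_iter = max_iter, seed = seed + i)
    fits[[i]] <- fit
    cost[i] <- fit$cost
    dunn[i] <- dunns_index(labels = fit$labels, D = D)
  }
  # Elbow in two parts. (i) Boundary test against the single-cluster cost:
  # when the per-k cost drop from k = 1 down to the smallest candidate
  # dwarfs the next drop (ratio > 3), the smallest candidate is the elbow —
  # a chord criterion cannot select the end of its own scan range.
  # (ii) Otherwise, the elbow is the k whose cost lies farthest below the
  # chord joining the endpoints of the scanned curve (L-method / maximum
  # chord distance), which finds the steep-to-flat transition and is
  # insensitive to unequal cluster masses, unlike a raw second difference.
  cost1 <- kmeans_cityblock(Xs, 1, n_init = 1, seed = seed)$cost
  ncost <- cost / cost1
  first_drop <- (cost1 - cost[1]) / (k_range[1] - 1)
  next_drop <- cost[1] - cost[2]
  if (first_drop > 3 * max(next_drop, 1e-12 * cost1)) {
    elbow_k <- k_range[1]
  } else {
    m <- length(k_range)
    chord <- ncost[1] + (ncost[m] - ncost[1]) *
      (k_range - k_range[1]) / (k_range[m] - k_range[1])
    elbow_k <- k_range[which.max(chord - ncost)]
  }
  dunn_k <- k_range[which.max(dunn)]
  divergence <- elbow_k != dunn_k
  if (divergence) {
    message("elbow (k = ", elbow_k, ") and Dunn's index (k = ", dunn_k,
            ") diverge; returning the elbow k")
  }
  list(k = elbow_k, elbow_k = elbow_k, dunn_k = dunn_k,
       divergence = divergence,
       diagnostics = data.frame(k = k_range, cost = cost,
                                normalised_cost = ncost, dunn = dunn),
       exemplar_rows = rows,
       exemplar_fits = fits)
}

#' Cluster pooled windowed FC into recurrent connectivity states
#'
#' Pools all participants' windows, optionally selects k (elbow + Dunn's
#' index convergence), clusters with city-block k-means, and re-codes state
#' identities by descending total occupancy across the cohort. For large
#' cohorts the restarts run on the exemplar subset and the full data is
#' then clustered once from the best exemplar centroids.
#'
#' @param wfc_list Named list of `windowed_fc` objects.
#' @param k Number of states; `NULL` (default) triggers [select_k()].
#' @param k_range Candidate ks when `k` is `NULL`.
#' @param n_init Restarts for the exemplar-stage clustering (default 20).
#' @param seed Integer seed.
#' @param max_points Exemplar-subset cap (default 2000).
#' @return Object of class `state_model`: `k`, `centroids` (k x n_pairs,
#'   rows = final state ids), `labels` (data frame: participant, window,
#'   window_start_TR, state), `occupancy` (windows per final state),
#'   `relabel_map` (original cluster id -> final state id), `cost`,
#'   `selection` (diagnostics from [select_k()] or NULL).
#' @export
cluster_states <- function(wfc_list, k = NULL, k_range = 2:10,
                           n_init = 20L, seed = 1L, max_points = 2000L) {
  pooled <- pool_windows(wfc_list)
  X <- pooled$X
  n <- nrow(X)
  # exemplar subset: non-overlapping windows when the slide overlaps,
  # so that near-duplicate adjacent windows do not enter the scan twice
  w <- wfc_list[[1]]$window_length
  s <- wfc_list[[1]]$slide
  ex_rows <- if (s < w) {
    which((pooled$index$window_start_TR %% w) == 0)
  } else seq_len(n)
  selection <- NULL
  if (is.null(k)) {
    selection <- select_k(X, k_range = k_range, seed = seed,
                          max_points = max_points, rows = ex_rows)
    k <- selection$k
  }
  rows <- if (length(ex_rows) > max_points) {
    ex_rows[unique(round(seq(1, length(ex_rows), length.out = max_points)))]
  } else ex_rows
  if (length(rows) < n) {
    stage1 <- kmeans_cityblock(X[rows, , drop = FALSE], k, n_init = n_init,
                               seed = seed)
    fit <- kmeans_cityblock(X, k, seed = seed,
                            init_centroids = stage1$centroids)
  } else {
    fit <- kmeans_cityblock(X, k, n_init = n_init, seed = seed)
  }
  model <- structure(
    list(k = as.integer(k), centroids = fit$centroids,
         labels = cbind(pooled$index, state = fit$labels),
         occupancy = tabulate(fit$labels, nbins = k),
         relabel_map = seq_len(k), cost = fit$cost,
         selection = selection, pair_index = wfc_list[[1]]$pair_index),
    class = "state_model")
  relabel_by_occupancy(model)
}

#' Re-code state identities by descending total occupancy
#'
#' Final state 1 is the cluster with the greatest total window count across
#' the cohort; ties are broken by ascending original cluster id.
#'
#' @param model A `state_model`.
#' @return The model with relabelled states, sorted `occupancy`, reordered
#'   centroid rows, and `relabel_map[original] = final`.
#' @export
relabel_by_occupancy <- function(model) {
  stopifnot(inherits(model, "state_model"))
  occ <- tabulate(model$labels$state, nbins = model$k)
  ord <- order(-occ, seq_len(model$k))   # descending occupancy, ties by id
  relabel <- integer(model$k)
  relabel[ord] <- seq_len(model$k)
  model$labels$state <- relabel[model$labels$state]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$occupancy <- occ[ord]
  model$relabel_map <- relabel
  model
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: k = %d states over %d windows (%d participants)\n",
              x$k, nrow(x$labels), length(unique(x$labels$participant))))
  cat("occupancy:", paste(x$occupancy, collapse = ", "), "\n")
  invisible(x)
}

#' Per-participant, per-state median FC vectors
#'
#' Coordinate-wise median over the participant's windows assigned to each
#' state; states the participant never visits are missing (`NA` rows), not
#' zero.
#'
#' @param wfc A `windowed_fc` object for one participant.
#' @param labels Integer state labels, one per window.
#' @param k Number of states (default `max(labels)`).
#' @return Matrix k x n_pairs of medians, with `NA` rows for unvisited
#'   states, and attribute `"visited"` (logical per state).
#' @export
participant_state_medians <- function(wfc, labels, k = max(labels)) {
  V <- if (inherits(wfc, "windowed_fc")) wfc$values else as.matrix(wfc)
  if (nrow(V) != length(labels)) stop("labels do not align with windows")
  out <- matrix(NA_real_, k, ncol(V))
  visited <- logical(k)
  for (s in seq_len(k)) {
    idx <- which(labels == s)
    if (length(idx)) {
      visited[s] <- TRUE
      out[s, ] <- if (length(idx) == 1) V[idx, ] else
        apply(V[idx, , drop = FALSE], 2, median)
    }
  }
  attr(out, "visited") <- visited
  out
}

#' Per-state median FC for every participant in a cohort
#'
#' @param wfc_list Named list of `windowed_fc` objects.
#' @param model A `state_model` fitted on the pooled windows (or a data
#'   frame of labels with columns `participant` and `state`).
#' @return 3-d array `[participant, state, pair]` with `NA` slices for
#'   unvisited states.
#' @export
state_medians_cohort <- function(wfc_list, model) {
  labels <- if (inherits(model, "state_model")) model$labels else model
  k <- if (inherits(model, "state_model")) model$k else max(labels$state)
  ids <- names(wfc_list)
  npair <- ncol(wfc_list[[1]]$values)
  out <- array(NA_real_, dim = c(length(ids), k, npair),
               dimnames = list(ids, paste0("state", seq_len(k)), NULL))
  for (i in seq_along(ids)) {
    lab_i <- labels$state[labels$participant == ids[i]]
    out[i, , ] <- participant_state_medians(wfc_list[[i]], lab_i, k = k)
  }
  out
}
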