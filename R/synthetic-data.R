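#' State-process configuration
#'
#' Defines the latent Markov state process that drives synthetic component
#' time-courses: `k_states` recurrent connectivity states, a row-stochastic
#' transition matrix at TR resolution, and one component-correlation matrix
#' (the state "centroid") per state. Centroid matrices must be symmetric
#' with unit diagonal; matrices that are indefinite within tolerance are
#' repaired by eigenvalue clipping and re-normalisation to unit diagonal.
#'
#' @param transition_matrix k x k row-stochastic matrix (rows sum to 1
#'   within 1e-12).
#' @param centroid_correlations List of k symmetric correlation matrices
#'   (n_comp x n_comp).
#' @param seed Integer seed stored with the configuration.
#' @return Object of class `state_process_config`.
#' @export
state_process_config <- function(transition_matrix, centroid_correlations,
                                 seed = 1L) {
  P <- as.matrix(transition_matrix)
  k <- nrow(P)
  if (k < 1 || ncol(P) != k) stop("transition_matrix must be square, k >= 1")
  if (any(P < 0)) stop("transition probabilities must be non-negative")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("non-stochastic transition row(s): ",
         paste(which(abs(rs - 1) > 1e-12), collapse = ", "))
  }
  if (!is.list(centroid_correlations) || length(centroid_correlations) != k) {
    stop("centroid_correlations must be a list of k matrices")
  }
  centroids <- lapply(centroid_correlations, repair_psd)
  n_comp <- nrow(centroids[[1]])
  if (any(vapply(centroids, nrow, 1L) != n_comp)) {
    stop("all centroid matrices must have the same dimension")
  }
  structure(list(k_states = k, transition_matrix = P,
                 centroid_correlations = centroids,
                 n_components = n_comp,
                 dwell_scale = 1 / (1 - pmin(diag(P), 1 - 1e-12)),
                 seed = as.integer(seed)),
            class = "state_process_config")
}

# eigenvalue-clipping PSD repair, then re-normalise to unit diagonal
repair_psd <- function(R, tol = 1e-10) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("centroid matrix must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("centroid matrix must be symmetric")
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol && max(abs(diag(R) - 1)) < 1e-12) return(R)
  vals <- pmax(e$values, 0)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- diag(R2)
  if (any(d <= 0)) stop("centroid matrix not repairable to a correlation matrix")
  R2 <- R2 / sqrt(tcrossprod(d))
  (R2 + t(R2)) / 2
}

#' Cohort configuration for the synthetic generator
#'
#' Group sizes default to the reference cohort structure: 101 healthy
#' controls, 36 patients without disability (EDSS <= 1) and 39 patients with
#' mild-to-moderate disability (EDSS >= 2); patients whose EDSS ties the
#' sample median (1.5) and unrated patients are generated in proportion
#' (17/75 and 9/75 of the two disability groups) so that the percentile
#' split reproduces the three-group structure.
#'
#' @param n_hc,n_mild,n_nodis Group sizes (healthy controls, mild-moderate
#'   disability, no disability).
#' @param n_components Number of signal components (default 47).
#' @param n_timepoints Number of TRs per scan (default 255).
#' @param TR Sampling interval in seconds (default 2.25).
#' @param group_occupancy_shift Additive bias on the transition-matrix
#'   diagonal for the mild-moderate group, length `k`; the default raises
#'   the state-5 diagonal by 0.02, increasing that group's state-5 dwell
#'   and fraction time.
#' @param clinical_effect_sizes Named per-domain standardised mean
#'   differences (impairment direction) between the EDSS subgroups.
#' @param missingness_rate Per-test probability of a missing clinical score.
#' @param seed Master seed; per-participant seeds are derived by fixed
#'   offset.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 101L, n_mild = 39L, n_nodis = 36L,
                          n_components = 47L, n_timepoints = 255L,
                          TR = 2.25,
                          group_occupancy_shift = c(0, 0, 0, 0, 0.02),
                          clinical_effect_sizes = c(
                            vision = 0.9, motor = 1.0, fatigue = 1.5,
                            depression = 0.75, cognition = 0.5,
                            brain_volume = 0.6, lesion_load = 0.8),
                          missingness_rate = 0.08,
                          seed = 1L) {
  stopifnot(n_hc >= 0, n_mild > 0, n_nodis > 0, n_components > 1,
            n_timepoints > 1, TR > 0)
  if (missingness_rate < 0 || missingness_rate >= 1) {
    stop("missingness_rate must be in [0, 1)")
  }
  structure(list(n_hc = as.integer(n_hc), n_mild = as.integer(n_mild),
                 n_nodis = as.integer(n_nodis),
                 n_components = as.integer(n_components),
                 n_timepoints = as.integer(n_timepoints), TR = TR,
                 group_occupancy_shift = group_occupancy_shift,
                 clinical_effect_sizes = clinical_effect_sizes,
                 missingness_rate = missingness_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default component-to-network assignment
#'
#' Eight resting-state networks over 47 signal components, with a
#' single-component basal-ganglia network: DMN 10, VIS 8, SMN 8, FPN 7,
#' dATT 6, vATT 4, CB 3, BG 1.
#'
#' @param n_components Number of components (default 47).
#' @return Data frame with columns `component_id` and `network`.
#' @export
default_network_assignment <- function(n_components = 47L) {
  counts <- c(DMN = 10, VIS = 8, SMN = 8, FPN = 7, dATT = 6, vATT = 4,
              CB = 3, BG = 1)
  if (n_components != sum(counts)) {
    if (n_components < 9) stop("need at least 9 components for 8 networks")
    # scale the multi-component networks, keep BG at one component
    base <- counts[names(counts) != "BG"]
    scaled <- setNames(pmax(1, round(base / sum(base) * (n_components - 1))),
                       names(base))
    while (sum(scaled) > n_components - 1) {
      j <- which(scaled == max(scaled))[1]
      scaled[j] <- scaled[j] - 1
    }
    while (sum(scaled) < n_components - 1) {
      j <- which(scaled == min(scaled))[1]
      scaled[j] <- scaled[j] + 1
    }
    counts <- c(scaled, BG = 1)
  }
  data.frame(component_id = paste0("comp", seq_len(n_components)),
             network = rep(names(counts), counts),
             stringsAsFactors = FALSE)
}

#' Default state centroid correlation matrices
#'
#' Five whole-brain connectivity states with network-block structure:
#' state 1 is weakly connected globally, states 2-4 each emphasise a
#' different set of networks (sensory, default-mode/frontoparietal,
#' attention), and state 5 is globally hyper-connected. All matrices are
#' PSD-repaired correlation matrices.
#'
#' @param assignment Component-to-network table
#'   ([default_network_assignment()] by default).
#' @return List of 5 correlation matrices.
#' @export
default_state_centroids <- function(assignment = default_network_assignment()) {
  nets <- assignment$network
  n <- nrow(assignment)
  block <- function(within, between, special_within = NULL,
                    special_between = NULL) {
    R <- matrix(between, n, n)
    for (nm in unique(nets)) {
      idx <- which(nets == nm)
      w <- if (!is.null(special_within) && nm %in% names(special_within)) {
        special_within[[nm]]
      } else within
      R[idx, idx] <- w
    }
    if (!is.null(special_between)) {
      for (p in special_between) {
        a <- which(nets == p[[1]]); b <- which(nets == p[[2]])
        R[a, b] <- p[[3]]; R[b, a] <- p[[3]]
      }
    }
    diag(R) <- 1
    R
  }
  # states are designed approximately equidistant in L1 so that model
  # selection over k is well-posed: states 2-4 carry disjoint network
  # signatures of similar total weight, state 1 is globally hypo- and
  # state 5 globally hyper-connected relative to the shared baseline
  list(
    block(0.05, 0.00),
    block(0.25, 0.10,
          special_within = list(VIS = 0.7, SMN = 0.7),
          special_between = list(list("VIS", "SMN", 0.45),
                                 list("DMN", "VIS", -0.35))),
    block(0.25, 0.10,
          special_within = list(DMN = 0.7, FPN = 0.6),
          special_between = list(list("DMN", "FPN", 0.45),
                                 list("CB", "DMN", -0.35))),
    block(0.25, 0.10,
          special_within = list(dATT = 0.7, vATT = 0.7),
          special_between = list(list("dATT", "vATT", 0.45),
                                 list("FPN", "dATT", 0.40),
                                 list("SMN", "VIS", -0.35))),
    block(0.45, 0.22)
  )
}

#' Default TR-resolution transition matrix
#'
#' Diagonals 0.985, 0.980, 0.975, 0.970, 0.960 (mean dwell about 67 down to
#' 25 TR), with the off-diagonal mass spread uniformly; the stationary
#' occupancy is decreasing in the state index, so state 1 is the most and
#' state 5 the least frequent state.
#'
#' @param k Number of states (default 5).
#' @param diagonals Self-transition probabilities (length `k`).
#' @return k x k row-stochastic matrix.
#' @export
default_transition_matrix <- function(k = 5L,
                                      diagonals = c(0.985, 0.98, 0.975,
                                                    0.97, 0.96)[seq_len(k)]) {
  P <- matrix(0, k, k)
  for (i in seq_len(k)) {
    off <- (1 - diagonals[i]) / (k - 1)
    P[i, ] <- off
    P[i, i] <- diagonals[i]
  }
  P
}

#' Default state-process configuration (47 components, 5 states)
#'
#' @param seed Integer seed.
#' @param assignment Component-to-network table.
#' @return A [state_process_config()].
#' @export
default_state_process <- function(seed = 1L,
                                  assignment = default_network_assignment()) {
  state_process_config(default_transition_matrix(5L),
                       default_state_centroids(assignment), seed = seed)
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  ix <- which(abs(e$values - 1) < 1e-8)
  if (length(ix) != 1) return(rep(1 / nrow(P), nrow(P)))
  v <- Re(e$vectors[, ix])
  v <- v / sum(v)
  if (any(v < -1e-10)) return(rep(1 / nrow(P), nrow(P)))
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Generate a Markov state-label sequence
#'
#' The first label is drawn from the stationary distribution of the
#' transition matrix (uniform if the stationary distribution is not
#' unique); subsequent labels follow the Markov kernel.
#'
#' @param cfg A [state_process_config()].
#' @param n_windows Sequence length (>= 1).
#' @param seed Integer seed (default: the config seed).
#' @param start Optional forced first state.
#' @return Integer vector of state labels in `1..k`.
#' @export
generate_state_sequence <- function(cfg, n_windows, seed = cfg$seed,
                                    start = NULL) {
  stopifnot(inherits(cfg, "state_process_config"), n_windows >= 1)
  P <- cfg$transition_matrix
  k <- cfg$k_states
  if (!is.null(seed)) set.seed(seed)
  labels <- integer(n_windows)
  labels[1] <- if (!is.null(start)) as.integer(start) else {
    sample.int(k, 1, prob = stationary_distribution(P))
  }
  if (n_windows > 1) {
    u <- runif(n_windows - 1)
    cumP <- t(apply(P, 1, cumsum))
    for (t in 2:n_windows) {
      labels[t] <- findInterval(u[t - 1], cumP[labels[t - 1], ]) + 1L
    }
  }
  labels
}

#' Generate one participant's component time-courses
#'
#' A TR-resolution state sequence is drawn from the Markov process, and each
#' TR's sample is drawn from a zero-mean multivariate normal whose
#' correlation matrix is the current state's centroid.
#'
#' @param cfg A [state_process_config()].
#' @param cohort A [cohort_config()] (supplies `n_timepoints` and `TR`).
#' @param participant_seed Integer seed for this participant.
#' @param transition_matrix Optional override of the config's transition
#'   matrix (used for group-specific occupancy shifts).
#' @param participant_id Participant label.
#' @return List with elements `timecourses` (a [component_timecourses()])
#'   and `state_labels` (ground-truth per-TR labels).
#' @export
generate_timecourses <- function(cfg, cohort, participant_seed,
                                 transition_matrix = NULL,
                                 participant_id = NULL) {
  stopifnot(inherits(cfg, "state_process_config"),
            inherits(cohort, "cohort_config"))
  if (cfg$n_components != cohort$n_components) {
    stop("centroid dimension (", cfg$n_components,
         ") does not match cohort n_components (", cohort$n_components, ")")
  }
  cfg_use <- cfg
  if (!is.null(transition_matrix)) {
    cfg_use$transition_matrix <- transition_matrix
  }
  T_len <- cohort$n_timepoints
  labels <- generate_state_sequence(cfg_use, T_len, seed = participant_seed)
  # eigen square-root factor: valid for semidefinite (repaired) centroids
  factors <- lapply(cfg$centroid_correlations, function(R) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < -1e-8) stop("centroid not PSD after repair")
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })
  X <- matrix(rnorm(cfg$n_components * T_len), nrow = cfg$n_components)
  for (s in seq_len(cfg$k_states)) {
    idx <- which(labels == s)
    if (length(idx)) {
      X[, idx] <- factors[[s]] %*% X[, idx, drop = FALSE]
    }
  }
  list(timecourses = component_timecourses(X, TR = cohort$TR,
                                           participant_id = participant_id),
       state_labels = labels)
}

# apply an additive diagonal bias and rescale the off-diagonal mass
shift_transition_diagonal <- function(P, shift) {
  k <- nrow(P)
  stopifnot(length(shift) == k)
  for (i in seq_len(k)) {
    new_diag <- min(max(P[i, i] + shift[i], 0), 1 - 1e-6)
    off <- P[i, -i]
    if (sum(off) > 0) {
      P[i, -i] <- off * (1 - new_diag) / sum(off)
    }
    P[i, i] <- new_diag
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  P
}

# Table-2-style clinical battery: test id, domain, direction of the raw
# score (+1 higher = worse, -1 higher = better)
default_clinical_tests <- function() {
  vision <- expand.grid(scale = c("etdrs100", "etdrs10", "sloan2.5", "sloan1.25"),
                        eye = c("re", "le"),
                        measure = c("acuity", "letters"),
                        stringsAsFactors = FALSE)
  vision_ids <- apply(vision, 1, paste, collapse = "_")
  data.frame(
    test = c(vision_ids,
             "t25fw", "nhpt",
             "fss", "bdi2",
             "srt_lts", "srt_cltr", "srt_dr", "spat", "spat_dr",
             "sdmt", "pasat", "wlg",
             "brain_volume", "lesion_load"),
    domain = c(rep("vision", length(vision_ids)),
               rep("motor", 2), "fatigue", "depression",
               rep("cognition", 8), "brain_volume", "lesion_load"),
    direction = c(rep(-1, length(vision_ids)),   # better acuity = higher
                  rep(1, 2),                     # slower times = higher
                  1, 1,                          # symptom scales
                  rep(-1, 8),                    # better cognition = higher
                  -1,                            # more volume = higher
                  1),                            # more lesions = higher
    stringsAsFactors = FALSE)
}

#' Default domain map (test-to-domain assignments)
#'
#' @return Data frame with columns `test` and `domain` covering the full
#'   clinical battery: 16 vision measures, 2 motor tests, single fatigue and
#'   depression scales, 8 cognitive sub-tests, and the two structural MRI
#'   measures.
#' @export
default_domain_map <- function() {
  default_clinical_tests()[, c("test", "domain")]
}

#' Generate the demographic and raw clinical table
#'
#' Draws, per participant: group label, age, sex, EDSS (on the 0-10 grid in
#' 0.5 steps, patients only), and raw clinical test scores with a planted
#' per-domain standardised mean difference between the EDSS subgroups
#' (median-tied patients receive half the shift). Healthy controls carry no
#' clinical scores. Age is drawn older in the higher-EDSS subgroup.
#'
#' @param cohort A [cohort_config()].
#' @param seed Integer seed (default: the config seed).
#' @return Data frame with one row per participant: `participant_id`,
#'   `group` (`"HC"`/`"MS"`), `subgroup_truth`, `age`, `sex`, `EDSS`, and
#'   one column per clinical test.
#' @export
generate_clinical_cohort <- function(cohort, seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_config"))
  set.seed(seed)
  n_pat2 <- cohort$n_nodis + cohort$n_mild
  n_tied <- round(17 / 75 * n_pat2)
  n_unrated <- round(9 / 75 * n_pat2)
  subgroup <- c(rep("HC", cohort$n_hc),
                rep("no_disability", cohort$n_nodis),
                rep("mild_moderate", cohort$n_mild),
                rep("median_tied", n_tied),
                rep("unrated", n_unrated))
  n <- length(subgroup)
  edss <- rep(NA_real_, n)
  edss[subgroup == "no_disability"] <-
    sample(c(0, 1), cohort$n_nodis, replace = TRUE, prob = c(16, 20))
  edss[subgroup == "mild_moderate"] <-
    sample(c(2, 2.5, 3, 3.5, 4, 5.5), cohort$n_mild, replace = TRUE,
           prob = c(14, 12, 6, 4, 2, 1))
  edss[subgroup == "median_tied"] <- 1.5
  age_mu <- c(HC = 35, no_disability = 31.6, mild_moderate = 40.2,
              median_tied = 36, unrated = 36)
  age_sd <- c(HC = 10.3, no_disability = 6.1, mild_moderate = 11.6,
              median_tied = 10, unrated = 10)
  age <- round(pmax(18, rnorm(n, age_mu[subgroup], age_sd[subgroup])), 1)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(67, 34))
  tests <- default_clinical_tests()
  # raw-score location/scale per test (arbitrary units; removed by z-scoring)
  test_mu <- setNames(rep(10, nrow(tests)), tests$test)
  test_sd <- setNames(rep(2, nrow(tests)), tests$test)
  shift_frac <- c(HC = NA, no_disability = 0, mild_moderate = 1,
                  median_tied = 0.5, unrated = 0.5)[subgroup]
  scores <- matrix(NA_real_, n, nrow(tests),
                   dimnames = list(NULL, tests$test))
  is_pat <- subgroup != "HC"
  for (j in seq_len(nrow(tests))) {
    d <- unname(cohort$clinical_effect_sizes[tests$domain[j]])
    if (length(d) != 1 || is.na(d)) d <- 0
    # direction -1 tests are "higher = better": the impaired group scores
    # lower on the raw scale, so that after the -1 recoding the planted
    # impairment difference is +d
    delta <- tests$direction[j] * d
    raw <- test_mu[j] + test_sd[j] *
      (delta * shift_frac[is_pat] + rnorm(sum(is_pat)))
    if (cohort$missingness_rate > 0) {
      raw[runif(sum(is_pat)) < cohort$missingness_rate] <- NA_real_
    }
    scores[is_pat, j] <- raw
  }
  out <- data.frame(
    participant_id = sprintf("sub%03d", seq_len(n)),
    group = ifelse(subgroup == "HC", "HC", "MS"),
    subgroup_truth = subgroup,
    age = age, sex = sex, EDSS = edss,
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper combining the clinical table and per-participant
#' state-switching component time-courses. Per-participant seeds are the
#' master seed plus a fixed offset times the participant index. The
#' mild-moderate group uses a transition matrix with
#' `group_occupancy_shift` added to the diagonal.
#'
#' @param cohort A [cohort_config()].
#' @param state_cfg A [state_process_config()]; defaults to
#'   [default_state_process()].
#' @param timecourses If `FALSE`, only the clinical table is generated.
#' @param seed Master seed (default: the cohort config seed).
#' @return List with `clinical` (data frame), and when requested
#'   `timecourses` (named list of [component_timecourses()]) and
#'   `truth_tr_labels` (named list of per-TR ground-truth state labels).
#' @export
simulate_cohort <- function(cohort, state_cfg = NULL,
                            timecourses = TRUE, seed = cohort$seed) {
  if (is.null(state_cfg)) {
    state_cfg <- default_state_process(
      seed = seed,
      assignment = default_network_assignment(cohort$n_components))
  }
  clinical <- generate_clinical_cohort(cohort, seed = seed)
  res <- list(clinical = clinical, state_cfg = state_cfg, cohort = cohort)
  if (!timecourses) return(res)
  shift <- cohort$group_occupancy_shift
  if (length(shift) != state_cfg$k_states) {
    stop("group_occupancy_shift must have length k_states")
  }
  P_mild <- shift_transition_diagonal(state_cfg$transition_matrix, shift)
  tcs <- vector("list", nrow(clinical))
  labs <- vector("list", nrow(clinical))
  for (i in seq_len(nrow(clinical))) {
    P_i <- if (clinical$subgroup_truth[i] == "mild_moderate") P_mild else NULL
    g <- generate_timecourses(state_cfg, cohort,
                              participant_seed = seed + 1000L + i,
                              transition_matrix = P_i,
                              participant_id = clinical$participant_id[i])
    tcs[[i]] <- g$timecourses
    labs[[i]] <- g$state_labels
  }
  names(tcs) <- names(labs) <- clinical$participant_id
  res$timecourses <- tcs
  res$truth_tr_labels <- labs
  res
}

#' Derive ground-truth window labels from TR labels
#'
#' Majority vote over the TRs each sliding window covers; ties are broken
#' in favour of the state that occurs earliest within the window.
#'
#' @param tr_labels Integer per-TR state labels.
#' @param w Window length in TR (default 22).
#' @param s Slide length in TR (default 1).
#' @return Integer per-window labels (length `floor((T - w)/s) + 1`).
#' @export
window_truth_labels <- function(tr_labels, w = 22L, s = 1L) {
  tr_labels <- as.integer(tr_labels)
  T_len <- length(tr_labels)
  k <- max(tr_labels)
  n_win <- (T_len - w) %/% s + 1L
  starts <- (seq_len(n_win) - 1L) * s + 1L
  # per-state counts in each window from cumulative indicator sums
  cnt <- vapply(seq_len(k), function(st) {
    cs <- cumsum(tr_labels == st)
    cs[starts + w - 1L] - c(0, cs)[starts]
  }, numeric(n_win))
  cnt <- matrix(cnt, nrow = n_win)
  out <- max.col(cnt, ties.method = "first")
  mx <- cnt[cbind(seq_len(n_win), out)]
  ties <- which(rowSums(cnt == mx) > 1)
  for (m in ties) {
    seg <- tr_labels[starts[m]:(starts[m] + w - 1L)]
    cand <- which(cnt[m, ] == mx[m])
    out[m] <- seg[seg %in% cand][1]
  }
  as.integer(out)
}
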