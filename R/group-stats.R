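#' Permutation two-sample T-test
#'
#' Welch-style two-sample T statistic with a permutation null: group labels
#' are permuted uniformly `n_perm` times and the two-sided p-value uses the
#' add-one formula `p = (1 + #{|T*| >= |T_obs|}) / (1 + n_perm)`, which is
#' a valid permutation p-value and never returns 0.
#'
#' @param x,y Numeric samples for the two groups (each n >= 2).
#' @param n_perm Number of permutations (default 9999, >= 100).
#' @param seed Integer seed.
#' @return List with `T` (observed Welch statistic) and `p`.
#' @export
permutation_t_test <- function(x, y, n_perm = 9999L, seed = 1L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
    return(list(T = 0, p = 1))
  }
  res <- perm_welch_matrix(matrix(c(x, y), ncol = 1),
                           g1 = c(rep(TRUE, length(x)), rep(FALSE, length(y))),
                           n_perm = n_perm, seed = seed)
  list(T = unname(res$T_obs), p = unname(res$p))
}

#' Mass-univariate permutation T-tests
#'
#' Column-wise Welch permutation T-tests comparing rows of `X` between two
#' groups, with a shared set of label permutations across columns (the
#' standard mass-univariate design). Used for the 1081 FC pair tests per
#' group comparison.
#'
#' @param X Numeric matrix, observations x variables.
#' @param g1 Logical vector marking group-1 rows.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `T_obs` and `p` (one per column).
#' @export
mass_univariate_perm_t <- function(X, g1, n_perm = 9999L, seed = 1L) {
  perm_welch_matrix(as.matrix(X), as.logical(g1), n_perm, seed)
}

# Welch T for all columns and all permutations via group-sum algebra
perm_welch_matrix <- function(X, g1, n_perm, seed) {
  n <- nrow(X)
  n1 <- sum(g1); n2 <- n - n1
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  S <- colSums(X); Q <- colSums(X^2)
  welch <- function(S1, Q1) {
    S2 <- S - S1; Q2 <- Q - Q1
    m1 <- S1 / n1; m2 <- S2 / n2
    v1 <- pmax((Q1 - n1 * m1^2) / (n1 - 1), 0)
    v2 <- pmax((Q2 - n2 * m2^2) / (n2 - 1), 0)
    num <- m1 - m2
    den <- sqrt(v1 / n1 + v2 / n2)
    t <- num / den
    t[den == 0 & num == 0] <- 0
    t[den == 0 & num > 0] <- Inf
    t[den == 0 & num < 0] <- -Inf
    t
  }
  T_obs <- welch(colSums(X[g1, , drop = FALSE]),
                 colSums(X[g1, , drop = FALSE]^2))
  if (!is.null(seed)) set.seed(seed)
  idx <- replicate(n_perm, sample.int(n, n1))
  P <- matrix(0, n, n_perm)
  P[cbind(as.vector(idx), rep(seq_len(n_perm), each = n1))] <- 1
  S1 <- crossprod(X, P)          # variables x n_perm
  Q1 <- crossprod(X^2, P)
  exceed <- integer(ncol(X))
  # welch() broadcasts over the permutation dimension column by column
  Tb <- matrix(0, ncol(X), n_perm)
  for (b in seq_len(n_perm)) Tb[, b] <- welch(S1[, b], Q1[, b])
  exceed <- rowSums(abs(Tb) >= abs(T_obs) - 1e-12)
  list(T_obs = T_obs, p = (1 + exceed) / (1 + n_perm))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled`, pooling the variances with
#' `(n_x - 1, n_y - 1)` weights.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return Scalar d.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs n >= 2")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR adjustment within one family
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1; input
#' order preserved.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Apply family-structured FDR correction
#'
#' Runs [bh_fdr()] independently within each declared family of tests.
#'
#' @param results Data frame with at least `p_uncorrected` and `family`
#'   columns; every row must carry a family id.
#' @return `results` with a `p_fdr` column added.
#' @export
apply_family_correction <- function(results) {
  if (!all(c("p_uncorrected", "family") %in% names(results))) {
    stop("results must have 'p_uncorrected' and 'family' columns")
  }
  if (any(is.na(results$family))) stop("orphan test without a family id")
  results$p_fdr <- NA_real_
  for (f in unique(results$family)) {
    i <- results$family == f
    results$p_fdr[i] <- bh_fdr(results$p_uncorrected[i])
  }
  results
}

#' Residuals after removing age-related variance
#'
#' Least-squares regression of the values on (intercept, age); residuals
#' are orthogonal to age. Missing values propagate as missing.
#'
#' @param values Numeric vector.
#' @param age Numeric vector of the same length; must vary.
#' @return Residual vector (same length, `NA` where inputs were missing).
#' @export
age_residuals <- function(values, age) {
  if (length(values) != length(age)) stop("lengths differ")
  ok <- !is.na(values) & !is.na(age)
  if (sum(ok) < 3) stop("need at least 3 complete observations")
  if (var(age[ok]) == 0) stop("age is constant")
  fit <- lm.fit(cbind(1, age[ok]), values[ok])
  out <- rep(NA_real_, length(values))
  out[ok] <- fit$residuals
  out
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction; p from the chi-squared
#' approximation with `groups - 1` degrees of freedom.
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 2).
#' @return List with `chisq`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, function(g) sum(!is.na(g)), 1L) < 2)) {
    stop("each group needs n >= 2")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ok <- !is.na(values)
  if (length(unique(values[ok])) == 1) stop("all values identical")
  kt <- kruskal.test(values[ok], g[ok])
  list(chisq = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc pairwise rank tests
#'
#' Pairwise Z statistics from the pooled ranks with tie correction,
#' two-sided p-values, and BH correction over the pairwise family.
#' Conventionally gated on a rejected Kruskal-Wallis omnibus; the gate is a
#' caller policy (`require_omnibus`).
#'
#' @param groups Named list of numeric samples.
#' @param omnibus_p Optional omnibus p-value, checked against `alpha` when
#'   `require_omnibus = TRUE`.
#' @param require_omnibus If `TRUE`, error unless `omnibus_p <= alpha`.
#' @param alpha Gate level (default 0.05).
#' @return Data frame: `group_a`, `group_b`, `Z`, `p_uncorrected`, `p_fdr`.
#' @export
dunns_posthoc <- function(groups, omnibus_p = NULL, require_omnibus = FALSE,
                          alpha = 0.05) {
  if (require_omnibus) {
    if (is.null(omnibus_p) || omnibus_p > alpha) {
      stop("omnibus test not rejected; Dunn's tests gated off")
    }
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  if (length(unique(values)) == 1) stop("all values identical")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  combs <- utils::combn(names(groups), 2)
  Z <- apply(combs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(sigma2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
  })
  p <- 2 * pnorm(-abs(Z))
  data.frame(group_a = combs[1, ], group_b = combs[2, ], Z = Z,
             p_uncorrected = p, p_fdr = bh_fdr(pmin(pmax(p, 1e-300), 1)),
             stringsAsFactors = FALSE)
}

#' Age-residualised Kruskal-Wallis with Dunn's post-hoc tests
#'
#' The group-comparison path used for temporal metrics and ASOC: linear
#' regression removes age-related variance, the residuals enter a
#' Kruskal-Wallis omnibus test across the groups, and Dunn's pairwise tests
#' (BH-corrected over the pairs) follow.
#'
#' @param values Numeric vector of the metric across participants.
#' @param age Numeric vector of ages.
#' @param group Factor/character group labels.
#' @param gate_posthoc If `TRUE`, Dunn's tests are only run when the
#'   omnibus rejects at `alpha`.
#' @param alpha Omnibus gate level.
#' @return List with `kw` (see [kruskal_wallis()]) and `dunn` (data frame
#'   or `NULL` when gated off).
#' @export
metric_group_test <- function(values, age, group, gate_posthoc = FALSE,
                              alpha = 0.05) {
  ok <- !is.na(values) & !is.na(age) & !is.na(group)
  res <- age_residuals(values[ok], age[ok])
  groups <- split(res, as.character(group[ok]))
  kw <- kruskal_wallis(groups)
  dunn <- NULL
  if (!gate_posthoc || kw$p <= alpha) {
    dunn <- dunns_posthoc(groups)
  }
  list(kw = kw, dunn = dunn)
}

#' Age-controlled Spearman partial correlation
#'
#' Ranks x, y and the covariate (average ranks for ties), computes the
#' partial Pearson correlation of the ranked x and y given the ranked
#' covariate, with p from the t approximation at n - 3 degrees of freedom.
#' Incomplete triples are dropped (pairwise deletion).
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric covariate (e.g. age).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_partial <- function(x, y, covariate) {
  ok <- complete.cases(x, y, covariate)
  n <- sum(ok)
  if (n < 4) stop("need at least 4 complete triples")
  rx <- rank(x[ok]); ry <- rank(y[ok]); rz <- rank(covariate[ok])
  if (var(rx) == 0 || var(ry) == 0) stop("zero variance after ranking")
  rxy <- cor(rx, ry)
  if (var(rz) == 0) {
    rho <- rxy
  } else {
    rxz <- cor(rx, rz); ryz <- cor(ry, rz)
    den <- sqrt((1 - rxz^2) * (1 - ryz^2))
    rho <- if (den == 0) 0 else (rxy - rxz * ryz) / den
  }
  rho <- min(max(rho, -1), 1)
  tval <- if (abs(rho) >= 1) Inf * sign(rho) else
    rho * sqrt((n - 3) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), df = n - 3), n = n)
}

# vectorised partial Spearman of each column of X with y given z
spearman_partial_many <- function(X, y, z) {
  n <- length(y)
  if (n < 4) stop("need at least 4 complete observations")
  Rx <- apply(X, 2, rank)
  ry <- rank(y); rz <- rank(z)
  rxy <- suppressWarnings(cor(Rx, ry))[, 1]
  if (var(rz) == 0) {
    rho <- rxy
  } else {
    rxz <- suppressWarnings(cor(Rx, rz))[, 1]
    ryz <- cor(ry, rz)
    den <- sqrt(pmax(1 - rxz^2, 0) * (1 - ryz^2))
    rho <- ifelse(den == 0, 0, (rxy - rxz * ryz) / den)
  }
  rho[is.na(rho)] <- 0
  rho <- pmin(pmax(rho, -1), 1)
  tval <- ifelse(abs(rho) >= 1, Inf * sign(rho),
                 rho * sqrt((n - 3) / pmax(1 - rho^2, 1e-300)))
  list(rho = rho, p = 2 * pt(-abs(tval), df = n - 3), n = n)
}

#' Age-controlled correlations between per-state FC and clinical domains
#'
#' For every connectivity state and clinical domain, Spearman partial
#' correlations (controlling for age) are computed between each FC pair's
#' per-state median value and the domain score, across patients with
#' complete data for that state and domain. FDR families are one state x
#' one domain (1081 tests each on the 47-component layout).
#'
#' @param medians 3-d array `[patient, state, pair]` of per-state median FC
#'   (see [state_medians_cohort()]).
#' @param domain_scores Data frame of impairment-coded domain z-scores, one
#'   row per patient (aligned with `medians`).
#' @param age Numeric vector of patient ages.
#' @return Data frame: `state`, `domain`, `pair`, `rho`, `p_uncorrected`,
#'   `n`, `family`, `p_fdr`.
#' @export
correlate_fc_clinical <- function(medians, domain_scores, age) {
  k <- dim(medians)[2]
  npair <- dim(medians)[3]
  doms <- names(domain_scores)
  out <- vector("list", k * length(doms))
  ct <- 0
  for (s in seq_len(k)) {
    Xs <- medians[, s, , drop = TRUE]
    visited <- !is.na(Xs[, 1])
    for (d in doms) {
      ct <- ct + 1
      yd <- domain_scores[[d]]
      ok <- visited & !is.na(yd) & !is.na(age)
      res <- spearman_partial_many(Xs[ok, , drop = FALSE], yd[ok], age[ok])
      out[[ct]] <- data.frame(
        state = s, domain = d, pair = seq_len(npair),
        rho = res$rho, p_uncorrected = pmin(pmax(res$p, 1e-300), 1),
        n = res$n,
        family = sprintf("state%d_%s", s, d),
        stringsAsFactors = FALSE)
    }
  }
  apply_family_correction(do.call(rbind, out))
}
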