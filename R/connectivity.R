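#' Fisher-Z transform of a correlation coefficient
#'
#' Applies the variance-stabilising transform `z = arctanh(r)`. Correlations
#' are clipped to `1 - 1e-7` in absolute value before the transform so that
#' perfectly (anti-)correlated pairs map to a finite value (about +/- 8.4)
#' while the ordering of all inputs is preserved.
#'
#' @param r Numeric vector of Pearson correlations in `[-1, 1]`.
#' @return Numeric vector of Fisher-Z values.
#' @export
#' @examples
#' fisher_z(c(0, 0.5, 1))
fisher_z <- function(r) {
  if (!is.numeric(r)) stop("`r` must be numeric")
  bad <- !is.na(r) & abs(r) > 1 + 1e-12
  if (any(bad)) {
    stop("correlation out of range [-1, 1]: ", paste(r[bad], collapse = ", "))
  }
  r_max <- 1 - 1e-7
  atanh(pmin(pmax(r, -r_max), r_max))
}

#' Vectorize the lower triangle of a symmetric matrix
#'
#' Extracts the strictly-lower-triangular entries in column-major order, the
#' canonical pair ordering used throughout the package: for `n` components
#' the pairs are (2,1), (3,1), ..., (n,1), (3,2), ..., (n, n-1), i.e.
#' component_i > component_j with j varying slowest. With 47 components this
#' yields 1081 pair values.
#'
#' @param M Symmetric numeric matrix (checked to tolerance `1e-10`).
#' @return Numeric vector of length `n * (n - 1) / 2` with attribute
#'   `"pair_index"`, a two-column integer matrix `(i, j)` with `i > j`.
#' @seealso [devectorize_lower_triangle()]
#' @export
vectorize_lower_triangle <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("`M` must be a square matrix")
  if (max(abs(M - t(M))) > 1e-10) stop("`M` is not symmetric within 1e-10")
  v <- M[lower.tri(M)]
  attr(v, "pair_index") <- pair_index(nrow(M))
  v
}

#' Pair index for the lower-triangle ordering
#'
#' @param n Number of components.
#' @return Integer matrix with columns `i`, `j` (`i > j`), rows in
#'   column-major lower-triangle order.
#' @export
pair_index <- function(n) {
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, "j"], idx[, "i"]), , drop = FALSE]
}

#' Rebuild a symmetric matrix from its lower-triangle vector
#'
#' @param v Numeric vector of length `n * (n - 1) / 2`.
#' @param diag Value placed on the diagonal (default 0; connectivity
#'   analyses here never use the self-pair).
#' @return Symmetric `n x n` matrix.
#' @export
devectorize_lower_triangle <- function(v, diag = 0) {
  p <- length(v)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(n - round(n)) > 1e-9) stop("length of `v` is not a triangular number")
  n <- as.integer(round(n))
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- v
  M <- M + t(M)
  base::diag(M) <- diag
  M
}

#' Static functional connectivity
#'
#' Pairwise Pearson correlations across all timepoints, Fisher-Z
#' transformed and vectorized in lower-triangle order.
#'
#' @param ts A [component_timecourses()] object, or a plain components x
#'   timepoints numeric matrix.
#' @return Fisher-Z FC vector (length `n_comp * (n_comp - 1) / 2`) with a
#'   `"pair_index"` attribute.
#' @export
static_fc <- function(ts) {
  X <- timecourse_matrix(ts)
  if (ncol(X) < 3) stop("need at least 3 timepoints")
  v <- apply(X, 1, var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- rownames(X)[v <= 0 | !is.finite(v)]
    if (is.null(bad)) bad <- which(v <= 0 | !is.finite(v))
    stop("zero-variance component(s): ", paste(bad, collapse = ", "))
  }
  R <- cor(t(X))
  fz <- fisher_z_matrix(R)
  vectorize_lower_triangle(fz)
}

# fisher_z on a full correlation matrix, keeping symmetry exactly
fisher_z_matrix <- function(R) {
  r_max <- 1 - 1e-7
  Z <- atanh(pmin(pmax(R, -r_max), r_max))
  diag(Z) <- 0
  (Z + t(Z)) / 2
}

#' Sliding-window dynamic functional connectivity
#'
#' Window `m` (0-based) covers TRs `[m*s, m*s + w)` (0-based, half-open).
#' Within each window, pairwise Pearson correlations (optionally weighted by
#' a Gaussian-convolved rectangular taper) are Fisher-Z transformed and
#' vectorized in lower-triangle order.
#'
#' @param ts A [component_timecourses()] object or components x timepoints
#'   matrix.
#' @param w Window length in TR (default 22).
#' @param s Slide length in TR (default 1).
#' @param taper `"none"` (rectangular, default) or `"gaussian"`
#'   (rectangle convolved with a Gaussian of `sigma` TR).
#' @param sigma Gaussian taper width in TR (default 3), used only when
#'   `taper = "gaussian"`.
#' @return An object of class `windowed_fc`: a list with `values`
#'   (windows x n_pairs matrix of Fisher-Z values), `window_start_TR`
#'   (0-based inclusive starts), `window_length`, `slide`, `pair_index`,
#'   and `participant_id`.
#' @export
sliding_window_fc <- function(ts, w = 22L, s = 1L, taper = c("none", "gaussian"),
                              sigma = 3) {
  taper <- match.arg(taper)
  X <- timecourse_matrix(ts)
  T_len <- ncol(X)
  w <- as.integer(w); s <- as.integer(s)
  if (w < 3) stop("window length must be at least 3 TR")
  if (w > T_len) stop("window length w = ", w, " exceeds T = ", T_len)
  if (s < 1) stop("slide length must be >= 1")
  n_win <- (T_len - w) %/% s + 1L
  weights <- if (taper == "gaussian") taper_weights(w, sigma) else rep(1, w)
  n <- nrow(X)
  npair <- n * (n - 1L) / 2L
  out <- matrix(NA_real_, n_win, npair)
  lower <- lower.tri(diag(n))
  for (m in seq_len(n_win)) {
    cols <- ((m - 1L) * s + 1L):((m - 1L) * s + w)
    R <- weighted_cor(t(X[, cols, drop = FALSE]), weights)
    out[m, ] <- fisher_z_matrix(R)[lower]
  }
  structure(
    list(values = out,
         window_start_TR = (seq_len(n_win) - 1L) * s,
         window_length = w, slide = s,
         pair_index = pair_index(n),
         participant_id = attr(ts, "participant_id") %||%
           (if (is.list(ts)) ts$participant_id else NULL)),
    class = "windowed_fc")
}

# rectangular window convolved with a gaussian, as in the sliding-window
# dFC literature; returned weights are positive and length w
taper_weights <- function(w, sigma) {
  half <- ceiling(3 * sigma)
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  rect <- rep(1, w)
  full <- stats::convolve(c(rep(0, half), rect, rep(0, half)), rev(g),
                          type = "open")
  centre <- (length(full) - w) %/% 2
  wts <- full[(centre + 1):(centre + w)]
  wts / max(wts)
}

# weighted Pearson correlation of columns of Y (rows = observations)
weighted_cor <- function(Y, wts) {
  wts <- wts / sum(wts)
  mu <- colSums(Y * wts)
  Yc <- sweep(Y, 2, mu)
  C <- crossprod(Yc * sqrt(wts))
  d <- sqrt(diag(C))
  if (any(d <= 0)) stop("zero-variance component within a window")
  R <- C / tcrossprod(d)
  R[R > 1] <- 1; R[R < -1] <- -1
  R
}

`%||%` <- function(a, b) if (is.null(a)) b else a
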