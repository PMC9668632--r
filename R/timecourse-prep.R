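#' Component time-course container
#'
#' Holds one participant's ICA component time-courses: a components x
#' timepoints matrix together with the sampling interval (TR) and labels.
#'
#' @param values Numeric matrix, components x timepoints.
#' @param TR Sampling interval in seconds (default 2.25).
#' @param component_ids Component labels; default `comp1..compN`.
#' @param participant_id Participant label.
#' @return An object of class `component_timecourses`.
#' @export
component_timecourses <- function(values, TR = 2.25,
                                  component_ids = NULL,
                                  participant_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (components x timepoints)")
  }
  if (!all(is.finite(values))) stop("`values` contains non-finite entries")
  if (TR <= 0) stop("TR must be positive")
  if (is.null(component_ids)) component_ids <- paste0("comp", seq_len(nrow(values)))
  if (length(component_ids) != nrow(values)) {
    stop("component_ids length must match the number of rows")
  }
  rownames(values) <- component_ids
  structure(list(values = values, TR = TR,
                 component_ids = component_ids,
                 participant_id = participant_id),
            class = "component_timecourses")
}

#' @export
print.component_timecourses <- function(x, ...) {
  cat(sprintf("component_timecourses: %d components x %d TR (TR = %g s)%s\n",
              nrow(x$values), ncol(x$values), x$TR,
              if (!is.null(x$participant_id)) paste0(" [", x$participant_id, "]") else ""))
  invisible(x)
}

# accept either the container or a bare matrix everywhere downstream
timecourse_matrix <- function(ts) {
  if (inherits(ts, "component_timecourses")) return(ts$values)
  if (is.matrix(ts) && is.numeric(ts)) return(ts)
  stop("expected a component_timecourses object or a numeric matrix")
}

replace_values <- function(ts, values) {
  if (inherits(ts, "component_timecourses")) {
    ts$values <- values
    ts
  } else {
    values
  }
}

#' Remove per-component linear trends
#'
#' Projects each component's series onto the orthogonal complement of
#' (intercept, time), removing offset and linear drift.
#'
#' @param ts A [component_timecourses()] object or matrix.
#' @return Object of the same type with detrended values (mean ~ 0 per
#'   component).
#' @export
detrend <- function(ts) {
  X <- timecourse_matrix(ts)
  T_len <- ncol(X)
  if (T_len < 3) stop("need at least 3 timepoints to detrend")
  B <- cbind(1, seq_len(T_len))
  # residual-maker applied to all components at once
  fit <- t(lm.fit(B, t(X))$residuals)
  dimnames(fit) <- dimnames(X)
  replace_values(ts, fit)
}

#' Winsorize transient spikes (MAD despiking)
#'
#' Samples farther than `c` robust standard deviations (1.4826 * MAD) from
#' the per-component median are clipped to the threshold. Components with
#' zero MAD (constant or near-constant) are returned unchanged.
#'
#' @param ts A [component_timecourses()] object or matrix.
#' @param c MAD multiplier, > 0 (default 4).
#' @return Object of the same type with despiked values.
#' @export
despike <- function(ts, c = 4) {
  if (c <= 0) stop("`c` must be positive")
  X <- timecourse_matrix(ts)
  out <- X
  for (i in seq_len(nrow(X))) {
    med <- median(X[i, ])
    rsd <- 1.4826 * median(abs(X[i, ] - med))
    if (rsd == 0) next
    lo <- med - c * rsd
    hi <- med + c * rsd
    out[i, ] <- pmin(pmax(X[i, ], lo), hi)
  }
  replace_values(ts, out)
}

#' Zero-phase band-pass filtering
#'
#' Butterworth band-pass (order 4 per direction) applied forward-backward
#' for zero phase shift, with reflection padding at the edges to suppress
#' filter transients.
#'
#' @param ts A [component_timecourses()] object (TR taken from the object)
#'   or a matrix, in which case `TR` must be supplied.
#' @param f_lo Lower pass-band edge in Hz (default 0.01).
#' @param f_hi Upper pass-band edge in Hz (default 0.15); must be below the
#'   Nyquist frequency `1 / (2 TR)`.
#' @param TR Sampling interval in seconds (only needed for bare matrices).
#' @param pad Reflection padding length in TR (default 22, one window
#'   length).
#' @return Object of the same type with filtered values.
#' @export
bandpass <- function(ts, f_lo = 0.01, f_hi = 0.15, TR = NULL, pad = 22L) {
  X <- timecourse_matrix(ts)
  if (inherits(ts, "component_timecourses")) TR <- ts$TR
  if (is.null(TR)) stop("TR required when filtering a bare matrix")
  nyq <- 1 / (2 * TR)
  if (!(f_lo >= 0 && f_lo < f_hi)) stop("need 0 <= f_lo < f_hi")
  if (f_hi >= nyq) {
    stop(sprintf("f_hi = %g Hz is at or above Nyquist (%.4g Hz at TR = %g s)",
                 f_hi, nyq, TR))
  }
  T_len <- ncol(X)
  pad <- min(as.integer(pad), T_len - 1L)
  flt <- signal::butter(4, c(max(f_lo, 1e-6), f_hi) / nyq, type = "pass")
  out <- X
  for (i in seq_len(nrow(X))) {
    # DC lies below the pass band: demean first so a constant input maps
    # to exactly zero rather than to an edge-transient residual
    y <- X[i, ] - mean(X[i, ])
    ypad <- c(rev(y[2:(pad + 1)]), y, rev(y[(T_len - pad):(T_len - 1)]))
    yf <- signal::filtfilt(flt, ypad)
    out[i, ] <- yf[(pad + 1):(pad + T_len)]
  }
  replace_values(ts, out)
}

#' Regress confound time series out of each component
#'
#' Least-squares regression of each component on the confound columns plus
#' an intercept; returns residuals, which are orthogonal to every confound
#' column. Rank-deficient confound sets are reduced by dropping linearly
#' dependent columns with a warning.
#'
#' @param ts A [component_timecourses()] object or matrix.
#' @param confounds Numeric matrix, timepoints x q.
#' @return Object of the same type containing the residual series.
#' @export
regress_confounds <- function(ts, confounds) {
  X <- timecourse_matrix(ts)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(X)) {
    stop("confound rows (", nrow(confounds), ") must match timepoints (",
         ncol(X), ")")
  }
  B <- cbind(intercept = 1, confounds)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    keep <- qrB$pivot[seq_len(qrB$rank)]
    warning("dropping ", ncol(B) - qrB$rank,
            " linearly dependent confound column(s)")
    B <- B[, sort(keep), drop = FALSE]
  }
  res <- t(lm.fit(B, t(X))$residuals)
  dimnames(res) <- dimnames(X)
  replace_values(ts, res)
}

#' Full nuisance-processing pipeline for component time-courses
#'
#' Applies, in order: despiking, detrending, confound regression (if
#' confounds are given), and band-pass filtering. The order is fixed and
#' recorded in the returned attribute `"prep_steps"`.
#'
#' @param ts A [component_timecourses()] object.
#' @param confounds Optional timepoints x q confound matrix.
#' @param despike_c MAD multiplier for despiking (default 4).
#' @param band Pass band in Hz (default `c(0.01, 0.15)`).
#' @return Processed [component_timecourses()] object.
#' @export
prep_timecourses <- function(ts, confounds = NULL, despike_c = 4,
                             band = c(0.01, 0.15)) {
  steps <- c("despike", "detrend")
  ts <- despike(ts, c = despike_c)
  ts <- detrend(ts)
  if (!is.null(confounds)) {
    ts <- regress_confounds(ts, confounds)
    steps <- c(steps, "regress_confounds")
  }
  ts <- bandpass(ts, f_lo = band[1], f_hi = band[2])
  steps <- c(steps, "bandpass")
  attr(ts, "prep_steps") <- steps
  ts
}
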