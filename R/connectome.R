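# Connectome construction: Pearson correlation matrices, Fisher z-transform,
# edge vectorization, the cohort edge matrix D, the multi-subject matrix, and
# node-level fALFF.

#' Pearson correlation matrix of ROI time series
#'
#' Computes the node-by-node Pearson correlation matrix of a multivariate
#' time series, optionally after band-pass filtering each node's series.
#'
#' @param ts Numeric matrix, nodes as rows and time points as columns.
#' @param bandpass Logical; if `TRUE`, each node series is filtered with a
#'   forward-backward Butterworth band-pass (0.01-0.1 Hz) before
#'   correlation. Requires `tr_seconds`.
#' @param tr_seconds Sampling interval in seconds (repetition time). Only
#'   used when `bandpass = TRUE`.
#' @param band Length-2 numeric, pass-band in Hz. Default `c(0.01, 0.1)`.
#' @param butter_order Butterworth filter order (default 4).
#' @return Symmetric numeric matrix with unit diagonal and entries in
#'   \[-1, 1\]; row/column names follow `rownames(ts)`.
#' @export
correlation_matrix <- function(ts, bandpass = FALSE, tr_seconds = NULL,
                               band = c(0.01, 0.1), butter_order = 4) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need at least 3 time points")
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(rownames(ts))) rownames(ts)[bad[1L]] else bad[1L]
    stop("constant time series for node ", nm)
  }
  if (bandpass) {
    if (is.null(tr_seconds)) stop("tr_seconds required for band-pass filtering")
    ts <- t(apply(ts, 1L, bandpass_series, tr_seconds = tr_seconds,
                  band = band, butter_order = butter_order))
  }
  r <- stats::cor(t(ts))
  # guard against accumulation slightly past +/-1
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Forward-backward Butterworth band-pass filter for one series
#'
#' @param x Numeric vector.
#' @param tr_seconds Sampling interval in seconds.
#' @param band Pass-band in Hz.
#' @param butter_order Filter order.
#' @return Filtered numeric vector of the same length.
#' @export
bandpass_series <- function(x, tr_seconds, band = c(0.01, 0.1),
                            butter_order = 4) {
  fs <- 1 / tr_seconds
  ny <- fs / 2
  if (band[2L] >= ny) stop("upper band edge must lie below Nyquist")
  bf <- signal::butter(butter_order, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Fisher z-transform of correlation coefficients
#'
#' Applies z = atanh(r) = 0.5 log((1 + r)/(1 - r)) elementwise.
#' Correlations with |r| = 1 are clipped to 1 - 1e-7 in magnitude so the
#' transform stays finite.
#'
#' @param r Numeric vector or matrix of correlations, |r| <= 1.
#' @return Object of the same shape with z-scores.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  clip <- 1 - 1e-7
  z <- atanh(sign(r) * pmin(abs(r), clip))
  z
}

#' Inverse Fisher transform
#' @param z Numeric vector or matrix of z-scores.
#' @return Correlations tanh(z).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Convert a symmetric matrix to its canonical edge vector
#'
#' The canonical edge ordering is row-major over node pairs (i, j) with
#' i < j, i.e. (1,2), (1,3), ..., (1,p), (2,3), ..., (p-1,p).
#'
#' @param M Symmetric numeric matrix (p x p).
#' @return Numeric vector of length p(p-1)/2 holding the upper triangle.
#' @export
vectorize_matrix <- function(M) {
  M <- as.matrix(M)
  p <- nrow(M)
  if (ncol(M) != p) stop("matrix must be square")
  t(M)[lower.tri(t(M))]  # row-major upper triangle
}

#' Canonical edge index for p nodes
#'
#' @param p Node count.
#' @return Two-column integer matrix (`i`, `j`) with i < j, in canonical
#'   (row-major upper-triangle) order.
#' @export
edge_index <- function(p) {
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p))
  cbind(i = i, j = as.integer(j))
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' @param v Edge vector of length p(p-1)/2.
#' @param node_count Number of nodes p; inferred from `length(v)` if `NULL`.
#' @param diag Value placed on the diagonal (default 1, the package's
#'   connectivity-matrix convention).
#' @return Symmetric p x p matrix.
#' @export
devectorize_matrix <- function(v, node_count = NULL, diag = 1) {
  m <- length(v)
  p <- if (is.null(node_count)) (1 + sqrt(1 + 8 * m)) / 2 else node_count
  if (p != round(p) || p * (p - 1) / 2 != m)
    stop("vector length ", m, " is not a triangular number for ", p, " nodes")
  p <- as.integer(round(p))
  M <- matrix(0, p, p)
  M[lower.tri(M)] <- v   # fills column-major lower tri == row-major upper tri
  M <- M + t(M)
  base::diag(M) <- diag
  M
}

#' One subject's Fisher-z connectivity matrix
#'
#' @inheritParams correlation_matrix
#' @return Symmetric matrix of Fisher-z values with unit diagonal.
#' @export
connectivity_matrix <- function(ts, bandpass = FALSE, tr_seconds = NULL,
                                band = c(0.01, 0.1), butter_order = 4) {
  r <- correlation_matrix(ts, bandpass = bandpass, tr_seconds = tr_seconds,
                          band = band, butter_order = butter_order)
  z <- fisher_z(r)
  diag(z) <- 1
  z
}

#' Build the cohort edge matrix D
#'
#' Stacks each subject's vectorized Fisher-z upper triangle as one column,
#' giving the m-edges x n-subjects matrix on which the component analysis
#' operates.
#'
#' @param cohort A `subject_cohort` (see [generate_cohort()]) or a plain
#'   list of node x time matrices sharing node order.
#' @param bandpass,band,butter_order Passed to [correlation_matrix()].
#' @return A list of class `cohort_edge_matrix` with elements `values`
#'   (m x n matrix), `edge_index` (two-column matrix of node pairs) and
#'   `subject_ids`.
#' @export
build_cohort_matrix <- function(cohort, bandpass = FALSE,
                                band = c(0.01, 0.1), butter_order = 4) {
  ts_list <- cohort_series(cohort)
  tr <- cohort_tr(cohort)
  p <- nrow(ts_list[[1L]])
  if (!all(vapply(ts_list, nrow, 0L) == p))
    stop("all subjects must share the same node set")
  cols <- lapply(ts_list, function(ts) {
    vectorize_matrix(connectivity_matrix(ts, bandpass = bandpass,
                                         tr_seconds = tr, band = band,
                                         butter_order = butter_order))
  })
  values <- do.call(cbind, cols)
  ids <- names(ts_list)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_along(ts_list))
  colnames(values) <- ids
  structure(list(values = values, edge_index = edge_index(p),
                 subject_ids = ids, n_nodes = p),
            class = "cohort_edge_matrix")
}

# internal accessors tolerating either a subject_cohort or a bare list
cohort_series <- function(cohort) {
  if (inherits(cohort, "subject_cohort")) cohort$time_series else cohort
}
cohort_tr <- function(cohort) {
  if (inherits(cohort, "subject_cohort")) cohort$tr_seconds else NULL
}

#' Multi-subject connectivity matrix
#'
#' Correlates node series over the concatenation of all subjects' time
#' axes (each subject's series z-scored per node first, so subjects with
#' different variances contribute equally), then Fisher-z transforms the
#' off-diagonal. This is the cohort's intrinsic connectivity template.
#'
#' @param cohort A `subject_cohort` or list of node x time matrices.
#' @return Symmetric Fisher-z matrix with unit diagonal.
#' @export
multi_subject_matrix <- function(cohort) {
  ts_list <- cohort_series(cohort)
  std <- lapply(ts_list, function(ts) {
    sds <- apply(ts, 1L, stats::sd)
    if (any(sds == 0)) stop("constant node series in multi-subject matrix")
    (ts - rowMeans(ts)) / sds
  })
  big <- do.call(cbind, std)
  r <- stats::cor(t(big))
  r[r > 1] <- 1; r[r < -1] <- -1
  z <- fisher_z(r)
  diag(z) <- 1
  (z + t(z)) / 2
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' For each node, the ratio of the amplitude spectrum summed over the
#' low-frequency band (0.01-0.1 Hz) to the sum over the full band of
#' interest (0.01-0.25 Hz), after linear detrending. A frequency bin
#' belongs to a band when its center frequency lies in the closed
#' interval.
#'
#' @param ts Numeric matrix, nodes x time, or a numeric vector (one node).
#' @param tr_seconds Sampling interval in seconds; 0.25 Hz must not exceed
#'   the Nyquist frequency 1/(2 tr).
#' @param low Low band in Hz, default `c(0.01, 0.1)`.
#' @param total Total band in Hz, default `c(0.01, 0.25)`.
#' @param spectrum `"amplitude"` (default) sums the modulus of the FFT;
#'   `"power"` sums its square.
#' @return Numeric vector of per-node fALFF values in \[0, 1\].
#' @export
compute_falff <- function(ts, tr_seconds, low = c(0.01, 0.1),
                          total = c(0.01, 0.25),
                          spectrum = c("amplitude", "power")) {
  spectrum <- match.arg(spectrum)
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1L)
  n <- ncol(ts)
  if (n < 64L) stop("time series too short for spectral estimation (need >= 64)")
  ny <- 1 / (2 * tr_seconds)
  if (total[2L] > ny + 1e-12)
    stop("total band upper edge ", total[2L], " Hz exceeds Nyquist ",
         signif(ny, 4), " Hz")
  freqs <- falff_freqs(n, tr_seconds)
  in_low <- freqs >= low[1L] & freqs <= low[2L]
  in_tot <- freqs >= total[1L] & freqs <= total[2L]
  if (!any(in_tot)) stop("no frequency bins in the total band")
  tt <- seq_len(n)
  apply(ts, 1L, function(x) {
    x <- stats::lm.fit(cbind(1, tt), x)$residuals  # linear detrend
    amp <- Mod(stats::fft(x))[seq_along(freqs)]
    if (spectrum == "power") amp <- amp^2
    sum(amp[in_low]) / sum(amp[in_tot])
  })
}

# positive FFT bin center frequencies for an n-point series
falff_freqs <- function(n, tr_seconds) {
  k <- seq_len(floor(n / 2))
  k / (n * tr_seconds)
}
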