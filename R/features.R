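# The nine feature subtypes computed per subject from preprocessed time
# series: FC, regional mean/SD/MSSD/fALFF, and the graph-signal-processing
# features (graph PSD, SDI, coupled and decoupled FC) defined on the
# connectome harmonics of the training set's consensus SC.

#' Names of the nine feature subtypes
#' @export
FEATURE_NAMES <- c("fc", "regional_mean", "regional_sd", "mssd", "falff",
                   "graph_psd", "sdi", "coupled_fc", "decoupled_fc")

#' Functional connectivity (vectorized Pearson correlations)
#'
#' Pearson correlation between every pair of regional time series; the strict
#' upper triangle is vectorized row-major (pairs (1,2), (1,3), ...,
#' (R-1,R)), giving R(R-1)/2 entries in [-1, 1]. R = 274 gives 37401.
#'
#' @param ts region x frame matrix with at least 3 frames.
#' @return numeric vector of length R(R-1)/2.
#' @export
fc <- function(ts) {
  assert_that(is.matrix(ts) && ncol(ts) >= 3, "need at least 3 frames")
  v <- apply(ts, 1, stats::sd)
  # numerically-zero variance (e.g. a filtered-out band) is zero variance
  assert_that(all(v > 1e-10 * max(1, max(v))),
              "zero-variance region: correlation undefined")
  upper_tri_vec(stats::cor(t(ts)))
}

#' Regional mean signal
#' @param ts region x frame matrix with at least 2 frames.
#' @return numeric vector of length R.
#' @export
regional_mean <- function(ts) {
  assert_that(is.matrix(ts) && ncol(ts) >= 2, "need at least 2 frames")
  rowMeans(ts)
}

#' Regional signal standard deviation (sample SD, denominator N - 1)
#' @inheritParams regional_mean
#' @return numeric vector of length R.
#' @export
regional_sd <- function(ts) {
  assert_that(is.matrix(ts) && ncol(ts) >= 2, "need at least 2 frames")
  apply(ts, 1, stats::sd)
}

#' Mean squared successive difference (BOLD variability)
#'
#' MSSD = (1/(N-1)) * sum over i of (x[i+1] - x[i])^2, the moment-to-moment
#' change of the signal, computed per region.
#'
#' @inheritParams regional_mean
#' @return nonnegative numeric vector of length R.
#' @export
mssd <- function(ts) {
  assert_that(is.matrix(ts) && ncol(ts) >= 2, "need at least 2 frames")
  d <- ts[, -1, drop = FALSE] - ts[, -ncol(ts), drop = FALSE]
  rowSums(d^2) / (ncol(ts) - 1)
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Ratio of the amplitude spectrum summed over the low-frequency band
#' (default 0.01-0.08 Hz, endpoints inclusive) to the amplitude summed over
#' all positive frequencies (DC excluded), per region, from a plain
#' untapered periodogram. Values lie in [0, 1].
#'
#' @param ts region x frame matrix.
#' @param tr_seconds sampling interval in seconds.
#' @param band numeric length-2 vector, band limits in Hz.
#' @return numeric vector of length R in [0, 1].
#' @export
falff <- function(ts, tr_seconds, band = c(0.01, 0.08)) {
  assert_that(is.matrix(ts) && ncol(ts) >= 8, "too few frames for a spectrum")
  nyq <- 1 / (2 * tr_seconds)
  assert_that(band[1] > 0 && band[2] < nyq && band[1] < band[2],
              "band must lie inside (0, Nyquist)")
  n <- ncol(ts)
  freqs <- (seq_len(floor(n / 2))) / (n * tr_seconds)
  amp <- abs(stats::mvfft(t(ts)))[1 + seq_len(floor(n / 2)), , drop = FALSE]
  in_band <- freqs >= band[1] & freqs <= band[2]
  num <- colSums(amp[in_band, , drop = FALSE])
  den <- colSums(amp)
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Graph Fourier transform of a regional time series
#'
#' Projects each frame onto the connectome harmonics: coefficients
#' xhat = U' x. Energy per frame is conserved (Parseval).
#'
#' @param ts region x frame matrix.
#' @param basis a [harmonic_basis()] with matching region count.
#' @return object of class `graph_signal` holding the harmonic x frame
#'   coefficient matrix and the basis.
#' @export
gft <- function(ts, basis) {
  assert_that(inherits(basis, "harmonic_basis"), "basis must be a harmonic_basis")
  assert_that(is.matrix(ts) && nrow(ts) == nrow(basis$eigenvectors),
              "region count must match the basis")
  structure(list(coefficients = crossprod(basis$eigenvectors, ts),
                 basis = basis),
            class = "graph_signal")
}

#' Inverse graph Fourier transform
#' @param gs a `graph_signal`.
#' @param basis optional basis override (defaults to the one stored in `gs`).
#' @return region x frame matrix.
#' @export
igft <- function(gs, basis = NULL) {
  assert_that(inherits(gs, "graph_signal"), "gs must be a graph_signal")
  if (is.null(basis)) basis <- gs$basis
  basis$eigenvectors %*% gs$coefficients
}

#' Graph power spectral density
#'
#' Per harmonic k, the l2 norm over frames of its coefficient series:
#' PSD_k = sqrt(sum over t of xhat_k(t)^2). With this definition the summed
#' squared PSD equals the total signal energy (Parseval over time), the
#' identity the test suite leans on.
#'
#' @param gs a `graph_signal` with at least one frame.
#' @return nonnegative numeric vector of length R.
#' @export
graph_psd <- function(gs) {
  assert_that(inherits(gs, "graph_signal"), "gs must be a graph_signal")
  assert_that(ncol(gs$coefficients) >= 1, "graph signal has no frames")
  sqrt(rowSums(gs$coefficients^2))
}

#' Graph filter specification
#'
#' `mode = "low"` keeps harmonic indices below `cutoff_index` (1-based:
#' harmonics 1..cutoff), `mode = "high"` keeps the rest. The default cutoff
#' floor(R/2) splits the spectrum in half; for R = 274 the low band is
#' harmonics 1..137.
#'
#' @param cutoff_index number of harmonics in the low band.
#' @param mode `"low"` or `"high"`.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_index, mode = c("low", "high")) {
  mode <- match.arg(mode)
  assert_that(is_count(cutoff_index), "cutoff_index must be a positive count")
  structure(list(cutoff_index = as.integer(cutoff_index), mode = mode),
            class = "filter_spec")
}

#' Graph-domain band filter
#'
#' Transforms to the graph domain, zeroes the complementary band, and
#' transforms back. Low- and high-pass parts sum to the original signal for
#' any cutoff.
#'
#' @param ts region x frame matrix.
#' @param basis a [harmonic_basis()].
#' @param spec a [filter_spec()]; `cutoff_index` may equal R (identity
#'   low-pass), but must be at least 1 and at most R.
#' @return filtered region x frame matrix.
#' @export
graph_filter <- function(ts, basis, spec) {
  assert_that(inherits(spec, "filter_spec"), "spec must be a filter_spec")
  R <- nrow(basis$eigenvectors)
  assert_that(spec$cutoff_index >= 1 && spec$cutoff_index <= R,
              "cutoff_index out of range")
  gs <- gft(ts, basis)
  keep <- if (spec$mode == "low") {
    seq_len(spec$cutoff_index)
  } else {
    setdiff(seq_len(R), seq_len(spec$cutoff_index))
  }
  coef <- matrix(0, R, ncol(gs$coefficients))
  coef[keep, ] <- gs$coefficients[keep, , drop = FALSE]
  basis$eigenvectors %*% coef
}

default_cutoff <- function(R) max(1L, as.integer(floor(R / 2)))

#' Coupled functional connectivity
#'
#' FC of the low-pass graph-filtered signal (cutoff floor(R/2)): correlations
#' among the spatial patterns aligned with (coupled to) the structural
#' connectome.
#'
#' @param ts region x frame matrix.
#' @param basis a [harmonic_basis()].
#' @param cutoff_index low-band size; default floor(R/2).
#' @return numeric vector of length R(R-1)/2.
#' @export
coupled_fc <- function(ts, basis, cutoff_index = NULL) {
  R <- nrow(basis$eigenvectors)
  if (is.null(cutoff_index)) cutoff_index <- default_cutoff(R)
  fc(graph_filter(ts, basis, filter_spec(cutoff_index, "low")))
}

#' Decoupled functional connectivity
#'
#' FC of the high-pass graph-filtered signal: correlations among patterns
#' decoupled from the structural connectome.
#'
#' @inheritParams coupled_fc
#' @return numeric vector of length R(R-1)/2.
#' @export
decoupled_fc <- function(ts, basis, cutoff_index = NULL) {
  R <- nrow(basis$eigenvectors)
  if (is.null(cutoff_index)) cutoff_index <- default_cutoff(R)
  fc(graph_filter(ts, basis, filter_spec(cutoff_index, "high")))
}

#' Structural decoupling index
#'
#' Per region, the ratio of the temporal l2 norm of the high-pass
#' graph-filtered signal to that of the low-pass signal (cutoff floor(R/2)).
#' 0 means the region's signal is entirely coupled to the connectome; larger
#' values mean more decoupled activity. No log transform is applied.
#'
#' @inheritParams coupled_fc
#' @return nonnegative numeric vector of length R.
#' @export
sdi <- function(ts, basis, cutoff_index = NULL) {
  R <- nrow(basis$eigenvectors)
  if (is.null(cutoff_index)) cutoff_index <- default_cutoff(R)
  lo <- graph_filter(ts, basis, filter_spec(cutoff_index, "low"))
  hi <- graph_filter(ts, basis, filter_spec(cutoff_index, "high"))
  lo_norm <- sqrt(rowSums(lo^2))
  assert_that(all(lo_norm > 0), "zero low-pass norm in a region: SDI undefined")
  sqrt(rowSums(hi^2)) / lo_norm
}

# Concatenate a subject's (preprocessed) sessions along time, optionally
# truncated to a session amount (see truncate_scan).
subject_timeseries <- function(subject, session_amount = NULL) {
  if (is.null(session_amount)) {
    do.call(cbind, subject$sessions)
  } else {
    truncate_scan(subject$sessions, session_amount)
  }
}

compute_feature <- function(ts, feature_name, basis, tr_seconds) {
  switch(feature_name,
    fc = fc(ts),
    regional_mean = regional_mean(ts),
    regional_sd = regional_sd(ts),
    mssd = mssd(ts),
    falff = falff(ts, tr_seconds),
    graph_psd = graph_psd(gft(ts, basis)),
    sdi = sdi(ts, basis),
    coupled_fc = coupled_fc(ts, basis),
    decoupled_fc = decoupled_fc(ts, basis),
    stop("unknown feature: ", feature_name, call. = FALSE))
}

needs_basis <- function(feature_name) {
  feature_name %in% c("graph_psd", "sdi", "coupled_fc", "decoupled_fc")
}

#' Assemble the subject x dimension feature matrix for one feature subtype
#'
#' Sessions are concatenated along time (after per-session preprocessing by
#' the caller), then one feature vector is computed per subject. Row order
#' follows cohort order; FC-family features have dimension R(R-1)/2, regional
#' and graph-spectral features dimension R.
#'
#' @param cohort list of (preprocessed) subject records.
#' @param feature_name one of [FEATURE_NAMES].
#' @param basis a [harmonic_basis()]; required for graph-signal features.
#' @param tr_seconds sampling interval (needed by fALFF).
#' @param session_amount optional scan-time truncation passed to
#'   [truncate_scan()] (NULL = use all sessions).
#' @return list of class `feature_matrix` with `values` (subject x dim
#'   matrix, rownames = subject IDs), `feature_name`, and `dim`.
#' @export
build_feature_matrix <- function(cohort, feature_name, basis = NULL,
                                 tr_seconds = 0.72, session_amount = NULL) {
  assert_that(feature_name %in% FEATURE_NAMES,
              paste("unknown feature:", feature_name))
  if (needs_basis(feature_name)) {
    assert_that(inherits(basis, "harmonic_basis"),
                paste(feature_name, "requires a harmonic basis"))
  }
  rows <- lapply(cohort, function(s) {
    compute_feature(subject_timeseries(s, session_amount), feature_name,
                    basis, tr_seconds)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort, `[[`, character(1), "subject_id")
  assert_that(!anyNA(X), "feature matrix contains missing values")
  structure(list(values = X, feature_name = feature_name, dim = ncol(X)),
            class = "feature_matrix")
}
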