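# Parcel-level denoising chain: initial-frame discard, confound regression
# with detrending, and zero-phase temporal high-pass filtering. The pipeline
# order is fixed: discard -> confound regression -> high-pass.

#' Preprocessing configuration
#'
#' @param n_discard number of initial frames to drop per session (default 6,
#'   removing scanner-drift frames at session start).
#' @param highpass_hz high-pass cutoff in Hz (default 0.01).
#' @param motion include the motion regressors in the confound design.
#' @param motion_derivatives include their first-order backward differences.
#' @param linear_trend include an intercept + linear trend (detrending).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 6, highpass_hz = 0.01,
                              motion = TRUE, motion_derivatives = TRUE,
                              linear_trend = TRUE) {
  assert_that(is.numeric(n_discard) && n_discard >= 0 &&
                n_discard == as.integer(n_discard), "n_discard must be >= 0")
  assert_that(is.numeric(highpass_hz) && highpass_hz > 0,
              "highpass_hz must be positive")
  structure(list(n_discard = as.integer(n_discard), highpass_hz = highpass_hz,
                 motion = motion, motion_derivatives = motion_derivatives,
                 linear_trend = linear_trend),
            class = "preprocess_config")
}

#' Discard initial frames of a session
#'
#' @param ts region x frame matrix.
#' @param n_discard number of leading frames to drop; must be smaller than
#'   the frame count.
#' @return region x (frames - n_discard) matrix; remaining columns unchanged.
#' @export
discard_frames <- function(ts, n_discard) {
  assert_that(is.matrix(ts), "ts must be a matrix")
  assert_that(n_discard >= 0, "n_discard must be >= 0")
  assert_that(ncol(ts) > n_discard,
              "n_discard must leave at least one frame")
  if (n_discard == 0) return(ts)
  ts[, -seq_len(n_discard), drop = FALSE]
}

# Build the confound design matrix: intercept (+ linear trend), motion
# regressors, and their backward-difference derivatives (first element 0).
confound_design <- function(confounds, n_frames, config) {
  cols <- list()
  if (config$linear_trend) {
    cols$intercept <- rep(1, n_frames)
    cols$trend <- seq_len(n_frames) - (n_frames + 1) / 2
  } else {
    cols$intercept <- rep(1, n_frames)
  }
  if (config$motion && !is.null(confounds)) {
    assert_that(nrow(confounds) == n_frames,
                "confound frame count must match the time series")
    cols$motion <- confounds
    if (config$motion_derivatives) {
      d <- rbind(0, diff(confounds))
      cols$derivatives <- d
    }
  }
  X <- do.call(cbind, cols)
  dimnames(X) <- NULL
  X
}

#' Regress confounds (and optionally a linear trend) out of a time series
#'
#' Ordinary least squares per region against a design holding an intercept,
#' a linear trend, the supplied motion regressors, and their first-order
#' backward-difference derivatives (per the config flags). Residuals are
#' orthogonal to every design column.
#'
#' @param ts region x frame matrix.
#' @param confounds frame x k matrix of nuisance regressors (or NULL).
#' @param config a [preprocess_config()].
#' @return region x frame residual matrix.
#' @export
regress_confounds <- function(ts, confounds = NULL, config = preprocess_config()) {
  assert_that(is.matrix(ts), "ts must be a matrix")
  X <- confound_design(confounds, ncol(ts), config)
  qrX <- qr(X)
  assert_that(qrX$rank == ncol(X),
              "confound design matrix is rank deficient")
  # residual maker applied to all regions at once (regions are rows)
  t(stats::resid(stats::lm.fit(X, t(ts))))
}

#' Zero-phase temporal high-pass filter
#'
#' Order-2 Butterworth high-pass run forward and backward
#' ([signal::filtfilt()]), giving an order-4-equivalent magnitude response
#' with no phase distortion (phase distortion would corrupt
#' successive-difference statistics such as MSSD).
#'
#' @param ts region x frame matrix.
#' @param tr_seconds sampling interval in seconds.
#' @param cutoff_hz cutoff frequency; must be below Nyquist = 1/(2 tr).
#' @return filtered region x frame matrix.
#' @export
highpass <- function(ts, tr_seconds, cutoff_hz) {
  assert_that(is.matrix(ts), "ts must be a matrix")
  nyq <- 1 / (2 * tr_seconds)
  assert_that(cutoff_hz > 0 && cutoff_hz < nyq,
              "cutoff must lie strictly between 0 and Nyquist")
  bf <- signal::butter(2, cutoff_hz / nyq, type = "high")
  out <- t(apply(ts, 1, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- NULL
  out
}

#' Run the full denoising chain on one session
#'
#' Fixed order: frame discard, confound regression (including detrending),
#' high-pass filtering.
#'
#' @param ts region x frame matrix (raw session).
#' @param confounds frame x k confound matrix aligned with the raw session.
#' @param tr_seconds sampling interval in seconds.
#' @param config a [preprocess_config()].
#' @return region x (frames - n_discard) preprocessed matrix.
#' @export
preprocess_session <- function(ts, confounds, tr_seconds,
                               config = preprocess_config()) {
  ts <- discard_frames(ts, config$n_discard)
  conf <- confounds
  if (!is.null(conf) && config$n_discard > 0) {
    conf <- conf[-seq_len(config$n_discard), , drop = FALSE]
  }
  ts <- regress_confounds(ts, conf, config)
  highpass(ts, tr_seconds, config$highpass_hz)
}

#' Preprocess every session of one subject record
#'
#' @param subject a subject record (see [generate_cohort()]).
#' @param tr_seconds sampling interval in seconds.
#' @param config a [preprocess_config()].
#' @return the subject record with `sessions` replaced by their preprocessed
#'   versions and a `preprocessed = TRUE` flag.
#' @export
preprocess_subject <- function(subject, tr_seconds,
                               config = preprocess_config()) {
  subject$sessions <- lapply(seq_along(subject$sessions), function(k) {
    preprocess_session(subject$sessions[[k]], subject$confounds[[k]],
                       tr_seconds, config)
  })
  subject$preprocessed <- TRUE
  subject
}
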