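# Brute-force oracles: every closed-form feature is checked against an
# explicit double loop on random small inputs.

brute_fc <- function(ts) {
  R <- nrow(ts)
  out <- numeric(0)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    out <- c(out, cor(ts[i, ], ts[j, ]))
  }
  out
}

brute_mssd <- function(ts) {
  apply(ts, 1, function(x) {
    n <- length(x)
    acc <- 0
    for (i in seq_len(n - 1)) acc <- acc + (x[i + 1] - x[i])^2
    acc / (n - 1)
  })
}

brute_falff <- function(ts, tr, band = c(0.01, 0.08)) {
  n <- ncol(ts)
  apply(ts, 1, function(x) {
    amp <- Mod(fft(x))[2:(floor(n / 2) + 1)]
    f <- (1:floor(n / 2)) / (n * tr)
    sum(amp[f >= band[1] & f <= band[2]]) / sum(amp)
  })
}

test_that("FC vectorizes the strict upper triangle with the right length", {
  set.seed(7)
  ts <- matrix(rnorm(4 * 30), 4, 30)
  expect_equal(fc(ts), brute_fc(ts), tolerance = 1e-12)
  expect_length(fc(matrix(rnorm(274 * 5), 274, 5) + 0), 37401)
  ts2 <- rbind(ts, ts[1, ])  # region 5 duplicates region 1
  v <- fc(ts2)
  expect_equal(v[4], 1.0)  # pair (1,5) is the 4th row-major entry
  expect_true(all(v >= -1 & v <= 1))
  tsz <- ts; tsz[2, ] <- 3
  expect_error(fc(tsz), "zero-variance")
})

test_that("regional mean and SD match hand arithmetic and loop oracles", {
  const <- matrix(5, 3, 10)
  expect_equal(regional_mean(const), rep(5, 3))
  expect_equal(regional_sd(const), rep(0, 3))
  two <- matrix(c(0, 2), 1, 2)
  expect_equal(regional_mean(two), 1)
  expect_equal(regional_sd(two), sqrt(2))
  set.seed(8)
  ts <- matrix(rnorm(10 * 50), 10, 50)
  expect_equal(regional_mean(ts), apply(ts, 1, mean), tolerance = 1e-12)
  expect_equal(regional_sd(ts), apply(ts, 1, sd), tolerance = 1e-12)
  expect_error(regional_sd(matrix(1, 2, 1)), "2 frames")
})

test_that("MSSD matches its definition", {
  expect_equal(mssd(matrix(3, 2, 20)), c(0, 0))
  expect_equal(mssd(matrix(c(0, 2, 0, 2, 0), 1, 5)), 4)
  set.seed(9)
  ts <- matrix(rnorm(10 * 40), 10, 40)
  expect_equal(mssd(ts), brute_mssd(ts), tolerance = 1e-12)
  expect_true(all(mssd(ts) >= 0))
})

test_that("fALFF matches the periodogram oracle and spectral expectations", {
  tr <- 0.72
  # 1250 frames put 0.04 Hz and 0.3 Hz exactly on periodogram bins
  t <- (0:1249) * tr
  low <- matrix(sin(2 * pi * 0.04 * t), 1)
  high <- matrix(sin(2 * pi * 0.3 * t), 1)
  expect_gte(falff(low, tr), 0.95)
  expect_lte(falff(high, tr), 0.05)
  set.seed(10)
  ts <- matrix(rnorm(10 * 256), 10, 256)
  expect_equal(falff(ts, tr), brute_falff(ts, tr), tolerance = 1e-10)
  # white noise: expected ratio ~ band bins / total bins
  big <- matrix(rnorm(40 * 2048), 40, 2048)
  f <- (1:1024) / (2048 * tr)
  expected <- mean(f >= 0.01 & f <= 0.08)
  expect_lt(abs(mean(falff(big, tr)) - expected) / expected, 0.2)
  expect_error(falff(ts, tr, band = c(0.01, 1)), "Nyquist")
})

test_that("GFT round-trips, is orthonormal, and conserves energy", {
  b <- small_basis()
  set.seed(11)
  ts <- matrix(rnorm(12 * 25), 12, 25)
  gs <- gft(ts, b)
  expect_equal(igft(gs), ts, tolerance = 1e-8)
  # a single harmonic maps to an indicator coefficient vector
  xk <- matrix(b$eigenvectors[, 4], ncol = 1)
  ck <- gft(xk, b)$coefficients
  expect_equal(as.numeric(ck), replace(rep(0, 12), 4, 1), tolerance = 1e-8)
  # Parseval per frame
  expect_equal(colSums(gs$coefficients^2), colSums(ts^2), tolerance = 1e-8)
  expect_error(gft(matrix(0, 5, 3), b), "region count")
})

test_that("graph PSD is the temporal l2 norm per harmonic", {
  b <- small_basis()
  ones <- structure(list(coefficients = matrix(1, 12, 9), basis = b),
                    class = "graph_signal")
  expect_equal(graph_psd(ones), rep(3, 12))  # sqrt(9)
  only0 <- matrix(b$eigenvectors[, 1], 12, 5)
  psd <- graph_psd(gft(only0, b))
  expect_equal(psd[-1], rep(0, 11), tolerance = 1e-8)
  set.seed(12)
  ts <- matrix(rnorm(12 * 30), 12, 30)
  psd2 <- graph_psd(gft(ts, b))
  expect_equal(sum(psd2^2), sum(ts^2), tolerance = 1e-8)
})

test_that("graph filtering is complementary, idempotent, and projective", {
  b <- small_basis()
  set.seed(13)
  ts <- matrix(rnorm(12 * 20), 12, 20)
  lo <- graph_filter(ts, b, filter_spec(6, "low"))
  hi <- graph_filter(ts, b, filter_spec(6, "high"))
  expect_equal(lo + hi, ts, tolerance = 1e-8)
  expect_equal(graph_filter(lo, b, filter_spec(6, "low")), lo,
               tolerance = 1e-8)
  # independent oracle: per-frame projection onto the eigenvector subset
  P <- b$eigenvectors[, 1:6] %*% t(b$eigenvectors[, 1:6])
  expect_equal(lo, P %*% ts, tolerance = 1e-8)
  # signal already in the low band passes through untouched
  in_low <- b$eigenvectors[, 1:6] %*% matrix(rnorm(6 * 10), 6, 10)
  expect_equal(graph_filter(in_low, b, filter_spec(6, "low")), in_low,
               tolerance = 1e-8)
  expect_lt(max(abs(graph_filter(in_low, b, filter_spec(6, "high")))), 1e-8)
  expect_error(graph_filter(ts, b, filter_spec(13, "low")), "out of range")
})

test_that("coupled/decoupled FC and SDI follow the filter decomposition", {
  b <- small_basis()
  set.seed(14)
  ts <- matrix(rnorm(12 * 40), 12, 40)
  # degenerate cutoff R: low-pass is the identity, coupled FC equals FC
  expect_equal(coupled_fc(ts, b, cutoff_index = 12), fc(ts), tolerance = 1e-8)
  expect_length(coupled_fc(ts, b), 66)
  expect_length(decoupled_fc(ts, b), 66)
  # SDI against the projection oracle
  lo <- graph_filter(ts, b, filter_spec(6, "low"))
  hi <- graph_filter(ts, b, filter_spec(6, "high"))
  expect_equal(sdi(ts, b), sqrt(rowSums(hi^2)) / sqrt(rowSums(lo^2)),
               tolerance = 1e-8)
  # signal entirely in the low band: SDI 0 everywhere, decoupled FC errors
  in_low <- b$eigenvectors[, 1:6] %*% matrix(rnorm(6 * 10), 6, 10)
  expect_equal(sdi(in_low, b), rep(0, 12), tolerance = 1e-8)
  expect_error(decoupled_fc(in_low, b), "zero-variance")
})

test_that("feature matrices have the documented dimensions and row order", {
  co <- small_preprocessed()
  b <- small_basis()
  for (fe in c("regional_mean", "regional_sd", "mssd", "falff", "graph_psd",
               "sdi")) {
    fm <- build_feature_matrix(co, fe, basis = b)
    expect_identical(dim(fm$values), c(24L, 12L))
  }
  for (fe in c("fc", "coupled_fc", "decoupled_fc")) {
    fm <- build_feature_matrix(co, fe, basis = b)
    expect_identical(dim(fm$values), c(24L, 66L))
  }
  one <- build_feature_matrix(co[1], "mssd")
  expect_identical(dim(one$values), c(1L, 12L))
  # subject order only permutes rows
  fm1 <- build_feature_matrix(co, "regional_sd")
  fm2 <- build_feature_matrix(rev(co), "regional_sd")
  expect_equal(fm1$values, fm2$values[rev(seq_len(24)), ], tolerance = 1e-12)
  expect_error(build_feature_matrix(co, "graph_psd"), "harmonic basis")
  expect_error(build_feature_matrix(co, "nope"), "unknown feature")
})
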