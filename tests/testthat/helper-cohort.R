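# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small default cohort reused by several files: 24 subjects, 12 regions,
# 2 sessions of 60 frames.
small_cohort <- function() {
  cached("small_cohort", generate_cohort(small_config()))
}

small_config <- function(...) {
  args <- list(n_subjects = 24, n_regions = 12, n_sessions = 2,
               frames_per_session = 60, n_communities = 3, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

small_preprocessed <- function() {
  cached("small_preprocessed",
         lapply(small_cohort(), preprocess_subject, tr_seconds = 0.72))
}

small_basis <- function() {
  cached("small_basis", train_basis(small_cohort())$basis)
}

# A random connected weighted graph for basis tests.
random_sc <- function(R, seed = 1) {
  set.seed(seed)
  A <- matrix(0, R, R)
  A[upper.tri(A)] <- ifelse(runif(R * (R - 1) / 2) < 0.5,
                            abs(rnorm(R * (R - 1) / 2)), 0)
  A <- A + t(A)
  for (i in seq_len(R - 1)) if (A[i, i + 1] == 0) A[i, i + 1] <- A[i + 1, i] <- 0.5
  A
}
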