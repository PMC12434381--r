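test_that("family splits keep families whole and hit the target sizes", {
  ids <- sprintf("S%03d", 1:100)
  fam <- ids  # all singleton families
  sch <- make_family_splits(ids, fam, n_outer_splits = 10,
                            test_fraction = 0.15, seed = 3)
  for (sp in sch$splits) {
    expect_length(sp$test_ids, 15)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  }
  # mixed family sizes: no family straddles train and test
  set.seed(1)
  fam2 <- sprintf("F%02d", rep(1:30, length.out = 100)[sample(100)])
  sch2 <- make_family_splits(ids, fam2, seed = 4)
  for (sp in sch2$splits) {
    expect_length(intersect(fam2[match(sp$train_ids, ids)],
                            fam2[match(sp$test_ids, ids)]), 0)
    expect_gte(length(sp$test_ids), 15)
  }
  # deterministic given seed
  expect_identical(sch, make_family_splits(ids, fam, n_outer_splits = 10,
                                           test_fraction = 0.15, seed = 3))
  # degenerate cases
  expect_error(make_family_splits(ids, rep("F1", 100)), "nonempty")
  expect_error(make_family_splits(ids, fam, test_fraction = 1.5), "\\(0, 1\\)")
})

test_that("R-squared matches its definition including negative values", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(0, 0, 0)), -1.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero-variance")
})

test_that("a realizable linear target is recovered almost perfectly", {
  set.seed(20)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  tr <- 1:150
  expect_gte(fit_predict_one_split(X[tr, ], y[tr], X[-tr, ], y[-tr],
                                   model_spec("elasticnet_reg")), 0.99)
  expect_gte(fit_predict_one_split(X[tr, ], y[tr], X[-tr, ], y[-tr],
                                   model_spec("krr")), 0.99)
  # classifiers on a separable latent
  yb <- as.numeric(y > 0)
  expect_gte(fit_predict_one_split(X[tr, ], yb[tr], X[-tr, ], yb[-tr],
                                   model_spec("elasticnet_clf")), 0.9)
  expect_gte(fit_predict_one_split(X[tr, ], yb[tr], X[-tr, ], yb[-tr],
                                   model_spec("svm")), 0.9)
  expect_error(fit_predict_one_split(X[tr, ], rep(1, 150), X[-tr, ], y[-tr],
                                     model_spec("krr")), "constant")
})

test_that("a target independent of the features scores near zero", {
  # Monte-Carlo over seeds: mean test R^2 of pure-noise targets stays <= 0.05
  scores <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(120 * 6), 120, 6)
    y <- rnorm(120)
    fit_predict_one_split(X[1:90, ], y[1:90], X[-(1:90), ], y[-(1:90)],
                          model_spec("krr"), seed = s)
  }, numeric(1))
  expect_lte(mean(scores), 0.05)
})

test_that("scaler statistics never see the test rows", {
  set.seed(21)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rnorm(60)
  tr <- 1:45
  s1 <- fit_predict_one_split(X[tr, ], y[tr], X[-tr, ], y[-tr],
                              model_spec("elasticnet_reg"), seed = 5)
  # mutate the test rows wildly: train-side standardization, inner-fold
  # hyperparameter choice, and the fitted model must be unchanged, so the
  # score with the ORIGINAL test rows must reproduce exactly
  Xmut <- X
  Xmut[-tr, ] <- Xmut[-tr, ] * 1000 + 7
  s2 <- fit_predict_one_split(Xmut[tr, ], y[tr], X[-tr, ], y[-tr],
                              model_spec("elasticnet_reg"), seed = 5)
  expect_identical(s1, s2)
})

test_that("the permutation null has splits x permutations entries", {
  co <- small_preprocessed()
  ids <- vapply(co, `[[`, character(1), "subject_id")
  fam <- vapply(co, `[[`, character(1), "family_id")
  sch <- make_family_splits(ids, fam, n_outer_splits = 4,
                            test_fraction = 0.2, seed = 6)
  fm <- build_feature_matrix(co, "regional_sd")
  y <- setNames(vapply(co, function(s) s$targets_continuous[["cognition"]],
                       numeric(1)), ids)
  out <- permutation_test(fm, y, sch, model_spec("krr"), n_permutations = 5,
                          seed = 7)
  expect_length(out$null_scores, 20)
  expect_length(out$result$per_split_scores, 4)
  expect_true(out$result$p_value > 0 && out$result$p_value <= 1)
  # summary statistics recomputable from the per-split scores
  sc <- out$result$per_split_scores
  expect_identical(out$result$mean, mean(sc))
  expect_identical(out$result$sd, sd(sc))
  expect_equal(c(out$result$q1, out$result$median, out$result$q3),
               quantile(sc, c(0.25, 0.5, 0.75), names = FALSE))
  expect_error(permutation_test(fm, y, sch, model_spec("krr"),
                                n_permutations = 0), "n_permutations")
})

test_that("scores that dominate the null give the smoothed minimum p", {
  # real scores all above max(null) => p = 1/(n_null + 1), significant
  set.seed(22)
  n <- 90
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("S%02d", 1:n), NULL))
  y <- setNames(2 * X[, 1] + 0.1 * rnorm(n), rownames(X))
  sch <- make_family_splits(rownames(X), rownames(X), n_outer_splits = 3,
                            test_fraction = 0.2, seed = 8)
  out <- permutation_test(X, y, sch, model_spec("krr"), n_permutations = 10,
                          seed = 9)
  expect_true(all(out$result$per_split_scores > max(out$null_scores)))
  expect_equal(out$result$p_value, 1 / 31)
  expect_true(out$result$significant)
})

test_that("stronger synthetic effects yield nondecreasing mean R^2", {
  means <- vapply(c(0, 0.3, 0.6), function(e) {
    cfg <- cohort_config(n_subjects = 150, n_regions = 10, n_sessions = 1,
                         frames_per_session = 80, n_communities = 2,
                         seed = 33,
                         effect_size_per_target = list(cognition = e),
                         informative_feature_per_target =
                           list(cognition = "regional_sd"))
    co <- generate_cohort(cfg)
    co <- lapply(co, preprocess_subject, tr_seconds = 0.72)
    ids <- vapply(co, `[[`, character(1), "subject_id")
    fam <- vapply(co, `[[`, character(1), "family_id")
    sch <- make_family_splits(ids, fam, n_outer_splits = 5, seed = 12)
    fm <- build_feature_matrix(co, "regional_sd")
    y <- setNames(vapply(co, function(s) s$targets_continuous[["cognition"]],
                         numeric(1)), ids)
    evaluate_feature_target(fm, y, sch, model_spec("krr"), seed = 13)$mean
  }, numeric(1))
  expect_true(all(diff(means) > -0.05))
  expect_gt(means[3], means[1])
})
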