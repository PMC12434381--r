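# Family-aware train/test evaluation with nested hyperparameter selection
# and the permutation-based significance test.
#
# Outer loop: 10 random family-respecting train/test partitions (test about
# 15% of subjects, rounded to whole families). Inner loop: 3 folds on the
# training set to select hyperparameters. Feature standardization statistics
# are computed on the training portion only, so no test information leaks
# into scaling, hyperparameter choice, or (upstream) the consensus SC.

#' Family-respecting outer train/test splits
#'
#' Members of one family are never separated across train and test; the test
#' set is grown family by family (in seeded random order) until it holds at
#' least `test_fraction` of the subjects, so test sizes vary slightly with
#' family granularity.
#'
#' @param subject_ids character vector of subject IDs.
#' @param family_ids character vector of family IDs, same length.
#' @param n_outer_splits number of random partitions (default 10).
#' @param test_fraction target fraction of subjects in each test set
#'   (default 0.15).
#' @param n_inner_folds inner folds used later for hyperparameter selection
#'   (default 3; stored with the scheme).
#' @param seed integer seed; the scheme is deterministic given it.
#' @return object of class `split_scheme` with a `splits` list of
#'   `(train_ids, test_ids)` pairs.
#' @export
make_family_splits <- function(subject_ids, family_ids, n_outer_splits = 10,
                               test_fraction = 0.15, n_inner_folds = 3,
                               seed = 1L) {
  n <- length(subject_ids)
  assert_that(length(family_ids) == n, "one family ID per subject required")
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  fams <- unique(family_ids)
  target <- test_fraction * n
  splits <- lapply(seq_len(n_outer_splits), function(k) {
    ord <- with_seed(child_seed(seed, "outer_split", k), sample(fams))
    test_f <- character(0)
    count <- 0
    for (f in ord) {
      if (count >= target) break
      test_f <- c(test_f, f)
      count <- count + sum(family_ids == f)
    }
    in_test <- family_ids %in% test_f
    assert_that(any(!in_test) && any(in_test),
                "cannot form a nonempty train/test partition that keeps families whole")
    list(train_ids = subject_ids[!in_test], test_ids = subject_ids[in_test])
  })
  structure(list(n_outer_splits = as.integer(n_outer_splits),
                 test_fraction = test_fraction,
                 n_inner_folds = as.integer(n_inner_folds),
                 seed = as.integer(seed), splits = splits),
            class = "split_scheme")
}

#' Model specification
#'
#' Four models, matched to the target type: `elasticnet_reg` and `krr`
#' (linear-kernel kernel ridge regression) for continuous targets,
#' `elasticnet_clf` and `svm` (linear support vector machine) for binary
#' targets. Default hyperparameter grids are small, standard, and
#' configurable: elastic-net mixing 0.1/0.5/0.9 with penalty strength
#' log-spaced 1e-3..1e3 (7 points); KRR ridge log-spaced 1e-3..1e3; SVM cost
#' log-spaced 1e-2..1e2.
#'
#' @param name one of `"elasticnet_reg"`, `"krr"`, `"elasticnet_clf"`,
#'   `"svm"`.
#' @param grid optional named list of hyperparameter candidate vectors
#'   overriding the defaults (`alpha`/`lambda` for elastic net, `lambda` for
#'   KRR, `cost` for SVM).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name = c("elasticnet_reg", "krr", "elasticnet_clf",
                                "svm"),
                       grid = NULL) {
  name <- match.arg(name)
  default <- switch(name,
    elasticnet_reg = ,
    elasticnet_clf = list(alpha = c(0.1, 0.5, 0.9),
                          lambda = 10^seq(-3, 3, length.out = 7)),
    krr = list(lambda = 10^seq(-3, 3, length.out = 7)),
    svm = list(cost = 10^seq(-2, 2, length.out = 5)))
  if (!is.null(grid)) {
    assert_that(all(names(grid) %in% names(default)),
                "unknown hyperparameter in grid")
    default[names(grid)] <- grid
  }
  assert_that(all(lengths(default) > 0), "hyperparameter grid must be nonempty")
  structure(list(name = name, grid = default, kernel = "linear",
                 type = if (name %in% c("elasticnet_clf", "svm"))
                   "binary" else "continuous"),
            class = "model_spec")
}

#' Coefficient of determination
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2). May be negative when
#' predictions are worse than the training-free mean predictor.
#'
#' @param y_true observed values (at least 2, nonconstant).
#' @param y_pred predictions, same length.
#' @return a single real number.
#' @export
r_squared <- function(y_true, y_pred) {
  assert_that(length(y_true) >= 2 && length(y_true) == length(y_pred),
              "need >= 2 paired observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  assert_that(ss_tot > 0, "zero-variance y_true: R^2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

accuracy <- function(y_true, y_pred) mean(y_true == y_pred)

# Standard scaler fitted on training rows only.
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}
apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# ---- model backends ----------------------------------------------------
# Each backend takes standardized train features and returns predictions on
# standardized validation/test features at every grid point (for inner CV)
# or at one chosen grid point (for the final fit).

# Linear-kernel kernel ridge regression in closed (dual) form:
# alpha = (K + lambda I)^{-1} (y - ybar), yhat = K* alpha + ybar.
krr_fit <- function(Xtr, ytr, lambda) {
  K <- tcrossprod(Xtr)
  ybar <- mean(ytr)
  n <- nrow(Xtr)
  a <- solve(K + lambda * diag(n), ytr - ybar)
  list(Xtr = Xtr, alpha = a, ybar = ybar)
}
krr_predict <- function(fit, Xnew) {
  as.numeric(Xnew %*% t(fit$Xtr) %*% fit$alpha) + fit$ybar
}

enet_predict_grid <- function(Xtr, ytr, Xval, alpha, lambdas, family) {
  fit <- glmnet::glmnet(Xtr, ytr, alpha = alpha, lambda = sort(lambdas,
    decreasing = TRUE), family = family, standardize = FALSE)
  type <- if (family == "binomial") "class" else "response"
  pred <- stats::predict(fit, Xval, s = lambdas, exact = FALSE, type = type)
  # columns follow the order of `lambdas`
  pred
}

svm_fit <- function(Xtr, ytr, cost) {
  e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = cost, scale = FALSE)
}

# First index of the maximal mean score; falls back to the first grid point
# when every fold degenerated.
pick_best <- function(means) {
  if (all(!is.finite(means))) 1L else which.max(means)
}

# Inner fold assignment; stratified by class for binary targets so every
# fold's training part sees both classes whenever possible.
assign_inner_folds <- function(y, k, binary) {
  n <- length(y)
  f <- integer(n)
  if (binary) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    f <- sample(rep_len(seq_len(k), n))
  }
  f
}

# Inner cross-validation over the model's grid; returns the best parameter
# combination by mean fold score (R^2 for regression, accuracy for
# classification). Folds whose training part degenerates (single class)
# score NA and are dropped from the mean.
inner_cv_select <- function(X, y, model, n_inner_folds, seed) {
  n <- nrow(X)
  folds <- with_seed(seed,
    assign_inner_folds(y, n_inner_folds, model$type == "binary"))
  grid <- model$grid
  score_raw <- if (model$type == "binary") accuracy else r_squared
  # degenerate folds (singleton or constant validation target) score NA
  score_fun <- function(yt, yp) {
    tryCatch(score_raw(yt, yp), error = function(e) NA_real_)
  }
  if (model$name %in% c("elasticnet_reg", "elasticnet_clf")) {
    family <- if (model$type == "binary") "binomial" else "gaussian"
    combos <- expand.grid(alpha = grid$alpha, lambda = grid$lambda)
    scores <- matrix(NA_real_, n_inner_folds, nrow(combos))
    for (f in seq_len(n_inner_folds)) {
      tr <- folds != f
      sc <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
      Xva <- apply_scaler(X[!tr, , drop = FALSE], sc)
      for (a in seq_along(grid$alpha)) {
        pred <- tryCatch(enet_predict_grid(Xtr, y[tr], Xva, grid$alpha[a],
                                           grid$lambda, family),
                         error = function(e) NULL)
        if (is.null(pred)) next
        for (l in seq_along(grid$lambda)) {
          idx <- which(combos$alpha == grid$alpha[a] &
                         combos$lambda == grid$lambda[l])
          p <- pred[, l]
          if (family == "binomial") p <- as.numeric(as.character(p))
          scores[f, idx] <- score_fun(y[!tr], p)
        }
      }
    }
    best <- pick_best(colMeans(scores, na.rm = TRUE))
    list(alpha = combos$alpha[best], lambda = combos$lambda[best])
  } else if (model$name == "krr") {
    scores <- matrix(NA_real_, n_inner_folds, length(grid$lambda))
    for (f in seq_len(n_inner_folds)) {
      tr <- folds != f
      sc <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
      Xva <- apply_scaler(X[!tr, , drop = FALSE], sc)
      K <- tcrossprod(Xtr)
      Kva <- Xva %*% t(Xtr)
      ybar <- mean(y[tr])
      for (l in seq_along(grid$lambda)) {
        a <- solve(K + grid$lambda[l] * diag(nrow(Xtr)), y[tr] - ybar)
        scores[f, l] <- score_fun(y[!tr], as.numeric(Kva %*% a) + ybar)
      }
    }
    list(lambda = grid$lambda[pick_best(colMeans(scores, na.rm = TRUE))])
  } else {  # svm
    scores <- matrix(NA_real_, n_inner_folds, length(grid$cost))
    for (f in seq_len(n_inner_folds)) {
      tr <- folds != f
      sc <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
      Xva <- apply_scaler(X[!tr, , drop = FALSE], sc)
      for (cidx in seq_along(grid$cost)) {
        scores[f, cidx] <- tryCatch({
          fit <- svm_fit(Xtr, y[tr], grid$cost[cidx])
          score_fun(y[!tr], as.numeric(as.character(stats::predict(fit, Xva))))
        }, error = function(e) NA_real_)
      }
    }
    list(cost = grid$cost[pick_best(colMeans(scores, na.rm = TRUE))])
  }
}

#' Fit one outer split with nested hyperparameter selection and score the test set
#'
#' Standardization statistics and hyperparameters are derived from the
#' training rows only. Returns R^2 (continuous models) or accuracy (binary
#' models) on the held-out test rows.
#'
#' @param X_train,y_train training features (rows = subjects) and target.
#' @param X_test,y_test held-out features and target.
#' @param model a [model_spec()].
#' @param n_inner_folds inner folds for hyperparameter selection (default 3).
#' @param seed seed controlling the inner fold assignment.
#' @return a single test score.
#' @export
fit_predict_one_split <- function(X_train, y_train, X_test, y_test, model,
                                  n_inner_folds = 3, seed = 1L) {
  assert_that(inherits(model, "model_spec"), "model must be a model_spec")
  if (model$type == "continuous") {
    assert_that(stats::sd(y_train) > 0,
                "constant training target: R^2 selection undefined")
  } else {
    assert_that(length(unique(y_train)) == 2,
                "binary models need both classes in training data")
  }
  best <- inner_cv_select(X_train, y_train, model, n_inner_folds, seed)
  sc <- fit_scaler(X_train)
  Xtr <- apply_scaler(X_train, sc)
  Xte <- apply_scaler(X_test, sc)
  pred <- switch(model$name,
    elasticnet_reg = {
      fit <- glmnet::glmnet(Xtr, y_train, alpha = best$alpha,
                            lambda = sort(model$grid$lambda, decreasing = TRUE),
                            standardize = FALSE)
      as.numeric(stats::predict(fit, Xte, s = best$lambda))
    },
    krr = krr_predict(krr_fit(Xtr, y_train, best$lambda), Xte),
    elasticnet_clf = {
      fit <- glmnet::glmnet(Xtr, y_train, family = "binomial",
                            alpha = best$alpha,
                            lambda = sort(model$grid$lambda, decreasing = TRUE),
                            standardize = FALSE)
      as.numeric(as.character(stats::predict(fit, Xte, s = best$lambda,
                                             type = "class")))
    },
    svm = as.numeric(as.character(stats::predict(svm_fit(Xtr, y_train,
                                                         best$cost), Xte))))
  if (model$type == "binary") accuracy(y_test, pred) else r_squared(y_test, pred)
}

summarize_scores <- function(scores, p_value = NA_real_) {
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_split_scores = scores, mean = mean(scores), sd = stats::sd(scores),
       median = q[2], q1 = q[1], q3 = q[3], p_value = p_value)
}

#' Evaluate one feature-target pair over all outer splits
#'
#' @param feature a `feature_matrix` (or plain subject x dim matrix with
#'   subject IDs as rownames).
#' @param target named numeric (or 0/1) vector indexed by subject ID, or an
#'   unnamed vector aligned with the feature rows.
#' @param scheme a [make_family_splits()] scheme.
#' @param model a [model_spec()].
#' @param seed master seed for inner fold assignment.
#' @return list with per-split scores and their mean, sd, median, q1, q3.
#' @export
evaluate_feature_target <- function(feature, target, scheme, model,
                                    seed = 1L) {
  X <- if (inherits(feature, "feature_matrix")) feature$values else feature
  ids <- rownames(X)
  assert_that(!is.null(ids), "feature matrix must carry subject IDs as rownames")
  y <- if (!is.null(names(target))) target[ids] else target
  assert_that(length(y) == nrow(X), "target length must match feature rows")
  scores <- vapply(seq_along(scheme$splits), function(k) {
    sp <- scheme$splits[[k]]
    tr <- match(sp$train_ids, ids)
    te <- match(sp$test_ids, ids)
    fit_predict_one_split(X[tr, , drop = FALSE], y[tr],
                          X[te, , drop = FALSE], y[te], model,
                          scheme$n_inner_folds,
                          seed = child_seed(seed, "inner", k))
  }, numeric(1))
  summarize_scores(scores)
}

#' Permutation-based significance test for one feature-target pair
#'
#' The target vector is reshuffled `n_permutations` times for each outer
#' split (reshuffled over the whole cohort, then scored with that split's
#' fixed train/test partition), and the full pipeline -- scaling, inner-fold
#' hyperparameter selection, refit -- is repeated on each reshuffle. Under
#' the defaults (10 splits x 100 permutations) the null holds 1000 scores.
#' The p-value is the +1-smoothed proportion of null scores at or above the
#' real mean score; the feature is flagged significant when the real mean
#' strictly exceeds the null's 95th percentile.
#'
#' @inheritParams evaluate_feature_target
#' @param n_permutations reshuffles per split (default 100).
#' @return list with `result` (as [evaluate_feature_target()], plus
#'   `p_value` and `significant`) and `null_scores` (length
#'   splits x permutations).
#' @export
permutation_test <- function(feature, target, scheme, model,
                             n_permutations = 100, seed = 1L) {
  assert_that(is_count(n_permutations), "n_permutations must be >= 1")
  X <- if (inherits(feature, "feature_matrix")) feature$values else feature
  ids <- rownames(X)
  y <- if (!is.null(names(target))) target[ids] else target
  real <- evaluate_feature_target(feature, target, scheme, model, seed)
  null_scores <- numeric(0)
  for (k in seq_along(scheme$splits)) {
    sp <- scheme$splits[[k]]
    tr <- match(sp$train_ids, ids)
    te <- match(sp$test_ids, ids)
    for (j in seq_len(n_permutations)) {
      yp <- with_seed(child_seed(seed, "perm", k, j), sample(y))
      s <- fit_predict_one_split(X[tr, , drop = FALSE], yp[tr],
                                 X[te, , drop = FALSE], yp[te], model,
                                 scheme$n_inner_folds,
                                 seed = child_seed(seed, "perm_inner", k, j))
      null_scores <- c(null_scores, s)
    }
  }
  mean_real <- real$mean
  p <- (1 + sum(null_scores >= mean_real)) / (1 + length(null_scores))
  real$p_value <- p
  real$significant <- mean_real > stats::quantile(null_scores, 0.95,
                                                  names = FALSE)
  list(result = real, null_scores = null_scores)
}
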