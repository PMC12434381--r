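# Sample-size x scan-time scaling experiments: the prediction pipeline is
# repeated over a grid of training-set fractions (0.2..1.0) and scan-time
# amounts (0.25 sessions doubling up to all 4), with the test set of each
# outer split held constant across training fractions.

#' Family-respecting nested subsampling of a training set
#'
#' Families are shuffled once (seeded) and taken in that order until the
#' subset holds at least `fraction` of the training subjects, so subsets are
#' nested across fractions for a given seed: the subjects used at fraction
#' 0.2 are all reused at 0.4, and so on. The test set is untouched.
#'
#' @param train_ids character vector of training subject IDs.
#' @param fraction fraction in (0, 1]; 1 returns the full training set.
#' @param family_ids named character vector mapping subject ID to family ID
#'   (or a vector aligned with `train_ids`).
#' @param seed integer seed fixing the family order.
#' @return character vector of retained training IDs (original order).
#' @export
subsample_train <- function(train_ids, fraction, family_ids, seed = 1L) {
  assert_that(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  if (fraction == 1) return(train_ids)
  fam <- if (!is.null(names(family_ids))) family_ids[train_ids] else family_ids
  fams <- unique(fam)
  ord <- with_seed(child_seed(seed, "subsample"), sample(fams))
  target <- fraction * length(train_ids)
  keep_f <- character(0)
  count <- 0
  for (f in ord) {
    if (count >= target) break
    keep_f <- c(keep_f, f)
    count <- count + sum(fam == f)
  }
  train_ids[fam %in% keep_f]
}

#' Truncate a subject's sessions to a scan-time amount
#'
#' Frames are always taken from the beginning of session one and extended
#' from there: fractional amounts take the leading fraction of session one's
#' (preprocessed) frames, amount 1 all of session one, amount 2 sessions one
#' and two, amount 4 everything. Every frame used at a smaller amount is
#' also used at every larger one.
#'
#' @param sessions list of region x frame matrices (preprocessed).
#' @param session_amount one of 0.25, 0.5, 1, 2, 4 (any positive value up to
#'   the available session count is accepted).
#' @return single region x frame matrix of the concatenated retained frames.
#' @export
truncate_scan <- function(sessions, session_amount) {
  assert_that(is.numeric(session_amount) && session_amount > 0,
              "session_amount must be positive")
  assert_that(session_amount <= length(sessions),
              "session_amount exceeds the available sessions")
  full <- floor(session_amount)
  frac <- session_amount - full
  parts <- sessions[seq_len(full)]
  if (frac > 0) {
    nxt <- sessions[[full + 1]]
    n_keep <- floor(frac * ncol(nxt))
    assert_that(n_keep >= 1, "fractional amount keeps no frames")
    parts <- c(parts, list(nxt[, seq_len(n_keep), drop = FALSE]))
  }
  do.call(cbind, parts)
}

#' Minutes of scan time for a session amount
#'
#' A quarter session is 3.6 minutes, so `minutes = amount * 4 * 3.6`: 0.25
#' sessions = 3.6 min, four full sessions = 57.6 min.
#'
#' @param session_amount positive session amount(s).
#' @param minutes_per_quarter_session default 3.6.
#' @return minutes, same length as `session_amount`.
#' @export
scan_time_axis <- function(session_amount, minutes_per_quarter_session = 3.6) {
  assert_that(all(session_amount > 0), "session amounts must be positive")
  session_amount * 4 * minutes_per_quarter_session
}

#' Run the scaling grid for one feature-target-model combination
#'
#' For every (training fraction, session amount) cell: the training set of
#' each outer split is subsampled (family-respecting, nested across
#' fractions), the consensus SC and harmonic basis are recomputed from the
#' reduced training set, features are recomputed from scan-time-truncated
#' sessions, and the model is evaluated on the split's unchanged test set.
#'
#' @param cohort list of preprocessed subject records.
#' @param feature_name one of [FEATURE_NAMES].
#' @param target named target vector indexed by subject ID.
#' @param model a [model_spec()].
#' @param scheme a [make_family_splits()] scheme.
#' @param train_fractions vector of fractions (default 0.2..1.0 step 0.2).
#' @param session_amounts vector of session amounts (default 0.25, 0.5, 1,
#'   2, 4).
#' @param tr_seconds sampling interval (for fALFF).
#' @param seed master seed for subsampling and inner folds.
#' @return object of class `scaling_grid`: a long-format data.frame with
#'   columns feature, target_name, model, train_fraction, sessions, split,
#'   score.
#' @export
run_scaling <- function(cohort, feature_name, target, model, scheme,
                        train_fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                        session_amounts = c(0.25, 0.5, 1, 2, 4),
                        tr_seconds = 0.72, seed = 1L) {
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  fam <- stats::setNames(vapply(cohort, `[[`, character(1), "family_id"), ids)
  target_name <- attr(target, "target_name")
  if (is.null(target_name)) target_name <- "target"
  rows <- list()
  for (amount in session_amounts) {
    for (k in seq_along(scheme$splits)) {
      sp <- scheme$splits[[k]]
      for (fr in train_fractions) {
        tr_ids <- subsample_train(sp$train_ids, fr, fam,
                                  seed = child_seed(seed, "frac", k))
        basis <- if (needs_basis(feature_name)) {
          train_basis(cohort, tr_ids)$basis
        } else NULL
        fmat <- build_feature_matrix(
          cohort[match(c(tr_ids, sp$test_ids), ids)], feature_name,
          basis = basis, tr_seconds = tr_seconds, session_amount = amount)
        X <- fmat$values
        y <- target[rownames(X)]
        ntr <- length(tr_ids)
        score <- fit_predict_one_split(
          X[seq_len(ntr), , drop = FALSE], y[seq_len(ntr)],
          X[-seq_len(ntr), , drop = FALSE], y[-seq_len(ntr)], model,
          scheme$n_inner_folds, seed = child_seed(seed, "inner", k))
        rows[[length(rows) + 1]] <- data.frame(
          feature = feature_name, target_name = target_name,
          model = model$name, train_fraction = fr, sessions = amount,
          split = k, score = score)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scaling_grid", class(out))
  out
}

#' Summarize a scaling grid into per-cell mean and SD
#'
#' @param grid a `scaling_grid` from [run_scaling()].
#' @return data.frame with one row per (train_fraction, sessions) cell:
#'   mean score, SD across splits, scan-time minutes.
#' @export
summarize_scaling <- function(grid) {
  agg <- stats::aggregate(score ~ feature + target_name + model +
                            train_fraction + sessions, data = grid,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- cbind(agg[, setdiff(names(agg), "score")],
               mean = agg$score[, "mean"], sd = agg$score[, "sd"])
  out$minutes <- scan_time_axis(out$sessions)
  out
}

#' Heatmap of the scaling grid (mean score per cell)
#'
#' @param grid a `scaling_grid`.
#' @return a ggplot object.
#' @export
plot_scaling_heatmap <- function(grid) {
  s <- summarize_scaling(grid)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(train_fraction),
                                  y = factor(sessions),
                                  fill = mean)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "training-set fraction", y = "sessions used",
                  fill = "mean score",
                  title = sprintf("%s predicting %s (%s)", s$feature[1],
                                  s$target_name[1], s$model[1])) +
    ggplot2::theme_minimal()
}

#' Scan-time tradeoff curves (one line per training fraction)
#'
#' Error band: per-point SD across the outer splits.
#'
#' @param grid a `scaling_grid`.
#' @return a ggplot object.
#' @export
plot_scan_time_curves <- function(grid) {
  s <- summarize_scaling(grid)
  s$train_fraction <- factor(s$train_fraction)
  ggplot2::ggplot(s, ggplot2::aes(x = minutes, y = mean,
                                  color = train_fraction,
                                  fill = train_fraction)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd,
                                      ymax = mean + sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "scan time (min)", y = "mean test score",
                  color = "train fraction", fill = "train fraction") +
    ggplot2::theme_minimal()
}
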