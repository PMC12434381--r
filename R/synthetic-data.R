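# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# community-structured structural connectome shared across subjects with
# subject-level variability, BOLD whose graph-spectral energy is concentrated
# on low connectome harmonics, multi-session acquisition with motion
# confounds, family groupings, and behavioral targets that are noisy linear
# functions of known ground-truth features.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the acquisition the analysis was designed around: R = 274
#' parcels, four resting-state sessions of 1200 frames at TR = 0.72 s.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of parcels R.
#' @param n_sessions sessions per subject.
#' @param frames_per_session frames per session before any discard.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param n_communities number of communities in the base structural graph.
#' @param family_size_probs probability vector over family sizes 1..5.
#' @param effect_size_per_target named list mapping target name to the
#'   fraction of target variance explained by its ground-truth feature
#'   (0 = pure noise target).
#' @param informative_feature_per_target named list mapping target name to
#'   one of `"fc_edges"`, `"regional_sd"`, `"graph_psd_low"`, `"none"`.
#' @param spectral_decay positive rate of graph-spectral energy decay: BOLD is
#'   synthesized with per-harmonic gain exp(-spectral_decay * lambda).
#' @param noise_sd standard deviation of additive regional noise on BOLD.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config including this seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          n_regions = 274,
                          n_sessions = 4,
                          frames_per_session = 1200,
                          tr_seconds = 0.72,
                          n_communities = 5,
                          family_size_probs = c(0.45, 0.25, 0.15, 0.10, 0.05),
                          effect_size_per_target = list(
                            mental_health = 0, cognition = 0.5,
                            processing_speed = 0.3, substance_use = 0,
                            age = 0.4, sex = 0.5),
                          informative_feature_per_target = list(
                            mental_health = "none", cognition = "fc_edges",
                            processing_speed = "graph_psd_low",
                            substance_use = "none", age = "fc_edges",
                            sex = "regional_sd"),
                          spectral_decay = 2.5,
                          noise_sd = 0.5,
                          seed = 1L) {
  for (v in list(n_subjects, n_regions, n_sessions, frames_per_session,
                 n_communities)) {
    assert_that(is_count(v), "all counts must be positive integers")
  }
  assert_that(is.numeric(tr_seconds) && tr_seconds > 0, "tr_seconds must be > 0")
  assert_that(length(family_size_probs) == 5 && all(family_size_probs >= 0) &&
                abs(sum(family_size_probs) - 1) < 1e-8,
              "family_size_probs must be 5 nonnegative values summing to 1")
  es <- unlist(effect_size_per_target)
  assert_that(all(es >= 0 & es <= 1), "effect sizes must lie in [0, 1]")
  feats <- unlist(informative_feature_per_target)
  assert_that(all(feats %in% c("fc_edges", "regional_sd", "graph_psd_low",
                               "none")),
              "unknown informative feature name")
  assert_that(setequal(names(effect_size_per_target),
                       names(informative_feature_per_target)),
              "effect sizes and informative features must name the same targets")
  assert_that(is.numeric(spectral_decay) && spectral_decay > 0,
              "spectral_decay must be positive")
  assert_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_sessions = as.integer(n_sessions),
    frames_per_session = as.integer(frames_per_session),
    tr_seconds = tr_seconds, n_communities = as.integer(n_communities),
    family_size_probs = family_size_probs,
    effect_size_per_target = effect_size_per_target,
    informative_feature_per_target = informative_feature_per_target,
    spectral_decay = spectral_decay, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "cohort_config")
}

# Base weighted graph: stochastic-block-model-like with denser, heavier
# within-community edges, ensuring the modular structure that consensus
# thresholding assumes. Guaranteed connected via a weighted ring backbone.
make_base_graph <- function(R, n_communities) {
  comm <- sort(rep_len(seq_len(n_communities), R))
  A <- matrix(0, R, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      within <- comm[i] == comm[j]
      p <- if (within) 0.6 else 0.15
      if (runif(1) < p) {
        mu <- if (within) 1.0 else 0.4
        A[i, j] <- mu * exp(rnorm(1, 0, 0.35))
      }
    }
  }
  A <- A + t(A)
  ring <- c(seq_len(R), 1)
  for (k in seq_len(R)) {  # backbone keeps every node connected
    i <- ring[k]; j <- ring[k + 1]
    if (A[i, j] == 0) A[i, j] <- A[j, i] <- 0.2
  }
  A
}

# Subject-level SC: multiplicative lognormal jitter on the base edges plus a
# small rate of random edge additions/deletions (keeps consensus construction
# nontrivial). Backbone edges are never deleted so each subject SC stays
# connected.
perturb_sc <- function(base, jitter_sd = 0.25, flip_rate = 0.02) {
  R <- nrow(base)
  ut <- which(upper.tri(base))
  w <- base[ut]
  w <- w * exp(rnorm(length(ut), 0, jitter_sd))
  present <- w > 0
  del <- present & (runif(length(ut)) < flip_rate)
  add <- !present & (runif(length(ut)) < flip_rate)
  w[del] <- 0
  w[add] <- 0.3 * exp(rnorm(sum(add), 0, jitter_sd))
  A <- matrix(0, R, R)
  A[ut] <- w
  A <- A + t(A)
  ring <- c(seq_len(R), 1)
  for (k in seq_len(R)) {
    i <- ring[k]; j <- ring[k + 1]
    if (A[i, j] == 0) A[i, j] <- A[j, i] <- 0.2
  }
  A
}

# BOLD synthesis in the subject's own harmonic coordinates:
# x(t) = U diag(g(lambda)) w(t) + eps(t), g(lambda) = exp(-decay * lambda),
# with w, eps white noise. Graph-spectral energy therefore decays with
# eigenvalue, concentrating on low harmonics.
synth_bold_session <- function(U, lambda, n_frames, decay, noise_sd) {
  R <- length(lambda)
  gains <- exp(-decay * lambda)
  w <- matrix(rnorm(R * n_frames), R, n_frames)
  x <- U %*% (gains * w)
  if (noise_sd > 0) x <- x + matrix(rnorm(R * n_frames, 0, noise_sd), R, n_frames)
  x
}

# Six motion regressors per session as smooth random walks (cumulated white
# noise passed through a short moving average).
synth_confounds <- function(n_frames, k = 6) {
  out <- matrix(0, n_frames, k)
  for (j in seq_len(k)) {
    rw <- cumsum(rnorm(n_frames, 0, 0.05))
    out[, j] <- stats::filter(rw, rep(1 / 9, 9), sides = 2, circular = TRUE)
  }
  out
}

# Ground-truth per-subject feature used to build targets. Computed from the
# subject's generative parameters, not the realized scan: under the model
# the time-marginal covariance of the BOLD is
#   C = U diag(g(lambda)^2) U' + noise_sd^2 I,
# so the subject's true (infinite-scan-time) FC, regional SD, and graph
# spectrum are deterministic functions of their connectome. Targets built on
# these stable traits are what measured features estimate -- mirroring
# brain-behavior studies, where behavior relates to the trait, not to the
# sampling noise of one scan.
ground_truth_feature <- function(subject, kind, cfg) {
  if (kind == "none") return(NULL)
  noise_sd <- if (!is.null(subject$noise_sd)) subject$noise_sd else cfg$noise_sd
  b <- harmonic_basis(normalized_laplacian(subject$sc))
  g2 <- exp(-2 * cfg$spectral_decay * b$eigenvalues)
  C <- b$eigenvectors %*% (g2 * t(b$eigenvectors)) +
    noise_sd^2 * diag(cfg$n_regions)
  switch(kind,
    fc_edges = {
      v <- upper_tri_vec(stats::cov2cor(C))
      # cap dimension so the projection stays well-conditioned at small n
      v[seq_len(min(length(v), 500))]
    },
    regional_sd = sqrt(diag(C)),
    graph_psd_low = {
      p <- sqrt(g2 + noise_sd^2)
      p[seq_len(floor(length(p) / 2))]
    })
}

#' Generate a fully synthetic cohort with known ground truth
#'
#' Subject structural connectomes are noisy perturbations of one base
#' community-structured graph; BOLD is synthesized from each subject's own
#' connectome harmonics with spectrally decaying gains so graph-spectral
#' energy concentrates on low harmonics; continuous targets are noisy linear
#' functions of a designated ground-truth feature scaled to the requested
#' effect size; the binary sex target is drawn from a logistic threshold on a
#' latent built from the regional-SD ground truth; subjects are grouped into
#' families of size 1 to 5.
#'
#' @param config a [cohort_config()].
#' @return a list of subject records, each with fields `subject_id`,
#'   `family_id`, `sc` (R x R symmetric nonnegative, zero diagonal),
#'   `sessions` (list of R x frames matrices), `confounds` (list of
#'   frames x 6 matrices), `targets_continuous` (named numeric), and
#'   `target_binary` (0/1). The list carries the config as attribute
#'   `"config"`.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  cfg <- config
  R <- cfg$n_regions

  base <- with_seed(child_seed(cfg$seed, "base_graph"),
                    make_base_graph(R, cfg$n_communities))

  fam_ids <- with_seed(child_seed(cfg$seed, "families"), {
    sizes <- integer(0)
    while (sum(sizes) < cfg$n_subjects) {
      sizes <- c(sizes, sample.int(5, 1, prob = cfg$family_size_probs))
    }
    rep(sprintf("F%04d", seq_along(sizes)), sizes)[seq_len(cfg$n_subjects)]
  })

  cohort <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    sc <- with_seed(child_seed(cfg$seed, "sc", s), perturb_sc(base))
    b <- harmonic_basis(normalized_laplacian(sc))
    # subject-level noise amplitude (lognormal around the config value):
    # scanner and physiological noise differ across individuals, and this
    # global coupling level is a stable subject trait that scales all
    # functional correlations
    noise_s <- cfg$noise_sd *
      with_seed(child_seed(cfg$seed, "noise_level", s), exp(rnorm(1, 0, 0.4)))
    sessions <- lapply(seq_len(cfg$n_sessions), function(k) {
      with_seed(child_seed(cfg$seed, "bold", s, k),
        synth_bold_session(b$eigenvectors, b$eigenvalues,
                           cfg$frames_per_session, cfg$spectral_decay,
                           noise_s))
    })
    confounds <- lapply(seq_len(cfg$n_sessions), function(k) {
      with_seed(child_seed(cfg$seed, "confounds", s, k),
        synth_confounds(cfg$frames_per_session))
    })
    cohort[[s]] <- list(
      subject_id = sprintf("S%04d", s), family_id = fam_ids[s],
      sc = sc, sessions = sessions, confounds = confounds,
      noise_sd = noise_s,
      targets_continuous = NULL, target_binary = NULL)
  }

  cohort <- assign_targets(cohort, cfg)
  attr(cohort, "config") <- cfg
  cohort
}

# Build targets: z-scored projection of the ground-truth feature on a fixed
# random weight vector, mixed with noise so the feature explains exactly the
# requested variance fraction in expectation.
assign_targets <- function(cohort, cfg) {
  n <- length(cohort)
  targets <- names(cfg$effect_size_per_target)
  latent <- function(kind, seed_label) {
    if (kind == "none") return(rep(0, n))
    feats <- lapply(cohort, ground_truth_feature, kind = kind, cfg = cfg)
    X <- do.call(rbind, feats)
    wvec <- with_seed(child_seed(cfg$seed, "weights", seed_label, kind),
                      rnorm(ncol(X)))
    s <- as.numeric(X %*% wvec)
    if (stats::sd(s) < 1e-12) rep(0, n) else as.numeric(scale(s))
  }
  vals <- list()
  for (tg in targets) {
    kind <- cfg$informative_feature_per_target[[tg]]
    e <- cfg$effect_size_per_target[[tg]]
    sig <- latent(kind, tg)
    noise <- with_seed(child_seed(cfg$seed, "target_noise", tg), rnorm(n))
    y <- sqrt(e) * sig + sqrt(1 - e) * noise
    vals[[tg]] <- y
  }
  # age mapped to the cohort's narrow 22-37 range
  if ("age" %in% targets) {
    vals$age <- 22 + 15 * stats::pnorm(vals$age)
  }
  sexp <- if ("sex" %in% targets) {
    with_seed(child_seed(cfg$seed, "sex_draw"),
              as.integer(runif(n) < stats::plogis(2 * vals$sex)))
  } else rep(NA_integer_, n)
  cont <- setdiff(targets, "sex")
  for (s in seq_len(n)) {
    cohort[[s]]$targets_continuous <-
      stats::setNames(vapply(cont, function(tg) vals[[tg]][s], numeric(1)), cont)
    cohort[[s]]$target_binary <- sexp[s]
  }
  cohort
}

#' Split a cohort into a factor-derivation holdout and a main-analysis set
#'
#' Families are kept whole: the holdout is grown family by family (in cohort
#' order) until it reaches the smallest family-respecting size at or above
#' `n_holdout`; everything else is the main-analysis set. With 979 singleton
#' families and `n_holdout = 145` this leaves 834 main-analysis subjects.
#'
#' @param cohort list of subject records.
#' @param n_holdout requested holdout size (0 allowed).
#' @return list with elements `holdout` and `main`, disjoint lists of subject
#'   records covering the cohort.
#' @export
partition_factor_subset <- function(cohort, n_holdout) {
  n <- length(cohort)
  assert_that(is.numeric(n_holdout) && n_holdout >= 0 && n_holdout == as.integer(n_holdout),
              "n_holdout must be a nonnegative integer")
  assert_that(n_holdout < n, "n_holdout must be smaller than the cohort size")
  if (n_holdout == 0) return(list(holdout = list(), main = cohort))
  fams <- vapply(cohort, `[[`, character(1), "family_id")
  hold_f <- character(0)
  count <- 0
  for (f in unique(fams)) {
    if (count >= n_holdout) break
    hold_f <- c(hold_f, f)
    count <- count + sum(fams == f)
  }
  in_hold <- fams %in% hold_f
  list(holdout = cohort[in_hold], main = cohort[!in_hold])
}

#' Write a cohort to a directory of delimited text files
#'
#' Layout: `subjects.tsv` (subject ID, family ID, targets) plus per-subject
#' directories holding `sc.tsv`, `sess-<k>_bold.tsv`, and
#' `sess-<k>_confounds.tsv`, all in the sidecar-header matrix format of
#' [write_matrix_tsv()].
#'
#' @param cohort list of subject records.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.table::data.table(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    family_id = vapply(cohort, `[[`, character(1), "family_id"),
    sex = vapply(cohort, `[[`, integer(1), "target_binary"))
  cont <- names(cohort[[1]]$targets_continuous)
  for (tg in cont) {
    tab[[tg]] <- vapply(cohort, function(s) s$targets_continuous[[tg]], numeric(1))
  }
  data.table::fwrite(tab, file.path(dir, "subjects.tsv"), sep = "\t")
  for (s in cohort) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    write_matrix_tsv(s$sc, file.path(sdir, "sc.tsv"))
    for (k in seq_along(s$sessions)) {
      write_matrix_tsv(s$sessions[[k]], file.path(sdir, sprintf("sess-%d_bold.tsv", k)))
      write_matrix_tsv(s$confounds[[k]], file.path(sdir, sprintf("sess-%d_confounds.tsv", k)))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list of subject records (targets restored from `subjects.tsv`).
#' @export
read_cohort <- function(dir) {
  tab <- data.table::fread(file.path(dir, "subjects.tsv"), sep = "\t")
  cont <- setdiff(names(tab), c("subject_id", "family_id", "sex"))
  lapply(seq_len(nrow(tab)), function(i) {
    sid <- tab$subject_id[i]
    sdir <- file.path(dir, sid)
    bold_files <- sort(list.files(sdir, pattern = "^sess-\\d+_bold\\.tsv$"))
    ks <- as.integer(sub("^sess-(\\d+)_bold\\.tsv$", "\\1", bold_files))
    ord <- order(ks)
    list(
      subject_id = sid, family_id = tab$family_id[i],
      sc = read_matrix_tsv(file.path(sdir, "sc.tsv")),
      sessions = lapply(bold_files[ord], function(f) read_matrix_tsv(file.path(sdir, f))),
      confounds = lapply(ks[ord], function(k)
        read_matrix_tsv(file.path(sdir, sprintf("sess-%d_confounds.tsv", k)))),
      targets_continuous = stats::setNames(as.numeric(tab[i, cont, with = FALSE]), cont),
      target_binary = tab$sex[i])
  })
}
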