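# Consensus structural connectome and its harmonic (graph-spectral) basis.
#
# The group-level SC is the Hadamard product of a binary consensus mask
# (edge-occurrence thresholding to a target density) with the element-wise
# mean of the subject SC matrices. Its normalized-Laplacian eigenvectors are
# the connectome harmonics used by every graph-signal-processing feature.
# Both are recomputed per training set by the prediction framework so no
# test-subject information leaks into the basis.

check_sc_list <- function(scs) {
  assert_that(length(scs) >= 1, "need at least one subject SC")
  R <- nrow(scs[[1]])
  for (m in scs) {
    assert_that(is.matrix(m) && nrow(m) == R && ncol(m) == R,
                "all SC matrices must share the same square shape")
    assert_that(max(abs(m - t(m))) < 1e-8, "SC matrices must be symmetric")
  }
  R
}

#' Binary consensus mask by edge-occurrence thresholding
#'
#' Edges are ranked by how many subjects carry them (ties broken by mean
#' weight, then by edge index) and kept in that order until the mask density
#' reaches the target. `target_density = "auto"` uses the mean subject edge
#' density, so the consensus is as dense as a typical subject.
#'
#' @param scs list of region x region symmetric nonnegative matrices.
#' @param target_density fraction of possible edges to keep, or `"auto"`.
#' @return binary symmetric region x region matrix with zero diagonal.
#' @export
consensus_mask <- function(scs, target_density = "auto") {
  R <- check_sc_list(scs)
  n_possible <- R * (R - 1) / 2
  occ <- Reduce(`+`, lapply(scs, function(m) (m > 0) * 1)) / length(scs)
  mw <- Reduce(`+`, scs) / length(scs)
  if (identical(target_density, "auto")) {
    target_density <- mean(vapply(scs, function(m)
      sum(m[upper.tri(m)] > 0) / n_possible, numeric(1)))
  }
  assert_that(is.numeric(target_density) && target_density >= 0 &&
                target_density <= 1, "target_density must be in [0, 1]")
  n_keep <- round(target_density * n_possible)
  ut <- which(upper.tri(occ))
  ord <- order(-occ[ut], -mw[ut], ut)
  keep <- ut[ord[seq_len(min(n_keep, sum(occ[ut] > 0)))]]
  mask <- matrix(0, R, R)
  mask[keep] <- 1
  mask + t(mask)
}

#' Group-consensus structural connectome
#'
#' Hadamard product of the consensus mask with the element-wise mean of the
#' subject SCs. Callers evaluating predictions must recompute this per
#' training set.
#'
#' @inheritParams consensus_mask
#' @return list of class `consensus_sc` with fields `weights`, `mask`, and
#'   `subject_ids_used`.
#' @export
consensus_sc <- function(scs, target_density = "auto") {
  R <- check_sc_list(scs)
  mask <- consensus_mask(scs, target_density)
  mw <- Reduce(`+`, scs) / length(scs)
  w <- mask * mw
  diag(w) <- 0
  structure(list(weights = w, mask = mask,
                 subject_ids_used = names(scs)),
            class = "consensus_sc")
}

#' Symmetric normalized graph Laplacian
#'
#' L = I - D^(-1/2) A D^(-1/2). Symmetric with eigenvalues in [0, 2]; the
#' symmetric (not random-walk) normalization is used because its eigenvectors
#' form an orthonormal basis, which the Parseval identity of the graph
#' Fourier transform requires.
#'
#' @param sc region x region symmetric nonnegative matrix, zero diagonal.
#' @return region x region normalized Laplacian.
#' @export
normalized_laplacian <- function(sc) {
  assert_that(is.matrix(sc) && nrow(sc) == ncol(sc), "sc must be square")
  assert_that(max(abs(sc - t(sc))) < 1e-8, "sc must be symmetric")
  assert_that(all(sc >= 0), "sc must be nonnegative")
  deg <- rowSums(sc)
  assert_that(all(deg > 0), "graph has an isolated node (zero degree)")
  dinv <- 1 / sqrt(deg)
  L <- diag(nrow(sc)) - (dinv * sc) * rep(dinv, each = nrow(sc))
  (L + t(L)) / 2
}

#' Harmonic basis: eigendecomposition of a normalized Laplacian
#'
#' Eigenvalues are returned ascending (low harmonics = spatially smooth
#' patterns first). Eigenvector signs follow a fixed convention -- the
#' largest-magnitude entry of each eigenvector is made positive -- so graph
#' Fourier coefficients are reproducible across runs and platforms.
#'
#' @param L symmetric matrix (normalized Laplacian).
#' @return object of class `harmonic_basis` with `eigenvalues` (ascending)
#'   and `eigenvectors` (orthonormal columns, column k pairing eigenvalue k).
#' @export
harmonic_basis <- function(L) {
  assert_that(is.matrix(L) && max(abs(L - t(L))) < 1e-8,
              "L must be symmetric")
  e <- eigen(L, symmetric = TRUE)
  idx <- order(e$values)
  vals <- e$values[idx]
  U <- e$vectors[, idx, drop = FALSE]
  for (k in seq_len(ncol(U))) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) U[, k] <- -U[, k]
  }
  structure(list(eigenvalues = vals, eigenvectors = U),
            class = "harmonic_basis")
}

#' Consensus connectome and harmonic basis for a set of training subjects
#'
#' Convenience wrapper chaining [consensus_sc()], [normalized_laplacian()],
#' and [harmonic_basis()].
#'
#' @param cohort list of subject records.
#' @param ids subject IDs to use (training set); default all.
#' @param target_density passed to [consensus_sc()].
#' @return list with `consensus` (a `consensus_sc`) and `basis` (a
#'   `harmonic_basis`).
#' @export
train_basis <- function(cohort, ids = NULL, target_density = "auto") {
  all_ids <- vapply(cohort, `[[`, character(1), "subject_id")
  if (is.null(ids)) ids <- all_ids
  sel <- cohort[match(ids, all_ids)]
  scs <- lapply(sel, `[[`, "sc")
  names(scs) <- ids
  cons <- consensus_sc(scs, target_density)
  basis <- harmonic_basis(normalized_laplacian(cons$weights))
  list(consensus = cons, basis = basis)
}
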