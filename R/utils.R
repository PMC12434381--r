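#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("train_fraction", "sessions", "minutes", "score"))

# Internal assertion helper: stop with the caller-supplied message when cond
# is not a single TRUE.
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == as.integer(x) && x > 0
}

#' Derive a child seed from a master seed and a path of stage labels
#'
#' Every random draw in the pipeline traces back to one master seed through
#' this function: the child seed is a deterministic 31-bit hash of the master
#' seed and an arbitrary sequence of labels (stage name, split index,
#' permutation index, ...). Distinct paths give effectively independent
#' streams; the same path always gives the same seed, independent of
#' evaluation order, which makes parallel or reordered execution reproducible.
#'
#' @param master_seed integer master seed.
#' @param ... labels (character or integer scalars) identifying the stage.
#' @return an integer in [1, 2^31 - 2] suitable for [set.seed()].
#' @export
#' @examples
#' child_seed(1, "splits", 3)
child_seed <- function(master_seed, ...) {
  labels <- c(as.character(as.integer(master_seed)), vapply(list(...),
    function(l) paste0(as.character(l), collapse = ","), character(1)))
  # 31-bit multiplicative string hash (FNV-style), stable across platforms
  m <- 2147483629  # prime < 2^31
  h <- 17
  for (lab in labels) {
    # multiplier kept small so h * 131 + code stays exact in doubles
    for (code in utf8ToInt(paste0(lab, "\x1f"))) {
      h <- (h * 131 + code) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr with a local RNG state seeded from `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write a numeric matrix as tab-separated text with a dimension sidecar line
#'
#' The first line is a comment of the form `# rows cols`, so files are
#' self-describing and diffable; the body is plain TSV without row or column
#' names.
#'
#' @param m numeric matrix.
#' @param path output file path.
#' @export
write_matrix_tsv <- function(m, path) {
  assert_that(is.matrix(m) && is.numeric(m), "m must be a numeric matrix")
  writeLines(sprintf("# %d %d", nrow(m), ncol(m)), path)
  data.table::fwrite(data.table::as.data.table(m), path,
    sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  header <- readLines(path, n = 1)
  dims <- as.integer(strsplit(sub("^#\\s*", "", header), "\\s+")[[1]])
  m <- as.matrix(data.table::fread(path, sep = "\t", skip = 1, header = FALSE))
  dimnames(m) <- NULL
  assert_that(nrow(m) == dims[1] && ncol(m) == dims[2],
    sprintf("dimension sidecar (%d x %d) disagrees with body (%d x %d) in %s",
      dims[1], dims[2], nrow(m), ncol(m), path))
  m
}

# Strict upper-triangle vectorization, row-major (row i < col j, j varies
# fastest). All FC-family features use this ordering.
upper_tri_vec <- function(m) {
  r <- nrow(m)
  t(m)[lower.tri(m)]  # t() converts column-major lower to row-major upper
}
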