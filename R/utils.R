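# Shared constants and small helpers.

# The 20 canonical amino acids, one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so seeded
#' generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
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
  set.seed(as.integer(seed))
  force(expr)
}

# Validate a protein sequence: 20 canonical codes plus X.
assert_protein_seq <- function(seq, allow_x = TRUE, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    abort(sprintf("`%s` must be a single non-empty string.", arg))
  }
  ok <- c(AA20, if (allow_x) "X")
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0L) {
    abort(sprintf("`%s` contains non-canonical residue code(s): %s",
                  arg, paste(bad, collapse = ", ")))
  }
  invisible(toupper(seq))
}

# Validate a symmetric dissimilarity/distance matrix with labels.
assert_distance_matrix <- function(D, arg = "D") {
  if (!is.matrix(D) || !is.numeric(D)) abort(sprintf("`%s` must be a numeric matrix.", arg))
  if (nrow(D) != ncol(D)) abort(sprintf("`%s` must be square.", arg))
  if (is.null(rownames(D)) || is.null(colnames(D))) {
    abort(sprintf("`%s` must have row and column labels.", arg))
  }
  if (!identical(rownames(D), colnames(D))) {
    abort(sprintf("`%s` row and column labels must match.", arg))
  }
  if (any(is.na(D))) abort(sprintf("`%s` contains missing values.", arg))
  if (any(D < 0)) abort(sprintf("`%s` contains negative entries.", arg))
  if (max(abs(D - t(D))) > 1e-8) abort(sprintf("`%s` is not symmetric.", arg))
  if (any(abs(diag(D)) > 1e-12)) abort(sprintf("`%s` must have a zero diagonal.", arg))
  invisible(D)
}

# Path to a file shipped under inst/extdata.
crystkit_extdata <- function(file) {
  path <- system.file("extdata", file, package = "crystkit")
  if (identical(path, "")) abort(sprintf("packaged data file '%s' not found", file))
  path
}
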