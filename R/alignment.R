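# Global pairwise alignment, percent identity, progressive MSA, codon
# threading, and conservation-logo information content.

#' Default protein substitution matrix (BLOSUM62)
#'
#' @return The BLOSUM62 matrix shipped with Biostrings.
#' @export
default_submatrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Simple match/mismatch substitution matrix
#'
#' @param alphabet Character vector of symbols.
#' @param match,mismatch Scores.
#' @return A square numeric matrix.
#' @export
match_submatrix <- function(alphabet = c("A", "C", "G", "T"),
                            match = 5, mismatch = -3) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment with affine gap penalties (Gotoh
#' recursion): a gap of length \eqn{k} costs
#' \eqn{open + (k-1) \cdot extend}. The traceback is deterministic
#' (diagonal preferred over up over left), so identical inputs always give
#' the identical alignment. Defaults are Clustal-like: BLOSUM62, gap open
#' 10, gap extend 0.5.
#'
#' @param a,b Sequences to align (non-empty; every character must appear in
#'   `matrix`).
#' @param matrix Substitution matrix with matching dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param ids Optional length-2 character vector of sequence labels.
#' @return An object of class `pairwise_alignment`: `ids`, `aligned_a`,
#'   `aligned_b`, `score`, `identities`, `mutually_ungapped`.
#' @examples
#' aln <- nw_align("GKITLYE", "GKITFYE")
#' percent_identity(aln)
#' @export
nw_align <- function(a, b, matrix = default_submatrix(),
                     gap_open = 10, gap_extend = 0.5,
                     ids = c("a", "b")) {
  for (s in list(a, b)) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
      abort("sequences must be single non-empty strings")
    }
  }
  a <- toupper(a); b <- toupper(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  bad <- setdiff(unique(c(ca, cb)), rownames(matrix))
  if (length(bad) > 0L) {
    abort(sprintf("character(s) not in substitution matrix: %s",
                  paste(bad, collapse = ", ")))
  }
  S <- matrix[ca, cb, drop = FALSE]
  res <- gotoh_align_cpp(unname(S), gap_open, gap_extend)
  ga <- ifelse(res$a_idx == 0L, "-", ca[pmax(res$a_idx, 1L)])
  gb <- ifelse(res$b_idx == 0L, "-", cb[pmax(res$b_idx, 1L)])
  ung <- res$a_idx > 0L & res$b_idx > 0L
  idn <- sum(ung & ga == gb)
  structure(list(ids = ids,
                 aligned_a = paste(ga, collapse = ""),
                 aligned_b = paste(gb, collapse = ""),
                 score = res$score,
                 identities = idn,
                 mutually_ungapped = sum(ung)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s  (score %.1f, PID %.1f%%)\n",
              x$ids[1], x$ids[2], x$score, percent_identity(x)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' @rdname nw_align
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @method tidy pairwise_alignment
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble(id_a = x$ids[1], id_b = x$ids[2], score = x$score,
         identities = x$identities, mutually_ungapped = x$mutually_ungapped,
         pid = percent_identity(x))
}

#' Percent identity of a pairwise alignment
#'
#' Default definition: 100 x identities / mutually ungapped columns. Two
#' alternative conventions are selectable: over the full alignment length,
#' or over the shorter of the two sequences.
#'
#' @param aln A `pairwise_alignment`.
#' @param method Denominator convention.
#' @return Percent in `[0, 100]`.
#' @export
percent_identity <- function(aln,
                             method = c("ungapped", "alignment_length", "shorter")) {
  method <- match.arg(method)
  denom <- switch(method,
    ungapped = aln$mutually_ungapped,
    alignment_length = nchar(aln$aligned_a),
    shorter = min(nchar(gsub("-", "", aln$aligned_a, fixed = TRUE)),
                  nchar(gsub("-", "", aln$aligned_b, fixed = TRUE))))
  if (denom == 0L) {
    warn("alignment has no mutually ungapped columns; percent identity set to 0")
    return(0)
  }
  100 * aln$identities / denom
}

#' All-vs-all percent-dissimilarity matrix
#'
#' Aligns every pair of sequences globally and returns the matrix of
#' 100 - percent identity, the dissimilarity used for identity-based
#' hierarchical clustering of crystallin sequences.
#'
#' @param records Tibble of protein records (`id`, `seq`), n >= 2, unique ids.
#' @param ... Passed to [nw_align()] (substitution matrix, gap penalties).
#' @return A symmetric labeled matrix with zero diagonal, entries in
#'   `[0, 100]`.
#' @export
dissimilarity_matrix <- function(records, ...) {
  n <- nrow(records)
  if (n < 2L) abort("need at least two sequences")
  if (anyDuplicated(records$id)) abort("duplicate sequence ids")
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- nw_align(records$seq[i], records$seq[j],
                      ids = c(records$id[i], records$id[j]), ...)
      D[i, j] <- D[j, i] <- 100 - percent_identity(aln)
    }
  }
  D
}

# ---- multiple alignment -----------------------------------------------------

new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  w <- unique(nchar(rows))
  if (length(w) != 1L) abort("MSA rows must have equal length")
  structure(list(ids = ids, rows = setNames(rows, ids), column_count = w),
            class = "crystal_msa")
}

#' @export
print.crystal_msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              length(x$ids), x$column_count))
  show <- utils::head(seq_along(x$ids), 8L)
  for (i in show) {
    cat(sprintf(" %-18s %s\n", x$ids[i],
                substr(x$rows[i], 1, min(60, x$column_count))))
  }
  if (length(x$ids) > 8L) cat(sprintf(" ... %d more rows\n", length(x$ids) - 8L))
  invisible(x)
}

#' @rdname progressive_msa
#' @param x A `crystal_msa`.
#' @param ... Unused.
#' @method tidy crystal_msa
#' @export
tidy.crystal_msa <- function(x, ...) {
  tibble(id = x$ids, aligned = unname(x$rows))
}

# Column frequency profile of a set of gapped rows: alphabet x L matrix,
# normalized by the number of rows (gap mass simply missing).
msa_profile <- function(rows, alphabet) {
  L <- nchar(rows[1])
  mat <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    keep <- ch != "-"
    idx <- match(ch[keep], alphabet)
    pos <- which(keep)
    for (k in seq_along(idx)) mat[idx[k], pos[k]] <- mat[idx[k], pos[k]] + 1
  }
  mat / length(rows)
}

# Align two gapped-row groups profile-to-profile with the shared Gotoh kernel.
align_profiles <- function(rows_a, rows_b, matrix, gap_open, gap_extend) {
  alphabet <- rownames(matrix)
  Fa <- msa_profile(rows_a, alphabet)
  Fb <- msa_profile(rows_b, alphabet)
  S <- t(Fa) %*% matrix %*% Fb
  res <- gotoh_align_cpp(unname(S), gap_open, gap_extend)
  thread <- function(rows, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
    }, character(1))
  }
  c(thread(rows_a, res$a_idx), thread(rows_b, res$b_idx))
}

# Minimal UPGMA on a dissimilarity matrix, returning a nested-list guide
# tree over leaf labels (deterministic tie-break: smallest label pair).
upgma_guide <- function(D) {
  labels <- rownames(D)
  nodes <- as.list(labels)
  sizes <- rep(1, length(labels))
  act <- seq_along(labels)
  M <- D
  while (length(act) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        i <- act[ii]; j <- act[jj]
        d <- M[i, j]
        if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    new <- list(nodes[[i]], nodes[[j]])
    ni <- sizes[i]; nj <- sizes[j]
    upd <- (ni * M[i, ] + nj * M[j, ]) / (ni + nj)
    M[i, ] <- upd; M[, i] <- upd; M[i, i] <- 0
    nodes[[i]] <- new
    sizes[i] <- ni + nj
    act <- setdiff(act, j)
  }
  nodes[[act]]
}

# Convert an ape phylo guide tree to nested lists of tip labels.
phylo_to_nested <- function(tree) {
  nt <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- children[[as.character(node)]]
    sub <- lapply(kids, rec)
    if (length(sub) == 1L) sub[[1]] else Reduce(function(a, b) list(a, b), sub)
  }
  rec(nt + 1L)
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment with profile-profile global alignment at
#' each merge (same affine-gap kernel as [nw_align()], profile column scores
#' as frequency-weighted substitution scores). The default guide tree is
#' UPGMA on the pairwise percent-dissimilarity matrix. This is a compact
#' progressive aligner in the Clustal tradition, not a Clustal Omega clone;
#' every output row de-gaps to its input sequence.
#'
#' @param records Tibble of sequence records (`id`, `seq`), n >= 2.
#' @param guide Optional guide tree: an `ape::phylo` whose tip labels equal
#'   the record ids, or `NULL` for the UPGMA default.
#' @param matrix,gap_open,gap_extend Scoring parameters as in [nw_align()].
#' @return A `crystal_msa`.
#' @export
progressive_msa <- function(records, guide = NULL,
                            matrix = default_submatrix(),
                            gap_open = 10, gap_extend = 0.5) {
  n <- nrow(records)
  if (n < 2L) abort("need at least two sequences")
  if (anyDuplicated(records$id)) abort("duplicate sequence ids")
  seqs <- setNames(toupper(records$seq), records$id)
  if (is.null(guide)) {
    nested <- if (n == 2L) list(records$id[1], records$id[2]) else
      upgma_guide(dissimilarity_matrix(records, matrix = matrix,
                                       gap_open = gap_open,
                                       gap_extend = gap_extend))
  } else {
    if (!inherits(guide, "phylo")) abort("`guide` must be an ape phylo tree")
    if (!setequal(guide$tip.label, records$id)) {
      abort("guide tree tip labels must match the record ids")
    }
    nested <- phylo_to_nested(guide)
  }
  build <- function(node) {
    if (is.character(node)) return(setNames(seqs[node], node))
    left <- build(node[[1]])
    right <- build(node[[2]])
    merged <- align_profiles(left, right, matrix, gap_open, gap_extend)
    setNames(merged, c(names(left), names(right)))
  }
  rows <- build(nested)
  rows <- rows[records$id]  # restore input order
  new_msa(records$id, unname(rows))
}

#' Thread coding sequences through a protein alignment
#'
#' Back-translates a protein MSA to a codon-level nucleotide MSA: each
#' amino-acid column becomes one codon column triple and each gap becomes
#' `---`. A trailing stop codon on a CDS is stripped automatically.
#'
#' @param protein_msa A `crystal_msa` of protein rows.
#' @param cds Named character vector or list mapping each MSA id to its CDS;
#'   each CDS must have length 3 x the ungapped protein length (after stop
#'   stripping).
#' @return A nucleotide `crystal_msa`.
#' @examples
#' msa <- progressive_msa(tibble::tibble(id = c("s1", "s2"),
#'                                       seq = c("MA", "MAC")))
#' codon_thread(msa, c(s1 = "ATGGCT", s2 = "ATGGCTTGT"))
#' @export
codon_thread <- function(protein_msa, cds) {
  stop_codons <- c("TAA", "TAG", "TGA")
  rows <- vapply(protein_msa$ids, function(id) {
    if (!id %in% names(cds)) abort(sprintf("no CDS supplied for '%s'", id))
    nt <- toupper(gsub("U", "T", cds[[id]]))
    prot <- gsub("-", "", protein_msa$rows[[id]], fixed = TRUE)
    need <- 3L * nchar(prot)
    if (nchar(nt) == need + 3L &&
        substr(nt, nchar(nt) - 2L, nchar(nt)) %in% stop_codons) {
      nt <- substr(nt, 1L, nchar(nt) - 3L)
    }
    if (nchar(nt) != need) {
      abort(sprintf("CDS length mismatch for '%s': expected %d nt (3 x %d aa), got %d",
                    id, need, nchar(prot), nchar(nt)))
    }
    ch <- strsplit(protein_msa$rows[[id]], "")[[1]]
    codons <- substring(nt, seq(1L, need, by = 3L), seq(3L, need, by = 3L))
    out <- character(length(ch))
    k <- 0L
    for (i in seq_along(ch)) {
      if (ch[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }, character(1))
  new_msa(protein_msa$ids, unname(rows))
}

#' Per-column conservation (sequence-logo information content)
#'
#' For each alignment column, computes the information content
#' \eqn{I = \log_2 20 - H} where \eqn{H} is the Shannon entropy (bits) of the
#' column's residue frequencies; gaps are excluded from the frequencies and
#' columns with more than `gap_flag` gap fraction are flagged. Letter heights
#' are frequency x information, the quantity drawn in a sequence logo.
#'
#' @param msa A protein `crystal_msa` with >= 2 rows.
#' @param gap_flag Gap-fraction threshold above which a column is flagged.
#' @return A tibble with one row per (column, residue) pair plus per-column
#'   `information` (bits) and `flagged`; all-gap columns carry information 0.
#' @export
conservation_logo <- function(msa, gap_flag = 0.5) {
  if (length(msa$ids) < 2L) abort("logo requires at least two rows")
  chars <- do.call(rbind, strsplit(unname(msa$rows), ""))
  max_info <- log2(20)
  out <- purrr::map_dfr(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    res <- col[col != "-"]
    gap_frac <- 1 - length(res) / length(col)
    if (length(res) == 0L) {
      return(tibble(column = j, residue = NA_character_, frequency = NA_real_,
                    height = NA_real_, information = 0, flagged = TRUE))
    }
    f <- table(res) / length(res)
    H <- -sum(f * log2(f))
    info <- max_info - H
    tibble(column = j, residue = names(f), frequency = as.numeric(f),
           height = as.numeric(f) * info, information = info,
           flagged = gap_frac > gap_flag)
  })
  out
}
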