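# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: alignment scores by exhaustive path enumeration,
# SASA by Monte-Carlo point sampling, and composition by direct arithmetic.

# Best global affine-gap alignment score by exhaustive enumeration of all
# monotone alignment paths (diag / up / left), scoring gap runs as
# open + (len - 1) * extend. Exponential; only for short sequences.
enum_align_score <- function(a, b, mat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > na && j > nb) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i <= na && j <= nb) {
      rec(i + 1L, j + 1L, score + mat[ca[i], cb[j]], "M")
    }
    if (i <= na) {
      rec(i + 1L, j, score - if (last == "X") gap_extend else gap_open, "X")
    }
    if (j <= nb) {
      rec(i, j + 1L, score - if (last == "Y") gap_extend else gap_open, "Y")
    }
  }
  rec(1L, 1L, 0, "start")
  best
}

# Monte-Carlo SASA: random points on each expanded sphere instead of the
# deterministic lattice.
mc_sasa <- function(model, probe = 1.4, npts = 3000L, radii = vdw_radii(),
                    seed = 42L) {
  set.seed(seed)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  r <- unname(radii[model$element])
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- r[i] + probe
    pts <- matrix(rnorm(3 * npts), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * Ri
    pts <- sweep(pts, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, npts)
    for (j in seq_len(n)) {
      if (j == i) next
      Rj <- r[j] + probe
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 >= Rj^2
      if (!any(exposed)) break
    }
    out[i] <- mean(exposed) * 4 * pi * Ri^2
  }
  out
}

# Random protein-record tibble for round-trip tests.
random_records <- function(n, min_len = 5L, max_len = 120L, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tibble::tibble(
    id = sprintf("rec%03d", seq_len(n)),
    description = ifelse(seq_len(n) %% 3 == 0, "", "synthetic record"),
    seq = vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
            collapse = "")
    }, character(1)),
    moltype = "protein")
}

# Random symmetric dissimilarity matrix with labels.
random_dissim <- function(n, lo = 1, hi = 80) {
  m <- matrix(runif(n * n, lo, hi), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(sprintf("L%02d", seq_len(n)), sprintf("L%02d", seq_len(n)))
  m
}

# Build a pairwise_alignment object directly from two gapped rows
# (for testing formula-level behaviour without running the aligner).
manual_alignment <- function(ga, gb, ids = c("x", "y")) {
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  ung <- ca != "-" & cb != "-"
  structure(list(ids = ids, aligned_a = ga, aligned_b = gb, score = NA_real_,
                 identities = sum(ung & ca == cb),
                 mutually_ungapped = sum(ung)),
            class = "pairwise_alignment")
}

# Minimal hand-written PDB text for parser tests.
toy_pdb_lines <- function() {
  c("HEADER    TOY STRUCTURE",
    "ATOM      1  N   CYS A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  CYS A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  SG  CYS A   1       2.000   1.500   0.500  1.00  0.00           S",
    "ATOM      4  CA  GLY A   2       4.100   0.200  -1.300  1.00  0.00           C",
    "END")
}
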