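test_that("identical sequences align gap-free with full identity", {
  aln <- nw_align("ACDEF", "ACDEF")
  expect_equal(aln$identities, 5L)
  expect_equal(aln$mutually_ungapped, 5L)
  expect_equal(percent_identity(aln), 100)
  expect_error(nw_align("AAAA", ""), "non-empty")
})

test_that("alignment score equals the exhaustive-enumeration optimum", {
  mat <- match_submatrix(match = 5, mismatch = -3)
  # linear gap penalty: open == extend == 4
  aln <- nw_align("AC", "AGC", matrix = mat, gap_open = 4, gap_extend = 4)
  expect_equal(aln$score, enum_align_score("AC", "AGC", mat, 4, 4))

  # sweep: every ordered pair of length <= 2 over ACGT, plus seeded random
  # longer pairs, under affine penalties
  alpha <- c("A", "C", "G", "T")
  short <- c(alpha, apply(expand.grid(alpha, alpha), 1, paste, collapse = ""))
  for (a in short) for (b in short) {
    expect_equal(nw_align(a, b, matrix = mat, gap_open = 6, gap_extend = 1)$score,
                 enum_align_score(a, b, mat, 6, 1))
  }
  set.seed(13)
  for (k in 1:40) {
    a <- paste(sample(alpha, sample(3:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(3:5, 1), replace = TRUE), collapse = "")
    expect_equal(nw_align(a, b, matrix = mat, gap_open = 6, gap_extend = 1)$score,
                 enum_align_score(a, b, mat, 6, 1))
  }
})

test_that("alignment is deterministic and de-gaps to its inputs", {
  recs <- random_records(6, min_len = 20, max_len = 40, seed = 4)
  for (i in 1:5) {
    a1 <- nw_align(recs$seq[i], recs$seq[i + 1])
    a2 <- nw_align(recs$seq[i], recs$seq[i + 1])
    expect_identical(a1$aligned_a, a2$aligned_a)
    expect_equal(gsub("-", "", a1$aligned_a), recs$seq[i])
    expect_equal(gsub("-", "", a1$aligned_b), recs$seq[i + 1])
  }
})

test_that("percent identity follows its stated formula and conventions", {
  aln <- manual_alignment("AC-D", "ACEE")
  expect_equal(percent_identity(aln), 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(percent_identity(aln, "alignment_length"), 50)
  gappy <- manual_alignment("A--", "-CC")
  expect_warning(pid <- percent_identity(gappy), "ungapped")
  expect_equal(pid, 0)
})

test_that("dissimilarity matrices are symmetric, bounded, and re-derivable pairwise", {
  recs <- random_records(5, min_len = 25, max_len = 45, seed = 10)
  D <- dissimilarity_matrix(recs)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 100))
  for (i in 1:4) for (j in (i + 1):5) {
    aln <- nw_align(recs$seq[i], recs$seq[j])
    expect_equal(D[i, j], 100 - percent_identity(aln))
  }
  same <- tibble::tibble(id = c("u", "v"), seq = rep(recs$seq[1], 2))
  expect_equal(unname(dissimilarity_matrix(same)[1, 2]), 0)
  expect_error(dissimilarity_matrix(tibble::tibble(id = c("u", "u"),
                                                   seq = recs$seq[1:2])),
               "duplicate")
})

test_that("progressive alignment reduces to pairwise alignment and respects inputs", {
  two <- tibble::tibble(id = c("p", "q"), seq = c("MKVAC", "MKAC"))
  msa <- progressive_msa(two)
  aln <- nw_align(two$seq[1], two$seq[2])
  expect_equal(unname(msa$rows), c(aln$aligned_a, aln$aligned_b))

  three <- tibble::tibble(id = c("a", "b", "c"), seq = rep("MKVLAC", 3))
  msa3 <- progressive_msa(three)
  expect_equal(msa3$column_count, 6L)
  expect_false(any(grepl("-", msa3$rows)))

  fam <- gen_family(seq_spec(n_sequences = 6, mutation_rate = 0.03,
                             indel_rate = 0.3, seed = 19))
  msaf <- progressive_msa(fam$records)
  expect_equal(unname(gsub("-", "", msaf$rows)), fam$records$seq)

  bad_guide <- ape::rtree(3, tip.label = c("x", "y", "z"))
  expect_error(progressive_msa(three, guide = bad_guide), "tip labels")
})

test_that("codon threading maps residues to codons and gaps to ---", {
  msa <- structure(list(ids = c("s1"), rows = c(s1 = "M-A"), column_count = 3L),
                   class = "crystal_msa")
  out <- codon_thread(msa, c(s1 = "ATGGCT"))
  expect_equal(unname(out$rows), "ATG---GCT")
  # stop codon stripped
  out2 <- codon_thread(msa, c(s1 = "ATGGCTTAA"))
  expect_equal(unname(out2$rows), "ATG---GCT")
  expect_error(codon_thread(msa, c(s1 = "ATGGC")), "s1")

  fam <- gen_family(seq_spec(n_sequences = 5, seed = 23))
  cds <- gen_cds_for(fam$records, seed = 24)
  msaf <- progressive_msa(fam$records)
  nt <- codon_thread(msaf, cds)
  expect_equal(unname(gsub("-", "", nt$rows)), unname(cds[msaf$ids]))
  shuffled <- cds
  shuffled[1] <- paste0(shuffled[1], "AAA")
  expect_error(codon_thread(msaf, shuffled), "mismatch")
})

test_that("conservation information matches the entropy definition", {
  msa <- structure(list(ids = c("r1", "r2", "r3"),
                        rows = c(r1 = "GA-", r2 = "GC-", r3 = "G--"),
                        column_count = 3L), class = "crystal_msa")
  logo <- conservation_logo(msa)
  col1 <- logo[logo$column == 1, ]
  expect_equal(unique(col1$information), log2(20), tolerance = 1e-12)
  col2 <- logo[logo$column == 2, ]
  expect_equal(unique(col2$information), log2(20) - 1, tolerance = 1e-12)
  expect_false(any(col2$flagged))         # only 1/3 gaps, below the flag level
  col3 <- logo[logo$column == 3, ]
  expect_equal(unique(col3$information), 0)
  expect_true(all(col3$flagged))

  # random column against a direct entropy recomputation
  set.seed(31)
  res <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 12, replace = TRUE)
  msa2 <- structure(list(ids = sprintf("r%02d", 1:12),
                         rows = setNames(res, sprintf("r%02d", 1:12)),
                         column_count = 1L), class = "crystal_msa")
  f <- table(res) / length(res)
  expected <- log2(20) + sum(f * log2(f))
  logo2 <- conservation_logo(msa2)
  expect_equal(unique(logo2$information), expected, tolerance = 1e-12)
  expect_equal(sum(logo2$height), expected, tolerance = 1e-12)

  # bound and monotonicity under duplicating a modal-residue row
  expect_true(all(logo$information >= 0 & logo$information <= log2(20)))
  modal <- names(which.max(table(res)))
  msa_dup <- structure(list(ids = c(msa2$ids, "extra"),
                            rows = c(msa2$rows, extra = modal),
                            column_count = 1L), class = "crystal_msa")
  expect_gte(unique(conservation_logo(msa_dup)$information),
             unique(logo2$information))
})
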