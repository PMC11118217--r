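test_that("ward clustering handles the two-leaf base case", {
  D <- matrix(c(0, 10, 10, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  dend <- ward_cluster(D)
  expect_equal(dend$height, 10)
  expect_equal(dend$merge, matrix(c(-1L, -2L), 1))
})

test_that("ward clustering agrees with the independent base-R implementation", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    D <- random_dissim(n)
    mine <- ward_cluster(D)
    ref <- stats::hclust(stats::as.dist(D), method = "ward.D2")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-9)
    # identical merge structure up to rotation: compare cophenetic matrices
    expect_equal(as.matrix(stats::cophenetic(stats::as.hclust(mine)))[rownames(D), rownames(D)],
                 as.matrix(stats::cophenetic(ref))[rownames(D), rownames(D)],
                 tolerance = 1e-9)
    expect_true(all(diff(mine$height) >= -1e-9))  # monotone linkage
  }
  bad <- random_dissim(4); bad[1, 2] <- -5
  expect_error(ward_cluster(bad), "negative")
})

test_that("cutting the dendrogram recovers planted groups and edge cases", {
  # two well-separated blobs: within ~1, between ~100
  set.seed(8)
  n <- 8
  D <- matrix(100 + rnorm(n * n, 0, 2), n)
  lab <- sprintf("s%d", 1:n)
  dimnames(D) <- list(lab, lab)
  blob <- rep(1:2, each = 4)
  for (i in 1:n) for (j in 1:n) if (blob[i] == blob[j]) D[i, j] <- abs(rnorm(1, 1, 0.1))
  D <- (D + t(D)) / 2; diag(D) <- 0
  dend <- ward_cluster(D)
  # the final (highest) merge joins the two blobs
  expect_equal(dend$merge[n - 1L, ], sort(c(n - 2L, n - 3L)), ignore_attr = TRUE)
  cut2 <- cut_dendrogram(dend, 2)
  expect_equal(length(unique(cut2[blob == 1])), 1L)
  expect_equal(length(unique(cut2[blob == 2])), 1L)
  expect_false(cut2[1] == cut2[5])

  expect_equal(unname(cut_dendrogram(dend, 1)), rep(1L, n))
  expect_equal(length(unique(cut_dendrogram(dend, n))), n)
  expect_error(cut_dendrogram(dend, 0), "between")
  expect_error(cut_dendrogram(dend, n + 1), "between")
})

test_that("nucleotide distances follow the JC69 closed form with pairwise deletion", {
  mk_msa <- function(rows) structure(list(ids = names(rows), rows = rows,
                                          column_count = nchar(rows[1])),
                                     class = "crystal_msa")
  same <- mk_msa(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(unname(nuc_distance(same)["a", "b"]), 0)

  # p = 3/10 = 0.3 -> jc69 = -(3/4) ln(1 - 0.4) = 0.3831
  d_expected <- -0.75 * log(1 - 4 * 0.3 / 3)
  expect_equal(round(d_expected, 4), 0.3831)
  pair30 <- mk_msa(c(a = "ACGTACGTAC", b = "ACGTACGCGA"))  # 3 diffs in 10
  expect_equal(unname(nuc_distance(pair30)["a", "b"]), d_expected,
               tolerance = 1e-9)
  pair4 <- mk_msa(c(a = "AAATACGTAC", b = "ACGTACGTCA"))   # 4 diffs in 10
  expect_equal(unname(nuc_distance(pair4, model = "p_distance")["a", "b"]), 0.4)

  # ambiguity column excluded from numerator and denominator
  amb <- mk_msa(c(a = "ACGTN", b = "ACGTA"))
  expect_equal(unname(nuc_distance(amb, model = "p_distance")["a", "b"]), 0)
  gap <- mk_msa(c(a = "ACGT-", b = "ACGTA"))
  expect_equal(unname(nuc_distance(gap, model = "p_distance")["a", "b"]), 0)

  # saturation flagged under jc69
  sat <- mk_msa(c(a = "AAAAAAAAAA", b = "CCCCCCCCCC"))
  Ds <- nuc_distance(sat)
  expect_true(is.na(Ds["a", "b"]))
  expect_length(attr(Ds, "failed"), 1L)

  # first-order agreement with p as p -> 0
  tiny <- mk_msa(c(a = strrep("A", 10000), b = paste0("C", strrep("A", 9999))))
  expect_lt(abs(unname(nuc_distance(tiny)["a", "b"]) - 1e-4), 1e-6)
})

test_that("nucleotide distances match the ape reference on random alignments", {
  set.seed(77)
  nts <- c("A", "C", "G", "T")
  base <- sample(nts, 60, TRUE)
  rows <- vapply(1:5, function(i) {
    mut <- base
    hit <- sample(60, 12)
    mut[hit] <- sample(nts, 12, TRUE)
    paste(mut, collapse = "")
  }, character(1))
  names(rows) <- sprintf("t%d", 1:5)
  msa <- structure(list(ids = names(rows), rows = rows, column_count = 60L),
                   class = "crystal_msa")
  mine <- nuc_distance(msa)
  bin <- ape::as.DNAbin(t(sapply(rows, function(r) strsplit(r, "")[[1]])))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE))
  expect_equal(unclass(mine)[names(rows), names(rows)],
               ref[names(rows), names(rows)], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the three-taxon NJ tree follows the closed-form branch lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 1)   # (d_AB + d_AC - d_BC) / 2
  expect_equal(unname(bl["B"]), 1)
  expect_equal(unname(bl["C"]), 3)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers random additive trees (topology and lengths)", {
  for (seed in 1:12) {
    g <- gen_additive_matrix(sample(4:12, 1), seed = seed)
    tr <- nj_tree(g$D)
    patristic <- ape::cophenetic.phylo(tr)[rownames(g$D), colnames(g$D)]
    expect_equal(patristic, g$D, tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(g$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ topology agrees with the independent ape implementation", {
  set.seed(55)
  for (rep in 1:5) {
    D <- random_dissim(7, lo = 5, hi = 60)
    mine <- nj_tree(D)
    ref <- ape::nj(stats::as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports behave at the degenerate extremes", {
  rows <- c(t1 = strrep("AAC", 10), t2 = strrep("AAT", 10),
            t3 = strrep("AGC", 10), t4 = strrep("AGT", 10))
  msa <- structure(list(ids = names(rows), rows = rows, column_count = 30L),
                   class = "crystal_msa")
  # all codon units identical -> every resample is the same alignment
  tr <- bootstrap_supports(msa, replicates = 25, seed = 2, unit = "codon")
  expect_true(all(attr(tr, "supports") == 100))
  tr1 <- bootstrap_supports(msa, replicates = 1, seed = 3, unit = "column")
  expect_true(all(attr(tr1, "supports") %in% c(0, 100)))
  expect_error(bootstrap_supports(msa, replicates = 10), "seed")
})

test_that("a strongly supported internal edge reaches high bootstrap support", {
  fam <- gen_family(seq_spec(n_sequences = 4, mutation_rate = 0.08, seed = 37))
  cds <- gen_cds_for(fam$records, seed = 38)
  msa <- progressive_msa(fam$records)
  nt <- codon_thread(msa, cds)
  tr <- bootstrap_supports(nt, replicates = 100, seed = 9, unit = "codon")
  sup <- attr(tr, "supports")
  expect_length(sup, 1L)   # one internal edge on 4 taxa
  expect_gte(unname(sup[1]), 95)
})

test_that("bootstrap supports are invariant to leaf order", {
  fam <- gen_family(seq_spec(n_sequences = 5, mutation_rate = 0.08, seed = 41))
  cds <- gen_cds_for(fam$records, seed = 42)
  nt <- codon_thread(progressive_msa(fam$records), cds)
  perm <- rev(seq_along(nt$ids))
  nt_perm <- structure(list(ids = nt$ids[perm], rows = nt$rows[perm],
                            column_count = nt$column_count),
                       class = "crystal_msa")
  s1 <- attr(bootstrap_supports(nt, replicates = 50, seed = 7), "supports")
  s2 <- attr(bootstrap_supports(nt_perm, replicates = 50, seed = 7), "supports")
  expect_setequal(names(s1), names(s2))
  # identical seed resamples identical column sets, so supports match exactly
  expect_equal(s1[sort(names(s1))], s2[sort(names(s1))])
})

test_that("Newick output round-trips trees and dendrograms", {
  f <- withr::local_tempfile(fileext = ".nwk")
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  write_newick(tr, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-8)

  set.seed(6)
  big <- ape::rtree(20)
  write_newick(big, f)
  back2 <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(big), ape::unroot(back2)), 0,
               ignore_attr = TRUE)

  writeLines("(A,(B,C));", f)
  parsed <- read_newick(f)
  expect_equal(sort(parsed$tip.label), c("A", "B", "C"))
  expect_equal(parsed$Nnode, 2L)

  writeLines("(A,(B,C);", f)
  expect_error(read_newick(f), "parenthes")

  dend <- ward_cluster(random_dissim(5))
  write_newick(dend, f)
  expect_equal(sort(read_newick(f)$tip.label), sort(rownames(random_dissim(5))))
})
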