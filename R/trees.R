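# Hierarchical clustering (ward.D2), Neighbor-Joining with bootstrap, and
# Newick I/O.

#' Agglomerative ward.D2 clustering of a dissimilarity matrix
#'
#' Implements the ward.D2 criterion directly: the algorithm operates on
#' squared dissimilarities with the Lance-Williams update
#' \deqn{d(k, i \cup j)^2 = \frac{(n_i+n_k) d(k,i)^2 + (n_j+n_k) d(k,j)^2 - n_k d(i,j)^2}{n_i+n_j+n_k}}
#' and reports the (unsquared) dissimilarity at each merge as the height.
#' Ties are broken deterministically by the lexicographically smallest pair
#' of cluster representative labels. Heights are monotone non-decreasing.
#'
#' @param D Symmetric labeled dissimilarity matrix (zero diagonal, >= 2 rows).
#' @return An object of class `crystal_dendrogram`, structurally compatible
#'   with `hclust` (fields `merge`, `height`, `order`, `labels`), with a
#'   `merges` tibble attached.
#' @examples
#' D <- matrix(c(0, 10, 10, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' ward_cluster(D)$height  # 10
#' @export
ward_cluster <- function(D) {
  assert_distance_matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  D2 <- D^2
  sizes <- rep(1, n)
  # cluster ids in hclust convention: -i singleton, +step for merge results
  ids <- -seq_len(n)
  rep_label <- labels           # representative = smallest member label
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    best <- NULL; bestd <- Inf; bestkey <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        d2 <- D2[i, j]
        key <- paste(sort(c(rep_label[i], rep_label[j])), collapse = "\r")
        if (d2 < bestd - 1e-12 ||
            (abs(d2 - bestd) <= 1e-12 && !is.null(bestkey) && key < bestkey)) {
          bestd <- d2; best <- c(i, j); bestkey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    pr <- c(ids[i], ids[j])
    # hclust row convention: singletons first, then ascending by index/step
    key_of <- function(v) if (v < 0L) c(0L, -v) else c(1L, v)
    ka <- key_of(pr[1]); kb <- key_of(pr[2])
    if (ka[1] > kb[1] || (ka[1] == kb[1] && ka[2] > kb[2])) pr <- rev(pr)
    merge[step, ] <- pr
    height[step] <- sqrt(max(bestd, 0))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      upd <- ((ni + nk) * D2[k, i] + (nj + nk) * D2[k, j] - nk * D2[i, j]) /
        (ni + nj + nk)
      D2[k, i] <- D2[i, k] <- upd
    }
    sizes[i] <- ni + nj
    ids[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  # leaf order by recursive traversal of the merge tree
  ord_rec <- function(node) {
    if (node < 0L) return(-node)
    c(ord_rec(merge[node, 1L]), ord_rec(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = ord_rec(n - 1L), labels = labels,
                 method = "ward.D2", call = match.call(),
                 dist.method = "percent-dissimilarity"),
            class = "crystal_dendrogram")
}

#' @export
as.hclust.crystal_dendrogram <- function(x, ...) {
  structure(unclass(x), class = "hclust")
}

#' @export
print.crystal_dendrogram <- function(x, ...) {
  cat(sprintf("ward.D2 dendrogram: %d leaves, merge heights %.3g .. %.3g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' @rdname ward_cluster
#' @param x A `crystal_dendrogram`.
#' @param ... Unused.
#' @method tidy crystal_dendrogram
#' @export
tidy.crystal_dendrogram <- function(x, ...) {
  tibble(step = seq_along(x$height),
         cluster_a = x$merge[, 1], cluster_b = x$merge[, 2],
         height = x$height)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges; because ward.D2 merge heights are
#' monotone, this equals keeping the first n - k merges.
#'
#' @param dend A `crystal_dendrogram`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector mapping each leaf label to a cluster id
#'   (numbered by first appearance in leaf order).
#' @export
cut_dendrogram <- function(dend, k) {
  n <- length(dend$labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    abort(sprintf("`k` must be between 1 and %d", n))
  }
  k <- as.integer(k)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cl_of_step <- integer(n - 1L)
  for (step in seq_len(n - k)) {
    side <- function(v) if (v < 0L) find(-v) else find(cl_of_step[v])
    a <- side(dend$merge[step, 1L]); b <- side(dend$merge[step, 2L])
    parent[b] <- a
    cl_of_step[step] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- setNames(match(roots, unique(roots[dend$order])), dend$labels)
  ids
}

#' Pairwise nucleotide distances from a codon or nucleotide alignment
#'
#' For each pair of rows, pairwise deletion removes every column in which
#' either row carries a gap or an ambiguity (anything outside A/C/G/T); the
#' proportion of differing sites p is taken over the remaining columns.
#' `model = "p_distance"` reports p; `model = "jc69"` reports the
#' Jukes-Cantor distance \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3} p)}
#' (base substitutions per site). Pairs with p >= 0.75 under jc69 are
#' recorded as failures and flagged `NA`.
#'
#' @param aln A nucleotide `crystal_msa`.
#' @param model `"jc69"` (default) or `"p_distance"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Symmetric labeled distance matrix; an attribute `failed` lists
#'   any jc69-saturated pairs.
#' @export
nuc_distance <- function(aln, model = c("jc69", "p_distance"),
                         deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  chars <- do.call(rbind, strsplit(unname(aln$rows), ""))
  valid <- matrix(chars %in% c("A", "C", "G", "T"), nrow = nrow(chars))
  if (deletion == "complete") {
    keep <- apply(valid, 2L, all)
    chars <- chars[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- length(aln$ids)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  failed <- character()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      use <- valid[i, ] & valid[j, ]
      nv <- sum(use)
      if (nv == 0L) {
        warn(sprintf("no comparable sites for pair %s/%s", aln$ids[i], aln$ids[j]))
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
      p <- sum(chars[i, use] != chars[j, use]) / nv
      d <- if (model == "p_distance") p else {
        if (p >= 0.75) {
          failed <- c(failed, paste(aln$ids[i], aln$ids[j], sep = "/"))
          NA_real_
        } else -0.75 * log(1 - 4 * p / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "failed") <- failed
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei Neighbor-Joining: iteratively joins the pair minimizing
#' \eqn{Q(i,j) = (r-2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)} with the
#' standard branch-length formulas; for an additive matrix, topology and
#' branch lengths are recovered exactly. Ties are broken by the smallest
#' label pair. Negative branch-length estimates are clamped to zero for
#' output; the raw values are kept in the `raw_edge_length` attribute.
#'
#' @param D Symmetric labeled distance matrix, n >= 3.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  assert_distance_matrix(D)
  n0 <- nrow(D)
  if (n0 < 3L) abort("Neighbor-Joining requires at least 3 taxa")
  labels <- rownames(D)
  # subtree newick fragments (without trailing length)
  frag <- labels
  act <- seq_len(n0)
  M <- D
  fmt <- function(x) sprintf("%.10g", x)
  while (length(act) > 3L) {
    r <- length(act)
    rs <- rowSums(M[act, act])
    bestQ <- Inf; best <- NULL; bestkey <- NULL
    for (ii in seq_len(r - 1L)) {
      for (jj in seq(ii + 1L, r)) {
        i <- act[ii]; j <- act[jj]
        Q <- (r - 2) * M[i, j] - rs[ii] - rs[jj]
        key <- paste(sort(c(labels[i], labels[j])), collapse = "\r")
        if (Q < bestQ - 1e-12 ||
            (abs(Q - bestQ) <= 1e-12 && !is.null(bestkey) && key < bestkey)) {
          bestQ <- Q; best <- c(i, j); bestkey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    ri <- sum(M[i, act]); rj <- sum(M[j, act])
    li <- M[i, j] / 2 + (ri - rj) / (2 * (r - 2))
    lj <- M[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    for (k in act) {
      if (k == i || k == j) next
      M[i, k] <- M[k, i] <- (M[i, k] + M[j, k] - M[i, j]) / 2
    }
    frag[i] <- new_frag
    labels[i] <- min(labels[i], labels[j])
    act <- setdiff(act, j)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- (M[a, b] + M[a, c3] - M[b, c3]) / 2
  lb <- (M[a, b] + M[b, c3] - M[a, c3]) / 2
  lc <- (M[a, c3] + M[b, c3] - M[a, b]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[a], fmt(la), frag[b], fmt(lb), frag[c3], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  attr(tree, "raw_edge_length") <- raw
  tree
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys.
# Each internal edge splits the leaves; the side not containing the
# alphabetically first leaf is the key.
tree_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  # postorder: process edges so children are complete before parents
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  for (k in rev(seq_len(nrow(edges)))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character()
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    if (ch <= nt) next
    side <- sort(desc[[ch]])
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2L || length(side) > nt - 2L) next
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a Neighbor-Joining tree
#'
#' Resamples alignment units (single columns or codon triples) with
#' replacement, rebuilds the distance matrix and NJ tree for each replicate,
#' and reports for each internal edge of the full-data tree the percentage
#' of replicates whose tree contains the same bipartition. The resampling
#' unit defaults to the codon since crystallin nucleotide alignments are
#' codon-threaded.
#'
#' @param aln Nucleotide `crystal_msa`.
#' @param model,deletion Passed to [nuc_distance()].
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (required; resampling is the only stochastic step).
#' @param unit `"codon"` (default) or `"column"`.
#' @return The full-data `phylo` tree with `node.label` carrying supports
#'   (percent; root label empty) and a `supports` attribute mapping
#'   bipartition keys to percentages.
#' @export
bootstrap_supports <- function(aln, model = "jc69", deletion = "pairwise",
                               replicates = 100L, seed, unit = c("codon", "column")) {
  unit <- match.arg(unit)
  if (missing(seed)) abort("`seed` is required for bootstrap resampling")
  if (!is.numeric(replicates) || replicates < 1L) {
    abort("`replicates` must be >= 1")
  }
  L <- aln$column_count
  if (unit == "codon" && L %% 3L != 0L) {
    abort("codon resampling requires an alignment length divisible by 3")
  }
  full_D <- nuc_distance(aln, model = model, deletion = deletion)
  if (any(is.na(full_D))) abort("full-data distance matrix contains undefined entries")
  full_tree <- nj_tree(full_D)
  target <- tree_bipartitions(full_tree)
  hits <- setNames(numeric(length(target)), target)
  n_units <- if (unit == "codon") L %/% 3L else L
  chars <- do.call(rbind, strsplit(unname(aln$rows), ""))
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      take <- sample.int(n_units, n_units, replace = TRUE)
      cols <- if (unit == "codon") {
        as.vector(vapply(take, function(u) (3L * (u - 1L)) + 1:3, integer(3)))
      } else take
      rows <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      rep_aln <- new_msa(aln$ids, rows)
      Dr <- tryCatch(nuc_distance(rep_aln, model = model, deletion = deletion),
                     warning = function(w) NULL, error = function(e) NULL)
      if (is.null(Dr) || any(is.na(Dr))) next
      bp <- tree_bipartitions(nj_tree(Dr))
      found <- target %in% bp
      hits[found] <- hits[found] + 1
    }
  })
  supports <- 100 * hits / replicates
  # attach node labels: map each internal node's bipartition to its support
  nt <- length(full_tree$tip.label)
  labs <- rep("", full_tree$Nnode)
  desc_keys <- tree_bipartitions_by_node(full_tree)
  for (nd in seq_len(full_tree$Nnode)) {
    key <- desc_keys[[nd]]
    if (!is.na(key) && key %in% names(supports)) {
      labs[nd] <- sprintf("%g", supports[[key]])
    }
  }
  full_tree$node.label <- labs
  attr(full_tree, "supports") <- supports
  full_tree
}

# Bipartition key for each internal node (NA for trivial/root splits).
tree_bipartitions_by_node <- function(tree) {
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  for (k in rev(seq_len(nrow(edges)))) {
    desc[[edges[k, 1]]] <- c(desc[[edges[k, 1]]], desc[[edges[k, 2]]])
  }
  out <- vector("list", tree$Nnode)
  for (nd in seq_len(tree$Nnode)) {
    side <- sort(desc[[nt + nd]])
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    out[[nd]] <- if (length(side) < 2L || length(side) > nt - 2L) NA_character_ else
      paste(side, collapse = "|")
  }
  out
}

#' Write a tree or dendrogram to Newick
#'
#' @param tree An `ape::phylo` or `crystal_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "crystal_dendrogram")) {
    tree <- ape::as.phylo(stats::as.hclust(tree))
  }
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo or crystal_dendrogram")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  bal <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                       ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (any(bal < 0L) || utils::tail(bal, 1L) != 0L) {
    pos <- if (any(bal < 0L)) which(bal < 0L)[1] else nchar(txt)
    abort(sprintf("unbalanced parentheses in Newick input near position %d", pos))
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) abort("failed to parse Newick input")
  tree
}
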