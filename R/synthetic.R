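# Seeded synthetic-data generators: sequence families with controlled
# Cys/Met composition, matching coding sequences, additive distance
# matrices, and toy structures with analytically known SASA. Every
# generator is deterministic under its seed and emits a ground-truth object
# alongside the data.

#' Specification for a synthetic sequence family
#'
#' @param n_sequences Number of sequences.
#' @param length_mean,length_sd,length_bounds Ancestral length distribution
#'   (normal, truncated to `length_bounds`).
#' @param cys_fraction,met_fraction Target Cys and Met composition of the
#'   family (fractions of residues).
#' @param motif Optional list `list(pattern =, position =)`: a residue
#'   pattern written into the ancestor at a fixed position and protected
#'   from substitution (e.g. a DCDCD loop).
#' @param mutation_rate Per-site substitution probability per unit branch
#'   length.
#' @param indel_rate Per-branch probability of one block deletion; deletions
#'   are placed only at 10-residue block boundaries so "domains" stay
#'   intact.
#' @param indel_len Length of a deleted block.
#' @param seed Mandatory integer seed.
#' @return A `seq_gen_spec` list.
#' @export
seq_spec <- function(n_sequences = 20L, length_mean = 174, length_sd = 6,
                     length_bounds = c(80L, 200L),
                     cys_fraction = 0.05, met_fraction = 0.05,
                     motif = NULL, mutation_rate = 0.05, indel_rate = 0,
                     indel_len = 5L, seed) {
  if (missing(seed)) abort("`seed` is mandatory for the sequence generator")
  if (cys_fraction < 0 || met_fraction < 0 ||
      cys_fraction + met_fraction >= 1) {
    abort("infeasible composition targets: fractions must be in [0,1) and sum below 1")
  }
  if (n_sequences < 1L) abort("`n_sequences` must be >= 1")
  structure(list(n_sequences = as.integer(n_sequences),
                 length_mean = length_mean, length_sd = length_sd,
                 length_bounds = as.integer(length_bounds),
                 cys_fraction = cys_fraction, met_fraction = met_fraction,
                 motif = motif, mutation_rate = mutation_rate,
                 indel_rate = indel_rate, indel_len = as.integer(indel_len),
                 seed = as.integer(seed)),
            class = "seq_gen_spec")
}

# Draw one residue set with the target composition.
target_composition_chars <- function(L, cys_fraction, met_fraction) {
  n_cys <- round(L * cys_fraction)
  n_met <- round(L * met_fraction)
  background <- setdiff(AA20, c("C", "M"))
  chars <- c(rep("C", n_cys), rep("M", n_met),
             sample(background, L - n_cys - n_met, replace = TRUE))
  sample(chars)
}

#' Generate a synthetic protein family with known history
#'
#' Builds an ancestral sequence with the spec's exact Cys/Met composition
#' (plus an optional protected motif), evolves it down a random binary tree
#' with per-site substitutions drawn from the target composition
#' distribution (so composition is preserved in expectation; this is a
#' composition-preserving toy process, not a named evolutionary model), and
#' applies optional block deletions at 10-residue boundaries.
#'
#' @param spec A [seq_spec()].
#' @return A list with `records` (tibble `id`, `description`, `seq`,
#'   `moltype`) and `truth` (ancestor, the `phylo` tree, per-tip event
#'   counts and indel positions).
#' @export
gen_family <- function(spec) {
  stopifnot(inherits(spec, "seq_gen_spec"))
  with_seed(spec$seed, {
    L <- round(rnorm(1, spec$length_mean, spec$length_sd))
    L <- max(spec$length_bounds[1], min(spec$length_bounds[2], L))
    chars <- target_composition_chars(L, spec$cys_fraction, spec$met_fraction)
    protected <- integer()
    if (!is.null(spec$motif)) {
      pat <- strsplit(toupper(spec$motif$pattern), "")[[1]]
      pos <- spec$motif$position
      if (pos < 1L || pos + length(pat) - 1L > L) {
        abort("motif does not fit inside the ancestral sequence")
      }
      idx <- seq(pos, pos + length(pat) - 1L)
      chars[idx] <- pat
      protected <- idx
    }
    ancestor <- paste(chars, collapse = "")
    n <- spec$n_sequences
    if (n == 1L) {
      tree <- NULL
      tips <- list(list(seq = chars, nsub = 0L, indels = integer()))
      names(tips) <- "seq01"
    } else {
      tree <- ape::rtree(n, tip.label = sprintf("seq%02d", seq_len(n)))
      nt <- n
      children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
      tips <- list()
      bg_prob <- setNames(rep((1 - spec$cys_fraction - spec$met_fraction) / 18, 20), AA20)
      bg_prob["C"] <- spec$cys_fraction
      bg_prob["M"] <- spec$met_fraction
      evolve <- function(node, chars, nsub, indels) {
        for (e in children[[as.character(node)]] %||% integer()) {
          child <- tree$edge[e, 2]
          bl <- tree$edge.length[e]
          p <- min(1, spec$mutation_rate * bl / mean(tree$edge.length))
          hit <- which(runif(length(chars)) < p)
          hit <- setdiff(hit, protected)
          new_chars <- chars
          if (length(hit) > 0L) {
            new_chars[hit] <- sample(AA20, length(hit), replace = TRUE,
                                     prob = bg_prob)
          }
          new_indels <- indels
          if (spec$indel_rate > 0 && runif(1) < spec$indel_rate) {
            starts <- seq(11L, length(new_chars) - spec$indel_len, by = 10L)
            starts <- setdiff(starts, protected)
            if (length(starts) > 0L) {
              s <- sample(starts, 1L)
              new_chars <- new_chars[-seq(s, s + spec$indel_len - 1L)]
              new_indels <- c(new_indels, s)
            }
          }
          if (child <= nt) {
            tips[[tree$tip.label[child]]] <<- list(seq = new_chars,
                                                   nsub = nsub + length(hit),
                                                   indels = new_indels)
          } else {
            evolve(child, new_chars, nsub + length(hit), new_indels)
          }
        }
      }
      evolve(nt + 1L, chars, 0L, integer())
      tips <- tips[tree$tip.label]
    }
    records <- tibble(id = names(tips),
                      description = "synthetic crystallin-like sequence",
                      seq = unname(vapply(tips, function(t)
                        paste(t$seq, collapse = ""), character(1))),
                      moltype = "protein")
    truth <- list(ancestor = ancestor, tree = tree,
                  events = tibble(id = names(tips),
                                  substitutions = vapply(tips, `[[`, integer(1), "nsub"),
                                  indel_starts = lapply(tips, `[[`, "indels")))
    list(records = records, truth = truth)
  })
}

#' Generate coding sequences consistent with protein records
#'
#' Assigns each residue a synonymous codon drawn uniformly from the standard
#' genetic code, so translating the output recovers the input protein
#' exactly.
#'
#' @param records Tibble of protein records (`id`, `seq`).
#' @param seed Integer seed.
#' @return Named character vector of CDS (length 3 x protein length, no
#'   stop codon).
#' @export
gen_cds_for <- function(records, seed) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  with_seed(seed, {
    out <- vapply(seq_len(nrow(records)), function(i) {
      chars <- strsplit(toupper(records$seq[i]), "")[[1]]
      bad <- setdiff(unique(chars), AA20)
      if (length(bad) > 0L) {
        abort(sprintf("non-canonical residue(s) in '%s': %s",
                      records$id[i], paste(bad, collapse = ", ")))
      }
      paste(vapply(chars, function(a) {
        cods <- by_aa[[a]]
        cods[sample.int(length(cods), 1L)]
      }, character(1)), collapse = "")
    }, character(1))
    setNames(out, records$id)
  })
}

#' Generate a random additive distance matrix with its tree
#'
#' Draws a random topology with branch lengths uniform in `[0.01, 1]` and
#' returns the exact path-length (additive) distance matrix, the oracle for
#' Neighbor-Joining recovery: NJ reconstructs the topology and branch
#' lengths of an additive matrix exactly.
#'
#' @param n_leaves Number of leaves (>= 4).
#' @param seed Integer seed.
#' @return List with `tree` (unrooted `phylo`) and `D` (labeled matrix).
#' @export
gen_additive_matrix <- function(n_leaves, seed) {
  if (n_leaves < 4L) abort("`n_leaves` must be >= 4")
  with_seed(seed, {
    tree <- ape::rtree(n_leaves, tip.label = sprintf("t%02d", seq_len(n_leaves)),
                       br = function(k) runif(k, 0.01, 1))
    tree <- ape::unroot(tree)
    D <- ape::cophenetic.phylo(tree)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    list(tree = tree, D = D)
  })
}

#' Specification for a toy structure
#'
#' @param kind One of `"single_atom"`, `"sphere_pair"`, `"shell_buried_cys"`,
#'   `"helix_peptide"`.
#' @param separation Centre distance (Angstrom) for `sphere_pair`.
#' @param shell_radius Shell radius (Angstrom) for `shell_buried_cys`.
#' @param n_shell Number of shell atoms.
#' @param buried For `shell_buried_cys`: put the Cys inside the shell
#'   (`TRUE`) or well outside it (`FALSE`).
#' @param cys_resno Residue number given to the Cys.
#' @param sequence Residue string for `helix_peptide`.
#' @param seed Integer seed.
#' @return A `struct_gen_spec` list.
#' @export
struct_spec <- function(kind = c("single_atom", "sphere_pair",
                                 "shell_buried_cys", "helix_peptide"),
                        separation = 10, shell_radius = 4.5, n_shell = 150L,
                        buried = TRUE, cys_resno = 1L,
                        sequence = "ACDEFGHIK", seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, separation = separation,
                 shell_radius = shell_radius, n_shell = as.integer(n_shell),
                 buried = buried, cys_resno = as.integer(cys_resno),
                 sequence = sequence, seed = as.integer(seed)),
            class = "struct_gen_spec")
}

# Deterministic, nearly uniform points on a sphere (golden spiral).
fibonacci_sphere <- function(n, radius = 1) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  cbind(x = radius * r * cos(phi), y = radius * r * sin(phi), z = radius * z)
}

#' Generate a toy structure with known exposure truth
#'
#' `single_atom` gives one carbon with analytic SASA
#' \eqn{4\pi(r + probe)^2}; `sphere_pair` gives two carbons at a set
#' separation (analytic two-sphere solution); `shell_buried_cys` gives a
#' cysteine sulfur either enclosed by a carbon shell (truth: buried) or far
#' outside it (truth: exposed); `helix_peptide` gives an ideal alpha-helix
#' CA trace of a sequence.
#'
#' @param spec A [struct_spec()].
#' @return List with `model` (a `crystal_structure`) and `truth`
#'   (kind-specific labels).
#' @export
gen_structure <- function(spec) {
  stopifnot(inherits(spec, "struct_gen_spec"))
  atom <- function(serial, element, atom_name, residue_name, resno, x, y, z) {
    tibble(serial = serial, element = element, atom_name = atom_name,
           residue_name = residue_name, residue_number = as.integer(resno),
           chain = "A", x = x, y = y, z = z, occupancy = 1)
  }
  out <- switch(spec$kind,
    single_atom = {
      model <- new_structure(atom(1L, "C", "CA", "GLY", 1L, 0, 0, 0))
      list(model = model, truth = list(analytic_sasa = 4 * pi * (1.70 + 1.4)^2))
    },
    sphere_pair = {
      d <- spec$separation
      model <- new_structure(dplyr::bind_rows(
        atom(1L, "C", "CA", "GLY", 1L, 0, 0, 0),
        atom(2L, "C", "CA", "GLY", 2L, d, 0, 0)))
      R <- 1.70 + 1.4
      iso <- 4 * pi * R^2
      analytic <- if (d >= 2 * R) c(iso, iso) else {
        # equal spheres: buried cap height h = R - d/2 on each
        h <- R - d / 2
        rep(iso - 2 * pi * R * h, 2L)
      }
      list(model = model, truth = list(analytic_sasa = analytic, separation = d))
    },
    shell_buried_cys = {
      shell <- fibonacci_sphere(spec$n_shell, spec$shell_radius)
      cys_pos <- if (spec$buried) c(0, 0, 0) else
        c(spec$shell_radius + 8, 0, 0)
      atoms <- dplyr::bind_rows(
        atom(1L, "S", "SG", "CYS", spec$cys_resno,
             cys_pos[1], cys_pos[2], cys_pos[3]),
        atom(seq_len(spec$n_shell) + 1L, "C", "CA", "ALA",
             spec$cys_resno + seq_len(spec$n_shell),
             shell[, 1], shell[, 2], shell[, 3]))
      list(model = new_structure(atoms),
           truth = list(buried = spec$buried, cys_resno = spec$cys_resno))
    },
    helix_peptide = {
      chars <- strsplit(assert_protein_seq(spec$sequence, allow_x = FALSE), "")[[1]]
      aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
               G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
               M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
               S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
      i <- seq_along(chars)
      theta <- (i - 1) * 100 * pi / 180
      atoms <- atom(i, "C", "CA", unname(aa3[chars]), i,
                    2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
      list(model = new_structure(atoms), truth = list(sequence = spec$sequence))
    })
  out
}
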