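#' Per-residue refractive index increment table
#'
#' Loads the packaged table of amino-acid residue refractive index increments
#' (dn/dc, mL/g) and residue masses (free amino acid minus one water, g/mol).
#' The increments are the standard literature values for the 20 canonical
#' residues; the table is shipped as a plain TSV so it can be swapped for an
#' alternative calibration.
#'
#' @param path Optional path to an alternative TSV with columns
#'   `residue`, `dndc_mL_per_g`, `mass_g_per_mol`, `source`.
#' @return A tibble with one row per canonical residue.
#' @export
residue_refractivity_table <- function(path = NULL) {
  if (is.null(path)) path <- crystkit_extdata("residue_refractivity.tsv")
  tab <- readr::read_tsv(path, col_types = readr::cols(
    residue = "c", dndc_mL_per_g = "d", mass_g_per_mol = "d", source = "c"))
  missing <- setdiff(AA20, tab$residue)
  if (length(missing) > 0L) {
    abort(sprintf("refractivity table is missing residue(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(tab$dndc_mL_per_g <= 0) || any(tab$mass_g_per_mol <= 0)) {
    abort("refractivity table must have positive dn/dc and mass values")
  }
  tab
}

#' dn/dc of a single residue
#'
#' @param residue Canonical one-letter code.
#' @param table Refractivity table, default the packaged one.
#' @return dn/dc in mL/g.
#' @examples
#' residue_dndc("R")  # 0.206
#' residue_dndc("K")  # 0.181
#' @export
residue_dndc <- function(residue, table = residue_refractivity_table()) {
  if (!is.character(residue) || length(residue) != 1L ||
      !(toupper(residue) %in% table$residue)) {
    abort(sprintf("unknown residue code: %s", as.character(residue)[1]))
  }
  table$dndc_mL_per_g[match(toupper(residue), table$residue)]
}

#' Additive (Gladstone-Dale) protein refractive index increment
#'
#' Models the protein dn/dc as the mass-fraction-weighted average of its
#' residues' increments: with \eqn{w_i} the mass fraction of residue type
#' \eqn{i} (residue mass = free amino acid minus one water),
#' \eqn{dn/dc = \sum_i w_i (dn/dc)_i}. This additive model ignores hydration
#' differences and interactions between aromatic pairs; an optional additive
#' correction per aromatic pair within a sequence window is available via
#' `pair_coef` (off by default, since no standard coefficient exists).
#'
#' @param seq Protein sequence (one-letter codes).
#' @param table Refractivity table.
#' @param ignore_unknown If `TRUE`, `X` residues are dropped from both
#'   numerator and denominator (with a warning); otherwise `X` is an error.
#' @param pair_coef Optional additive dn/dc increment (mL/g) applied once per
#'   aromatic pair (F/W/Y) whose sequence separation is at most
#'   `pair_window`; `NULL` disables the correction.
#' @param pair_window Sequence-distance window for the pair correction.
#' @return A list of class `protein_refractivity` with `dndc` (mL/g),
#'   `mass_fractions` (named numeric, sums to 1), and `n_residues`.
#' @examples
#' protein_dndc(strrep("R", 25))$dndc  # 0.206
#' @export
protein_dndc <- function(seq, table = residue_refractivity_table(),
                         ignore_unknown = FALSE,
                         pair_coef = NULL, pair_window = 8L) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  if (any(chars == "X")) {
    if (!isTRUE(ignore_unknown)) {
      abort("sequence contains X; set `ignore_unknown = TRUE` to drop unknown residues")
    }
    warn(sprintf("dropping %d unknown (X) residue(s) from dn/dc calculation",
                 sum(chars == "X")))
    chars <- chars[chars != "X"]
  }
  if (length(chars) == 0L) abort("no canonical residues left in sequence")
  counts <- table(factor(chars, levels = table$residue))
  mass <- as.numeric(counts) * table$mass_g_per_mol
  w <- mass / sum(mass)
  dndc <- sum(w * table$dndc_mL_per_g)
  if (!is.null(pair_coef)) {
    arom <- which(chars %in% c("F", "W", "Y"))
    n_pairs <- 0L
    if (length(arom) > 1L) {
      d <- outer(arom, arom, function(a, b) abs(a - b))
      n_pairs <- sum(d[upper.tri(d)] <= pair_window)
    }
    dndc <- dndc + pair_coef * n_pairs
  }
  structure(list(dndc = dndc,
                 mass_fractions = setNames(w, table$residue),
                 n_residues = length(chars)),
            class = "protein_refractivity")
}

#' @export
print.protein_refractivity <- function(x, ...) {
  cat(sprintf("Gladstone-Dale protein refractivity: dn/dc = %.4f mL/g (%d residues)\n",
              x$dndc, x$n_residues))
  invisible(x)
}

#' @rdname protein_dndc
#' @param x A `protein_refractivity` object.
#' @param ... Unused.
#' @method tidy protein_refractivity
#' @export
tidy.protein_refractivity <- function(x, ...) {
  tibble(residue = names(x$mass_fractions),
         mass_fraction = as.numeric(x$mass_fractions))
}

#' @rdname protein_dndc
#' @method glance protein_refractivity
#' @export
glance.protein_refractivity <- function(x, ...) {
  tibble(dndc = x$dndc, n_residues = x$n_residues)
}

#' Refractivity report for a set of protein records
#'
#' @param records Tibble of protein records (`id`, `seq`).
#' @param ... Passed to [protein_dndc()].
#' @return A tibble with `id`, `length`, `dndc`.
#' @export
refractivity_report <- function(records, ...) {
  purrr::pmap_dfr(list(records$id, records$seq), function(id, seq) {
    r <- protein_dndc(seq, ...)
    tibble(id = id, length = nchar(seq), dndc = r$dndc)
  })
}
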