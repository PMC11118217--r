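#' Count occurrences of a residue in a protein sequence
#'
#' When `mature = TRUE`, the initiator methionine is excluded: if the residue
#' being counted is `M` and the sequence starts with `M`, position 1 is not
#' counted, matching the convention that initiator methionines are cleaved
#' from mature eukaryotic proteins. Percent denominators elsewhere still use
#' the full stored length, which is the convention of the packaged survey
#' table.
#'
#' @param seq Protein sequence (one-letter codes).
#' @param residue Single canonical one-letter code.
#' @param mature Exclude an initiator Met from the count?
#' @return Integer count.
#' @examples
#' count_residue("MAMC", "M", mature = TRUE)  # 1
#' @export
count_residue <- function(seq, residue, mature = FALSE) {
  seq <- assert_protein_seq(seq)
  if (!is.character(residue) || length(residue) != 1L ||
      !(toupper(residue) %in% AA20)) {
    abort("`residue` must be one of the 20 canonical one-letter codes.")
  }
  residue <- toupper(residue)
  n <- stringr::str_count(seq, stringr::fixed(residue))
  if (isTRUE(mature) && residue == "M" && startsWith(seq, "M")) n <- n - 1L
  as.integer(n)
}

#' Per-protein amino-acid composition statistics
#'
#' Computes, for each protein record, the Cys and Met counts and percentages
#' (1 decimal, round-half-to-even), the Lys/Arg count ratio, and the Ala/Cys
#' count ratio (3 decimals). Ratios with a zero denominator are reported as
#' `NA`. With `mature = TRUE` an initiator Met is excluded from the Met count
#' while percentages keep the full length as denominator.
#'
#' @param records Tibble of protein records (`id`, `seq`), or a single record
#'   row.
#' @param mature Exclude initiator methionines from Met counts?
#' @return A tibble with one row per record: `id`, `length`, `cys_count`,
#'   `cys_pct`, `met_count`, `met_pct`, `kr_ratio`, `ala_cys_ratio`.
#' @examples
#' recs <- tibble::tibble(id = "toy", seq = strrep("ACDM", 10))
#' composition_row(recs)
#' @export
composition_row <- function(records, mature = TRUE) {
  if (nrow(records) == 0L) abort("`records` is empty.")
  purrr::pmap_dfr(list(records$id, records$seq), function(id, seq) {
    seq <- assert_protein_seq(seq)
    len <- nchar(seq)
    cys <- count_residue(seq, "C")
    met <- count_residue(seq, "M", mature = mature)
    lys <- count_residue(seq, "K")
    arg <- count_residue(seq, "R")
    ala <- count_residue(seq, "A")
    tibble(id = id, length = len,
           cys_count = cys, cys_pct = round(cys / len * 100, 1),
           met_count = met, met_pct = round(met / len * 100, 1),
           kr_ratio = if (arg > 0) round(lys / arg, 3) else NA_real_,
           ala_cys_ratio = if (cys > 0) round(ala / cys, 3) else NA_real_)
  })
}

#' Full residue composition of a protein sequence
#'
#' @param seq Protein sequence.
#' @param mature Exclude an initiator Met?
#' @return Named integer vector over the 20 canonical residues.
#' @export
residue_counts <- function(seq, mature = FALSE) {
  seq <- assert_protein_seq(seq, allow_x = FALSE)
  counts <- vapply(AA20, function(a) count_residue(seq, a, mature = mature),
                   integer(1))
  counts
}

#' Group mean Cys and Met percentages
#'
#' Unweighted arithmetic mean of per-protein Cys and Met percentages within a
#' subfamily block, rounded to 1 decimal. Works on the packaged survey table
#' (columns `block`, `cys_pct`, `met_pct`) or on [composition_row()] output
#' joined with a `block` column.
#'
#' @param tab Tibble with columns `block`, `cys_pct`, `met_pct`.
#' @param group Optional single block name; default summarizes every block.
#' @return A tibble with `group`, `n`, `mean_cys_pct`, `mean_met_pct`.
#' @examples
#' group_means(load_table1_fixture(), "gammaM")
#' @export
group_means <- function(tab, group = NULL) {
  if (!all(c("block", "cys_pct", "met_pct") %in% names(tab))) {
    abort("`tab` must have columns block, cys_pct, met_pct.")
  }
  if (!is.null(group)) {
    tab <- dplyr::filter(tab, .data$block == group)
    if (nrow(tab) == 0L) abort(sprintf("group '%s' is empty", group))
  }
  dplyr::summarise(dplyr::group_by(tab, group = .data$block),
    n = dplyr::n(),
    mean_cys_pct = round(mean(.data$cys_pct), 1),
    mean_met_pct = round(mean(.data$met_pct), 1),
    .groups = "drop")
}

#' Render a decimal ratio in "1:n" style
#'
#' @param ratio A decimal quotient such as a Lys/Arg count ratio.
#' @param digits Decimals for the right-hand side.
#' @return Character like `"1:4"`.
#' @export
format_one_to <- function(ratio, digits = 1) {
  if (is.na(ratio) || ratio <= 0) return(NA_character_)
  sprintf("1:%s", format(round(1 / ratio, digits)))
}
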