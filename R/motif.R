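# Asp-Cys (DCDCDC) loop detection and gammaS-like vs gammaD-like
# subfamily classification.

#' Find Asp-Cys pairs in an N-terminal window
#'
#' Counts non-overlapping `DC` residue pairs in positions `1..window_end`,
#' scanning left to right, so the canonical gammaS cysteine-loop signature
#' `DCDCDC` yields 3 pairs. Positions are 1-based indices of each pair's
#' Asp, in the numbering that counts Met1 as residue 1.
#'
#' @param seq Protein sequence.
#' @param window_end Last residue of the search window (>= 2, at most the
#'   sequence length; longer values are truncated to the length).
#' @return A list of class `motif_hit`: `positions`, `dc_pair_count`,
#'   `window`.
#' @examples
#' find_dc_pairs("AADCDCDCAA", 10)$dc_pair_count  # 3
#' @export
find_dc_pairs <- function(seq, window_end = 90L) {
  seq <- assert_protein_seq(seq)
  if (!is.numeric(window_end) || window_end < 2L) {
    abort("`window_end` must be at least 2")
  }
  window_end <- min(as.integer(window_end), nchar(seq))
  win <- substr(seq, 1L, window_end)
  m <- gregexpr("DC", win, fixed = TRUE)[[1]]
  positions <- if (m[1] == -1L) integer() else as.integer(m)
  structure(list(positions = positions,
                 dc_pair_count = length(positions),
                 window = c(start = 1L, end = window_end)),
            class = "motif_hit")
}

#' @export
print.motif_hit <- function(x, ...) {
  cat(sprintf("DC pairs in window %d..%d: %d at [%s]\n",
              x$window[1], x$window[2], x$dc_pair_count,
              paste(x$positions, collapse = ", ")))
  invisible(x)
}

#' Classify a crystallin as gammaS-like or gammaD-like
#'
#' Rule-based subfamily call from the N-terminal Asp-Cys signature:
#' gammaS-crystallins generally carry at least two DC pairs (the DCDCD
#' loop region around C23/C25/C27 in human gammaS), while gammaD-like
#' crystallins lack it. A record is `gammaS_like` when its DC-pair count in
#' the window reaches `threshold`; otherwise it is `gammaD_like` if long
#' enough to be a four-Greek-key two-domain protein, else `unclassified`.
#'
#' @param records Tibble of protein records (`id`, `seq`).
#' @param threshold Minimum DC pairs for a gammaS-like call (default 2).
#' @param window_end N-terminal window (default 90 residues, covering the
#'   NTD of ~174-183-residue gamma-crystallins).
#' @param min_two_domain_len Minimum length to call a protein two-domain
#'   (default 140 residues).
#' @return A tibble with `id`, `dc_pair_count`, `positions` (list column),
#'   `call`.
#' @export
classify_subfamily <- function(records, threshold = 2L, window_end = 90L,
                               min_two_domain_len = 140L) {
  purrr::pmap_dfr(list(records$id, records$seq), function(id, seq) {
    hit <- find_dc_pairs(seq, window_end = window_end)
    call <- if (hit$dc_pair_count >= threshold) "gammaS_like"
      else if (nchar(seq) >= min_two_domain_len) "gammaD_like"
      else "unclassified"
    tibble(id = id, dc_pair_count = hit$dc_pair_count,
           positions = list(hit$positions), call = call)
  })
}

#' Tally domain-exposure classes and exceptions
#'
#' Summarizes an [exposure_report()]: how many proteins expose cysteines in
#' the NTD only, the CTD only, neither, or both. Proteins classified "both"
#' break the one-exposed-domain pattern and are listed as exceptions.
#'
#' @param reports An `exposure_report` tibble (needs `id`,
#'   `exposure_class`).
#' @return A list with `counts` (tibble class/n) and `exceptions`
#'   (character vector of ids classified `"both"`).
#' @export
exclusivity_test <- function(reports) {
  if (nrow(reports) < 1L) abort("need at least one exposure report")
  counts <- dplyr::count(as_tibble(reports),
                         exposure_class = factor(.data$exposure_class,
                           levels = c("NTD", "CTD", "both", "neither")),
                         .drop = FALSE)
  list(counts = as_tibble(counts),
       exceptions = reports$id[reports$exposure_class == "both"])
}
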