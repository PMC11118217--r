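#' Read sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of sequence records, one row per entry,
#' in file order. The first whitespace-delimited token of each header becomes
#' the record `id`; the remainder is kept as `description`.
#'
#' @param path Path to a FASTA file.
#' @param moltype Either `"protein"` or `"cds"`; stored on every record.
#' @return A tibble with columns `id`, `description`, `seq`, `moltype`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">CRYGS_HUMAN test", "GKITLYE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, moltype = c("protein", "cds")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warn(sprintf("FASTA file is empty: %s", path))
    return(tibble(id = character(), description = character(),
                  seq = character(), moltype = character()))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("malformed FASTA: line %d is sequence data before any '>' header", first))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  tibble(id = unname(id), description = unname(desc),
         seq = unname(as.character(set)), moltype = moltype)
}

#' Write sequence records to a FASTA file
#'
#' Writes standard FASTA with 60-column sequence wrapping. Inverse of
#' [read_fasta()] on well-formed records.
#'
#' @param records Tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) abort("`records` must contain at least one sequence.")
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate sequence id(s): %s", paste(dup, collapse = ", ")))
  }
  headers <- records$id
  desc <- records[["description"]]
  if (!is.null(desc)) {
    has_desc <- !is.na(desc) & nzchar(desc)
    headers[has_desc] <- paste(records$id[has_desc], desc[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Filter crystallin records by length and name patterns
#'
#' Operationalizes the dataset inclusion rule used for crystallin surveys:
#' complete double-Greek-key crystallins fall in a length window (the
#' single-domain tunicate protein, 84 residues, at the low end; four-domain
#' gamma-crystallins around 174-183 residues), while truncated fragments and
#' non-lens homologs such as AIM-1 are excluded by length and name pattern.
#'
#' @param records Tibble of protein records (`id`, `seq`, optionally
#'   `description`/`protein_name`).
#' @param min_len,max_len Inclusive residue-length window (defaults 80-200).
#' @param exclude_patterns Character vector of name substrings; a record whose
#'   id, description, or protein name contains any pattern is excluded.
#' @return A list with `kept` (tibble) and `excluded` (tibble with a
#'   machine-readable `reason` column: `"truncated"`, `"overlong"`, or
#'   `"pattern:<p>"`).
#' @export
filter_crystallins <- function(records, min_len = 80L, max_len = 200L,
                               exclude_patterns = c("AIM")) {
  if (min_len > max_len) abort("`min_len` must not exceed `max_len`.")
  len <- nchar(records$seq)
  name_fields <- paste(records$id,
                       records[["description"]] %||% "",
                       records[["protein_name"]] %||% "")
  reason <- rep(NA_character_, nrow(records))
  for (p in exclude_patterns) {
    hit <- is.na(reason) & grepl(p, name_fields, fixed = TRUE)
    reason[hit] <- paste0("pattern:", p)
  }
  reason[is.na(reason) & len < min_len] <- "truncated"
  reason[is.na(reason) & len > max_len] <- "overlong"
  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], excluded = as_tibble(excluded))
}

#' Load the packaged crystallin composition table
#'
#' Returns the packaged survey of Cys and Met content of beta/gamma- and
#' gamma-crystallins in representative chordates: one row per protein with
#' its UniProt accession, mature-chain length, Cys/Met counts and printed
#' percentages, and the subfamily block (`betagamma`, `gammaS`,
#' `gammaD_like`, `gammaM`). Initiator methionines are assumed cleaved in
#' the mature protein and are not included in the counts.
#'
#' One printed percentage (CRG3_XENLA Cys) is internally inconsistent with
#' its own count/length in the source table; the row is stored as printed
#' and flagged by [table1_consistency()].
#'
#' @return A tibble with columns `organism`, `protein`, `uniprot_id`,
#'   `method`, `length`, `cys_count`, `cys_pct`, `met_count`, `met_pct`,
#'   `block`.
#' @examples
#' tab <- load_table1_fixture()
#' dplyr::count(tab, block)
#' @export
load_table1_fixture <- function() {
  tab <- readr::read_tsv(crystkit_extdata("table1_crystallins.tsv"),
                         col_types = readr::cols(
                           organism = "c", protein = "c", uniprot_id = "c",
                           method = "i", length = "i", cys_count = "i",
                           cys_pct = "d", met_count = "i", met_pct = "d",
                           block = "c"))
  blocks <- c(betagamma = 4L, gammaS = 11L, gammaD_like = 16L, gammaM = 11L)
  counts <- table(factor(tab$block, levels = names(blocks)))
  if (nrow(tab) != sum(blocks) || !all(as.integer(counts) == blocks)) {
    abort("packaged composition table failed its block-structure integrity check")
  }
  if (anyDuplicated(tab$uniprot_id)) {
    abort("packaged composition table contains duplicated accessions")
  }
  cons <- table1_consistency(tab)
  bad <- cons$uniprot_id[!cons$consistent]
  if (!identical(bad, "CRG3_XENLA")) {
    abort("packaged composition table failed its printed-percentage integrity check")
  }
  tab
}

#' Check printed percentages of the composition table against its own counts
#'
#' For every row, recomputes `round(count / length * 100, 1)` and compares it
#' with the printed percentage (round-half-to-even, as in base R).
#'
#' @param tab A fixture tibble from [load_table1_fixture()]; loaded if missing.
#' @return A tibble with per-row recomputed percentages and `consistent`
#'   flags.
#' @export
table1_consistency <- function(tab = NULL) {
  if (is.null(tab)) tab <- load_table1_fixture()
  dplyr::transmute(tab,
    uniprot_id = .data$uniprot_id,
    cys_pct_printed = .data$cys_pct,
    cys_pct_computed = round(.data$cys_count / .data$length * 100, 1),
    met_pct_printed = .data$met_pct,
    met_pct_computed = round(.data$met_count / .data$length * 100, 1),
    consistent = .data$cys_pct_printed == .data$cys_pct_computed &
      .data$met_pct_printed == .data$met_pct_computed)
}

#' Fetch protein sequences from UniProt (network-gated)
#'
#' Downloads sequences for a set of UniProt accessions. Network access is
#' off by default and must be enabled explicitly; in offline mode the
#' function fails with an explicit error rather than attempting a request.
#' Unresolvable accessions are reported in the `failed` component, never
#' silently dropped.
#'
#' @param ids Character vector of UniProt accessions or entry names.
#' @param online Set `TRUE` to allow network access.
#' @param retries Number of retry attempts per accession.
#' @return A list with `records` (tibble as from [read_fasta()]) and
#'   `failed` (character vector of accessions that could not be resolved).
#' @export
fetch_uniprot <- function(ids, online = FALSE, retries = 2L) {
  if (length(ids) == 0L) {
    return(list(records = tibble(id = character(), description = character(),
                                 seq = character(), moltype = character()),
                failed = character()))
  }
  if (!isTRUE(online)) {
    abort("fetch_uniprot() is offline: pass `online = TRUE` to allow network access.")
  }
  records <- list()
  failed <- character()
  for (acc in ids) {
    url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", acc)
    got <- NULL
    for (k in seq_len(retries + 1L)) {
      got <- tryCatch({
        tf <- tempfile(fileext = ".fasta")
        utils::download.file(url, tf, quiet = TRUE, mode = "wb")
        rec <- read_fasta(tf, moltype = "protein")
        if (nrow(rec) == 0L) NULL else rec
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(got)) break
    }
    if (is.null(got)) failed <- c(failed, acc) else records[[acc]] <- got
  }
  list(records = if (length(records)) dplyr::bind_rows(records) else
         tibble(id = character(), description = character(),
                seq = character(), moltype = character()),
       failed = failed)
}
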