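# End-to-end orchestration: FASTA (+ optional CDS and structures) ->
# composition report, refractivity report, dissimilarity dendrogram,
# NJ bootstrap tree, exposure report, subfamily calls.

#' Build a pipeline configuration
#'
#' Collects every tunable of the analysis in one serializable list. Every
#' stochastic stage (the bootstrap) requires an explicit seed; the
#' configuration is echoed into the output directory so a run can be
#' reproduced byte-for-byte.
#'
#' @param fasta Path to the protein FASTA (or `NULL` if `records` given).
#' @param records Optional tibble of protein records, used instead of
#'   `fasta`.
#' @param cds Optional named character vector of coding sequences (or path
#'   to a CDS FASTA) enabling the nucleotide tree stages.
#' @param groups Optional named character vector mapping ids to subfamily
#'   blocks.
#' @param structures Optional named list of `crystal_structure` objects (or
#'   named character vector of PDB paths).
#' @param boundaries,control_residues Named vectors for the exposure stage.
#' @param gap_open,gap_extend Alignment penalties.
#' @param distance_model `"jc69"` or `"p_distance"`.
#' @param k Number of clusters for the dendrogram cut.
#' @param bootstrap_replicates,bootstrap_seed,bootstrap_unit Bootstrap
#'   settings; the seed is mandatory whenever `cds` is supplied.
#' @param probe,points,threshold_multiplier SASA settings.
#' @param out_dir Output directory (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, records = NULL, cds = NULL,
                            groups = NULL, structures = NULL,
                            boundaries = NULL, control_residues = NULL,
                            gap_open = 10, gap_extend = 0.5,
                            distance_model = "jc69", k = 4L,
                            bootstrap_replicates = 100L,
                            bootstrap_seed = NULL,
                            bootstrap_unit = "codon",
                            probe = 1.4, points = 960L,
                            threshold_multiplier = 1,
                            out_dir = tempfile("crystkit_run_")) {
  if (is.null(fasta) && is.null(records)) {
    abort("pipeline config error: one of `fasta` or `records` is required")
  }
  if (!is.null(cds) && is.null(bootstrap_seed)) {
    abort("pipeline config error: `bootstrap_seed` is required when CDS are supplied")
  }
  structure(list(fasta = fasta, records = records, cds = cds, groups = groups,
                 structures = structures, boundaries = boundaries,
                 control_residues = control_residues,
                 gap_open = gap_open, gap_extend = gap_extend,
                 distance_model = distance_model, k = as.integer(k),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 bootstrap_seed = bootstrap_seed,
                 bootstrap_unit = bootstrap_unit,
                 probe = probe, points = as.integer(points),
                 threshold_multiplier = threshold_multiplier,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_phylip_square <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(formatC(rownames(D)[i], width = -12),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

run_stage <- function(name, log, expr) {
  res <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  log(sprintf("stage=%s status=ok", name))
  res
}

#' Run the full crystallin analysis pipeline
#'
#' Executes, in order: sequence input, composition report, refractivity
#' report, all-vs-all percent-dissimilarity matrix, ward.D2 dendrogram (cut
#' at k), subfamily classification, and - when coding sequences and
#' structures are supplied - the codon-threaded nucleotide alignment,
#' Neighbor-Joining bootstrap tree, and per-domain cysteine exposure
#' report. All outputs are plain-text (TSV, FASTA, Newick, PHYLIP, JSON);
#' rerunning with the same configuration reproduces every output
#' byte-for-byte (timestamps live only in the run log).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of result objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log <- function(msg) writeLines(paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg), log_con)
  outputs <- list()
  p <- function(f) file.path(config$out_dir, f)

  records <- run_stage("input", log, {
    r <- if (!is.null(config$records)) as_tibble(config$records)
      else read_fasta(config$fasta, moltype = "protein")
    if (nrow(r) < 2L) abort("need at least two protein sequences")
    r
  })

  comp <- run_stage("composition", log, {
    tab <- composition_row(records)
    if (!is.null(config$groups)) tab$block <- config$groups[tab$id]
    readr::write_tsv(tab, p("composition.tsv"))
    tab
  })
  outputs$composition <- comp

  refr <- run_stage("refractivity", log, {
    tab <- refractivity_report(records)
    readr::write_tsv(tab, p("refractivity.tsv"))
    tab
  })
  outputs$refractivity <- refr

  D <- run_stage("dissimilarity", log, {
    D <- dissimilarity_matrix(records, gap_open = config$gap_open,
                              gap_extend = config$gap_extend)
    write_phylip_square(D, p("dissimilarity.phylip"))
    readr::write_tsv(as_tibble(D, rownames = "id"), p("dissimilarity.tsv"))
    D
  })
  outputs$dissimilarity <- D

  dend <- run_stage("clustering", log, {
    dend <- ward_cluster(D)
    write_newick(dend, p("dendrogram.nwk"))
    cut <- cut_dendrogram(dend, min(config$k, nrow(records)))
    readr::write_tsv(tibble(id = names(cut), cluster = unname(cut)),
                     p("clusters.tsv"))
    dend
  })
  outputs$dendrogram <- dend

  calls <- run_stage("subfamily", log, {
    calls <- classify_subfamily(records)
    readr::write_tsv(dplyr::mutate(calls,
      positions = vapply(.data$positions, paste, character(1), collapse = ",")),
      p("subfamily_calls.tsv"))
    calls
  })
  outputs$subfamily <- calls

  if (!is.null(config$cds)) {
    tree <- run_stage("phylogeny", log, {
      cds <- config$cds
      if (is.character(cds) && length(cds) == 1L && file.exists(cds)) {
        cds_rec <- read_fasta(cds, moltype = "cds")
        cds <- setNames(cds_rec$seq, cds_rec$id)
      }
      msa <- progressive_msa(records, gap_open = config$gap_open,
                             gap_extend = config$gap_extend)
      write_fasta(tibble(id = msa$ids, seq = unname(msa$rows)),
                  p("protein_msa.fasta"))
      nt_msa <- codon_thread(msa, cds)
      write_fasta(tibble(id = nt_msa$ids, seq = unname(nt_msa$rows)),
                  p("codon_msa.fasta"))
      Dn <- nuc_distance(nt_msa, model = config$distance_model)
      write_phylip_square(Dn, p("nuc_distance.phylip"))
      tree <- bootstrap_supports(nt_msa, model = config$distance_model,
                                 replicates = config$bootstrap_replicates,
                                 seed = config$bootstrap_seed,
                                 unit = config$bootstrap_unit)
      write_newick(tree, p("nj_bootstrap.nwk"))
      tree
    })
    outputs$nj_tree <- tree
  }

  if (!is.null(config$structures)) {
    expo <- run_stage("exposure", log, {
      structs <- config$structures
      if (is.character(structs)) {
        structs <- lapply(structs, read_structure)
      }
      rep <- exposure_report(structs, boundaries = config$boundaries,
                             controls = config$control_residues,
                             probe = config$probe, points = config$points,
                             multiplier = config$threshold_multiplier)
      readr::write_tsv(as_tibble(rep), p("exposure.tsv"))
      rep
    })
    outputs$exposure <- expo
    outputs$exclusivity <- exclusivity_test(expo)
  }

  run_stage("config_echo", log, {
    echo <- config
    echo$records <- if (!is.null(config$records)) "(inline records)" else NULL
    echo$structures <- if (!is.null(config$structures)) names(config$structures) else NULL
    jsonlite::write_json(unclass(echo), p("config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  })
  outputs$out_dir <- config$out_dir
  invisible(outputs)
}
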