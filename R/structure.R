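# Structure reading, Shrake-Rupley SASA, and per-domain cysteine exposure
# classification against a buried-control baseline.

#' Default van der Waals radii (Angstrom)
#'
#' @return Named numeric vector by element symbol.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

new_structure <- function(atoms, source = "synthetic") {
  atoms <- as_tibble(atoms)
  need <- c("serial", "element", "atom_name", "residue_name",
            "residue_number", "chain", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0L) {
    abort(sprintf("structure atoms missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) == 0L) abort("structure contains no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("structure contains non-finite coordinates")
  }
  structure(atoms, class = c("crystal_structure", class(atoms)),
            source = source)
}

#' Read a protein structure (PDB or mmCIF)
#'
#' Loads heavy atoms of the first model (the convention for multi-model NMR
#' files); alternate locations are resolved to the highest occupancy.
#' Residue numbers follow the numbering in the file; pass `renumber_offset`
#' to shift them onto the UniProt convention that counts Met1 as residue 1.
#'
#' @param path Structure file.
#' @param format `"pdb"` or `"mmcif"`.
#' @param keep_hydrogens Keep H atoms? Default drops them.
#' @param renumber_offset Integer added to every residue number.
#' @return A `crystal_structure` tibble of atoms with columns `serial`,
#'   `element`, `atom_name`, `residue_name`, `residue_number`, `chain`,
#'   `x`, `y`, `z`, `occupancy`.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif"),
                           keep_hydrogens = FALSE, renumber_offset = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("structure file not found: %s", path))
  atoms <- if (format == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
  if (nrow(atoms) == 0L) abort("structure file contains no atoms")
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  known <- names(vdw_radii())
  bad <- setdiff(unique(atoms$element), known)
  if (length(bad) > 0L) {
    abort(sprintf("unknown element(s) with no van der Waals radius: %s",
                  paste(bad, collapse = ", ")))
  }
  # resolve altlocs: keep highest occupancy per (chain, residue, atom name)
  atoms <- dplyr::slice_max(
    dplyr::group_by(atoms, .data$chain, .data$residue_number, .data$atom_name),
    order_by = .data$occupancy, n = 1L, with_ties = FALSE)
  atoms <- dplyr::arrange(dplyr::ungroup(atoms), .data$serial)
  atoms$residue_number <- atoms$residue_number + as.integer(renumber_offset)
  new_structure(atoms, source = path)
}

read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM" | pdb$atom$type == "HETATM", , drop = FALSE]
  elem <- trimws(at$elesy)
  noel <- is.na(elem) | elem == ""
  elem[noel] <- substr(gsub("[0-9]", "", trimws(at$elety[noel])), 1, 1)
  tibble(serial = at$eleno, element = toupper(elem),
         atom_name = trimws(at$elety), residue_name = trimws(at$resid),
         residue_number = as.integer(at$resno), chain = as.character(at$chain),
         x = at$x, y = at$y, z = at$z,
         occupancy = ifelse(is.na(at$o), 1, at$o))
}

# Minimal mmCIF _atom_site loop parser (model 1 only). No installed R
# package parses mmCIF, so the loop table is tokenized directly.
read_structure_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*loop_\\s*$", lines)
  for (s in starts) {
    i <- s + 1L
    fields <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(fields, "_atom_site."))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
          startsWith(ln, "_") || startsWith(ln, "data_")) break
      toks <- scan(text = ln, what = character(), quiet = TRUE)
      if (length(toks) == length(fields)) rows[[length(rows) + 1L]] <- toks
      i <- i + 1L
    }
    if (length(rows) == 0L) abort("empty _atom_site loop in mmCIF file")
    m <- do.call(rbind, rows)
    colnames(m) <- fields
    get <- function(nm, alt = NULL) {
      if (nm %in% fields) m[, nm] else if (!is.null(alt) && alt %in% fields)
        m[, alt] else rep(NA_character_, nrow(m))
    }
    model <- suppressWarnings(as.integer(get("pdbx_PDB_model_num")))
    keep <- if (all(is.na(model))) rep(TRUE, nrow(m)) else model == min(model, na.rm = TRUE)
    occ <- suppressWarnings(as.numeric(get("occupancy")))
    return(tibble(
      serial = suppressWarnings(as.integer(get("id")))[keep],
      element = toupper(get("type_symbol"))[keep],
      atom_name = get("label_atom_id", "auth_atom_id")[keep],
      residue_name = get("label_comp_id", "auth_comp_id")[keep],
      residue_number = suppressWarnings(as.integer(get("auth_seq_id", "label_seq_id")))[keep],
      chain = get("auth_asym_id", "label_asym_id")[keep],
      x = as.numeric(get("Cartn_x"))[keep],
      y = as.numeric(get("Cartn_y"))[keep],
      z = as.numeric(get("Cartn_z"))[keep],
      occupancy = ifelse(is.na(occ[keep]), 1, occ[keep])))
  }
  abort("no _atom_site loop found in mmCIF file")
}

#' Write a structure to PDB format
#'
#' @param model A `crystal_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   resno = model$residue_number,
                   resid = model$residue_name,
                   eleno = model$serial,
                   elety = model$atom_name,
                   chain = ifelse(is.na(model$chain), "A", model$chain),
                   o = model$occupancy %||% rep(1, nrow(model)),
                   b = rep(0, nrow(model)),
                   elesy = model$element)
  invisible(path)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface: each atom's expanded
#' sphere (r_vdw + probe) carries a deterministic golden-spiral lattice of
#' test points, and per-atom SASA is the exposed-point fraction times the
#' expanded sphere area \eqn{4 \pi (r + probe)^2}. Per-residue SASA is the
#' sum over the residue's atoms.
#'
#' @param model A `crystal_structure`.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param points Test points per atom (>= 92; default 960).
#' @param radii Named vector of van der Waals radii by element.
#' @return An object of class `sasa_result` with `per_atom` and
#'   `per_residue` tibbles and the `parameters` used.
#' @examples
#' one <- gen_structure(struct_spec("single_atom"))
#' sum(shrake_rupley(one$model)$per_atom$sasa)  # ~ 4*pi*(1.7+1.4)^2
#' @export
shrake_rupley <- function(model, probe = 1.4, points = 960L,
                          radii = vdw_radii()) {
  if (!is.numeric(probe) || probe <= 0) abort("`probe` must be positive")
  if (!is.numeric(points) || points < 92L) abort("`points` must be >= 92")
  r <- radii[model$element]
  if (any(is.na(r))) {
    abort(sprintf("no radius for element(s): %s",
                  paste(unique(model$element[is.na(r)]), collapse = ", ")))
  }
  xyz <- as.matrix(model[, c("x", "y", "z")])
  sasa <- sasa_cpp(xyz, as.numeric(r), probe, as.integer(points))
  per_atom <- tibble(serial = model$serial, element = model$element,
                     atom_name = model$atom_name,
                     residue_name = model$residue_name,
                     residue_number = model$residue_number,
                     chain = model$chain, sasa = sasa)
  per_residue <- dplyr::summarise(
    dplyr::group_by(per_atom, .data$chain, .data$residue_number,
                    .data$residue_name),
    sasa = sum(.data$sasa), .groups = "drop")
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 parameters = list(probe = probe, points = as.integer(points),
                                   radii_set = "default")),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %d atoms, %d residues, total %.1f A^2 (probe %.2f A, %d points)\n",
              nrow(x$per_atom), nrow(x$per_residue), sum(x$per_atom$sasa),
              x$parameters$probe, x$parameters$points))
  invisible(x)
}

#' @rdname shrake_rupley
#' @param x A `sasa_result`.
#' @param ... Unused.
#' @method tidy sasa_result
#' @export
tidy.sasa_result <- function(x, ...) x$per_residue

#' @rdname shrake_rupley
#' @method glance sasa_result
#' @export
glance.sasa_result <- function(x, ...) {
  tibble(total_sasa = sum(x$per_atom$sasa),
         n_atoms = nrow(x$per_atom),
         probe = x$parameters$probe,
         points = x$parameters$points)
}

#' Combined cysteine SASA by domain
#'
#' Sums per-residue SASA over cysteines on either side of the interdomain
#' boundary: residues numbered at or below `boundary` belong to the
#' N-terminal domain, the rest to the C-terminal domain.
#'
#' @param model A `crystal_structure`.
#' @param sasa Matching `sasa_result` (computed if missing).
#' @param boundary Residue number separating NTD from CTD.
#' @param sidechain_only Sum side-chain atoms only (excludes N/CA/C/O)?
#' @return Named numeric vector `c(ntd = , ctd = )` in Angstrom^2.
#' @export
domain_cys_sasa <- function(model, sasa = NULL, boundary,
                            sidechain_only = FALSE) {
  rng <- range(model$residue_number)
  if (!is.numeric(boundary) || boundary < rng[1] || boundary > rng[2]) {
    abort(sprintf("`boundary` must lie within the residue range %d..%d",
                  rng[1], rng[2]))
  }
  if (is.null(sasa)) sasa <- shrake_rupley(model)
  at <- sasa$per_atom
  cys <- at[at$residue_name == "CYS", , drop = FALSE]
  if (sidechain_only) {
    cys <- cys[!(cys$atom_name %in% c("N", "CA", "C", "O")), , drop = FALSE]
  }
  if (nrow(cys) == 0L) {
    warn("structure contains no cysteine residues")
    return(c(ntd = 0, ctd = 0))
  }
  c(ntd = sum(cys$sasa[cys$residue_number <= boundary]),
    ctd = sum(cys$sasa[cys$residue_number > boundary]))
}

#' Buried-control SASA baseline
#'
#' Mean and sample standard deviation of the SASA of a conserved buried
#' control cysteine (such as C83 of human gammaS-crystallin) across a set of
#' structures. The exposure threshold for classification is mean + 1 SD.
#'
#' @param controls Tibble with columns `id` and `control_sasa` (Angstrom^2),
#'   one row per structure; rows with missing control are dropped and
#'   reported in a warning.
#' @return A list `mean`, `sd`, `n`.
#' @export
buried_control_baseline <- function(controls) {
  ok <- !is.na(controls$control_sasa)
  if (any(!ok)) {
    warn(sprintf("excluding %d structure(s) without a control cysteine: %s",
                 sum(!ok), paste(controls$id[!ok], collapse = ", ")))
    controls <- controls[ok, , drop = FALSE]
  }
  if (nrow(controls) < 2L) {
    abort("need >= 2 structures with a control cysteine (sd undefined otherwise)")
  }
  list(mean = mean(controls$control_sasa),
       sd = stats::sd(controls$control_sasa),
       n = nrow(controls))
}

#' Classify domain-level cysteine exposure
#'
#' A domain counts as solvent-exposed when its combined cysteine SASA
#' strictly exceeds `baseline_mean + multiplier * baseline_sd`, the
#' buried-control threshold.
#'
#' @param ntd_sum,ctd_sum Combined Cys SASA per domain (Angstrom^2).
#' @param baseline_mean,baseline_sd Buried-control baseline.
#' @param multiplier SD multiplier for the threshold (default 1).
#' @return One of `"NTD"`, `"CTD"`, `"both"`, `"neither"`.
#' @examples
#' classify_exposure(50, 2, 3, 1)  # "NTD"
#' @export
classify_exposure <- function(ntd_sum, ctd_sum, baseline_mean, baseline_sd,
                              multiplier = 1) {
  vals <- c(ntd_sum, ctd_sum, baseline_mean, baseline_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all SASA inputs must be finite and non-negative")
  }
  thr <- baseline_mean + multiplier * baseline_sd
  ntd <- ntd_sum > thr
  ctd <- ctd_sum > thr
  if (ntd && ctd) "both" else if (ntd) "NTD" else if (ctd) "CTD" else "neither"
}

#' Per-protein exposure report for a structure set
#'
#' Computes SASA for every structure, sums cysteine SASA by domain, builds
#' the buried-control baseline from the designated control residues, and
#' classifies each protein's exposure pattern.
#'
#' @param structures Named list of `crystal_structure` objects.
#' @param boundaries Named integer vector: interdomain boundary residue per
#'   structure.
#' @param controls Named integer vector: control (buried) Cys residue number
#'   per structure; structures whose control residue is absent are excluded
#'   from the baseline and flagged.
#' @param probe,points Passed to [shrake_rupley()].
#' @param multiplier Threshold SD multiplier.
#' @return A tibble of class `exposure_report`: `id`, `boundary`,
#'   `ntd_cys_sasa`, `ctd_cys_sasa`, `control_sasa`, `baseline_mean`,
#'   `baseline_sd`, `exposure_class`.
#' @export
exposure_report <- function(structures, boundaries, controls,
                            probe = 1.4, points = 960L, multiplier = 1) {
  ids <- names(structures)
  if (is.null(ids)) abort("`structures` must be a named list")
  rows <- purrr::map_dfr(ids, function(id) {
    model <- structures[[id]]
    sasa <- shrake_rupley(model, probe = probe, points = points)
    dom <- domain_cys_sasa(model, sasa, boundary = boundaries[[id]])
    ctrl <- NA_real_
    if (!is.null(controls[[id]]) && !is.na(controls[[id]])) {
      pr <- sasa$per_residue
      hit <- pr$residue_number == controls[[id]] & pr$residue_name == "CYS"
      if (any(hit)) ctrl <- sum(pr$sasa[hit])
    }
    tibble(id = id, boundary = as.integer(boundaries[[id]]),
           ntd_cys_sasa = dom[["ntd"]], ctd_cys_sasa = dom[["ctd"]],
           control_sasa = ctrl)
  })
  base <- buried_control_baseline(rows[, c("id", "control_sasa")])
  rows$baseline_mean <- base$mean
  rows$baseline_sd <- base$sd
  rows$exposure_class <- vapply(seq_len(nrow(rows)), function(i) {
    classify_exposure(rows$ntd_cys_sasa[i], rows$ctd_cys_sasa[i],
                      base$mean, base$sd, multiplier = multiplier)
  }, character(1))
  structure(rows, class = c("exposure_report", class(rows)))
}
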