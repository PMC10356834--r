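# Reading complex structures, chain-pair selection, chimera exclusion and
# representative picking.

#' Construct a complex structure object
#'
#' A `complex_structure` bundles the coordinates of one receptor/G-protein
#' complex with its identity metadata. It is the unit every downstream stage
#' (contact extraction, superposition, model QC) consumes.
#'
#' @param structure_id identifier of the structure (e.g. a PDB id or a model
#'   name)
#' @param atom data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`, and optionally `occ` (occupancy, default 1) and
#'   `alt` (alternate-location indicator, default none)
#' @param receptor_chain,galpha_chain analyzed chain pair (may be `NA` until
#'   [select_chain_pair()] has been run)
#' @param resolution resolution in Angstrom, or `NA`
#' @param receptor_accession,gprotein_accession UniProt accessions of the
#'   declared receptor / G-alpha pair
#' @param gprotein_family one of `"Gs"`, `"Gi/o"`, `"Gq/11"`, `"G12/13"`
#' @param receptor_class receptor class (`"A"`, `"B1"`, `"B2"`, `"C"`, `"F"`)
#' @return an object of class `complex_structure`
#' @export
complex_structure <- function(structure_id, atom,
                              receptor_chain = NA_character_,
                              galpha_chain = NA_character_,
                              resolution = NA_real_,
                              receptor_accession = NA_character_,
                              gprotein_accession = NA_character_,
                              gprotein_family = NA_character_,
                              receptor_class = NA_character_) {
  stopifnot(is.data.frame(atom))
  stop_if_missing_cols(atom, c("chain", "resno", "resid", "elety",
                               "x", "y", "z"), "atom table")
  if (nrow(atom) == 0) stop("empty structure: no ATOM records", call. = FALSE)
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (is.null(atom$insert)) atom$insert <- ""
  atom$insert[is.na(atom$insert)] <- ""
  if (is.null(atom$occ)) atom$occ <- 1
  atom$occ[is.na(atom$occ)] <- 1
  if (is.null(atom$alt)) atom$alt <- ""
  atom$alt[is.na(atom$alt)] <- ""
  if (!is.na(gprotein_family)) {
    gprotein_family <- match.arg(gprotein_family,
                                 c("Gs", "Gi/o", "Gq/11", "G12/13"))
  }
  structure(list(
    structure_id = structure_id,
    atom = atom,
    receptor_chain = receptor_chain,
    galpha_chain = galpha_chain,
    resolution = resolution,
    receptor_accession = receptor_accession,
    gprotein_accession = gprotein_accession,
    gprotein_family = gprotein_family,
    receptor_class = receptor_class
  ), class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  nres <- nrow(unique(x$atom[, c("chain", "resno", "insert")]))
  cat(sprintf("complex_structure '%s': %d chains, %d residues, %d atoms\n",
              x$structure_id, length(unique(x$atom$chain)), nres,
              nrow(x$atom)))
  cat(sprintf("  pair: %s (receptor) / %s (Galpha); family %s; resolution %s\n",
              x$receptor_chain, x$galpha_chain, x$gprotein_family,
              format(x$resolution)))
  invisible(x)
}

#' Read the complex metadata table
#'
#' Sidecar TSV carrying per-structure identity and quality metadata (the
#' stand-in for SIFTS-style annotation). Required columns: `structure_id`,
#' `receptor_chain_candidates`, `galpha_chain_candidates`,
#' `receptor_accession`, `gprotein_accession`, `gprotein_family`,
#' `receptor_class`, `resolution`, `gprotein_coverage`. Candidate chain
#' columns hold comma-separated chain ids.
#'
#' @param path TSV path
#' @return data frame
#' @export
read_complex_metadata <- function(path) {
  md <- read_tsv(path)
  stop_if_missing_cols(md, c("structure_id", "receptor_chain_candidates",
                             "galpha_chain_candidates", "receptor_accession",
                             "gprotein_accession", "gprotein_family",
                             "receptor_class", "resolution",
                             "gprotein_coverage"),
                       "complex metadata")
  if (anyDuplicated(md$structure_id)) {
    stop("duplicate structure_id in metadata", call. = FALSE)
  }
  bad <- !is.na(md$resolution) & md$resolution <= 0
  if (any(bad)) stop("resolution must be > 0 when present", call. = FALSE)
  cov <- md$gprotein_coverage
  if (any(!is.na(cov) & (cov < 0 | cov > 1))) {
    stop("gprotein_coverage must lie in [0,1]", call. = FALSE)
  }
  md
}

#' Load a complex structure from PDB or mmCIF
#'
#' Coordinates are read with bio3d; only ATOM records are kept. Residue
#' numbering and insertion codes are preserved as authored. When a metadata
#' table (see [read_complex_metadata()]) is supplied, the row matching
#' `structure_id` populates accessions, family, class and resolution; a
#' missing row is an error.
#'
#' @param path coordinate file
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`
#' @param metadata optional metadata data frame
#' @param structure_id identifier; defaults to the file base name
#' @return a [complex_structure()]
#' @export
load_complex <- function(path, format = c("auto", "pdb", "cif"),
                         metadata = NULL, structure_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|cif)$", "", basename(path),
                        ignore.case = TRUE)
  }
  # read.cif emits beta-status / header-parsing notes irrelevant here
  pdb <- if (format == "cif") {
    suppressWarnings(bio3d::read.cif(path))
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no ATOM records", call. = FALSE)
  atom <- data.frame(
    chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  cs <- complex_structure(structure_id, atom)
  if (!is.null(metadata)) {
    row <- metadata[metadata$structure_id == structure_id, , drop = FALSE]
    if (nrow(row) != 1) {
      stop(sprintf("no metadata row for structure '%s'", structure_id),
           call. = FALSE)
    }
    cs$resolution <- row$resolution
    cs$receptor_accession <- row$receptor_accession
    cs$gprotein_accession <- row$gprotein_accession
    cs$gprotein_family <- row$gprotein_family
    cs$receptor_class <- row$receptor_class
  }
  cs
}

#' Write a complex structure to PDB or mmCIF
#'
#' PDB output goes through [bio3d::write.pdb()]. mmCIF output is a minimal
#' `atom_site` loop (group, serial, element, atom id, residue, chain, seq id,
#' insertion code, Cartesian coordinates, occupancy, B) sufficient for
#' round-tripping through [load_complex()].
#'
#' @param x a [complex_structure()]
#' @param path output file
#' @param format `"auto"`, `"pdb"` or `"cif"`
#' @return `path`, invisibly
#' @export
write_complex <- function(x, path, format = c("auto", "pdb", "cif")) {
  stopifnot(inherits(x, "complex_structure"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  a <- x$atom
  if (format == "pdb") {
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, chain = a$chain, resid = a$resid,
                     elety = a$elety,
                     insert = ifelse(a$insert == "", "", a$insert),
                     o = a$occ, b = rep(0, nrow(a)))
  } else {
    # canonical wwPDB atom_site layout (21 columns)
    elem <- substr(gsub("[^A-Za-z]", "", a$elety), 1, 1)
    lines <- c(
      sprintf("data_%s", x$structure_id),
      "#", "loop_",
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
      "_atom_site.label_atom_id", "_atom_site.label_alt_id",
      "_atom_site.label_comp_id", "_atom_site.label_asym_id",
      "_atom_site.label_entity_id", "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
      "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
      sprintf("ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
              seq_len(nrow(a)), elem, a$elety,
              ifelse(a$alt == "", ".", a$alt), a$resid, a$chain, a$resno,
              ifelse(a$insert == "", "?", a$insert),
              a$x, a$y, a$z, a$occ, 0, a$resno, a$resid, a$chain, a$elety),
      "#")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Select the analyzed receptor / G-alpha chain pair
#'
#' When a structure holds more than one candidate receptor or G-alpha chain,
#' the analyzed pair is the one with the highest number of inter-chain
#' contacts (representative-atom distance below the cutoff). Ties are broken
#' lexicographically on (receptor chain id, G-alpha chain id) so selection is
#' deterministic.
#'
#' @param x a [complex_structure()]
#' @param receptor_chains,galpha_chains candidate chain ids (character)
#' @param params a [contact_params()]
#' @return named list with `receptor_chain`, `galpha_chain`, `n_contacts`;
#'   the fields are also set on the returned structure under attribute
#'   `"structure"`
#' @export
select_chain_pair <- function(x, receptor_chains, galpha_chains,
                              params = contact_params()) {
  stopifnot(length(receptor_chains) >= 1, length(galpha_chains) >= 1)
  grid <- expand.grid(receptor = sort(unique(receptor_chains)),
                      galpha = sort(unique(galpha_chains)),
                      stringsAsFactors = FALSE)
  grid$n <- vapply(seq_len(nrow(grid)), function(i) {
    nrow(interface_residue_pairs(x, grid$receptor[i], grid$galpha[i], params))
  }, integer(1))
  if (all(grid$n == 0)) stop("no interface: no candidate chain pair has contacts",
                             call. = FALSE)
  grid <- grid[order(-grid$n, grid$receptor, grid$galpha), , drop = FALSE]
  best <- grid[1, ]
  out <- x
  out$receptor_chain <- best$receptor
  out$galpha_chain <- best$galpha
  res <- list(receptor_chain = best$receptor, galpha_chain = best$galpha,
              n_contacts = best$n)
  attr(res, "structure") <- out
  res
}

#' Test whether a complex is chimeric at the interface
#'
#' A structure is chimeric when any interface contact residue maps to a
#' UniProt accession different from the declared receptor/G-alpha pair, or
#' is not mapped at all (unmapped interface residues are conservatively
#' treated as chimeric evidence, i.e. the structure is excluded).
#'
#' @param x a [complex_structure()] with the chain pair set
#' @param mapping residue mapping data frame (see [read_mapping_table()])
#' @param params a [contact_params()]
#' @return `TRUE` if chimeric
#' @export
is_chimeric <- function(x, mapping, params = contact_params()) {
  stopifnot(inherits(x, "complex_structure"))
  if (is.na(x$receptor_chain) || is.na(x$galpha_chain)) {
    stop("chain pair not set; run select_chain_pair() first", call. = FALSE)
  }
  pairs <- interface_residue_pairs(x, x$receptor_chain, x$galpha_chain, params)
  if (nrow(pairs) == 0) return(FALSE)
  map <- mapping[mapping$structure_id == x$structure_id, , drop = FALSE]
  key2acc <- stats::setNames(map$uniprot_acc,
                             res_key(map$chain, map$resnum, map$icode))
  acc_side <- function(keys, declared) {
    acc <- key2acc[keys]
    any(is.na(acc)) || any(acc != declared)
  }
  acc_side(unique(pairs$key_a), x$receptor_accession) ||
    acc_side(unique(pairs$key_b), x$gprotein_accession)
}

#' Pick one representative structure per receptor/G-protein pair
#'
#' Among all structures sharing a (receptor accession, G-protein accession)
#' pair the representative is the one with the best (numerically smallest)
#' resolution; ties fall back to the largest G-alpha coverage, then to the
#' lexicographically smallest `structure_id`.
#'
#' @param records data frame with columns `structure_id`,
#'   `receptor_accession`, `gprotein_accession`, `resolution`,
#'   `gprotein_coverage`
#' @return data frame with one row per pair: accessions, chosen
#'   `structure_id` and a human-readable `reason`
#' @export
select_representatives <- function(records) {
  cols <- c("structure_id", "receptor_accession", "gprotein_accession",
            "resolution", "gprotein_coverage")
  stop_if_missing_cols(records, cols, "complex records")
  if (nrow(records) == 0) {
    return(data.frame(receptor_accession = character(),
                      gprotein_accession = character(),
                      structure_id = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$receptor_accession, records$gprotein_accession,
               sep = "|")
  out <- lapply(split(records, key), function(g) {
    g <- g[order(g$resolution, -g$gprotein_coverage, g$structure_id), ,
           drop = FALSE]
    reason <- if (nrow(g) == 1) {
      "single structure"
    } else if (sum(g$resolution == g$resolution[1]) == 1) {
      "highest resolution"
    } else if (sum(g$resolution == g$resolution[1] &
                   g$gprotein_coverage == g$gprotein_coverage[1]) == 1) {
      "resolution tie, largest G-protein coverage"
    } else {
      "full tie, lexicographic structure id"
    }
    data.frame(receptor_accession = g$receptor_accession[1],
               gprotein_accession = g$gprotein_accession[1],
               structure_id = g$structure_id[1], reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$receptor_accession, out$gprotein_accession), , drop = FALSE]
}
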