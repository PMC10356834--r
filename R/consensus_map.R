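# Consensus numbering: residue -> UniProt -> GPCRdb / CGN labels, SSE
# assignment from label prefixes, loop aggregation, and consensus cores.

# Receptor segment order used for deterministic core layout: N-terminus,
# the 7TM bundle with its loops, helix 8, C-terminus.
.receptor_segment_order <- c("Nterm", "TM1", "ICL1", "TM2", "ECL1", "TM3",
                             "ICL2", "TM4", "ECL2", "TM5", "ICL3", "TM6",
                             "ECL3", "TM7", "H8", "Cterm")

# CGN segment order along the Galpha fold (Ras-like domain first, helical
# domain segments after their insertion point, H5 last).
.cgn_segment_order <- c("HN", "hns1", "S1", "s1h1", "H1", "h1ha", "HA",
                        "hahb", "HB", "hbhc", "HC", "hchd", "HD", "hdhe",
                        "HE", "hehf", "HF", "hfs2", "S2", "s2s3", "S3",
                        "s3h2", "H2", "h2s4", "S4", "s4h3", "H3", "h3s5",
                        "S5", "s5hg", "HG", "hgh4", "H4", "h4s6", "S6",
                        "s6h5", "H5")

#' Read a residue mapping table
#'
#' One row per structure residue, carrying its UniProt position, consensus
#' label and SSE. Required columns: `structure_id`, `chain`, `resnum`,
#' `icode`, `uniprot_acc`, `uniprot_pos`, `consensus_label`, `sse`.
#' Duplicate residue keys within one structure are an error.
#'
#' @param path TSV path, or a data frame to validate in place
#' @return validated data frame
#' @export
read_mapping_table <- function(path) {
  map <- if (is.data.frame(path)) {
    path
  } else {
    read_tsv(path, colClasses = c(structure_id = "character",
                                  chain = "character", icode = "character",
                                  uniprot_acc = "character",
                                  consensus_label = "character",
                                  sse = "character"))
  }
  stop_if_missing_cols(map, c("structure_id", "chain", "resnum", "icode",
                              "uniprot_acc", "uniprot_pos",
                              "consensus_label", "sse"), "residue mapping")
  map$icode[is.na(map$icode)] <- ""
  key <- paste(map$structure_id, res_key(map$chain, map$resnum, map$icode))
  if (anyDuplicated(key)) {
    stop("duplicate residue key in mapping table", call. = FALSE)
  }
  lab <- map$consensus_label
  ok <- !is.na(lab) & nzchar(lab)
  if (!all(ok)) stop("malformed (empty) consensus label", call. = FALSE)
  map
}

#' Derive the SSE of a consensus label
#'
#' Receptor labels: `"3.50"` -> `"TM3"`, `"8.51"` -> `"H8"`,
#' `"ICL2.51"`/`"ICL3"` -> the loop, `"Nterm"`/`"Cterm"` pass through,
#' `"ICL3(299)"` -> `"ICL3"`. G-alpha CGN labels: the middle field,
#' `"G.H5.25"` -> `"H5"`.
#'
#' @param label consensus label
#' @param side `"receptor"` or `"galpha"`
#' @return SSE name
#' @export
sse_from_label <- function(label, side = c("receptor", "galpha")) {
  side <- match.arg(side)
  if (side == "galpha") {
    m <- regmatches(label, regexec("^G\\.([A-Za-z0-9]+)(\\.|$)", label))[[1]]
    if (length(m) == 0) stop(sprintf("malformed CGN label '%s'", label),
                             call. = FALSE)
    return(m[2])
  }
  if (grepl("^[1-7]\\.", label)) return(paste0("TM", substr(label, 1, 1)))
  if (grepl("^8\\.", label)) return("H8")
  m <- regmatches(label, regexec("^((ICL|ECL)[0-9]|Nterm|Cterm)", label))[[1]]
  if (length(m) > 0) return(m[2])
  stop(sprintf("malformed receptor label '%s'", label), call. = FALSE)
}

#' Aggregate loop / terminus labels for fingerprinting
#'
#' Receptor positions in loops, N- or C-termini that lack a residue-level
#' generic number (written `"SEG(resnum)"`, e.g. `"ICL3(299)"`) collapse to
#' their segment name (`"ICL3"`). Residue-level receptor labels (`"3.50"`,
#' `"ICL2.51"`) and all G-alpha CGN labels pass through unchanged. The
#' function is idempotent.
#'
#' @param label consensus label
#' @param side `"receptor"` or `"galpha"`
#' @return fingerprint label
#' @export
aggregate_label <- function(label, side = c("receptor", "galpha")) {
  side <- match.arg(side)
  if (side == "galpha") {
    sse_from_label(label, "galpha")  # validates
    return(label)
  }
  m <- regmatches(label,
                  regexec("^((ICL|ECL)[0-9]|Nterm|Cterm)\\([0-9]+\\)$", label))[[1]]
  if (length(m) > 0) return(m[2])
  sse_from_label(label, "receptor")  # validates
  label
}

# Sort keys for deterministic core ordering.
.receptor_label_order <- function(labels) {
  seg <- vapply(labels, sse_from_label, character(1), side = "receptor")
  segi <- match(seg, .receptor_segment_order)
  pos <- suppressWarnings(as.numeric(sub("^.*\\.", "", labels)))
  pos[is.na(pos)] <- 0
  order(segi, pos, labels)
}

.galpha_label_order <- function(labels) {
  seg <- vapply(labels, sse_from_label, character(1), side = "galpha")
  segi <- match(seg, .cgn_segment_order)
  segi[is.na(segi)] <- length(.cgn_segment_order) + 1L
  pos <- suppressWarnings(as.numeric(sub("^.*\\.", "", labels)))
  pos[is.na(pos)] <- 0
  order(segi, pos, labels)
}

# Consensus labels with a resolved Calpha in one structure, one side.
.resolved_labels <- function(x, mapping, chain) {
  map <- mapping[mapping$structure_id == x$structure_id &
                   mapping$chain == chain, , drop = FALSE]
  ca <- x$atom[x$atom$chain == chain & x$atom$elety == "CA", , drop = FALSE]
  keys <- res_key(ca$chain, ca$resno, ca$insert)
  map$consensus_label[res_key(map$chain, map$resnum, map$icode) %in% keys]
}

#' Build the consensus core of an ensemble
#'
#' The core is, separately for the receptor and the G-alpha side, the set of
#' consensus labels with a resolved Calpha in every structure of the
#' ensemble — the positions on which superposition (receptor core) and RMSD
#' (G-alpha core) are computed. Receptor labels are ordered by (segment,
#' position), G-alpha labels by CGN segment order.
#'
#' @param structures list of [complex_structure()] with chain pairs set
#' @param mapping residue mapping covering all structures
#' @return object of class `consensus_core`: list with ordered `receptor`
#'   and `galpha` label vectors
#' @export
build_consensus_core <- function(structures, mapping) {
  stopifnot(length(structures) >= 2)
  rec_sets <- lapply(structures, function(x)
    unique(.resolved_labels(x, mapping, x$receptor_chain)))
  ga_sets <- lapply(structures, function(x)
    unique(.resolved_labels(x, mapping, x$galpha_chain)))
  rec <- Reduce(intersect, rec_sets)
  ga <- Reduce(intersect, ga_sets)
  if (length(rec) == 0 || length(ga) == 0) {
    stop("no common core: label intersection across the ensemble is empty",
         call. = FALSE)
  }
  rec <- rec[.receptor_label_order(rec)]
  ga <- ga[.galpha_label_order(ga)]
  structure(list(receptor = rec, galpha = ga), class = "consensus_core")
}

#' @export
print.consensus_core <- function(x, ...) {
  cat(sprintf("consensus_core: %d receptor + %d Galpha positions\n",
              length(x$receptor), length(x$galpha)))
  invisible(x)
}
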