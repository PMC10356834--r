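# Interface contact extraction and per-pair aggregation.
#
# A contact is a residue pair from the two analyzed chains whose
# representative atoms (Cbeta; Calpha for glycine) lie strictly closer than
# the cutoff (8 Angstrom by default). Contacts are reported on consensus
# labels after loop aggregation so every downstream stage shares one
# feature universe.

#' Contact definition parameters
#'
#' @param cutoff distance cutoff in Angstrom; the comparison is a strict
#'   less-than
#' @return object of class `contact_params`
#' @export
contact_params <- function(cutoff = 8.0) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  structure(list(cutoff = cutoff), class = "contact_params")
}

# One representative atom per residue of one chain.
# Rules: altloc resolved to the highest-occupancy conformer (then altloc
# "A"/blank); Cbeta, except glycine which uses Calpha; a non-glycine residue
# with no Cbeta falls back to Calpha with a warning; residues with neither
# atom are skipped with a warning.
residue_rep_atoms <- function(x, chain, warn = TRUE) {
  a <- x$atom[x$atom$chain == chain & x$atom$elety %in% c("CA", "CB"), ,
              drop = FALSE]
  if (nrow(a) == 0) {
    stop(sprintf("structure '%s' has no CA/CB atoms in chain '%s'",
                 x$structure_id, chain), call. = FALSE)
  }
  # altloc: keep best conformer per (residue, atom name)
  a <- a[order(a$resno, a$insert, a$elety, -a$occ, a$alt), , drop = FALSE]
  a <- a[!duplicated(a[, c("resno", "insert", "elety")]), , drop = FALSE]
  a$key <- res_key(a$chain, a$resno, a$insert)
  has_cb <- a$key[a$elety == "CB"]
  is_gly <- a$resid == "GLY"
  use <- (a$elety == "CB" & !is_gly) |
    (a$elety == "CA" & (is_gly | !(a$key %in% has_cb)))
  rep <- a[use, , drop = FALSE]
  # a residue could still contribute twice if GLY carries a stray CB; keep CA
  rep <- rep[order(rep$key, rep$elety), , drop = FALSE]
  rep <- rep[!duplicated(rep$key), , drop = FALSE]
  if (warn) {
    fb <- sum(rep$elety == "CA" & rep$resid != "GLY")
    if (fb > 0) {
      warning(sprintf("%d non-glycine residue(s) in chain %s lack Cbeta; using Calpha",
                      fb, chain), call. = FALSE)
    }
  }
  rep[, c("key", "resno", "insert", "resid", "x", "y", "z")]
}

# All index pairs (i in a, j in b) with distance strictly below cutoff.
# method "cell": grid/cell-list spatial index; "brute": full O(n*m)
# distance matrix. Both return identical pair sets (tested property).
contact_pairs <- function(xyz_a, xyz_b, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  empty <- data.frame(i = integer(), j = integer())
  if (na == 0 || nb == 0) return(empty)
  cut2 <- cutoff^2
  if (method == "brute") {
    d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
      2 * xyz_a %*% t(xyz_b)
    idx <- which(d2 < cut2, arr.ind = TRUE)
    return(data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2])))
  }
  cell_of <- function(m) {
    k <- floor(m / cutoff)
    paste(k[, 1], k[, 2], k[, 3], sep = ",")
  }
  kb <- floor(xyz_b / cutoff)
  b_cells <- split(seq_len(nb), paste(kb[, 1], kb[, 2], kb[, 3], sep = ","))
  ka <- floor(xyz_a / cutoff)
  a_cells <- split(seq_len(na), paste(ka[, 1], ka[, 2], ka[, 3], sep = ","))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  res_i <- list(); res_j <- list(); nres <- 0L
  for (ck in names(a_cells)) {
    ia <- a_cells[[ck]]
    base <- as.integer(strsplit(ck, ",", fixed = TRUE)[[1]])
    neigh <- sweep(off, 2, base, "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3], sep = ",")
    jb <- unlist(b_cells[keys], use.names = FALSE)
    if (length(jb) == 0) next
    sa <- xyz_a[ia, , drop = FALSE]
    sb <- xyz_b[jb, , drop = FALSE]
    d2 <- outer(rowSums(sa^2), rowSums(sb^2), "+") - 2 * sa %*% t(sb)
    hit <- which(d2 < cut2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      nres <- nres + 1L
      res_i[[nres]] <- ia[hit[, 1]]
      res_j[[nres]] <- jb[hit[, 2]]
    }
  }
  if (nres == 0L) return(empty)
  out <- data.frame(i = unlist(res_i), j = unlist(res_j))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Residue-level interface contacts between two chains
#'
#' Lower-level worker returning the raw residue-key pairs in contact
#' (before consensus mapping); used for chain-pair selection, chimera
#' detection and pDockQ interface definition.
#'
#' @param x a [complex_structure()]
#' @param chain_a,chain_b chain ids (receptor side first)
#' @param params a [contact_params()]
#' @param method `"cell"` (spatial index) or `"brute"` (dense distances)
#' @return data frame with columns `key_a`, `key_b`
#' @export
interface_residue_pairs <- function(x, chain_a, chain_b,
                                    params = contact_params(),
                                    method = c("cell", "brute")) {
  method <- match.arg(method)
  if (!all(c(chain_a, chain_b) %in% x$atom$chain)) {
    stop(sprintf("structure '%s' lacks chain '%s' or '%s'",
                 x$structure_id, chain_a, chain_b), call. = FALSE)
  }
  ra <- residue_rep_atoms(x, chain_a)
  rb <- residue_rep_atoms(x, chain_b)
  hits <- contact_pairs(as.matrix(ra[, c("x", "y", "z")]),
                        as.matrix(rb[, c("x", "y", "z")]),
                        params$cutoff, method)
  data.frame(key_a = ra$key[hits$i], key_b = rb$key[hits$j],
             stringsAsFactors = FALSE)
}

#' Extract the consensus-labelled interface contact set of one complex
#'
#' Residue pairs within the contact cutoff are mapped through the residue
#' mapping to consensus labels; receptor labels are collapsed through
#' [aggregate_label()] (loops/termini without residue-level generic numbers
#' aggregate to their segment). Contact residues without a consensus label
#' are dropped with a warning.
#'
#' @param x a [complex_structure()] with chain pair set
#' @param mapping residue mapping data frame (see [read_mapping_table()])
#' @param params a [contact_params()]
#' @param method contact search method, see [interface_residue_pairs()]
#' @return object of class `contact_set`: list with `receptor_accession`,
#'   `gprotein_accession`, `gprotein_family`, `contacts` (data frame
#'   `receptor_label`, `galpha_label`), `structures`
#' @export
interface_contacts <- function(x, mapping, params = contact_params(),
                               method = c("cell", "brute")) {
  method <- match.arg(method)
  if (is.na(x$receptor_chain) || is.na(x$galpha_chain)) {
    stop("chain pair not set; run select_chain_pair() first", call. = FALSE)
  }
  pairs <- interface_residue_pairs(x, x$receptor_chain, x$galpha_chain,
                                   params, method)
  map <- mapping[mapping$structure_id == x$structure_id, , drop = FALSE]
  key2lab <- stats::setNames(map$consensus_label,
                             res_key(map$chain, map$resnum, map$icode))
  rl <- key2lab[pairs$key_a]
  gl <- key2lab[pairs$key_b]
  drop <- is.na(rl) | is.na(gl)
  if (any(drop)) {
    warning(sprintf("%d contact(s) dropped: residue(s) without consensus label",
                    sum(drop)), call. = FALSE)
  }
  rl <- vapply(rl[!drop], aggregate_label, character(1), side = "receptor")
  gl <- vapply(gl[!drop], aggregate_label, character(1), side = "galpha")
  contacts <- unique(data.frame(receptor_label = unname(rl),
                                galpha_label = unname(gl),
                                stringsAsFactors = FALSE))
  contacts <- contacts[order(contacts$receptor_label, contacts$galpha_label), ,
                       drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(receptor_accession = x$receptor_accession,
                 gprotein_accession = x$gprotein_accession,
                 gprotein_family = x$gprotein_family,
                 contacts = contacts,
                 structures = x$structure_id),
            class = "contact_set")
}

#' Construct a contact set directly from label pairs
#'
#' Used by the synthetic cohort generator and by table import.
#'
#' @param receptor_accession,gprotein_accession complex identity
#' @param contacts data frame with `receptor_label`, `galpha_label`
#' @param gprotein_family G-protein family of the complex
#' @param structures contributing structure ids
#' @return a `contact_set`
#' @export
contact_set <- function(receptor_accession, gprotein_accession, contacts,
                        gprotein_family = NA_character_,
                        structures = character()) {
  stop_if_missing_cols(contacts, c("receptor_label", "galpha_label"),
                       "contacts")
  contacts <- unique(contacts[, c("receptor_label", "galpha_label")])
  contacts <- contacts[order(contacts$receptor_label, contacts$galpha_label), ,
                       drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(receptor_accession = receptor_accession,
                 gprotein_accession = gprotein_accession,
                 gprotein_family = gprotein_family,
                 contacts = contacts, structures = structures),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set %s|%s (%s): %d contacts from %d structure(s)\n",
              x$receptor_accession, x$gprotein_accession, x$gprotein_family,
              nrow(x$contacts), length(x$structures)))
  invisible(x)
}

complex_key <- function(cs) {
  paste(cs$receptor_accession, cs$gprotein_accession, sep = "|")
}

#' Pool contact sets of the same receptor/G-protein pair
#'
#' Contacts of different structures of the same complex are aggregated by
#' set union, so an equivalent residue pair seen in several structures is
#' counted once. All inputs must share the complex key.
#'
#' @param sets list of `contact_set` objects with a common complex key
#' @return a single pooled `contact_set` whose `structures` lists all
#'   contributors
#' @export
pool_by_pair <- function(sets) {
  stopifnot(length(sets) >= 1)
  keys <- vapply(sets, complex_key, character(1))
  if (length(unique(keys)) != 1) {
    stop("cannot pool contact sets with mixed complex keys", call. = FALSE)
  }
  contacts <- unique(do.call(rbind, lapply(sets, `[[`, "contacts")))
  contact_set(sets[[1]]$receptor_accession, sets[[1]]$gprotein_accession,
              contacts, sets[[1]]$gprotein_family,
              sort(unique(unlist(lapply(sets, `[[`, "structures")))))
}

#' Pool a cohort of contact sets by complex key
#'
#' @param sets list of `contact_set` objects (any mixture of complexes)
#' @return named list of pooled `contact_set`s, one per complex key
#' @export
pool_cohort <- function(sets) {
  keys <- vapply(sets, complex_key, character(1))
  out <- lapply(split(sets, keys), pool_by_pair)
  out[order(names(out))]
}

#' Per-group contact frequencies
#'
#' For every observed contact pair and every G-protein group, the fraction
#' of unique complexes in the group displaying the contact.
#'
#' @param pooled named list of pooled `contact_set`s (one per complex)
#' @param groups named character vector complex key -> group label; by
#'   default taken from each set's `gprotein_family`
#' @param min_frequency optional reporting threshold (e.g. 0.2 for heatmap
#'   export); default 0 reports all contacts
#' @return data frame `receptor_label`, `galpha_label`, `group`, `n`,
#'   `frequency`, with group sizes in attribute `"group_sizes"`
#' @export
contact_frequency <- function(pooled, groups = NULL, min_frequency = 0) {
  if (is.null(groups)) {
    groups <- vapply(pooled, `[[`, character(1), "gprotein_family")
    names(groups) <- vapply(pooled, complex_key, character(1))
  }
  keys <- vapply(pooled, complex_key, character(1))
  if (!all(keys %in% names(groups))) {
    stop("every complex must be assigned to a group", call. = FALSE)
  }
  grp <- groups[keys]
  sizes <- table(grp)
  if (any(sizes == 0)) stop("empty group", call. = FALSE)
  long <- do.call(rbind, lapply(seq_along(pooled), function(i) {
    co <- pooled[[i]]$contacts
    if (nrow(co) == 0) return(NULL)
    cbind(co, group = unname(grp[i]), stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0) {
    out <- data.frame(receptor_label = character(),
                      galpha_label = character(), group = character(),
                      n = integer(), frequency = numeric())
    attr(out, "group_sizes") <- sizes
    return(out)
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(long))),
                          long[, c("receptor_label", "galpha_label", "group")],
                          sum)
  agg$frequency <- agg$n / as.integer(sizes[agg$group])
  agg <- agg[agg$frequency > min_frequency | min_frequency == 0, , drop = FALSE]
  agg <- agg[order(agg$receptor_label, agg$galpha_label, agg$group), ,
             drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "group_sizes") <- sizes
  agg
}
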