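# Interface fingerprints (CF/RF/GF), log-odds-ratio contact enrichment,
# the informative-feature filter, Ward clustering of complexes and
# cluster coupling profiles.

#' Build a binary interface fingerprint matrix
#'
#' One row per unique complex, one column per feature. In `CF` mode the
#' features are receptor-label x G-alpha-label contact pairs (encoded
#' `"<receptor>|<galpha>"`); `RF` and `GF` project the contact pairs onto
#' the receptor or G-alpha positions alone. Entries are 1 if the complex
#' shows the feature, else 0.
#'
#' @param pooled named list of pooled `contact_set`s (one per complex, see
#'   [pool_cohort()])
#' @param mode `"CF"`, `"RF"` or `"GF"`
#' @param universe optional character vector fixing the feature set (e.g.
#'   a filtered universe); defaults to the union over the cohort
#' @return binary matrix with complex keys as row names and feature labels
#'   as column names; row annotations (G-protein family) in attribute
#'   `"groups"`
#' @export
build_fingerprints <- function(pooled, mode = c("CF", "RF", "GF"),
                               universe = NULL) {
  mode <- match.arg(mode)
  feat_of <- function(cs) {
    co <- cs$contacts
    switch(mode,
           CF = paste(co$receptor_label, co$galpha_label, sep = "|"),
           RF = unique(co$receptor_label),
           GF = unique(co$galpha_label))
  }
  feats <- lapply(pooled, feat_of)
  if (is.null(universe)) universe <- sort(unique(unlist(feats)))
  if (length(universe) == 0) stop("empty feature universe", call. = FALSE)
  keys <- vapply(pooled, complex_key, character(1))
  m <- matrix(0L, nrow = length(pooled), ncol = length(universe),
              dimnames = list(keys, universe))
  for (i in seq_along(pooled)) {
    m[i, intersect(feats[[i]], universe)] <- 1L
  }
  attr(m, "groups") <- stats::setNames(
    vapply(pooled, `[[`, character(1), "gprotein_family"), keys)
  m
}

#' Contingency table of one feature against one coupling group
#'
#' Cells follow the coupled/contact layout: `CC` coupled-and-contact,
#' `CN` coupled-no-contact, `NC` not-coupled-and-contact, `NN`
#' not-coupled-no-contact, where "coupled" means membership in group `g`.
#'
#' @param fingerprints binary fingerprint matrix
#' @param feature column name
#' @param groups group label per row (named by row or in row order)
#' @param g the group treated as "coupled"
#' @return named integer vector `c(CC, CN, NC, NN)` of class
#'   `contingency_table`
#' @export
contingency <- function(fingerprints, feature, groups, g) {
  v <- fingerprints[, feature]
  if (!is.null(names(groups))) groups <- groups[rownames(fingerprints)]
  ing <- groups == g
  if (!any(ing) || all(ing)) {
    stop(sprintf("group '%s' is empty or universal", g), call. = FALSE)
  }
  out <- c(CC = sum(v == 1 & ing), CN = sum(v == 0 & ing),
           NC = sum(v == 1 & !ing), NN = sum(v == 0 & !ing))
  structure(as.integer(out), names = names(out),
            class = "contingency_table")
}

#' Log-odds ratio of a 2x2 contingency table
#'
#' The `standard` variant is the log odds ratio
#' `ln((CC * NN) / (CN * NC))`; the `as_printed` variant is
#' `ln((CC / NN) * (NC / CN))`, i.e. `ln((CC * NC) / (NN * CN))` — the two
#' differ, and both are exposed (see the package vignette for why). If any
#' cell is zero a Haldane-Anscombe pseudocount is added to all four cells.
#'
#' @param table contingency counts: a `contingency_table`, or a numeric
#'   vector/list with elements `CC`, `CN`, `NC`, `NN`
#' @param variant `"standard"` (default) or `"as_printed"`
#' @param pseudocount value added to every cell when any cell is zero
#'   (default 0.5)
#' @return log-odds ratio in natural-log units
#' @export
log_odds <- function(table, variant = c("standard", "as_printed"),
                     pseudocount = 0.5) {
  variant <- match.arg(variant)
  tb <- unlist(table)[c("CC", "CN", "NC", "NN")]
  if (any(is.na(tb)) || any(tb < 0)) {
    stop("contingency cells must be non-negative counts CC, CN, NC, NN",
         call. = FALSE)
  }
  if (all(tb == 0)) stop("all contingency cells are zero", call. = FALSE)
  if (any(tb == 0)) tb <- tb + pseudocount
  if (variant == "standard") {
    # difference of log-sums: swapping the group with its complement maps
    # (CC,CN,NC,NN) -> (NC,NN,CC,CN) and negates the value bit-exactly
    (log(tb[["CC"]]) + log(tb[["NN"]])) -
      (log(tb[["CN"]]) + log(tb[["NC"]]))
  } else {
    log((tb[["CC"]] / tb[["NN"]]) * (tb[["NC"]] / tb[["CN"]]))
  }
}

#' Per-feature, per-group enrichment records
#'
#' Computes the contingency table and log-odds ratio of every fingerprint
#' column against every group, plus the overall contact frequency of the
#' column across the cohort.
#'
#' @inheritParams contingency
#' @param groups group label per row
#' @param variant passed to [log_odds()]
#' @param pseudocount passed to [log_odds()]
#' @return data frame `feature`, `group`, `CC`, `CN`, `NC`, `NN`, `lor`,
#'   `frequency`, `pseudocount_applied`
#' @export
enrichment_table <- function(fingerprints, groups,
                             variant = c("standard", "as_printed"),
                             pseudocount = 0.5) {
  variant <- match.arg(variant)
  if (!is.null(names(groups))) groups <- groups[rownames(fingerprints)]
  levs <- sort(unique(groups))
  rows <- list()
  for (g in levs) {
    for (f in colnames(fingerprints)) {
      tb <- contingency(fingerprints, f, groups, g)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group = g,
        CC = tb[["CC"]], CN = tb[["CN"]], NC = tb[["NC"]], NN = tb[["NN"]],
        lor = log_odds(tb, variant, pseudocount),
        frequency = mean(fingerprints[, f]),
        pseudocount_applied = any(tb == 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep informative fingerprint features
#'
#' A column is retained when its contact frequency over the whole cohort is
#' at least `min_frequency` and its absolute log-odds ratio exceeds
#' `min_abs_lor` for at least one group.
#'
#' @param fingerprints binary fingerprint matrix
#' @param enrichment output of [enrichment_table()] covering all columns
#' @param min_frequency minimum cohort-wide frequency (default 0.10)
#' @param min_abs_lor |LOR| must exceed this in some group (default 2,
#'   natural-log units; strict inequality)
#' @return the filtered matrix (possibly with zero columns, with a warning)
#' @export
filter_informative <- function(fingerprints, enrichment,
                               min_frequency = 0.10, min_abs_lor = 2) {
  if (!all(colnames(fingerprints) %in% enrichment$feature)) {
    stop("enrichment records do not cover all fingerprint columns",
         call. = FALSE)
  }
  freq <- colMeans(fingerprints)
  maxlor <- tapply(abs(enrichment$lor), enrichment$feature, max)
  keep <- freq >= min_frequency &
    maxlor[colnames(fingerprints)] > min_abs_lor
  if (!any(keep)) warning("no informative features retained", call. = FALSE)
  out <- fingerprints[, keep, drop = FALSE]
  attr(out, "groups") <- attr(fingerprints, "groups")
  out
}

#' Ward clustering of fingerprint rows
#'
#' Agglomerative hierarchical clustering of the binary rows with Euclidean
#' distance and Ward linkage (`ward.D2`, the Ward criterion on unsquared
#' distances, matching the usual scipy/seaborn behaviour), cut into `k`
#' clusters.
#'
#' @param fingerprints binary fingerprint matrix (rows are complexes)
#' @param k number of clusters (default 2)
#' @return integer cluster labels named by row; the `hclust` tree is in
#'   attribute `"tree"`
#' @export
cluster_fingerprints <- function(fingerprints, k = 2) {
  n <- nrow(fingerprints)
  if (k > n) stop("k exceeds the number of complexes", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  hc <- stats::hclust(stats::dist(fingerprints), method = "ward.D2")
  # the cut into k clusters removes the top k-1 merges; if the first of
  # those merges has zero height, the split is arbitrary
  if (hc$height[n - k + 1] == 0) {
    warning("degenerate clustering: zero-height merges at the cut level",
            call. = FALSE)
  }
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}

#' Coupling composition of fingerprint clusters
#'
#' For each cluster and each G-protein family, the fraction of its
#' receptors experimentally reported as coupled according to the coupling
#' map. Receptors absent from the map are counted separately as unknown.
#'
#' @param labels cluster labels named by complex key
#'   (`"<receptor>|<gprotein>"`) or by receptor accession
#' @param coupling_map data frame `receptor_accession`, `family`,
#'   `coupled` (0/1)
#' @return data frame `cluster`, `family`, `n_receptors`, `n_coupled`,
#'   `fraction`, plus per-cluster `n_unknown` in attribute `"unknown"`
#' @export
cluster_coupling_profile <- function(labels, coupling_map) {
  stop_if_missing_cols(coupling_map,
                       c("receptor_accession", "family", "coupled"),
                       "coupling map")
  recs <- sub("\\|.*$", "", names(labels))
  fams <- sort(unique(coupling_map$family))
  unknown <- integer(0)
  rows <- list()
  for (cl in sort(unique(labels))) {
    rc <- recs[labels == cl]
    known <- rc %in% coupling_map$receptor_accession
    unknown[as.character(cl)] <- sum(!known)
    for (fam in fams) {
      sub <- coupling_map[coupling_map$family == fam &
                            coupling_map$receptor_accession %in% rc[known], ,
                          drop = FALSE]
      n <- length(rc[known])
      nc <- sum(sub$coupled == 1)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, family = fam, n_receptors = n, n_coupled = nc,
        fraction = if (n > 0) nc / n else 0, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unknown") <- unknown
  out
}
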