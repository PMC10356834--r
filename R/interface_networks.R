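# SSE-level contact networks, per-structure contact graphs, Frobenius
# graph distances and permutation tests (PERMANOVA / PERMDISP).

#' Build the secondary-structure contact network of a group
#'
#' Contacting consensus positions are projected onto their secondary
#' structure elements. Nodes are SSEs (receptor and G-alpha side flagged);
#' a node's weight is the total number of distinct contact pairs it
#' mediates across the group; an edge's weight is the number of unique
#' complexes showing at least one contact between the two SSEs, and its
#' conservation is the mean per-position-pair contact fraction.
#'
#' @param pooled named list of pooled `contact_set`s belonging to one group
#' @param group group label recorded on the network
#' @param frequency output of [contact_frequency()] holding the per-pair
#'   fractions for `group`; computed from `pooled` when omitted
#' @return object of class `sse_network`: list with `nodes` and `edges`
#'   data frames and `group`
#' @export
build_sse_network <- function(pooled, group = NA_character_,
                              frequency = NULL) {
  if (length(pooled) == 0) stop("empty group", call. = FALSE)
  if (is.null(frequency)) {
    frequency <- contact_frequency(pooled,
                                   groups = stats::setNames(
                                     rep(group, length(pooled)),
                                     vapply(pooled, complex_key, character(1))))
  } else {
    frequency <- frequency[frequency$group %in% group, , drop = FALSE]
  }
  long <- do.call(rbind, lapply(pooled, function(cs) {
    co <- cs$contacts
    if (nrow(co) == 0) return(NULL)
    data.frame(complex = complex_key(cs),
               receptor_label = co$receptor_label,
               galpha_label = co$galpha_label, stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0) {
    return(structure(list(
      nodes = data.frame(name = character(), side = character(),
                         weight = integer()),
      edges = data.frame(receptor_sse = character(),
                         galpha_sse = character(), n_complexes = integer(),
                         conservation = numeric()),
      group = group), class = "sse_network"))
  }
  long$rsse <- vapply(long$receptor_label, sse_from_label, character(1),
                      side = "receptor")
  long$gsse <- vapply(long$galpha_label, sse_from_label, character(1),
                      side = "galpha")
  # node weight: distinct contact pairs (complex-deduplicated upstream,
  # summed over complexes) mediated by the SSE
  rw <- tapply(rep(1L, nrow(long)), long$rsse, sum)
  gw <- tapply(rep(1L, nrow(long)), long$gsse, sum)
  nodes <- rbind(
    data.frame(name = names(rw), side = "receptor",
               weight = as.integer(rw), stringsAsFactors = FALSE),
    data.frame(name = names(gw), side = "galpha",
               weight = as.integer(gw), stringsAsFactors = FALSE))
  ek <- paste(long$rsse, long$gsse, sep = "~")
  n_complexes <- tapply(long$complex, ek, function(z) length(unique(z)))
  # conservation: mean frequency of the position pairs behind the edge
  frequency$rsse <- vapply(frequency$receptor_label, sse_from_label,
                           character(1), side = "receptor")
  frequency$gsse <- vapply(frequency$galpha_label, sse_from_label,
                           character(1), side = "galpha")
  fk <- paste(frequency$rsse, frequency$gsse, sep = "~")
  cons <- tapply(frequency$frequency, fk, mean)
  ekeys <- sort(unique(ek))
  parts <- strsplit(ekeys, "~", fixed = TRUE)
  edges <- data.frame(
    receptor_sse = vapply(parts, `[`, character(1), 1),
    galpha_sse = vapply(parts, `[`, character(1), 2),
    n_complexes = as.integer(n_complexes[ekeys]),
    conservation = as.numeric(cons[ekeys]),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$side, nodes$name), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, group = group),
            class = "sse_network")
}

#' Convert an SSE network to an igraph graph
#'
#' Bipartite, undirected; node and edge attributes carried over. Receptor
#' and G-alpha SSEs sharing a name are disambiguated by side prefix.
#'
#' @param net an `sse_network`
#' @return an [igraph::graph] object
#' @export
sse_network_igraph <- function(net) {
  vid <- function(name, side) paste(ifelse(side == "receptor", "R", "G"),
                                    name, sep = ":")
  vertices <- data.frame(name = vid(net$nodes$name, net$nodes$side),
                         side = net$nodes$side, weight = net$nodes$weight,
                         stringsAsFactors = FALSE)
  edges <- data.frame(from = vid(net$edges$receptor_sse, "receptor"),
                      to = vid(net$edges$galpha_sse, "galpha"),
                      n_complexes = net$edges$n_complexes,
                      conservation = net$edges$conservation,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Node degree and betweenness of an SSE network
#'
#' Shortest-path betweenness on the unweighted graph (tied shortest paths
#' split equally), unnormalized by default; disconnected components are
#' handled pairwise.
#'
#' @param net an `sse_network` or an igraph graph
#' @param normalized rescale betweenness by the number of ordered pairs
#' @return data frame `node`, `side`, `degree`, `betweenness`
#' @export
node_betweenness <- function(net, normalized = FALSE) {
  g <- if (inherits(net, "sse_network")) sse_network_igraph(net) else net
  bt <- igraph::betweenness(g, directed = FALSE, weights = NA,
                            normalized = normalized)
  dg <- igraph::degree(g)
  nm <- igraph::V(g)$name
  side <- if ("side" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$side
  } else rep(NA_character_, length(nm))
  data.frame(node = nm, side = side, degree = as.integer(dg),
             betweenness = as.numeric(bt), stringsAsFactors = FALSE)
}

#' Binary per-structure contact graph over a fixed universe
#'
#' @param cs a `contact_set`
#' @param universe list with `receptor` and `galpha` label vectors fixing
#'   the adjacency dimensions across the cohort
#' @return binary matrix, rows = receptor labels, columns = G-alpha labels
#' @export
structure_contact_graph <- function(cs, universe) {
  stopifnot(is.list(universe), !is.null(universe$receptor),
            !is.null(universe$galpha))
  co <- cs$contacts
  out_r <- setdiff(co$receptor_label, universe$receptor)
  out_g <- setdiff(co$galpha_label, universe$galpha)
  if (length(out_r) + length(out_g) > 0) {
    stop(sprintf("contact outside universe: %s",
                 paste(c(out_r, out_g), collapse = ", ")), call. = FALSE)
  }
  m <- matrix(0L, length(universe$receptor), length(universe$galpha),
              dimnames = list(universe$receptor, universe$galpha))
  if (nrow(co) > 0) m[cbind(co$receptor_label, co$galpha_label)] <- 1L
  m
}

#' Universe of contact labels across a cohort
#'
#' @param pooled list of `contact_set`s
#' @return list with sorted `receptor` and `galpha` label vectors
#' @export
contact_universe <- function(pooled) {
  all <- do.call(rbind, lapply(pooled, `[[`, "contacts"))
  list(receptor = sort(unique(all$receptor_label)),
       galpha = sort(unique(all$galpha_label)))
}

#' Frobenius distance between two contact adjacencies
#'
#' @param a,b matrices of identical shape
#' @return `sqrt(sum((a - b)^2))`
#' @export
graph_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Pairwise Frobenius distance matrix of a cohort's contact graphs
#'
#' @param pooled named list of `contact_set`s (one per complex)
#' @param universe optional fixed universe; defaults to the cohort union
#' @return symmetric distance matrix with complex keys as dimnames and the
#'   per-complex group labels in attribute `"groups"`
#' @export
graph_distance_matrix <- function(pooled, universe = NULL) {
  if (is.null(universe)) universe <- contact_universe(pooled)
  adjs <- lapply(pooled, structure_contact_graph, universe = universe)
  keys <- vapply(pooled, complex_key, character(1))
  n <- length(adjs)
  d <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- graph_distance(adjs[[i]], adjs[[j]])
    }
  }
  attr(d, "groups") <- stats::setNames(
    vapply(pooled, `[[`, character(1), "gprotein_family"), keys)
  d
}

# Within-group sum of squared interpoint distances / group size, summed
# over groups (the PERMANOVA residual sum of squares).
.ssw <- function(d2, groups) {
  s <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

.permanova_f <- function(d2, groups, n, a, sst) {
  ssw <- .ssw(d2, groups)
  ssa <- sst - ssw
  if (ssw == 0 && ssa == 0) return(NaN)
  (ssa / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F
#' statistic compares between-group to within-group sums of squared
#' distances and is recomputed under random permutations of the group
#' labels. The p-value uses the standard permutation estimator
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' @param d distance matrix (or `dist`)
#' @param groups group label per row
#' @param n_permutations number of label permutations (default 9999)
#' @param seed RNG seed for the permutations
#' @return object of class `permutation_test`: list with `statistic`,
#'   `p_value`, `n_permutations`, `seed`, `method`
#' @export
permanova <- function(d, groups, n_permutations = 9999, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  n <- length(groups)
  stopifnot(nrow(d) == n)
  a <- length(unique(groups))
  if (a < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least two members", call. = FALSE)
  }
  d2 <- d^2
  sst <- sum(d2) / (2 * n)
  f_obs <- .permanova_f(d2, groups, n, a, sst)
  if (is.nan(f_obs)) {
    stop("pseudo-F undefined: all pairwise distances are zero",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    fp <- .permanova_f(d2, sample(groups), n, a, sst)
    if (!is.nan(fp) && fp >= f_obs) count <- count + 1L
  }
  structure(list(statistic = f_obs,
                 p_value = (1 + count) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed,
                 method = "PERMANOVA"),
            class = "permutation_test")
}

#' PERMDISP on a distance matrix
#'
#' Homogeneity-of-dispersion test: points are embedded by principal
#' coordinates ([vegan::betadisper()], centroid type), each point's
#' distance to its group centroid is taken as its dispersion, and the
#' one-way ANOVA F on those distances is recomputed under permutations of
#' the distances across groups.
#'
#' @inheritParams permanova
#' @return a `permutation_test` (method `"PERMDISP"`)
#' @export
permdisp <- function(d, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  n <- length(groups)
  a <- length(unique(groups))
  if (a < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least two members", call. = FALSE)
  }
  bd <- vegan::betadisper(stats::as.dist(d), groups, type = "centroid")
  z <- as.numeric(bd$distances)
  f_stat <- function(z, g) {
    gm <- tapply(z, g, mean)
    ng <- tapply(z, g, length)
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[g])^2)
    if (ssw == 0 && ssb == 0) return(0)
    if (ssw == 0) return(Inf)
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(z, groups)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    if (f_stat(z[sample.int(n)], groups) >= f_obs) count <- count + 1L
  }
  structure(list(statistic = f_obs,
                 p_value = (1 + count) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed,
                 method = "PERMDISP"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
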