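# Superposition on consensus cores, docking-mode RMSD analysis, pose
# clustering, centroid selection and per-position RMSF profiles.

#' Coordinate set on a consensus core
#'
#' Calpha coordinates of one complex restricted to the consensus core,
#' split into the receptor-core block (used for fitting) and the
#' G-alpha-core block (used for RMSD/RMSF).
#'
#' @param receptor numeric matrix n_rec x 3 with receptor core labels as
#'   row names
#' @param galpha numeric matrix n_ga x 3 with G-alpha core labels as row
#'   names
#' @return object of class `coordinate_set`
#' @export
coordinate_set <- function(receptor, galpha) {
  receptor <- as.matrix(receptor); galpha <- as.matrix(galpha)
  stopifnot(ncol(receptor) == 3, ncol(galpha) == 3,
            !is.null(rownames(receptor)), !is.null(rownames(galpha)),
            all(is.finite(receptor)), all(is.finite(galpha)))
  structure(list(receptor = receptor, galpha = galpha),
            class = "coordinate_set")
}

#' Extract core Calpha coordinates from a structure
#'
#' @param x a [complex_structure()] with chain pair set
#' @param mapping residue mapping table
#' @param core a [build_consensus_core()] result
#' @return a [coordinate_set()]; missing core positions are an error
#' @export
structure_to_coordset <- function(x, mapping, core) {
  map <- mapping[mapping$structure_id == x$structure_id, , drop = FALSE]
  get_block <- function(chain, labels) {
    ca <- x$atom[x$atom$chain == chain & x$atom$elety == "CA", ,
                 drop = FALSE]
    key2xyz <- as.matrix(ca[, c("x", "y", "z")])
    rownames(key2xyz) <- res_key(ca$chain, ca$resno, ca$insert)
    sub <- map[map$chain == chain, , drop = FALSE]
    lab2key <- stats::setNames(res_key(sub$chain, sub$resnum, sub$icode),
                               sub$consensus_label)
    keys <- lab2key[labels]
    if (any(is.na(keys)) || !all(keys %in% rownames(key2xyz))) {
      stop(sprintf("structure '%s' is missing core position(s): %s",
                   x$structure_id,
                   paste(labels[is.na(keys) |
                                  !(keys %in% rownames(key2xyz))][1:3],
                         collapse = ", ")), call. = FALSE)
    }
    m <- key2xyz[keys, , drop = FALSE]
    rownames(m) <- labels
    m
  }
  coordinate_set(get_block(x$receptor_chain, core$receptor),
                 get_block(x$galpha_chain, core$galpha))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Returns the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `target` over paired points. Degenerate inputs (< 3
#' points, or a collinear point set, for which the rotation about the line
#' is undetermined) are errors.
#'
#' @param mobile,target n x 3 coordinate matrices with matching rows
#' @return list with `rotation` (3x3, determinant +1) and `translation`
#'   (length 3), mapping x to `rotation %*% x + translation`
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("point sets differ in size",
                                         call. = FALSE)
  if (nrow(mobile) < 3) stop("need at least 3 fit points", call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  M <- sweep(mobile, 2, cm); Tt <- sweep(target, 2, ct)
  sv <- svd(M)$d
  if (sv[2] <= 1e-8 * max(sv[1], 1)) {
    stop("degenerate fit set: points are collinear", call. = FALSE)
  }
  s <- svd(t(M) %*% Tt)
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(ct - R %*% cm))
}

#' Apply a rigid transform to coordinates
#'
#' @param x n x 3 matrix or a [coordinate_set()]
#' @param tf transform from [kabsch_fit()]
#' @return object of the same type, transformed
#' @export
apply_transform <- function(x, tf) {
  tx <- function(m) sweep(m %*% t(tf$rotation), 2, tf$translation, "+")
  if (inherits(x, "coordinate_set")) {
    out <- x
    out$receptor <- tx(x$receptor)
    out$galpha <- tx(x$galpha)
    return(out)
  }
  tx(as.matrix(x))
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Docking-mode RMSD between two complexes
#'
#' `b` is fitted onto `a` using the receptor-core Calphas; the RMSD is then
#' computed over the G-alpha-core Calphas under that transform, so the
#' value measures how differently the G-protein docks onto a common
#' receptor frame.
#'
#' @param a,b [coordinate_set()] objects covering the same core
#' @return RMSD in Angstrom
#' @export
pose_rmsd <- function(a, b) {
  if (!identical(rownames(a$receptor), rownames(b$receptor)) ||
      !identical(rownames(a$galpha), rownames(b$galpha))) {
    stop("coordinate sets cover different cores", call. = FALSE)
  }
  tf <- kabsch_fit(b$receptor, a$receptor)
  .rmsd(a$galpha, apply_transform(b$galpha, tf))
}

#' Pairwise docking-mode RMSD matrix of an ensemble
#'
#' The small fit-direction asymmetry of [pose_rmsd()] is removed
#' deterministically: each entry is computed with the lexicographically
#' smaller complex key as the fit target.
#'
#' @param ensemble named list of [coordinate_set()]s
#' @param groups optional group label per member (named)
#' @return symmetric matrix with zero diagonal; groups (if given) in
#'   attribute `"groups"`
#' @export
rmsd_matrix <- function(ensemble, groups = NULL) {
  stopifnot(length(ensemble) >= 2, !is.null(names(ensemble)))
  keys <- names(ensemble)
  n <- length(keys)
  d <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tgt <- if (keys[i] <= keys[j]) i else j
      mob <- if (tgt == i) j else i
      d[i, j] <- d[j, i] <- pose_rmsd(ensemble[[tgt]], ensemble[[mob]])
    }
  }
  if (!is.null(groups)) attr(d, "groups") <- groups[keys]
  d
}

#' Ward clustering of docking modes
#'
#' The RMSD matrix rows are treated as feature vectors (as a clustermap
#' would) and clustered with Euclidean distance / Ward linkage, cut at
#' `k`.
#'
#' @param d RMSD matrix from [rmsd_matrix()]
#' @param k number of pose clusters (default 3)
#' @return integer labels named by complex key, tree in attribute
#'   `"tree"`
#' @export
cluster_rmsd <- function(d, k = 3) {
  n <- nrow(d)
  if (k > n) stop("k exceeds the ensemble size", call. = FALSE)
  hc <- stats::hclust(stats::dist(d), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}

#' Centroid complex of a pose group
#'
#' The member with the least mean RMSD to the other members of the group;
#' ties resolved lexicographically on the complex key.
#'
#' @param d RMSD matrix
#' @param members keys of the group (default: all rows)
#' @return the centroid's complex key
#' @export
pose_centroid <- function(d, members = rownames(d)) {
  if (length(members) == 0) stop("empty group", call. = FALSE)
  if (length(members) == 1) return(members)
  sub <- d[members, members, drop = FALSE]
  means <- rowSums(sub) / (length(members) - 1)
  members[order(means, members)][1]
}

#' Per-position RMSF profile of an ensemble
#'
#' Each member is fitted onto the reference using the receptor core; for
#' every G-alpha core position the fluctuation is the root of the mean
#' (over members) squared Euclidean deviation from the reference
#' coordinate. The per-position mean and SD of the deviations are reported
#' alongside.
#'
#' @param ensemble named list of [coordinate_set()]s
#' @param reference a [coordinate_set()] (e.g. the group centroid or a
#'   known mean structure) covering the same core
#' @return data frame `label`, `rmsf`, `mean_dev`, `sd_dev`
#' @export
rmsf_profile <- function(ensemble, reference) {
  stopifnot(length(ensemble) >= 1)
  labs <- rownames(reference$galpha)
  devs <- vapply(ensemble, function(m) {
    if (!identical(rownames(m$galpha), labs)) {
      stop("ensemble member does not cover the reference core",
           call. = FALSE)
    }
    tf <- kabsch_fit(m$receptor, reference$receptor)
    sqrt(rowSums((apply_transform(m$galpha, tf) - reference$galpha)^2))
  }, numeric(length(labs)))
  devs <- matrix(devs, nrow = length(labs),
                 dimnames = list(labs, names(ensemble)))
  data.frame(label = labs,
             rmsf = sqrt(rowMeans(devs^2)),
             mean_dev = rowMeans(devs),
             sd_dev = apply(devs, 1, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}
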