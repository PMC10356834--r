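# Seeded synthetic complexes, cohorts and model sets with planted ground
# truth. The generators emulate the study conditions of the analysis
# pipeline: an idealized 7TM receptor bundle docked by a G-alpha whose
# C-terminal helix (H5) inserts into the intracellular cavity; cohorts of
# contact fingerprints with group-specific planted contact probabilities;
# pose ensembles with group-specific rigid docking modes plus isotropic
# Gaussian coordinate noise; and predicted-model sets whose pass/fail
# verdict at every QC stage is known by construction.

# Ideal helix in local coordinates: radius (A), rise per residue (A),
# 100-degree turn; n CA positions along +z starting at z0.
.helix_points <- function(n, radius = 2.3, rise = 1.5, z0 = 0,
                          phase = 0, direction = 1) {
  i <- seq_len(n) - 1
  ang <- phase + i * 100 * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), z0 + direction * rise * i)
}

#' Build the synthetic complex template
#'
#' An idealized receptor/G-alpha complex: seven transmembrane helical arcs
#' on a circle (the 7TM bundle, intracellular face at z = 0) and a G-alpha
#' whose H5 helix inserts into the intracellular cavity from below, an H4
#' arm running under the intracellular face, and the remaining CGN
#' segments (HN, S1, S3) further away. Every residue carries backbone
#' pseudo-atoms (N, CA, C, O) plus CB/CG/CD side-chain pseudo-atoms
#' (glycines: backbone only), a GPCRdb-style or CGN consensus label and an
#' SSE assignment. Deterministic for a given seed.
#'
#' @param n_receptor_core receptor core size (split over the 7 TM helices;
#'   >= 7)
#' @param n_galpha_core G-alpha core size (H5 plus HN/S1/S3; >= 4)
#' @param seed RNG seed for the small coordinate jitter that avoids exact
#'   degeneracies
#' @return list with `structure` (a [complex_structure()] with chain pair
#'   `R`/`G` set), `mapping` (residue mapping data frame, structure_id
#'   `"template"`), and `labels` (list `receptor`, `galpha` in core order)
#' @export
make_template <- function(n_receptor_core = 70, n_galpha_core = 36,
                          seed = 1) {
  stopifnot(n_receptor_core >= 7, n_galpha_core >= 4)
  set.seed(seed)
  bundle_radius <- 6.0
  per_tm <- rep(n_receptor_core %/% 7, 7)
  extra <- n_receptor_core %% 7
  if (extra > 0) per_tm[seq_len(extra)] <- per_tm[seq_len(extra)] + 1
  rec <- list()
  for (h in 1:7) {
    ctr_ang <- 2 * pi * (h - 1) / 7
    ctr <- bundle_radius * c(cos(ctr_ang), sin(ctr_ang))
    ca <- .helix_points(per_tm[h], z0 = 0, phase = h)
    ca[, 1] <- ca[, 1] + ctr[1]
    ca[, 2] <- ca[, 2] + ctr[2]
    rec[[h]] <- data.frame(
      label = sprintf("%d.%d", h, 45 + seq_len(per_tm[h]) - 1),
      x = ca[, 1], y = ca[, 2], z = ca[, 3],
      # CB points radially out of the helix axis
      hx = ctr[1], hy = ctr[2], stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rec)
  # G-alpha: H5 inserts from below; HN, S1, S3 sit deeper
  n_h5 <- min(16L, max(4L, round(0.45 * n_galpha_core)))
  n_rest <- n_galpha_core - n_h5
  n_h4 <- min(10L, n_rest %/% 2)
  n_rest <- n_rest - n_h4
  n_s1 <- n_rest %/% 3
  n_s3 <- n_rest %/% 3
  n_hn <- n_rest - n_s1 - n_s3
  h5 <- .helix_points(n_h5, z0 = 12.0, direction = -1)
  h5[, 1] <- h5[, 1] + 0.8
  ga <- data.frame(
    label = sprintf("G.H5.%d", 25 - seq_len(n_h5) + 1),
    x = h5[, 1], y = h5[, 2], z = h5[, 3],
    hx = 0.8, hy = 0, stringsAsFactors = FALSE)
  z_deep <- min(h5[, 3]) - 4
  add_seg <- function(n, name, x0, y0) {
    if (n == 0) return(NULL)
    data.frame(label = sprintf("G.%s.%d", name, seq_len(n)),
               x = x0, y = y0, z = z_deep - 3.0 * (seq_len(n) - 1),
               hx = x0 * 2, hy = y0 * 2, stringsAsFactors = FALSE)
  }
  # H4 runs horizontally under the intracellular face, widening the
  # interface beyond the inserted H5 tip
  h4 <- if (n_h4 > 0) {
    yy <- 2.2 * (seq_len(n_h4) - (n_h4 + 1) / 2)
    data.frame(label = sprintf("G.H4.%d", seq_len(n_h4)),
               x = 4.3, y = yy, z = -2.2, hx = 9, hy = yy,
               stringsAsFactors = FALSE)
  } else NULL
  ga <- rbind(ga, h4, add_seg(n_hn, "HN", 0, 6), add_seg(n_s1, "S1", 6, 0),
              add_seg(n_s3, "S3", -6, 0))
  build_atoms <- function(df, chain) {
    n <- nrow(df)
    is_gly <- (seq_len(n) %% 7) == 0
    ca <- data.frame(chain = chain, resno = seq_len(n), insert = "",
                     resid = ifelse(is_gly, "GLY", "ALA"), elety = "CA",
                     x = df$x, y = df$y, z = df$z, occ = 1, alt = "",
                     stringsAsFactors = FALSE)
    # backbone pseudo-atoms flank the CA along the chain direction so the
    # model has realistic atom density for surface-area work
    mk <- function(base, ety, dx, dy, dz) {
      out <- base
      out$elety <- ety
      out$x <- out$x + dx; out$y <- out$y + dy; out$z <- out$z + dz
      out
    }
    bbN <- mk(ca, "N", 0.8, 0.5, -1.0)
    bbC <- mk(ca, "C", -0.8, 0.5, 1.0)
    bbO <- mk(ca, "O", -1.2, -0.6, 1.6)
    # side-chain pseudo atoms point away from the local helix/strand axis
    dir <- cbind(df$x - df$hx, df$y - df$hy, 0)
    nrm <- sqrt(rowSums(dir^2)); nrm[nrm == 0] <- 1
    dir <- dir / nrm
    cb <- ca[!is_gly, , drop = FALSE]
    cb$elety <- "CB"
    cb$x <- cb$x + 1.5 * dir[!is_gly, 1]
    cb$y <- cb$y + 1.5 * dir[!is_gly, 2]
    cg <- ca[!is_gly, , drop = FALSE]
    cg$elety <- "CG"
    cg$x <- cg$x + 2.9 * dir[!is_gly, 1]
    cg$y <- cg$y + 2.9 * dir[!is_gly, 2]
    cd <- ca[!is_gly, , drop = FALSE]
    cd$elety <- "CD"
    cd$x <- cd$x + 4.2 * dir[!is_gly, 1]
    cd$y <- cd$y + 4.2 * dir[!is_gly, 2]
    out <- rbind(ca, bbN, bbC, bbO, cb, cg, cd)
    out[order(out$resno, out$elety), , drop = FALSE]
  }
  atoms <- rbind(build_atoms(rec, "R"), build_atoms(ga, "G"))
  # sub-Angstrom jitter: breaks exact symmetries/collinearities
  atoms$x <- atoms$x + stats::runif(nrow(atoms), -0.05, 0.05)
  atoms$y <- atoms$y + stats::runif(nrow(atoms), -0.05, 0.05)
  atoms$z <- atoms$z + stats::runif(nrow(atoms), -0.05, 0.05)
  st <- complex_structure("template", atoms,
                          receptor_chain = "R", galpha_chain = "G",
                          receptor_accession = "RCPT01",
                          gprotein_accession = "GNAS01",
                          gprotein_family = "Gs", receptor_class = "A")
  mapping <- rbind(
    data.frame(structure_id = "template", chain = "R",
               resnum = seq_len(nrow(rec)), icode = "",
               uniprot_acc = "RCPT01", uniprot_pos = seq_len(nrow(rec)),
               consensus_label = rec$label,
               sse = vapply(rec$label, sse_from_label, character(1),
                            side = "receptor"), stringsAsFactors = FALSE),
    data.frame(structure_id = "template", chain = "G",
               resnum = seq_len(nrow(ga)), icode = "",
               uniprot_acc = "GNAS01", uniprot_pos = seq_len(nrow(ga)),
               consensus_label = ga$label,
               sse = vapply(ga$label, sse_from_label, character(1),
                            side = "galpha"), stringsAsFactors = FALSE))
  list(structure = st, mapping = mapping,
       labels = list(receptor = rec$label, galpha = ga$label))
}

# Rotation matrix about a unit axis by angle (radians).
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)),
    3, 3, byrow = TRUE)
}

# Apply a rigid transform to the G-alpha chain of a template-derived
# structure, leaving the receptor in place.
.transform_galpha <- function(st, rotation, translation) {
  out <- st
  idx <- out$atom$chain == out$galpha_chain
  xyz <- as.matrix(out$atom[idx, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  out$atom[idx, c("x", "y", "z")] <- xyz
  out
}

#' Sample a pose ensemble with planted docking modes
#'
#' Each ensemble member is the receptor template plus the G-alpha template
#' transformed by its group's rigid docking transform, with i.i.d.
#' isotropic Gaussian noise of the given standard deviation added to every
#' atom coordinate.
#'
#' @param template output of [make_template()]
#' @param transforms named list, one entry per group, each a list with
#'   `rotation` (3x3) and `translation` (length 3) applied to the G-alpha
#'   block
#' @param n_per_group members per group (recycled over groups)
#' @param sigma per-coordinate noise SD in Angstrom
#' @param seed RNG seed
#' @return list with `structures` (named list of [complex_structure()]),
#'   `mapping` (rows for every member), `groups` (named vector
#'   structure_id -> group), `transforms`
#' @export
sample_pose_ensemble <- function(template,
                                 transforms = list(
                                   A = list(rotation = diag(3),
                                            translation = c(0, 0, 0)),
                                   B = list(rotation = diag(3),
                                            translation = c(12, 0, 0))),
                                 n_per_group = 10, sigma = 0.5, seed = 1) {
  set.seed(seed)
  n_per_group <- rep(n_per_group, length.out = length(transforms))
  structures <- list()
  groups <- character()
  maps <- list()
  for (gi in seq_along(transforms)) {
    g <- names(transforms)[gi]
    for (i in seq_len(n_per_group[gi])) {
      id <- sprintf("pose_%s_%02d", gsub("[^A-Za-z0-9]", "", g), i)
      st <- .transform_galpha(template$structure,
                              transforms[[gi]]$rotation,
                              transforms[[gi]]$translation)
      st$structure_id <- id
      st$receptor_accession <- sprintf("R%s%02d", gsub("[^A-Za-z0-9]", "", g), i)
      st$gprotein_accession <- sprintf("G%s", gsub("[^A-Za-z0-9]", "", g))
      st$gprotein_family <- if (g %in% c("Gs", "Gi/o", "Gq/11", "G12/13")) {
        g
      } else if (gi == 1) "Gs" else "Gi/o"
      n <- nrow(st$atom)
      st$atom$x <- st$atom$x + stats::rnorm(n, 0, sigma)
      st$atom$y <- st$atom$y + stats::rnorm(n, 0, sigma)
      st$atom$z <- st$atom$z + stats::rnorm(n, 0, sigma)
      structures[[id]] <- st
      groups[id] <- g
      m <- template$mapping
      m$structure_id <- id
      maps[[id]] <- m
    }
  }
  list(structures = structures, mapping = do.call(rbind, maps),
       groups = groups, transforms = transforms)
}

#' Specification of a synthetic contact cohort
#'
#' @param n_per_group named integer vector, complexes per G-protein group
#' @param n_receptor_labels,n_galpha_labels size of the label pools whose
#'   cross product forms the feature universe
#' @param n_enriched number of features planted as enriched in the first
#'   group
#' @param p_in contact probability at a group's enriched features
#' @param p_out background contact probability
#' @param promiscuity probability that a receptor is also coupled to a
#'   family other than its own in the coupling map
#' @param seed RNG seed
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = c("Gs" = 20, "Gi/o" = 20),
                        n_receptor_labels = 10, n_galpha_labels = 6,
                        n_enriched = 15, p_in = 0.8, p_out = 0.2,
                        promiscuity = 0.1, seed = 1) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            n_enriched <= n_receptor_labels * n_galpha_labels)
  structure(list(n_per_group = n_per_group,
                 n_receptor_labels = n_receptor_labels,
                 n_galpha_labels = n_galpha_labels,
                 n_enriched = n_enriched, p_in = p_in, p_out = p_out,
                 promiscuity = promiscuity, seed = seed),
            class = "cohort_spec")
}

# Plausible receptor/G-alpha consensus label pools for cohort features.
.receptor_label_pool <- function(n) {
  pool <- c("2.37", "2.39", "2.40", "3.49", "3.50", "3.53", "3.54", "3.57",
            "5.61", "5.64", "5.65", "5.68", "6.29", "6.32", "6.33", "6.36",
            "7.56", "8.47", "8.48", "8.49", "ICL2.51", "ICL2.52", "ICL3",
            "ICL1", "Nterm", "Cterm")
  stopifnot(n <= length(pool))
  pool[seq_len(n)]
}

.galpha_label_pool <- function(n) {
  pool <- c("G.H5.25", "G.H5.24", "G.H5.23", "G.H5.22", "G.H5.20",
            "G.H5.19", "G.H5.16", "G.H5.15", "G.H5.12", "G.H5.11",
            "G.S3.1", "G.S3.2", "G.hns1.2", "G.hns1.3", "G.H4.26",
            "G.h4s6.9")
  stopifnot(n <= length(pool))
  pool[seq_len(n)]
}

#' Sample a contact cohort with planted enrichment
#'
#' Every complex draws its contacts independently: Bernoulli(`p_in`) at
#' its group's enriched features, Bernoulli(`p_out`) elsewhere. The first
#' group of the spec carries the planted enriched features; the expected
#' standard log-odds ratio at an enriched feature is
#' `ln((p_in/(1-p_in)) / (p_out/(1-p_out)))`. A coupling map consistent
#' with the groups is generated alongside (each receptor coupled to its
#' own family, and to others with probability `promiscuity`).
#'
#' @param spec a [cohort_spec()]
#' @return list with `contact_sets` (pooled, one per complex), `groups`
#'   (named vector), `coupling_map`, `universe` (feature strings
#'   `"rec|ga"`), `enriched` (planted features), `expected_lor`
#' @export
sample_contact_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  rl <- .receptor_label_pool(spec$n_receptor_labels)
  gl <- .galpha_label_pool(spec$n_galpha_labels)
  uni <- as.matrix(expand.grid(receptor_label = rl, galpha_label = gl,
                               stringsAsFactors = FALSE))
  universe <- paste(uni[, 1], uni[, 2], sep = "|")
  enriched <- universe[seq_len(spec$n_enriched)]
  groups_lv <- names(spec$n_per_group)
  gacc <- stats::setNames(sprintf("GA%02d", seq_along(groups_lv)), groups_lv)
  sets <- list()
  groups <- character()
  coupling <- list()
  ridx <- 0
  for (g in groups_lv) {
    enr <- if (g == groups_lv[1]) enriched else character(0)
    p <- ifelse(universe %in% enr, spec$p_in, spec$p_out)
    for (i in seq_len(spec$n_per_group[[g]])) {
      ridx <- ridx + 1
      racc <- sprintf("R%03d", ridx)
      present <- stats::runif(length(universe)) < p
      co <- data.frame(receptor_label = uni[present, 1],
                       galpha_label = uni[present, 2],
                       stringsAsFactors = FALSE)
      cs <- contact_set(racc, gacc[[g]], co, gprotein_family = g,
                        structures = sprintf("synth_%s", racc))
      key <- complex_key(cs)
      sets[[key]] <- cs
      groups[key] <- g
      coupled <- ifelse(groups_lv == g, 1L,
                        as.integer(stats::runif(length(groups_lv)) <
                                     spec$promiscuity))
      coupling[[racc]] <- data.frame(receptor_accession = racc,
                                     family = groups_lv, coupled = coupled,
                                     stringsAsFactors = FALSE)
    }
  }
  expected_lor <- log((spec$p_in / (1 - spec$p_in)) /
                        (spec$p_out / (1 - spec$p_out)))
  list(contact_sets = sets, groups = groups,
       coupling_map = do.call(rbind, c(coupling, make.row.names = FALSE)),
       universe = universe, enriched = enriched,
       expected_lor = expected_lor, spec = spec)
}

#' Sample a predicted-model set with known QC verdicts
#'
#' Builds one model per requested kind from the complex template:
#' \describe{
#'   \item{`pass`}{docked as in the template, uniform pLDDT 90 — survives
#'     every stage.}
#'   \item{`pass_trim`}{as `pass` but with a few low-confidence terminal
#'     receptor residues (pLDDT 50) that the trim stage removes; still
#'     survives.}
#'   \item{`anchor_fail`}{the G-alpha is flipped upside down and re-docked
#'     at the same gap, so the interface is mediated by HN/S segments and
#'     no H5 anchor position — fails the topology stage.}
#'   \item{`pdockq_fail`}{docked, but uniform pLDDT 30 drives pDockQ below
#'     threshold — fails the pDockQ stage.}
#'   \item{`dsasa_fail`}{the G-alpha is pulled away along z so that only
#'     the H5 tip grazes the receptor: a handful of anchor contacts and
#'     high pLDDT keep it past the earlier stages, but the buried area is
#'     far below threshold.}
#' }
#'
#' @param template output of [make_template()]
#' @param kinds character vector of model kinds (one model each)
#' @param seed RNG seed (numbering/jitter)
#' @return list with `models` (list of records for [qc_filter()]),
#'   `mapping`, and `expected` (data frame `model_id`, `kind`,
#'   `expected_fail` — `NA` for survivors)
#' @export
sample_model_set <- function(template,
                             kinds = c(rep("pass", 3), "pass_trim",
                                       rep("anchor_fail", 2),
                                       rep("pdockq_fail", 3), "dsasa_fail"),
                             seed = 1) {
  set.seed(seed)
  tmpl <- template$structure
  ga_idx <- tmpl$atom$chain == tmpl$galpha_chain
  ga_xyz <- as.matrix(tmpl$atom[ga_idx, c("x", "y", "z")])
  ga_ctr <- colMeans(ga_xyz)
  models <- list()
  maps <- list()
  expected <- list()
  res_keys <- function(st) unique(res_key(st$atom$chain, st$atom$resno,
                                          st$atom$insert))
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    id <- sprintf("model_%02d_%s", i, kind)
    st <- tmpl
    st$structure_id <- id
    plddt_level <- 90
    if (kind == "anchor_fail") {
      flip <- rotation_about(c(1, 0, 0), pi)
      st <- .transform_galpha(st, flip,
                              as.numeric(ga_ctr - flip %*% ga_ctr))
      # re-dock: restore the original gap below the receptor
      zmax_new <- max(st$atom$z[st$atom$chain == st$galpha_chain &
                                  st$atom$elety == "CA"])
      zmax_old <- max(ga_xyz[tmpl$atom$elety[ga_idx] == "CA", 3])
      st <- .transform_galpha(st, diag(3), c(0, 0, zmax_old - zmax_new))
    } else if (kind == "dsasa_fail") {
      # pull the G-alpha away until only the H5 tip grazes the receptor
      st <- .transform_galpha(st, diag(3), c(0, 0, -14))
      plddt_level <- 98
    } else if (kind == "pdockq_fail") {
      plddt_level <- 20
    }
    keys <- res_keys(st)
    plddt <- stats::setNames(rep(plddt_level, length(keys)), keys)
    if (kind == "pass_trim") {
      plddt[res_key("R", 1:2, "")] <- 50
    }
    m <- template$mapping
    m$structure_id <- id
    maps[[id]] <- m
    models[[id]] <- list(model_id = id, structure = st, plddt = plddt,
                         ptm = 0.8, iptm = 0.9)
    expected[[id]] <- data.frame(
      model_id = id, kind = kind,
      expected_fail = switch(kind, anchor_fail = "anchor",
                             pdockq_fail = "pdockq", dsasa_fail = "dsasa",
                             NA_character_), stringsAsFactors = FALSE)
  }
  list(models = models, mapping = do.call(rbind, maps),
       expected = do.call(rbind, c(expected, make.row.names = FALSE)))
}
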