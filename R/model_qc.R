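# Composite quality filter for predicted receptor/G-protein complex
# models: best-of-N ranking, H5-anchor topology check, pDockQ threshold,
# low-pLDDT trimming and buried-surface-area threshold, with a per-stage
# audit trail.

#' QC configuration
#'
#' @param h5_anchor_labels CGN labels of the G-alpha C-terminal helix (H5)
#'   positions that recurrently anchor the receptor interface; a model must
#'   contact at least one of them
#' @param pdockq_min minimum pDockQ (inclusive)
#' @param plddt_min per-residue pLDDT below which residues are trimmed
#'   (strict less-than)
#' @param dsasa_min minimum interface buried area in Angstrom^2 (inclusive)
#' @param pdockq_L,pdockq_k,pdockq_x0,pdockq_b sigmoid constants of the
#'   pDockQ curve
#' @return object of class `qc_config`
#' @export
qc_config <- function(h5_anchor_labels = c("G.H5.16", "G.H5.19", "G.H5.20",
                                           "G.H5.23", "G.H5.24", "G.H5.25"),
                      pdockq_min = 0.23, plddt_min = 70, dsasa_min = 1500,
                      pdockq_L = 0.724, pdockq_k = 0.052,
                      pdockq_x0 = 152.611, pdockq_b = 0.018) {
  stopifnot(length(h5_anchor_labels) >= 1, pdockq_min > 0, plddt_min > 0,
            dsasa_min > 0)
  structure(list(h5_anchor_labels = h5_anchor_labels,
                 pdockq_min = pdockq_min, plddt_min = plddt_min,
                 dsasa_min = dsasa_min, pdockq_L = pdockq_L,
                 pdockq_k = pdockq_k, pdockq_x0 = pdockq_x0,
                 pdockq_b = pdockq_b), class = "qc_config")
}

#' Composite model confidence score
#'
#' The weighted combination `0.2 * pTM + 0.8 * ipTM` used to rank the
#' models predicted for one complex.
#'
#' @param ptm,iptm predicted TM-score and interface TM-score, both in
#'   \[0, 1\]
#' @return score in \[0, 1\]
#' @export
model_score <- function(ptm, iptm) {
  stopifnot(all(ptm >= 0 & ptm <= 1), all(iptm >= 0 & iptm <= 1))
  0.2 * ptm + 0.8 * iptm
}

#' Pick the best model of one complex
#'
#' @param records data frame with `model_id`, `ptm`, `iptm`
#' @return the `model_id` with the highest [model_score()]; ties broken
#'   lexicographically
#' @export
rank_models <- function(records) {
  stop_if_missing_cols(records, c("model_id", "ptm", "iptm"), "model records")
  if (nrow(records) == 0) stop("no models to rank", call. = FALSE)
  score <- model_score(records$ptm, records$iptm)
  records$model_id[order(-score, records$model_id)][1]
}

#' H5 anchor topology check
#'
#' A predicted complex has a plausible docking topology only if at least
#' one interface contact involves one of the recurrent G-alpha H5 anchor
#' positions.
#'
#' @param cs a `contact_set` on consensus labels
#' @param config a [qc_config()]
#' @return `TRUE` if the model passes
#' @export
h5_anchor_check <- function(cs, config = qc_config()) {
  any(cs$contacts$galpha_label %in% config$h5_anchor_labels)
}

#' pDockQ interface quality estimate
#'
#' Sigmoid `L / (1 + exp(-k * (x - x0))) + b` with
#' `x = mean interface pLDDT * ln(number of interface contacts)`.
#'
#' @param interface_plddt pLDDT values of the interface residues (both
#'   chains)
#' @param n_contacts number of interface residue-residue contacts
#' @param config a [qc_config()] carrying the sigmoid constants
#' @return pDockQ value; `NA` when there are no interface contacts (the
#'   model then fails the pDockQ stage)
#' @export
compute_pdockq <- function(interface_plddt, n_contacts,
                           config = qc_config()) {
  if (n_contacts < 1 || length(interface_plddt) == 0) return(NA_real_)
  x <- mean(interface_plddt) * log(n_contacts)
  config$pdockq_L / (1 + exp(-config$pdockq_k * (x - config$pdockq_x0))) +
    config$pdockq_b
}

#' Trim low-confidence residues from a model
#'
#' Removes every residue whose pLDDT is strictly below the threshold;
#' retained residues (coordinates included) are untouched.
#'
#' @param x a [complex_structure()]
#' @param plddt named numeric vector, residue key (see [res_key()]) ->
#'   pLDDT in \[0, 100\]
#' @param threshold trim threshold (default 70)
#' @return the trimmed [complex_structure()]
#' @export
trim_low_plddt <- function(x, plddt, threshold = 70) {
  keys <- res_key(x$atom$chain, x$atom$resno, x$atom$insert)
  p <- plddt[keys]
  if (any(is.na(p))) stop("pLDDT missing for some residues", call. = FALSE)
  keep <- p >= threshold
  if (!any(keep)) stop("empty after trim: no residue reaches the pLDDT threshold",
                       call. = FALSE)
  out <- x
  out$atom <- x$atom[keep, , drop = FALSE]
  rownames(out$atom) <- NULL
  out
}

# ---- Shrake-Rupley solvent-accessible surface area ------------------------

# Deterministic quasi-uniform unit sphere points (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Element vdW radii (Angstrom) looked up from the first letter of the atom
# name; pseudo-atom models in this package only carry C atoms.
.vdw_radius <- function(elety) {
  first <- substr(gsub("[^A-Za-z]", "", elety), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)[first]
  r[is.na(r)] <- 1.80
  as.numeric(r)
}

#' Solvent-accessible surface area of an atom set
#'
#' Shrake-Rupley quadrature: each atom's solvent-inflated sphere is sampled
#' on a deterministic Fibonacci lattice and the accessible fraction of its
#' points (those outside every neighbouring inflated sphere) is converted
#' to area.
#'
#' @param xyz n x 3 coordinate matrix
#' @param radii per-atom vdW radii in Angstrom
#' @param probe probe radius (default 1.4)
#' @param n_points quadrature points per atom (default 100)
#' @return total SASA in Angstrom^2
#' @export
sasa <- function(xyz, radii, probe = 1.4, n_points = 100) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, n >= 1)
  sph <- fibonacci_sphere(n_points)
  rr <- radii + probe
  # neighbour prefilter: atoms whose inflated spheres can intersect
  maxr <- max(rr)
  total <- 0
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rr[i] + maxr & seq_len(n) != i)
    nb <- nb[di[nb] < rr[i] + rr[nb]]
    pts <- sweep(sph * rr[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- colSums((t(pts) - xyz[j, ])^2)
        acc <- acc & d2 > rr[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    total <- total + frac * 4 * pi * rr[i]^2
  }
  total
}

#' Buried surface area of a two-chain interface
#'
#' `SASA(receptor alone) + SASA(G-alpha alone) - SASA(complex)`, computed
#' geometrically (no side-chain repacking) with Shrake-Rupley quadrature.
#'
#' @param x a [complex_structure()] with chain pair set (or pass chains
#'   explicitly)
#' @param chain_a,chain_b the two chains; default the analyzed pair
#' @param probe probe radius in Angstrom
#' @param n_points quadrature points per atom
#' @return buried area in Angstrom^2 (non-negative up to quadrature error)
#' @export
delta_sasa <- function(x, chain_a = x$receptor_chain,
                       chain_b = x$galpha_chain, probe = 1.4,
                       n_points = 100) {
  if (is.na(chain_a) || is.na(chain_b)) {
    stop("chain pair not set", call. = FALSE)
  }
  a <- x$atom[x$atom$chain == chain_a, , drop = FALSE]
  b <- x$atom[x$atom$chain == chain_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("missing chain", call. = FALSE)
  s <- function(at) sasa(as.matrix(at[, c("x", "y", "z")]),
                         .vdw_radius(at$elety), probe, n_points)
  s(a) + s(b) - s(rbind(a, b))
}

#' Composite QC filter with audit trail
#'
#' Stages are applied in order: (1) H5-anchor topology check on the
#' model's interface contacts; (2) pDockQ >= threshold, with the interface
#' defined by the same representative-atom contact rule as the rest of the
#' package; (3) trimming of residues with pLDDT below threshold (a model
#' fails here only if nothing survives the trim, or its interface vanishes);
#' (4) buried area of the trimmed model >= threshold. The audit records
#' every computed metric and the first failing stage of each model.
#'
#' @param models list of model records; each a list with `model_id`,
#'   `structure` (a [complex_structure()] with chain pair set), `plddt`
#'   (named per-residue vector), and optionally `ptm`, `iptm`
#' @param mapping residue mapping covering the model structures
#' @param config a [qc_config()]
#' @param params a [contact_params()] for the interface definition
#' @param sasa_points quadrature points per atom for the area stage
#' @return list with `survivors` (model ids) and `audit` (data frame:
#'   `model_id`, `n_contacts`, `anchor_ok`, `pdockq`, `n_trimmed`,
#'   `delta_sasa`, `first_fail`, `pass`)
#' @export
qc_filter <- function(models, mapping, config = qc_config(),
                      params = contact_params(), sasa_points = 100) {
  audit <- lapply(models, function(m) {
    x <- m$structure
    rec <- list(model_id = m$model_id, n_contacts = NA_integer_,
                anchor_ok = NA, pdockq = NA_real_, n_trimmed = NA_integer_,
                delta_sasa = NA_real_, first_fail = NA_character_,
                pass = FALSE)
    cs <- interface_contacts(x, mapping, params)
    rpairs <- interface_residue_pairs(x, x$receptor_chain, x$galpha_chain,
                                      params)
    rec$n_contacts <- nrow(rpairs)
    rec$anchor_ok <- h5_anchor_check(cs, config)
    if (!rec$anchor_ok) {
      rec$first_fail <- "anchor"
      return(rec)
    }
    iface_res <- unique(c(rpairs$key_a, rpairs$key_b))
    rec$pdockq <- compute_pdockq(m$plddt[iface_res], nrow(rpairs), config)
    if (is.na(rec$pdockq) || rec$pdockq < config$pdockq_min) {
      rec$first_fail <- "pdockq"
      return(rec)
    }
    trimmed <- tryCatch(trim_low_plddt(x, m$plddt, config$plddt_min),
                        error = function(e) NULL)
    rec$n_trimmed <- if (is.null(trimmed)) {
      nrow(unique(x$atom[, c("chain", "resno", "insert")]))
    } else {
      nrow(unique(x$atom[, c("chain", "resno", "insert")])) -
        nrow(unique(trimmed$atom[, c("chain", "resno", "insert")]))
    }
    if (is.null(trimmed) ||
        !all(c(x$receptor_chain, x$galpha_chain) %in% trimmed$atom$chain)) {
      rec$first_fail <- "trim"
      return(rec)
    }
    rec$delta_sasa <- delta_sasa(trimmed, n_points = sasa_points)
    if (rec$delta_sasa < config$dsasa_min) {
      rec$first_fail <- "dsasa"
      return(rec)
    }
    rec$pass <- TRUE
    rec
  })
  audit <- do.call(rbind, lapply(audit, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(audit) <- NULL
  list(survivors = audit$model_id[audit$pass], audit = audit)
}
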