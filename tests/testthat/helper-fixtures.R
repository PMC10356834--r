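# Shared in-code fixtures: tiny structures and tables built fresh per run.

# Minimal two-chain structure from residue-level coordinates.
# coords: data.frame(chain, resno, resid, x, y, z); one CA per residue,
# plus a CB offset by +1 in x for non-glycines unless cb = FALSE.
toy_structure <- function(coords, id = "toy", cb = TRUE, ...) {
  ca <- data.frame(chain = coords$chain, resno = coords$resno, insert = "",
                   resid = coords$resid, elety = "CA",
                   x = coords$x, y = coords$y, z = coords$z,
                   occ = 1, alt = "", stringsAsFactors = FALSE)
  atom <- ca
  if (cb) {
    cbdf <- ca[ca$resid != "GLY", , drop = FALSE]
    if (nrow(cbdf) > 0) {
      cbdf$elety <- "CB"
      cbdf$x <- cbdf$x + 1
      atom <- rbind(ca, cbdf)
    }
  }
  complex_structure(id, atom, ...)
}

# Mapping rows for a toy structure: labels supplied per residue in order.
toy_mapping <- function(st, labels, acc_by_chain) {
  res <- unique(st$atom[, c("chain", "resno", "insert")])
  data.frame(structure_id = st$structure_id, chain = res$chain,
             resnum = res$resno, icode = res$insert,
             uniprot_acc = acc_by_chain[res$chain],
             uniprot_pos = res$resno,
             consensus_label = labels,
             sse = NA_character_, stringsAsFactors = FALSE)
}

# Random rigid transform (proper rotation + translation).
random_transform <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(rotation = R, translation = stats::rnorm(3, 0, 10))
}

# Apply a rigid transform to every atom of a complex_structure.
transform_structure <- function(st, tf) {
  xyz <- as.matrix(st$atom[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(tf$rotation), 2, tf$translation, "+")
  st$atom[, c("x", "y", "z")] <- xyz
  st
}

# Random two-chain point cloud structure for contact-search stress tests.
# Residues are glycines so the single pseudo-atom per residue is, by the
# contact rule, its representative atom.
random_complex <- function(n_a, n_b, spread = 30, id = "rand") {
  coords <- data.frame(
    chain = rep(c("A", "B"), c(n_a, n_b)),
    resno = c(seq_len(n_a), seq_len(n_b)),
    resid = "GLY",
    x = stats::runif(n_a + n_b, -spread, spread),
    y = stats::runif(n_a + n_b, -spread, spread),
    z = stats::runif(n_a + n_b, -spread, spread),
    stringsAsFactors = FALSE)
  toy_structure(coords, id = id, cb = FALSE)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
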