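mk_set <- function(acc, fam, pairs) {
  contact_set(acc, paste0("GA_", gsub("[^A-Za-z0-9]", "", fam)),
              data.frame(receptor_label = pairs[, 1],
                         galpha_label = pairs[, 2], stringsAsFactors = FALSE),
              fam)
}

test_that("fingerprint modes encode pairs and their projections", {
  s1 <- mk_set("R1", "Gs", cbind("3.50", "G.H5.25"))
  s2 <- mk_set("R2", "Gi/o", cbind(c("3.50", "6.33"),
                                   c("G.H5.25", "G.H5.23")))
  sets <- list(`R1|GA_Gs` = s1, `R2|GA_Gio` = s2)
  cf <- build_fingerprints(sets, "CF")
  expect_equal(colnames(cf), c("3.50|G.H5.25", "6.33|G.H5.23"))
  expect_equal(unname(cf["R1|GA_Gs", ]), c(1L, 0L))
  rf <- build_fingerprints(sets, "RF")
  expect_equal(unname(rf["R1|GA_Gs", "3.50"]), 1L)
  gf <- build_fingerprints(sets, "GF")
  expect_equal(unname(gf["R2|GA_Gio", c("G.H5.23", "G.H5.25")]), c(1L, 1L))
  expect_error(build_fingerprints(list(), "CF"), "empty")
})

test_that("CF column sums equal brute-force per-feature support counts", {
  co <- sample_contact_cohort(cohort_spec(seed = 41))
  fp <- build_fingerprints(co$contact_sets, "CF")
  naive <- sapply(colnames(fp), function(f) {
    parts <- strsplit(f, "|", fixed = TRUE)[[1]]
    sum(vapply(co$contact_sets, function(cs)
      any(cs$contacts$receptor_label == parts[1] &
            cs$contacts$galpha_label == parts[2]), logical(1)))
  })
  expect_equal(unname(colSums(fp)), unname(naive))
})

test_that("contingency counts coupled/contact cells correctly", {
  m <- matrix(0L, 10, 1, dimnames = list(sprintf("R%02d|GA", 1:10), "f"))
  m[c(1, 2, 3, 4, 7), 1] <- 1L  # 4 carriers in group, 1 outside
  groups <- rep(c("g", "other"), c(6, 4))
  tb <- contingency(m, "f", groups, "g")
  expect_equal(unclass(tb)[c("CC", "CN", "NC", "NN")],
               c(CC = 4L, CN = 2L, NC = 1L, NN = 3L))
  expect_equal(sum(tb), 10)
  # feature absent everywhere
  m0 <- m; m0[, 1] <- 0L
  tb0 <- contingency(m0, "f", groups, "g")
  expect_equal(unclass(tb0)[c("CC", "NC")], c(CC = 0L, NC = 0L))
  expect_error(contingency(m, "f", rep("g", 10), "g"), "universal")
})

test_that("log-odds ratios match direct arithmetic in both variants", {
  expect_equal(log_odds(c(CC = 8, CN = 2, NC = 2, NN = 8)), log(16))
  expect_equal(log_odds(c(CC = 5, CN = 5, NC = 5, NN = 5)), 0)
  expect_equal(log_odds(c(CC = 5, CN = 5, NC = 5, NN = 5), "as_printed"), 0)
  # Haldane-Anscombe pseudocount on any zero cell
  expect_equal(log_odds(c(CC = 10, CN = 0, NC = 3, NN = 7)),
               log((10.5 * 7.5) / (0.5 * 3.5)))
  expect_equal(log_odds(c(CC = 10, CN = 0, NC = 3, NN = 7)), log(45),
               tolerance = 1e-12)
  expect_error(log_odds(c(CC = 0, CN = 0, NC = 0, NN = 0)), "zero")
})

test_that("log-odds agrees with direct arithmetic on random tables", {
  set.seed(43)
  for (i in 1:1000) {
    tb <- c(CC = rpois(1, 5), CN = rpois(1, 5), NC = rpois(1, 5),
            NN = rpois(1, 5))
    if (all(tb == 0)) next
    tb2 <- if (any(tb == 0)) tb + 0.5 else tb
    expect_equal(log_odds(tb),
                 log(tb2[["CC"]] * tb2[["NN"]] / (tb2[["CN"]] * tb2[["NC"]])),
                 tolerance = 1e-12)
    expect_equal(log_odds(tb, "as_printed"),
                 log((tb2[["CC"]] / tb2[["NN"]]) * (tb2[["NC"]] / tb2[["CN"]])),
                 tolerance = 1e-12)
  }
})

test_that("standard LOR is antisymmetric under group swap and monotone in CC", {
  set.seed(47)
  for (i in 1:50) {
    tb <- c(CC = sample(1:20, 1), CN = sample(1:20, 1),
            NC = sample(1:20, 1), NN = sample(1:20, 1))
    swapped <- c(CC = tb[["NC"]], CN = tb[["NN"]], NC = tb[["CC"]],
                 NN = tb[["CN"]])
    expect_equal(log_odds(tb), -log_odds(swapped))
  }
  lors <- sapply(1:10, function(cc)
    log_odds(c(CC = cc, CN = 5, NC = 5, NN = 5)))
  expect_true(all(diff(lors) > 0))
})

test_that("informative-feature filter applies frequency and LOR thresholds", {
  n <- 20
  m <- matrix(0L, n, 3, dimnames = list(
    sprintf("R%02d|GA", 1:n), c("rare_high_lor", "common_low_lor",
                                "common_high_lor")))
  groups <- rep(c("Gs", "Gi/o"), each = 10)
  m[1, 1] <- 1L                           # frequency 0.05
  m[c(1:4, 11:14), 2] <- 1L               # freq 0.4, balanced -> LOR 0
  m[3:10, 3] <- 1L                        # freq 0.4, all in Gs -> |LOR| > 2
  enr <- enrichment_table(m, groups)
  kept <- filter_informative(m, enr)
  expect_equal(colnames(kept), "common_high_lor")
  # negative enrichment also qualifies
  m2 <- m[, 3, drop = FALSE]
  colnames(m2) <- "depleted_in_gio"
  enr2 <- enrichment_table(m2, groups)
  expect_true(any(enr2$lor < -2))
  expect_equal(ncol(filter_informative(m2, enr2)), 1)
})

test_that("Ward clustering recovers separable blocks and is permutation-stable", {
  block <- function(seed, n, p) {
    set.seed(seed); matrix(rbinom(n * 12, 1, p), n, 12)
  }
  m <- rbind(matrix(rep(c(1L, 0L), each = 6), 10, 12, byrow = TRUE),
             matrix(rep(c(0L, 1L), each = 6), 10, 12, byrow = TRUE))
  rownames(m) <- sprintf("R%02d|GA", 1:20)
  lab <- cluster_fingerprints(m, k = 2)
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand(lab, truth), 1)
  # permutation stability: shuffled rows give the same partition
  set.seed(53)
  perm <- sample(nrow(m))
  lab_p <- cluster_fingerprints(m[perm, ], k = 2)
  expect_equal(adjusted_rand(lab_p, truth[perm]), 1)
  expect_equal(adjusted_rand(lab_p[rownames(m)], lab), 1)
  # identical rows -> degenerate warning
  flat <- matrix(1L, 6, 4, dimnames = list(sprintf("R%d|G", 1:6), NULL))
  expect_warning(cluster_fingerprints(flat, k = 2), "degenerate")
  expect_error(cluster_fingerprints(m, k = 50), "exceeds")
})

test_that("cluster coupling profiles report per-family coupled fractions", {
  labels <- stats::setNames(c(1, 1, 1, 1, 2, 2),
                            paste0(c("R1", "R2", "R3", "R4", "R5", "R9"),
                                   "|GA"))
  cmap <- data.frame(
    receptor_accession = rep(c("R1", "R2", "R3", "R4", "R5"), each = 2),
    family = rep(c("Gs", "Gq/11"), 5),
    coupled = c(1, 1, 1, 1, 0, 0, 1, 0, 1, 0), stringsAsFactors = FALSE)
  prof <- cluster_coupling_profile(labels, cmap)
  # cluster 1: R1-R4; 2 of 4 coupled to Gq/11
  expect_equal(prof$fraction[prof$cluster == 1 & prof$family == "Gq/11"], 0.5)
  expect_equal(prof$fraction[prof$cluster == 1 & prof$family == "Gs"], 0.75)
  # R9 unknown to the map, counted separately
  expect_equal(attr(prof, "unknown")[["2"]], 1)
})

test_that("planted coupling promiscuity is recovered within binomial bounds", {
  co <- sample_contact_cohort(cohort_spec(
    n_per_group = c("Gs" = 60, "Gi/o" = 60), promiscuity = 0.25, seed = 59))
  cm <- co$coupling_map
  own <- cm$coupled[paste0("GA_", gsub("[^A-Za-z0-9/]", "", cm$family)) ==
                      ""]
  # every receptor is coupled to its own family
  fam_of <- co$groups[paste0(cm$receptor_accession, "|",
                             ifelse(cm$family == "Gs", "GA01", "GA02"))]
  # off-family coupling rate ~ promiscuity
  off <- cm[apply(cm, 1, function(r) {
    key <- names(co$groups)[startsWith(names(co$groups),
                                       paste0(r[["receptor_accession"]], "|"))]
    co$groups[[key]] != r[["family"]]
  }), ]
  rate <- mean(off$coupled)
  band <- qbinom(c(0.005, 0.995), nrow(off), 0.25) / nrow(off)
  expect_true(rate >= band[1] && rate <= band[2])
})
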