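mk_coordset <- function(n_rec = 8, n_ga = 6, seed = 1) {
  set.seed(seed)
  rec <- matrix(rnorm(n_rec * 3, sd = 5), n_rec, 3,
                dimnames = list(sprintf("3.%d", 45 + seq_len(n_rec) - 1),
                                NULL))
  ga <- matrix(rnorm(n_ga * 3, sd = 5), n_ga, 3,
               dimnames = list(sprintf("G.H5.%d", 20 + seq_len(n_ga)), NULL))
  coordinate_set(rec, ga)
}

test_that("Kabsch fit recovers planted rigid motions exactly", {
  set.seed(87)
  for (rep in 1:20) {
    cloud <- matrix(rnorm(50 * 3, sd = 8), 50, 3)
    tf <- random_transform()
    target <- sweep(cloud %*% t(tf$rotation), 2, tf$translation, "+")
    fit <- kabsch_fit(cloud, target)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    moved <- apply_transform(cloud, fit)
    expect_lt(sqrt(mean(rowSums((moved - target)^2))), 1e-8)
  }
  # 90-degree rotation about z plus translation, explicit
  cloud <- matrix(rnorm(12 * 3), 12, 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  target <- sweep(cloud %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- kabsch_fit(cloud, target)
  expect_equal(fit$rotation, Rz, tolerance = 1e-10)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-10)
  # identical sets -> identity
  fit0 <- kabsch_fit(cloud, cloud)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("Kabsch fit agrees with the bio3d superposition", {
  set.seed(89)
  mobile <- matrix(rnorm(30 * 3, sd = 6), 30, 3)
  tf <- random_transform()
  target <- sweep(mobile %*% t(tf$rotation), 2, tf$translation, "+") +
    rnorm(90, sd = 0.3)
  fit <- kabsch_fit(mobile, target)
  ours <- apply_transform(mobile, fit)
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(target)),
                                         mobile = as.numeric(t(mobile))))
  ref <- matrix(ref, ncol = 3, byrow = TRUE)
  expect_equal(ours, ref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate fit sets are rejected", {
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "3 fit points")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch_fit(line, line + 1), "collinear")
})

test_that("pose RMSD isolates the G-alpha displacement", {
  a <- mk_coordset(seed = 91)
  expect_equal(pose_rmsd(a, a), 0, tolerance = 1e-10)
  # uniform (0,3,4) displacement of the Galpha block -> exactly 5 A
  b <- a
  b$galpha <- sweep(a$galpha, 2, c(0, 3, 4), "+")
  expect_equal(pose_rmsd(a, b), 5.0, tolerance = 1e-8)
  # invariance under a global rigid motion of the whole complex
  tf <- random_transform()
  c2 <- apply_transform(a, tf)
  expect_equal(pose_rmsd(a, c2), 0, tolerance = 1e-8)
  d2 <- apply_transform(b, tf)
  expect_equal(pose_rmsd(a, d2), 5.0, tolerance = 1e-8)
})

test_that("pose RMSD is symmetric to numerical tolerance", {
  set.seed(93)
  for (rep in 1:10) {
    a <- mk_coordset(seed = rep)
    b <- mk_coordset(seed = rep + 100)
    expect_equal(pose_rmsd(a, b), pose_rmsd(b, a), tolerance = 1e-6)
  }
})

test_that("RMSD matrices are symmetric, zero-diagonal and cluster poses", {
  tmpl <- make_template(28, 16, seed = 8)
  ens <- sample_pose_ensemble(tmpl, n_per_group = 10, sigma = 0.5, seed = 95)
  core <- build_consensus_core(ens$structures, ens$mapping)
  cs <- lapply(ens$structures, structure_to_coordset, mapping = ens$mapping,
               core = core)
  d <- rmsd_matrix(cs, ens$groups)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0))
  lab <- cluster_rmsd(d, k = 2)
  expect_equal(adjusted_rand(lab, ens$groups[names(lab)]), 1)
  expect_error(cluster_rmsd(d, k = 100), "exceeds")
})

test_that("noise-free planted poses give exact within/between RMSDs", {
  tmpl <- make_template(28, 16, seed = 9)
  ens <- sample_pose_ensemble(tmpl, n_per_group = 2, sigma = 0, seed = 97)
  core <- build_consensus_core(ens$structures, ens$mapping)
  cs <- lapply(ens$structures, structure_to_coordset, mapping = ens$mapping,
               core = core)
  keys <- names(cs)
  gA <- keys[ens$groups[keys] == names(ens$transforms)[1]]
  gB <- keys[ens$groups[keys] == names(ens$transforms)[2]]
  expect_equal(pose_rmsd(cs[[gA[1]]], cs[[gA[2]]]), 0, tolerance = 1e-8)
  # pure translation by (12,0,0): uniform displacement closed form
  expect_equal(pose_rmsd(cs[[gA[1]]], cs[[gB[1]]]), 12, tolerance = 1e-8)
})

test_that("centroid selection equals brute-force argmin with lexicographic ties", {
  d <- matrix(c(0, 1.2, 1.2, 1.2, 0, 0.2, 1.2, 0.2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(pose_centroid(d), "B")
  expect_equal(pose_centroid(d, "C"), "C")  # singleton group
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * n), n, n)
    m <- m + t(m); diag(m) <- 0
    rownames(m) <- colnames(m) <- sprintf("k%02d", seq_len(n))
    means <- rowSums(m) / (n - 1)
    best <- sort(rownames(m)[means == min(means)])[1]
    expect_equal(pose_centroid(m), best)
  }
})

test_that("RMSF reproduces closed forms and planted noise tiers", {
  ref <- mk_coordset(seed = 103)
  # all members equal the reference -> zero profile
  prof0 <- rmsf_profile(list(a = ref, b = ref), ref)
  expect_equal(prof0$rmsf, rep(0, nrow(prof0)), tolerance = 1e-10)
  # +d / -d displacement of one position along one axis -> rho = d
  m1 <- ref; m2 <- ref
  m1$galpha[2, 1] <- m1$galpha[2, 1] + 1.7
  m2$galpha[2, 1] <- m2$galpha[2, 1] - 1.7
  prof <- rmsf_profile(list(p = m1, m = m2), ref)
  expect_equal(prof$rmsf[2], 1.7, tolerance = 1e-8)
  expect_equal(prof$rmsf[-2], rep(0, nrow(prof) - 1), tolerance = 1e-8)
})

test_that("RMSF recovers sigma*sqrt(3) across noise tiers with exact ranking", {
  tmpl <- make_template(28, 18, seed = 10)
  core <- list()
  ref_map <- tmpl$mapping
  ref <- structure_to_coordset(
    tmpl$structure, ref_map,
    structure(list(receptor = tmpl$labels$receptor,
                   galpha = tmpl$labels$galpha), class = "consensus_core"))
  tiers <- c(0.5, 1.0, 2.0)
  set.seed(107)
  means <- sapply(tiers, function(sg) {
    members <- lapply(1:50, function(i) {
      m <- ref
      m$receptor <- m$receptor + rnorm(length(m$receptor), 0, sg)
      m$galpha <- m$galpha + rnorm(length(m$galpha), 0, sg)
      m
    })
    names(members) <- sprintf("m%02d", 1:50)
    mean(rmsf_profile(members, ref)$rmsf)
  })
  expect_true(all(abs(means - tiers * sqrt(3)) / (tiers * sqrt(3)) < 0.2))
  expect_equal(order(means), 1:3)  # perfect tier ranking
})

test_that("RMSD matrix and RMSF are invariant to rigid motion of one member", {
  tmpl <- make_template(28, 16, seed = 12)
  ens <- sample_pose_ensemble(tmpl, n_per_group = 3, sigma = 0.3, seed = 109)
  core <- build_consensus_core(ens$structures, ens$mapping)
  cs <- lapply(ens$structures, structure_to_coordset, mapping = ens$mapping,
               core = core)
  d1 <- rmsd_matrix(cs)
  set.seed(113)
  cs2 <- cs
  cs2[[2]] <- apply_transform(cs2[[2]], random_transform())
  d2 <- rmsd_matrix(cs2)
  expect_equal(d1, d2, tolerance = 1e-7)
  prof1 <- rmsf_profile(cs, cs[[1]])
  prof2 <- rmsf_profile(cs2, cs[[1]])
  expect_equal(prof1$rmsf, prof2$rmsf, tolerance = 1e-7)
})
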