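test_that("superposition removes rigid-body motion exactly", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  at <- toy_atoms(10)

  # frame against itself
  cc <- array(NA_real_, c(2, 10, 3)); cc[1, , ] <- X; cc[2, , ] <- X
  sp <- superpose(conformation_ensemble(at, cc), reference = 1)
  expect_lt(max(sp$rmsd), 1e-8)

  # rotated + translated copy aligns back to machine precision
  R <- rotation_z(0.7) %*% matrix(c(1, 0, 0, 0, cos(0.3), -sin(0.3),
                                    0, sin(0.3), cos(0.3)), 3, 3, byrow = TRUE)
  cc[2, , ] <- X %*% R + matrix(c(3, -2, 5), 10, 3, byrow = TRUE)
  sp2 <- superpose(conformation_ensemble(at, cc), reference = 1)
  expect_lt(sp2$rmsd[2], 1e-6)

  # 4-point toy set with a known 1 A displacement per atom after alignment:
  # square +-1 in x/y, second frame scaled so each atom moves radially by 1
  sq <- cbind(c(1, -1, -1, 1), c(1, 1, -1, -1), 0)
  sq2 <- sq * (1 + 1 / sqrt(2))          # each corner shifts by exactly 1
  cc4 <- array(NA_real_, c(2, 4, 3)); cc4[1, , ] <- sq; cc4[2, , ] <- sq2
  sp4 <- superpose(conformation_ensemble(toy_atoms(4), cc4), reference = 1)
  expect_equal(sp4$rmsd[2], 1, tolerance = 1e-9)

  expect_error(superpose(conformation_ensemble(at, cc), fit_sel = integer(0)),
               "empty")
})

test_that("superposition matches the bio3d reference on random pairs", {
  set.seed(7)
  X <- matrix(rnorm(45), 15, 3)
  R <- rotation_z(1.1)
  Y <- (X + matrix(rnorm(45, sd = 0.6), 15, 3)) %*% R + 5
  cc <- array(NA_real_, c(2, 15, 3)); cc[1, , ] <- X; cc[2, , ] <- Y
  sp <- superpose(conformation_ensemble(toy_atoms(15), cc), reference = 1)
  oracle <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
  expect_equal(sp$rmsd[2], oracle, tolerance = 1e-3)
})

test_that("RMSD behaves as a pseudometric on superposed frames", {
  spec <- toy_ensemble_spec(n_frames = 6, jitter_sd = 1, seed = 3)
  ens <- superpose(make_toy_ensemble(spec))
  nf <- 6
  d <- matrix(0, nf, nf)
  for (i in 1:nf) for (j in 1:nf) {
    d[i, j] <- sqrt(mean(rowSums((ens$coords[i, , ] - ens$coords[j, , ])^2)))
  }
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(diag(d) == 0))
  for (i in 1:nf) for (j in 1:nf) for (k in 1:nf) {
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
  }
})

test_that("ellipticity is scale-, rotation- and translation-invariant", {
  ens <- make_toy_ensemble(toy_ensemble_spec(n_frames = 1, radius_a = 20,
                                             radius_b = 10, jitter_sd = 0))
  e0 <- ellipticity_series(ens)
  moved <- ens
  moved$coords[1, , ] <- 3.7 * ens$coords[1, , ] %*% rotation_z(0.9) +
    matrix(c(12, -4, 8), nrow(ens$atoms), 3, byrow = TRUE)
  expect_equal(ellipticity_series(moved), e0, tolerance = 1e-9)

  # jittered circle stays within 2% of circular
  jit <- make_toy_ensemble(toy_ensemble_spec(n_frames = 20, radius_a = 15,
                                             radius_b = 15, jitter_sd = 0.1,
                                             seed = 5))
  expect_true(all(abs(ellipticity_series(jit) - 1) < 0.02))

  # colinear points have no defined cross-section
  line <- ens
  line$coords[1, , 2] <- 0
  expect_error(ellipticity_series(line), "colinear")
})

test_that("residue z statistics use the population convention", {
  at <- data.frame(resid = 1:3, resname = "GLY", role = "CA", segment = "tail")
  cc <- array(0, c(2, 3, 3))
  cc[1, , 3] <- c(5, 1, 0); cc[2, , 3] <- c(-5, 1, 0)
  ens <- conformation_ensemble(at, cc)
  st <- residue_z_stats(ens, residues = 1:2)
  expect_equal(st$mean_z, c(0, 1))
  expect_equal(st$sd_z, c(5, 0))      # population SD: divide by n
  expect_error(residue_z_stats(ens, residues = 9), "missing residue: 9")

  # a mid-pore horizontal tail sits within 2 A of the pore centre plane
  hor <- make_toy_ensemble(toy_ensemble_spec(placement = "horizontal-mid-pore",
                                             jitter_sd = 0.2, seed = 2))
  st2 <- residue_z_stats(hor, residues = 1:11)
  expect_true(all(abs(st2$mean_z) <= 2))
})

test_that("PCA landscapes satisfy their closed-form and reconstruction
           identities", {
  at <- toy_atoms(8)
  set.seed(11)
  A <- matrix(rnorm(24), 8, 3)

  # identical frames: degenerate, zero variance
  cc <- array(NA_real_, c(3, 8, 3)); for (i in 1:3) cc[i, , ] <- A
  expect_true(pca_landscape(conformation_ensemble(at, cc),
                            sel = 1:8)$degenerate)

  # two distinct conformations repeated: PC1 carries all variance, along
  # the difference vector
  B <- A + matrix(rnorm(24), 8, 3)
  cc2 <- array(NA_real_, c(6, 8, 3))
  for (i in 1:6) cc2[i, , ] <- if (i %% 2) A else B
  lmod <- pca_landscape(conformation_ensemble(at, cc2), sel = 1:8)
  expect_equal(lmod$explained[1], 1, tolerance = 1e-9)
  dvec <- as.vector(B - A); dvec <- dvec / sqrt(sum(dvec^2))
  expect_equal(abs(sum(lmod$basis[, 1] * dvec)), 1, tolerance = 1e-9)

  # reconstruction: back-projection with the full basis restores the
  # centred coordinates; explained variances match an independent eigen
  cc3 <- array(rnorm(10 * 8 * 3, sd = 2), c(10, 8, 3))
  ens3 <- conformation_ensemble(at, cc3)
  m3 <- pca_landscape(ens3, sel = 1:8)
  X <- t(vapply(1:10, function(i) as.vector(cc3[i, , ]), numeric(24)))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  p <- stats::prcomp(X)
  k <- ncol(m3$basis)
  recon <- (Xc %*% p$rotation[, 1:9]) %*% t(p$rotation[, 1:9])
  expect_equal(recon, Xc, tolerance = 1e-9, ignore_attr = TRUE)
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(m3$explained[1:2], (ev / sum(ev))[1:2], tolerance = 1e-9)
  # basis orthonormality
  expect_equal(crossprod(m3$basis), diag(k), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("tail-up and tail-down ensembles separate along PC1", {
  up <- superpose(make_toy_ensemble(
    toy_ensemble_spec(placement = "vertical", jitter_sd = 0.3, n_frames = 15,
                      seed = 1), condition = "up"))
  down <- superpose(make_toy_ensemble(
    toy_ensemble_spec(placement = "detached-below", jitter_sd = 0.3,
                      n_frames = 15, seed = 2), condition = "down"))
  lmod <- pca_landscape(list(up, down))
  pc1 <- lmod$projections$PC1
  grp <- lmod$projections$condition
  # silhouette of the 2-group split on PC1
  sil <- vapply(seq_along(pc1), function(i) {
    own <- pc1[grp == grp[i]]
    a <- mean(abs(pc1[i] - own[own != pc1[i]]))
    b <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("landscape overlap matches trivial and analytic references", {
  same <- data.frame(PC1 = rep(seq(-2, 2, 0.1), 2),
                     PC2 = rep(seq(-2, 2, 0.1), 2),
                     condition = rep(c("a", "b"), each = 41))
  expect_equal(ensemble_overlap(same, "a", "b", grid_bins = 10)$overlap, 1)

  apart <- data.frame(PC1 = c(rnorm(100), rnorm(100) + 100),
                      PC2 = rnorm(200), condition = rep(c("a", "b"), each = 100))
  expect_equal(ensemble_overlap(apart, "a", "b")$overlap, 0)

  # two unit Gaussian clouds 2 sigma apart: overlap = 2 Phi(-1) = 0.317
  set.seed(2)
  gaus <- data.frame(PC1 = c(rnorm(2000), rnorm(2000) + 2),
                     PC2 = rnorm(4000),
                     condition = rep(c("a", "b"), each = 2000))
  ov <- ensemble_overlap(gaus, "a", "b", grid_bins = 25)
  expect_equal(ov$overlap, 2 * pnorm(-1), tolerance = 0.05)
  expect_error(ensemble_overlap(gaus, "a", "missing"), "empty condition")
})

test_that("clustering recovers ground truth and is deterministic", {
  at <- toy_atoms(10)
  set.seed(4)
  A <- matrix(rnorm(30), 10, 3); B <- A + 4
  cc <- array(NA_real_, c(20, 10, 3))
  for (i in 1:20) cc[i, , ] <- (if (i <= 10) A else B) +
      matrix(rnorm(30, sd = 0.05), 10, 3)
  ens <- conformation_ensemble(at, cc)

  cl <- cluster_frames(ens, 2)
  expect_equal(cl$assignment[1:10], rep(cl$assignment[1], 10))
  expect_equal(cl$assignment[11:20], rep(cl$assignment[11], 10))
  expect_false(cl$assignment[1] == cl$assignment[11])
  expect_true(cl$representatives[1] %in% which(cl$assignment == 1))

  # determinism on repetition
  expect_identical(cluster_frames(ens, 2), cl)

  # n_clusters = n_frames: singletons, each its own representative
  singl <- cluster_frames(ens, 20)
  expect_equal(sort(singl$representatives), 1:20)
  expect_equal(singl$assignment, 1:20)

  # single cluster: global medoid
  one <- cluster_frames(ens, 1)
  dm <- one$rmsd_matrix
  expect_equal(one$representatives, unname(which.min(rowSums(dm))))

  expect_error(cluster_frames(ens, 0), "positive")
  expect_error(cluster_frames(ens, 21), "exceed")
})

test_that("average structures and RMSF follow the generator statistics", {
  spec <- toy_ensemble_spec(n_frames = 1, jitter_sd = 0)
  single <- make_toy_ensemble(spec)
  avg1 <- average_structure(single)
  expect_equal(avg1$xyz, single$coords[1, , ], ignore_attr = TRUE)
  expect_true(all(avg1$rmsf == 0))

  # two frames mirrored about z = 0: averaged atoms land on the plane
  at <- toy_atoms(5)
  cc <- array(NA_real_, c(2, 5, 3))
  cc[1, , ] <- cbind(1:5, 2, 3); cc[2, , ] <- cbind(1:5, 2, -3)
  avg2 <- average_structure(conformation_ensemble(at, cc))
  expect_true(all(avg2$xyz[, 3] == 0))

  # CLT: mean structure sits within a few jitter_sd / sqrt(n) of the template
  n <- 60
  jit <- make_toy_ensemble(toy_ensemble_spec(n_frames = n, jitter_sd = 0.5,
                                             seed = 6))
  avg3 <- average_structure(jit)
  dev <- sqrt(rowSums((avg3$xyz - attr(jit, "template"))^2))
  expect_lt(max(dev), 6 * 0.5 / sqrt(n))
  expect_error(average_structure(jit, frames = integer(0)), "empty")
})

test_that("multi-model PDB export reads back with bio3d", {
  ens <- make_toy_ensemble(toy_ensemble_spec(n_frames = 3, n_points = 6,
                                             n_rings = 2, n_residues = 4,
                                             jitter_sd = 0.2, seed = 1))
  path <- file.path(tempdir(), "ens.pdb")
  write_ensemble_pdb(ens, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  expect_equal(dim(pdb$xyz)[1], 3)
  expect_equal(ncol(pdb$xyz) / 3, nrow(ens$atoms))
  back <- matrix(pdb$xyz[2, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(back - ens$coords[2, , ])), 1e-3)  # PDB keeps 3 decimals
  unlink(path)
})

test_that("apparent sequence charge follows Henderson-Hasselbalch", {
  # glycine peptide: termini almost cancel at pH 7 (hand HH: -0.0095)
  expect_equal(sequence_apparent_charge("GGGG"), -0.009503, tolerance = 1e-4)
  # a single aspartate at the textbook pKa
  pka <- default_pka_table(); pka["D"] <- 3.67
  expect_equal(
    sequence_apparent_charge("D", pKa = pka, n_terminus = FALSE,
                             c_terminus = FALSE),
    -0.9995, tolerance = 1e-4)
  # half-titration: charge is exactly -1/2 at pH = pKa
  expect_equal(
    sequence_apparent_charge("E", pH = default_pka_table()[["E"]],
                             n_terminus = FALSE, c_terminus = FALSE),
    -0.5)
  expect_equal(
    sequence_apparent_charge("K", pH = default_pka_table()[["K"]],
                             n_terminus = FALSE, c_terminus = FALSE),
    0.5)
  expect_error(sequence_apparent_charge("GXZ"), "unknown residue")
})
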