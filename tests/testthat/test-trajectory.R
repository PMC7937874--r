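random_cloud <- function(n, seed) {
  withr::with_seed(seed, matrix(rnorm(n * 3), n, 3))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("Kabsch superposition removes rigid-body motion exactly", {
  x <- random_cloud(10, 1)
  expect_equal(attr(kabsch_superpose(x, x), "rmsd"), 0, tolerance = 1e-12)
  moved <- x %*% t(rotation_z(90)) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, x)
  expect_equal(attr(fit, "rmsd"), 0, tolerance = 1e-10)
  expect_equal(unclass(fit), x, tolerance = 1e-10, ignore_attr = TRUE)
  ## the returned rotation is always proper
  expect_equal(det(attr(fit, "rotation")), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD matches the quaternion-method oracle on random clouds", {
  for (seed in 1:8) {
    a <- random_cloud(10, seed)
    b <- random_cloud(10, seed + 100)
    expect_equal(kabsch_rmsd(a, b), oracle_quaternion_rmsd(a, b),
                 tolerance = 1e-10)
  }
})

test_that("Kabsch RMSD agrees with bio3d's fitting routine", {
  a <- random_cloud(12, 3)
  b <- random_cloud(12, 4)
  ref_rmsd <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  ## bio3d prints at 3-decimal precision
  expect_equal(kabsch_rmsd(a, b), ref_rmsd, tolerance = 1e-3)
})

test_that("degenerate selections are flagged", {
  line <- cbind(seq_len(5) * 0.1, 0, 0)
  fit <- kabsch_superpose(line, line)
  expect_true(attr(fit, "degenerate"))
  cloud <- random_cloud(5, 9)
  expect_false(attr(kabsch_superpose(cloud, cloud), "degenerate"))
})

test_that("RMSF is zero for static ensembles and d for two-point alternation", {
  xyz <- random_cloud(6, 2)
  ens <- constant_ensemble(xyz, n_frames = 8)
  expect_equal(rmsf(ens)$rmsf, rep(0, 6))
  ## atom alternating between x = +-d about its mean has RMSF d
  d <- 0.07
  frames <- lapply(1:8, function(f) {
    m <- xyz
    m[1, 1] <- m[1, 1] + ifelse(f %% 2 == 0, d, -d)
    m
  })
  ens2 <- ensemble(frames, ens$atoms)
  r <- rmsf(ens2, window = "all")
  expect_equal(r$rmsf[1], d, tolerance = 1e-12)
  expect_equal(r$rmsf[-1], rep(0, 5))
})

test_that("isotropic Gaussian displacements give RMSF ~ s * sqrt(3)", {
  s_true <- 0.05
  xyz <- random_cloud(5, 3)
  frames <- withr::with_seed(31, lapply(1:10000, function(f) {
    xyz + matrix(rnorm(15, sd = s_true), 5, 3)
  }))
  ens <- ensemble(frames, constant_ensemble(xyz)$atoms)
  r <- rmsf(ens, window = "all")
  expect_equal(r$rmsf, rep(s_true * sqrt(3), 5), tolerance = 0.03)
})

test_that("RMSF default window is the last half of the trajectory", {
  xyz <- matrix(0, 1, 3)
  ## first half noisy, last half static: default window sees only the static part
  frames <- c(lapply(1:5, function(f) matrix(rnorm(3), 1, 3)),
              lapply(1:5, function(f) xyz))
  ens <- ensemble(frames, constant_ensemble(xyz)$atoms)
  expect_equal(rmsf(ens)$rmsf, 0)
  expect_gt(rmsf(ens, window = "all")$rmsf, 0)
})

test_that("RMSF is invariant under a rigid motion applied uniformly to all frames", {
  beads <- assign_backbone_beads(make_ideal_helix(8))
  ens <- make_gaussian_ensemble(beads, c(0.02, 0.01), 200, seed = 5)
  r1 <- rmsf(ens, window = "all")$rmsf
  rot <- rotation_z(35)
  moved <- ens$coords
  for (f in seq_len(dim(moved)[1])) {
    moved[f, , ] <- moved[f, , ] %*% t(rot) + matrix(c(1, 2, 3), 8, 3,
                                                     byrow = TRUE)
  }
  ens2 <- ensemble(moved, ens$atoms)
  expect_equal(rmsf(ens2, window = "all")$rmsf, r1, tolerance = 1e-10)
})

test_that("PCA isolates a single varying coordinate", {
  xyz <- random_cloud(4, 7)
  frames <- lapply(1:20, function(f) {
    m <- xyz
    m[2, 3] <- m[2, 3] + 0.1 * sin(f)   # only atom 2's z moves
    m
  })
  ens <- ensemble(frames, constant_ensemble(xyz)$atoms)
  p <- pca_ensemble(ens)
  w <- abs(p$vectors[, 1])
  expect_equal(which.max(w), 6L)        # coordinate z of atom 2 (x1 y1 z1 x2 y2 z2)
  expect_equal(sum(w[-6]), 0, tolerance = 1e-10)
  expect_equal(p$values[-1], rep(0, length(p$values) - 1), tolerance = 1e-12)
})

test_that("PCA eigenvalue sum equals the covariance trace and per-coordinate variance sum", {
  beads <- assign_backbone_beads(make_ideal_helix(6))
  ens <- make_gaussian_ensemble(beads, c(0.5, 0.2, 0.1), 300, seed = 8)
  p <- pca_ensemble(ens)
  expect_equal(sum(p$values), p$trace, tolerance = 1e-8)
  flat <- do.call(rbind, lapply(seq_len(300), function(f) {
    as.numeric(t(ensemble_frame(ens, f)))
  }))
  expect_equal(p$trace, sum(apply(flat, 2, var)), tolerance = 1e-10)
  ## eigenvector matrix is orthonormal
  g <- crossprod(p$vectors)
  expect_equal(g, diag(nrow(g)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA projections reconstruct the centered coordinates", {
  beads <- assign_backbone_beads(make_ideal_helix(5))
  ens <- make_gaussian_ensemble(beads, c(0.3, 0.1), 50, seed = 12)
  p <- pca_ensemble(ens)
  proj <- as.matrix(p$projections[, -1])
  rec <- proj %*% t(p$vectors) +
    matrix(as.numeric(t(p$mean)), 50, 15, byrow = TRUE)
  flat <- do.call(rbind, lapply(1:50, function(f) as.numeric(t(ensemble_frame(ens, f)))))
  expect_equal(rec, flat, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("planted Gaussian spectra are recovered by PCA", {
  beads <- assign_backbone_beads(make_ideal_helix(10))
  ens <- make_gaussian_ensemble(beads, c(1.0, 0.5, 0.1), 5000, seed = 21)
  p <- pca_ensemble(ens)
  expect_equal(p$values[1:3], c(1.0, 0.5, 0.1), tolerance = 0.05)
  e1 <- attr(ens, "modes")[, 1]
  expect_gt(abs(sum(p$vectors[, 1] * e1)), 0.99)
})

test_that("joint PCA projects ensembles onto common components", {
  beads <- assign_backbone_beads(make_ideal_helix(6))
  ens <- make_gaussian_ensemble(beads, c(0.2, 0.1), 100, seed = 4)
  jp <- joint_pca(list(a = ens, b = ens))
  pa <- jp$projections[jp$projections$ensemble == "a", -1]
  pb <- jp$projections[jp$projections$ensemble == "b", -1]
  expect_equal(pa, pb, ignore_attr = TRUE, tolerance = 1e-10)
  ## projections of the pooled set are centered on every component
  expect_equal(colMeans(as.matrix(jp$projections[, -(1:2)])),
               rep(0, ncol(jp$projections) - 2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("joint PCA separates ensembles with shifted means along PC1", {
  beads <- assign_backbone_beads(make_ideal_helix(6))
  ens_a <- make_gaussian_ensemble(beads, c(0.001), 150, seed = 6)
  ## an internal deformation that no rigid fit can absorb
  shifted <- beads
  shifted$x <- beads$x + 0.05 * rep(c(-1, 1), length.out = nrow(beads))
  ens_b <- make_gaussian_ensemble(shifted, c(0.001), 150, seed = 7)
  jp <- joint_pca(list(a = ens_a, b = ens_b))
  m_a <- mean(jp$projections$PC1[jp$projections$ensemble == "a"])
  m_b <- mean(jp$projections$PC1[jp$projections$ensemble == "b"])
  ## the two ensembles sit on opposite sides of the common mean
  expect_lt(m_a * m_b, 0)
  expect_gt(abs(m_a - m_b), 3 * sqrt(0.001))
})

test_that("RMSIP is 1 for identical subspaces and 0 for orthogonal ones", {
  beads <- assign_backbone_beads(make_ideal_helix(12))
  ens <- make_gaussian_ensemble(beads, c(0.5, 0.3, 0.2, 0.1), 400, seed = 2)
  p <- pca_ensemble(ens)
  expect_equal(rmsip(p, p, n_modes = 10), 1, tolerance = 1e-10)
  d <- 30
  basis <- random_orthonormal(d, 20, seed = 5)
  u <- basis[, 1:10]
  v <- basis[, 11:20]
  expect_equal(rmsip(u, v, n_modes = 10), 0, tolerance = 1e-10)
})

test_that("RMSIP equals the explicit double sum, is symmetric and rotation-invariant", {
  u <- random_orthonormal(30, 10, seed = 1)
  v <- random_orthonormal(30, 10, seed = 2)
  expect_equal(rmsip(u, v, 10), oracle_rmsip(u, v, 10), tolerance = 1e-12)
  expect_equal(rmsip(u, v, 10), rmsip(v, u, 10), tolerance = 1e-12)
  ## rotating within the 10-mode subspace leaves RMSIP unchanged
  q <- random_orthonormal(10, 10, seed = 3)
  expect_equal(rmsip(u %*% q, v, 10), rmsip(u, v, 10), tolerance = 1e-10)
  expect_error(rmsip(u[1:10, ], v, 10), "dimension")
  expect_error(rmsip(u, v, 11), "modes")
})

test_that("Q_AB is 1 on the native frame, 0 after dilation, and thresholds correctly", {
  td <- make_toy_dimer(n = 20, k = 3)
  imap <- build_interface_contacts(td$structure, "A", "B", 0.5)
  beads <- assign_backbone_beads(td$structure)
  native <- as.matrix(beads[, c("x", "y", "z")])
  dilated <- sweep(sweep(native, 2, colMeans(native)) * 2, 2,
                   colMeans(native), "+")
  ens <- ensemble(list(native, dilated),
                  beads[, c("chain", "resid", "ins", "resname")])
  q <- qab(ens, imap, window = "all")
  expect_equal(q$qab[1], 1)
  expect_equal(q$qab[2], 0)
  ## single contact at 1.30 r0 present, at 1.40 r0 absent (threshold 1.3363)
  one <- imap[1, ]
  for (fac in c(1.30, 1.40)) {
    scaled <- sweep(sweep(native, 2, colMeans(native)) * fac, 2,
                    colMeans(native), "+")
    ens1 <- ensemble(list(scaled), beads[, c("chain", "resid", "ins")])
    expect_equal(qab(ens1, one, window = "all")$qab, as.numeric(fac < 1.3365))
  }
})

test_that("Q_AB is invariant under rigid motion of a frame", {
  td <- make_toy_dimer(n = 20, k = 3, seed = 5)
  imap <- build_interface_contacts(td$structure, "A", "B", 0.5)
  beads <- assign_backbone_beads(td$structure)
  native <- as.matrix(beads[, c("x", "y", "z")])
  withr::with_seed(10, {
    wig <- native + matrix(rnorm(length(native), sd = 0.05), nrow(native), 3)
  })
  moved <- wig %*% t(rotation_z(72)) + matrix(c(3, -1, 2), nrow(wig), 3,
                                              byrow = TRUE)
  ens <- ensemble(list(wig, moved), beads[, c("chain", "resid", "ins")])
  q <- qab(ens, imap, window = "all")
  expect_equal(q$qab[1], q$qab[2])
  expect_error(qab(ens, imap[0, ]), "empty")
})

test_that("minimum-distance series matches brute force and tracks approach", {
  xyz <- random_cloud(6, 5)
  frames <- lapply(1:5, function(f) {
    m <- xyz
    m[1, ] <- c(0, 0, 1.0 - 0.1 * f)   # atom 1 approaches atom 2 at origin
    m[2, ] <- 0
    m
  })
  ens <- ensemble(frames, constant_ensemble(xyz)$atoms)
  d12 <- min_distance_series(ens, 1, 2)
  expect_equal(d12$min_dist, 1.0 - 0.1 * (1:5), tolerance = 1e-12)
  expect_true(all(diff(d12$min_dist) < 0))
  ## random selections vs exhaustive scan
  sel_a <- c(1, 3, 5); sel_b <- c(2, 4, 6)
  got <- min_distance_series(ens, sel_a, sel_b)$min_dist
  want <- vapply(frames, function(m) {
    min(as.matrix(dist(m))[sel_a, sel_b])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  ## static atoms give a constant series
  two <- ensemble(replicate(3, rbind(c(0, 0, 0), c(0.5, 0, 0)),
                            simplify = FALSE),
                  tibble::tibble(chain = "A", resid = 1:2, ins = ""))
  expect_equal(min_distance_series(two, 1, 2)$min_dist, rep(0.5, 3))
})

test_that("ensembles reject frames with differing atom counts", {
  a <- matrix(0, 3, 3)
  b <- matrix(0, 4, 3)
  expect_error(ensemble(list(a, b), tibble::tibble(chain = "A", resid = 1:3,
                                                   ins = "")),
               "atom counts")
})

test_that("multi-model PDB and GRO ensembles round trip", {
  beads <- assign_backbone_beads(make_ideal_helix(5))
  ens <- make_gaussian_ensemble(beads, c(0.01), 4, seed = 3)
  fp <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, fp)
  back <- read_ensemble_pdb(fp)
  expect_equal(n_frames(back), 4)
  expect_equal(n_atoms(back), 5)
  ## PDB stores angstrom at 3 decimals: 5e-5 nm bound
  expect_lt(max(abs(back$coords - ens$coords)), 5.1e-5)
  fg <- tempfile(fileext = ".gro")
  write_ensemble_gro(ens, fg)
  back2 <- read_ensemble_gro(fg)
  ## GRO stores nm at 3 decimals: 5e-4 nm bound
  expect_lt(max(abs(back2$coords - ens$coords)), 5.1e-4)
})
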