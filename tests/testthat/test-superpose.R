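test_that("superposition removes pure translations and rotations", {
  xyz <- tiny_coords(3)
  coords <- array(NA_real_, c(3, nrow(xyz), 3))
  coords[1, , ] <- xyz
  coords[2, , ] <- sweep(xyz, 2, c(5, 5, 5), "+")
  coords[3, , ] <- xyz %*% rotation_z(pi / 2)
  ens <- superpose_models(conformer_ensemble(coords, tiny_atoms(3)))
  mat <- pairwise_rmsd(ens)
  expect_lt(mat[1, 2], 1e-6)
  expect_lt(mat[1, 3], 1e-6)
  # reference model untouched
  expect_equal(ens$coords[1, , ], xyz)
})

test_that("the fitted rotation is optimal and proper", {
  withr::local_seed(7)
  for (i in 1:5) {
    mobile <- random_coords(10)
    target <- random_coords(10)
    fit <- kabsch(mobile, target)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)  # no reflection
    before <- sqrt(mean(rowSums((mobile - target)^2)))
    expect_lte(fit$rmsd, before + 1e-12)
    # independent oracle: dense search over Euler-angle rotations
    expect_lte(fit$rmsd, grid_search_rmsd(mobile, target, n = 16) + 1e-9)
  }
})

test_that("superposition agrees with the reference least-squares fitter", {
  withr::local_seed(21)
  target <- random_coords(20)
  mobile <- random_coords(20)
  fit <- kabsch(mobile, target)
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(target)),
                                         mobile = as.vector(t(mobile))))
  ours <- mobile %*% fit$rotation + rep(fit$translation, each = 20)
  # bio3d::rmsd prints at 3-decimal precision
  expect_equal(sqrt(mean(rowSums((ours - target)^2))),
               bio3d::rmsd(as.vector(t(target)), ref),
               tolerance = 1e-3)
})

test_that("degenerate collinear geometry is rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 1), "collinear")
})

test_that("pairwise RMSD matches hand computation and matrix invariants", {
  # two 2-atom models, per-atom displacements 3 and 4 A
  coords <- array(0, c(2, 2, 3))
  coords[1, , ] <- rbind(c(0, 0, 0), c(10, 0, 0))
  coords[2, , ] <- rbind(c(3, 0, 0), c(10, 4, 0))
  ens <- conformer_ensemble(coords, tiny_atoms(1)[1:2, ])
  ens$superposed <- TRUE  # measure as-is
  mat <- pairwise_rmsd(ens)
  expect_equal(mat[1, 2], sqrt((9 + 16) / 2))
  expect_equal(mat, t(mat))
  expect_equal(diag(mat), c(`1` = 0, `2` = 0))
  # identical models give an all-zero matrix
  m0 <- pairwise_rmsd(superpose_models(identical_ensemble(3)))
  expect_true(all(m0 < 1e-10))
})

test_that("downstream statistics are invariant to global rigid motion of the input", {
  fx <- make_two_state_ensemble(n_models = 6, n_residues = 15, seed = 5)
  ens <- fx$ensemble
  moved <- ens
  R <- rotation_z(0.7)
  for (m in seq_len(n_models(ens)))
    moved$coords[m, , ] <- sweep(ens$coords[m, , ] %*% R, 2, c(3, -2, 8), "+")
  m1 <- pairwise_rmsd(superpose_models(ens))
  m2 <- pairwise_rmsd(superpose_models(moved))
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-8)
  expect_equal(radius_of_gyration(ens)$rg, radius_of_gyration(moved)$rg,
               tolerance = 1e-8)
})

test_that("RMSD summaries use off-diagonal pairs once", {
  mat <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                dimnames = list(1:3, 1:3))
  s <- rmsd_summary(mat)
  expect_equal(s$stats$mean, 2)
  expect_equal(s$stats$min, 1)
  expect_equal(s$stats$max, 3)
  expect_equal(s$stats$n_pairs, 3L)
  expect_equal(s$per_model$mean_rmsd, c(1.5, 2, 2.5))
  z <- matrix(0, 2, 2)
  expect_equal(rmsd_summary(z)$stats$mean, 0)
  expect_equal(rmsd_summary(z)$stats$sd, 0)
  expect_error(rmsd_summary(matrix(0, 1, 1)), "at least 2")
})

test_that("radius of gyration matches direct two-pass computation", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(two), 2)
  withr::local_seed(9)
  pts <- random_coords(10)
  ctr <- colMeans(pts)
  direct <- sqrt(sum(sweep(pts, 2, ctr)^2) / 10)
  expect_equal(radius_of_gyration(pts), direct)
})

test_that("RMSF is zero for identical models and exact for a planted oscillation", {
  ens <- identical_ensemble(4, 3)
  ens$superposed <- TRUE
  prof <- rmsf_profile(ens)
  expect_true(all(prof$per_atom$rmsf < 1e-12))
  # one atom moving +/-1 A in x across two models, all others fixed:
  # measure without re-fitting so the planted deviation is untouched
  coords <- array(0, c(2, 12, 3))
  coords[1, , ] <- tiny_coords(3)
  coords[2, , ] <- tiny_coords(3)
  coords[1, 5, 1] <- coords[1, 5, 1] + 1
  coords[2, 5, 1] <- coords[2, 5, 1] - 1
  ens2 <- conformer_ensemble(coords, tiny_atoms(3))
  ens2$superposed <- TRUE
  prof2 <- rmsf_profile(ens2)
  expect_equal(prof2$per_atom$rmsf[5], 1)
  expect_true(all(prof2$per_atom$rmsf[-5] < 1e-12))
})

test_that("isotropic coordinate noise gives the closed-form RMSF level", {
  fx <- make_two_state_ensemble(n_models = 30, n_residues = 60,
                                occupancies = 1, noise_sigma = 0.5,
                                seed = 31)
  prof <- rmsf_profile(superpose_models(fx$ensemble))
  # E[RMSF] ~ sqrt(3) * sigma (slightly shrunk by mean estimation/fitting)
  expect_equal(mean(prof$per_residue$rmsf), sqrt(3) * 0.5, tolerance = 0.06)
  expect_equal(prof$threshold_75,
               unname(quantile(prof$per_residue$rmsf, 0.75)))
  expect_setequal(
    prof$per_residue$resno[prof$per_residue$high_flex],
    prof$per_residue$resno[prof$per_residue$rmsf > prof$threshold_75])
})

test_that("a single-model ensemble yields all-zero RMSF with a warning", {
  ens <- identical_ensemble(1, 2)
  expect_warning(prof <- rmsf_profile(ens), "single-model")
  expect_true(all(prof$per_atom$rmsf == 0))
})
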