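# A mid-sized fixture for trajectory statistics: 20-residue extended peptide
traj_fixture <- function() build_peptide(20, -120, 120)

test_that("rmsd series is zero for static and purely rigid-body trajectories", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  static <- trajectory3d(s, replicate(5, coords(s), simplify = FALSE), 40)
  expect_equal(rmsd_series(static, sel)$series$rmsd, rep(0, 5), tolerance = 1e-9)
  rigid <- trajectory3d(s, lapply(1:6, function(k) random_rigid(coords(s), k)), 40)
  expect_lt(max(rmsd_series(rigid, sel)$series$rmsd), 1e-9)
})

test_that("rmsd series equals an independent per-frame Kabsch oracle", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  traj <- make_harmonic_traj(s, 0.6, 50, seed = 31)
  r <- rmsd_series(traj, sel, units = "angstrom")
  oracle <- vapply(traj$frames, function(f)
    rmsd_oracle(f[sel, , drop = FALSE], traj$frames[[1]][sel, , drop = FALSE]),
    numeric(1))
  expect_equal(r$series$rmsd, oracle, tolerance = 1e-9)
  # plateau magnitude: fitted RMSD of two frames with iid per-coordinate
  # sigma is ~ sqrt(2 * 3) * sigma, reduced by the 6 fitted rigid DOF
  expected <- sqrt(2 * 3 * (1 - 6 / (3 * length(sel)))) * 0.6
  expect_lt(abs(r$plateau_mean - expected) / expected, 0.15)
  # nm toggle
  expect_equal(rmsd_series(traj, sel)$series$rmsd, r$series$rmsd / 10,
               tolerance = 1e-12)
})

test_that("rmsf recovers isotropic fluctuation amplitudes and ordering", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  static <- trajectory3d(s, replicate(3, coords(s), simplify = FALSE), 40)
  expect_equal(rmsf_profile(static, sel)$profile$rmsf, rep(0, 20))
  sigma <- 0.5
  traj <- make_harmonic_traj(s, sigma, 1000, seed = 32)
  prof <- rmsf_profile(traj, sel, units = "angstrom")
  # closed form: per-atom RMSF -> sqrt(3) * sigma, reduced by the 6 rigid
  # degrees of freedom the superposition absorbs: factor sqrt(1 - 6/(3N))
  expected <- sqrt(3) * sigma * sqrt(1 - 6 / (3 * length(sel)))
  expect_lt(abs(prof$mean - expected) / expected, 0.03)
  expect_equal(prof$max, max(prof$profile$rmsf))
  expect_equal(prof$mean, mean(prof$profile$rmsf))
  # only one residue moves -> its RMSF dominates
  sig2 <- stats::setNames(c(rep(0.001, 19), 1), unique(s$atoms$res_id))
  traj2 <- make_harmonic_traj(s, sig2, 200, seed = 33)
  prof2 <- rmsf_profile(traj2, sel, units = "angstrom")
  expect_equal(which.max(prof2$profile$rmsf), 20)
  # the fit leaks a little of the moving residue's noise into the static
  # ones, so the contrast is large but not sigma-ratio large
  expect_gt(prof2$profile$rmsf[20], 10 * stats::median(prof2$profile$rmsf[1:19]))
})

test_that("rmsf and pca are invariant under per-frame rigid motions", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  traj <- make_harmonic_traj(s, 0.4, 60, seed = 34)
  moved <- trajectory3d(s, lapply(seq_along(traj$frames), function(k)
    random_rigid(traj$frames[[k]], 100 + k)), 40)
  f1 <- rmsf_profile(traj, sel); f2 <- rmsf_profile(moved, sel)
  expect_equal(f2$profile$rmsf, f1$profile$rmsf, tolerance = 1e-9)
  p1 <- pca_ca(traj, sel); p2 <- pca_ca(moved, sel)
  expect_equal(p2$eigenvalues, p1$eigenvalues, tolerance = 1e-9)
  r1 <- rmsd_series(traj, sel); r2 <- rmsd_series(moved, sel)
  expect_equal(r2$series$rmsd, r1$series$rmsd, tolerance = 1e-9)
})

test_that("B-factor conversion follows the Debye-Waller closed form", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  traj <- make_harmonic_traj(s, 0.3, 30, seed = 35)
  prof <- rmsf_profile(traj, sel, units = "angstrom")
  b <- bfactor_from_rmsf(prof)
  expect_equal(b$b_factor, (8 * pi^2 / 3) * prof$profile$rmsf^2,
               tolerance = 1e-12)
  # unit independence: nm profile converts identically
  prof_nm <- rmsf_profile(traj, sel, units = "nm")
  expect_equal(bfactor_from_rmsf(prof_nm)$b_factor, b$b_factor,
               tolerance = 1e-9)
  # RMSF of exactly 1 A -> 8 pi^2 / 3; doubling quadruples
  prof1 <- prof; prof1$profile$rmsf <- rep(1, 20); prof1$units <- "angstrom"
  expect_equal(bfactor_from_rmsf(prof1)$b_factor, rep(8 * pi^2 / 3, 20))
  prof2 <- prof1; prof2$profile$rmsf <- rep(2, 20)
  expect_equal(bfactor_from_rmsf(prof2)$b_factor,
               4 * bfactor_from_rmsf(prof1)$b_factor)
  # peak sets coincide (monotone transform)
  expect_equal(which.max(b$b_factor), which.max(prof$profile$rmsf))
})

test_that("pca eigen-structure is exact: sums, orthonormality, SVD oracle", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  traj <- make_harmonic_traj(s, 0.4, 80, seed = 36)
  p <- pca_ca(traj, sel, units = "angstrom")
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-9)
  expect_equal(sort(p$eigenvalues, decreasing = TRUE), p$eigenvalues)
  expect_equal(t(p$eigenvectors) %*% p$eigenvectors,
               diag(ncol(p$eigenvectors)), tolerance = 1e-9)
  # independent oracle: singular values of the centred data matrix
  ft <- ltqdyn:::fit_to_mean(traj, sel)
  X <- t(vapply(ft$frames, function(f) as.numeric(t(f[sel, , drop = FALSE])),
                numeric(3 * length(sel))))
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  expect_equal(p$eigenvalues[seq_along(sv$d)], sv$d^2 / nrow(X),
               tolerance = 1e-9)
  # agreement with the RMSF profile under the same superposition
  prof <- rmsf_profile(traj, sel, units = "angstrom")
  expect_equal(sum(p$eigenvalues), sum(prof$profile$rmsf^2),
               tolerance = 1e-6 * sum(p$eigenvalues))
  expect_error(pca_ca(trajectory3d(s, list(coords(s)), 40), sel), "2 frames")
})

test_that("a single collective mode captures >99 percent of the variance", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  set.seed(37)
  mode <- matrix(stats::rnorm(3 * nrow(s$atoms)), ncol = 3)
  mode <- mode / sqrt(sum(mode^2))
  frames <- lapply(1:100, function(t)
    coords(s) + sin(t / 7) * 4 * mode +
      matrix(stats::rnorm(3 * nrow(s$atoms), sd = 0.01), ncol = 3))
  p <- pca_ca(trajectory3d(s, frames, 40), sel)
  expect_gt(p$variance_fractions[1], 0.99)
})

test_that("displacement field flags exactly the moved residue", {
  s <- traj_fixture()
  sel <- select_atoms(s, atom_name = "CA")
  same <- trajectory3d(s, list(coords(s), coords(s)), 40)
  expect_length(displacement_field(same, selection = sel)$exceeding, 0)
  xyz2 <- coords(s)
  moved <- s$atoms$res_id == 10
  xyz2[moved, ] <- xyz2[moved, ] + rep(c(4, 0, 0), each = sum(moved))
  # put the moved frame through a global rigid motion too: the fit removes it
  xyz2 <- random_rigid(xyz2, 38)
  traj <- trajectory3d(s, list(coords(s), xyz2), 40)
  d <- displacement_field(traj, selection = sel, threshold = 3)
  expect_equal(d$exceeding, 10)
  expect_gt(d$field$magnitude[d$field$res_id == 10], 3)
  # threshold 0 lists every residue
  expect_length(displacement_field(traj, selection = sel, threshold = 0)$exceeding,
                20)
})

test_that("tau series tracks geometry interpolation and flags undefined frames", {
  base <- make_ideal_metal_site("interpolated", tau_target = 0)
  static <- trajectory3d(make_ideal_metal_site("square-pyramidal"),
                         replicate(4, coords(make_ideal_metal_site("square-pyramidal")),
                                   simplify = FALSE), 40)
  ts0 <- tau_series(static, "CU")
  expect_equal(ts0$series$tau, rep(0, 4), tolerance = 1e-9)
  expect_equal(ts0$max, 0, tolerance = 1e-9)
  grid <- seq(0, 1, length.out = 21)
  frames <- lapply(grid, function(t)
    coords(make_ideal_metal_site("interpolated", tau_target = t)))
  ts <- tau_series(trajectory3d(base, frames, 40), "CU")
  expect_equal(ts$series$tau, grid, tolerance = 1e-9)
  expect_true(all(diff(ts$series$tau) > 0))
  # ligand pushed outside the cutoff -> frame undefined, not dropped silently
  f_bad <- frames
  f_bad[[5]][2, ] <- f_bad[[5]][2, ] * 2
  ts2 <- tau_series(trajectory3d(base, f_bad, 40), "CU")
  expect_false(ts2$series$defined[5])
  expect_equal(ts2$n_undefined, 1)
  expect_equal(ts2$series$n_ligands[5], 4)
  expect_equal(ts2$mean, mean(grid[-5]), tolerance = 1e-9)
})

test_that("rotamer series recovers a switching schedule exactly", {
  base <- make_lys_sidechain(c(65, 180, 180, 65))
  sched <- data.frame(code = c("pttp", "mtmt", "pttp"),
                      length = c(80, 60, 40))
  traj <- make_rotamer_switch_traj(base, 1, sched, jitter = 8, seed = 41)
  rs <- rotamer_series(traj, 1)
  expect_equal(rs$runs$code, c("pttp", "mtmt", "pttp"))
  expect_equal(rs$runs$first_frame, c(1, 81, 141))
  expect_equal(rs$runs$last_frame, c(80, 140, 180))
  # constant trajectory -> a single run
  one <- make_rotamer_switch_traj(base, 1, data.frame(code = "tttt", length = 12),
                                  jitter = 0, seed = 42)
  rs1 <- rotamer_series(one, 1)
  expect_equal(nrow(rs1$runs), 1)
  expect_equal(rs1$runs$code, "tttt")
  # zero jitter -> canonical chi, zero deviation codes
  expect_true(all(rs1$codes == "tttt"))
})

test_that("rapid single-frame flips are reported as mobile", {
  base <- make_lys_sidechain(c(65, 180, 180, 65))
  flip <- data.frame(code = rep(c("pttp", "mtmt"), 10), length = 1)
  traj <- make_rotamer_switch_traj(base, 1, flip, jitter = 0, seed = 43)
  rs <- rotamer_series(traj, 1, min_run = 5)
  expect_equal(rs$runs$code, "mobile")
  expect_equal(nrow(rs$runs), 1)
  expect_equal(rs$runs$first_frame, 1)
  expect_equal(rs$runs$last_frame, 20)
})
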