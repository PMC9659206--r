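test_that("segment dihedral extraction round-trips ideal peptides", {
  hel <- build_peptide(6, -57, -47)
  sd <- extract_segment_dihedrals(hel, "A", 1:6)
  expect_true(is.na(sd$backbone$phi[1]))
  expect_true(is.na(sd$backbone$psi[6]))
  expect_equal(sd$backbone$phi[2:6], rep(-57, 5), tolerance = 1e-6)
  expect_equal(sd$backbone$psi[1:5], rep(-47, 5), tolerance = 1e-6)
  str <- build_peptide(4, -120, 120)
  sd2 <- extract_segment_dihedrals(str, "A", 1:4)
  expect_equal(sd2$backbone$phi[2:4], rep(-120, 3), tolerance = 1e-6)
  expect_equal(sd2$backbone$psi[1:3], rep(120, 3), tolerance = 1e-6)
  two <- build_peptide(2, -57, -47)
  expect_true(is.na(extract_segment_dihedrals(two, "A", 1:2)$backbone$phi[1]))
  # missing backbone atom is reported with the residue
  broken <- structure3d(hel$atoms[hel$atoms$name != "CA" |
                                    hel$atoms$res_id != 3, ])
  expect_error(extract_segment_dihedrals(broken, "A", 1:6), "residue 3")
})

test_that("identity transplant is a no-op on helix, strand and random torsions", {
  set.seed(20)
  fixtures <- list(build_peptide(6, -57, -47),
                   build_peptide(6, -120, 120),
                   build_peptide(6, stats::runif(6, -180, 180),
                                 stats::runif(6, -180, 180)))
  for (s in fixtures) {
    out <- transplant_segment_dihedrals(s, "A", 1:6,
                                        extract_segment_dihedrals(s, "A", 1:6))
    expect_lt(max(abs(coords(out) - coords(s))), 1e-6)
  }
})

test_that("transplanted segments reproduce requested angles, torsion-only", {
  ext <- build_peptide(6, -120, 120)
  hel_d <- extract_segment_dihedrals(build_peptide(6, -57, -47), "A", 1:6)
  out <- transplant_segment_dihedrals(ext, "A", 1:6, hel_d)
  got <- extract_segment_dihedrals(out, "A", 1:6)
  expect_equal(got$backbone$phi[2:6], rep(-57, 5), tolerance = 1e-4)
  expect_equal(got$backbone$psi[1:5], rep(-47, 5), tolerance = 1e-4)
  # anchor side bitwise unmoved
  expect_identical(atom_xyz(out, 1, "N"), atom_xyz(ext, 1, "N"))
  # bond lengths and angles untouched (torsion-only rebuild)
  for (r in 2:5) {
    expect_equal(vec_distance(atom_xyz(out, r, "N"), atom_xyz(out, r, "CA")),
                 vec_distance(atom_xyz(ext, r, "N"), atom_xyz(ext, r, "CA")),
                 tolerance = 1e-6)
    expect_equal(vec_angle(atom_xyz(out, r, "N"), atom_xyz(out, r, "CA"),
                           atom_xyz(out, r, "C")),
                 vec_angle(atom_xyz(ext, r, "N"), atom_xyz(ext, r, "CA"),
                           atom_xyz(ext, r, "C")), tolerance = 1e-6)
  }
  # helical angles compact the extended hexapeptide
  expect_lt(vec_distance(atom_xyz(out, 1, "CA"), atom_xyz(out, 6, "CA")), 10)
  expect_gt(vec_distance(atom_xyz(ext, 1, "CA"), atom_xyz(ext, 6, "CA")), 15)
})

test_that("a single psi change rotates downstream atoms per the rotation oracle", {
  s <- build_peptide(4, -120, 120)
  d <- extract_segment_dihedrals(s, "A", 1:4)
  d$backbone$psi[2] <- -47
  out <- transplant_segment_dihedrals(s, "A", 1:4, d)
  # oracle: explicit rotation of everything beyond CA2-C2 about that axis
  ca <- atom_xyz(s, 2, "CA"); cc <- atom_xyz(s, 2, "C")
  delta <- -47 - 120
  expected <- coords(s)
  later <- which(s$atoms$res_id > 2 | (s$atoms$res_id == 2 & s$atoms$name == "O"))
  expected[later, ] <- ltqdyn:::rotate_points(expected[later, , drop = FALSE],
                                              ca, cc - ca, delta)
  expect_equal(coords(out), expected, tolerance = 1e-9, ignore_attr = TRUE)
  # upstream residue 1 untouched
  expect_identical(atom_xyz(out, 1, "CA"), atom_xyz(s, 1, "CA"))
})

test_that("downstream anchor fixes the C-terminal side instead", {
  ext <- build_peptide(6, -120, 120)
  hel_d <- extract_segment_dihedrals(build_peptide(6, -57, -47), "A", 1:6)
  out <- transplant_segment_dihedrals(ext, "A", 1:6, hel_d, anchor = "downstream")
  got <- extract_segment_dihedrals(out, "A", 1:6)
  expect_equal(got$backbone$phi[2:6], rep(-57, 5), tolerance = 1e-4)
  expect_identical(atom_xyz(out, 6, "C"), atom_xyz(ext, 6, "C"))
})

test_that("chain breaks inside the segment are refused", {
  s <- build_peptide(4, -120, 120)
  xyz <- coords(s)
  shift <- s$atoms$res_id >= 3
  xyz[shift, ] <- xyz[shift, ] + 10
  broken <- set_coords(s, xyz)
  expect_error(
    transplant_segment_dihedrals(broken, "A", 1:4,
                                 extract_segment_dihedrals(s, "A", 1:4)),
    "chain break")
})

test_that("side-chain grafting is a rigid fit that leaves the backbone alone", {
  donor <- make_lys_sidechain(c(65, 180, 180, 65))
  target <- make_lys_sidechain(c(-65, 180, -65, 180), res_id = 7)
  out <- graft_sidechain_template(target, 7, donor)
  # backbone untouched
  for (nm in c("N", "CA", "C", "O"))
    expect_equal(atom_xyz(out, 7, nm), atom_xyz(target, 7, nm))
  # grafted side chain now carries the donor's rotamer
  expect_equal(classify_rotamer(chi_angles(out, 7))$code, "pttp")
  # grafting a residue onto itself reproduces it exactly
  self <- graft_sidechain_template(target, 7, make_lys_sidechain(c(-65, 180, -65, 180)))
  expect_equal(chi_angles(self, 7), chi_angles(target, 7), tolerance = 1e-6)
  # CB stays put under the (N, CA, CB) frame fit of an identical frame
  expect_equal(atom_xyz(self, 7, "CB"), atom_xyz(target, 7, "CB"),
               tolerance = 1e-6)
  no_cb <- structure3d(target$atoms[target$atoms$name != "CB", ])
  expect_error(graft_sidechain_template(no_cb, 7, donor), "CB")
})

test_that("crosslink patch edits atom/bond counts exactly and is invertible", {
  fx <- make_precursor_fixture()
  p <- patch_tpq2hp_to_ltq2hp(40, 20)
  out <- apply_patch(fx, p)
  expect_equal(nrow(out$atoms), nrow(fx$atoms) - 1)        # one oxygen deleted
  expect_equal(nrow(out$bonds), nrow(fx$bonds) - 1 + 1)    # -C2:O2, +NZ:C2
  nz <- which(out$atoms$name == "NZ"); c2 <- which(out$atoms$name == "C2")
  expect_true(any(out$bonds[, 1] == min(nz, c2) & out$bonds[, 2] == max(nz, c2)))
  expect_false(any(out$atoms$name == "O2"))
  expect_equal(unique(out$atoms$res_name[out$atoms$res_id == 20]), "LTQ")
  # invertibility: atom set and bond graph restored
  back <- apply_patch(out, invert_patch(p, fx))
  key <- function(s) sort(paste(s$atoms$res_id, s$atoms$name))
  bond_key <- function(s) {
    lab <- paste(s$atoms$res_id, s$atoms$name)
    sort(apply(cbind(lab[s$bonds[, 1]], lab[s$bonds[, 2]]), 1,
               function(r) paste(sort(r), collapse = "|")))
  }
  expect_identical(key(back), key(fx))
  expect_identical(bond_key(back), bond_key(fx))
  expect_equal(sort(unique(back$atoms$res_name[back$atoms$res_id == 20])),
               sort(unique(fx$atoms$res_name[fx$atoms$res_id == 20])))
})

test_that("hydrazone-strip patch removes adduct atoms and restores the C5 carbonyl", {
  # LTQ-2HP-like fixture: quinone ring + N1/N3/pyridine carbons hanging off C5
  toy <- make_toy_active_site()
  at <- toy$atoms
  c5 <- which(at$name == "C5" & at$res_id == 20)
  hyd <- data.frame(name = c("N1", "N3", "C7", "C8", "C9", "C10", "C11"))
  base <- at[c5, c("x", "y", "z")]
  rows <- do.call(rbind, lapply(seq_len(nrow(hyd)), function(i) {
    r <- at[c5, ]
    r$serial <- max(at$serial) + i; r$name <- hyd$name[i]
    r$element <- substr(hyd$name[i], 1, 1)
    r[, c("x", "y", "z")] <- base + c(0, 0.5 * i, 1.2)
    r
  }))
  b <- toy$bonds
  n1 <- nrow(at) + 1                                  # N1 bonded to C5
  b <- rbind(b, c(c5, n1))
  for (i in 2:nrow(hyd)) b <- rbind(b, c(nrow(at) + i - 1, nrow(at) + i))
  fx <- structure3d(rbind(at, rows), b, toy$title)
  p <- patch_ltq2hp_to_ltq(20)
  out <- apply_patch(fx, p)
  expect_equal(nrow(out$atoms), nrow(fx$atoms) - 7 + 1)
  expect_false(any(out$atoms$name %in% hyd$name & out$atoms$res_id == 20))
  o5 <- which(out$atoms$name == "O5" & out$atoms$res_id == 20)
  expect_length(o5, 1)
  # O5 placed by its internal-coordinate rule: 1.23 A from C5 at 120 deg
  c5o <- atom_xyz(out, 20, "C5"); c4 <- atom_xyz(out, 20, "C4")
  expect_equal(vec_distance(coords(out)[o5, ], c5o), 1.23, tolerance = 1e-6)
  expect_equal(vec_angle(c4, c5o, coords(out)[o5, ]), 120, tolerance = 1e-6)
})

test_that("deletions that would leave dangling bonds are refused", {
  fx <- make_precursor_fixture()
  bad <- cofactor_patch(atoms_deleted = data.frame(res_id = 20, name = "C3"))
  expect_error(apply_patch(fx, bad), "dangling")
})

test_that("patch text format round-trips", {
  p <- patch_ltq2hp_to_ltq(20)
  f <- withr::local_tempfile(fileext = ".patch")
  write_patch(p, f)
  p2 <- read_patch(f)
  expect_equal(p2$atoms_deleted$name, p$atoms_deleted$name)
  expect_equal(p2$atoms_added$bond_length, p$atoms_added$bond_length)
  expect_equal(p2$bonds_added, p$bonds_added, ignore_attr = TRUE)
  expect_error(read_patch({writeLines("frobnicate 1 2", f); f}), "bad patch line")
})

test_that("metal swap replaces the element in place", {
  site <- make_ideal_metal_site("tetrahedral")
  zn <- swap_metal(site, "CU", "ZN")
  expect_equal(zn$atoms$element[1], "ZN")
  expect_equal(coords(zn), coords(site), ignore_attr = TRUE)
  out <- swap_metal(zn, "ZN", "CU")
  expect_equal(out$atoms$element[1], "CU")
  expect_error(swap_metal(site, "ZN", "CU"), "no ZN")
  two <- structure3d(rbind(site$atoms,
                           transform(site$atoms[1, ], serial = 99, res_id = 99L)))
  expect_error(swap_metal(two, "CU", "ZN"), "site")
})

test_that("coordination waters complete a square pyramid", {
  site <- make_ideal_metal_site("square-pyramidal")
  s3 <- structure3d(transform(site$atoms[c(1, 2, 4, 5), ], serial = 1:4))
  out <- place_coordination_waters(s3, "CU", 2:4)
  sph <- find_coordination_sphere(out, "CU")
  expect_length(sph$ligands, 5)
  weq <- coords(out)[out$atoms$res_name == "WEQ", ]
  wax <- coords(out)[out$atoms$res_name == "WAX", ]
  # Weq fills the open basal position (trans to the gap): here along -x
  expect_lt(vec_angle(weq, c(0, 0, 0), c(-1, 0, 0)), 5)
  expect_equal(vec_angle(wax, c(0, 0, 0), weq), 90, tolerance = 5)
  expect_equal(vec_distance(weq, c(0, 0, 0)), 2.0, tolerance = 1e-6)
  expect_equal(vec_distance(wax, c(0, 0, 0)), 2.4, tolerance = 1e-6)
  # resulting 5-sphere is square-pyramidal
  expect_lt(addison_tau(sph)$tau, 0.1)
  # symmetric 4-donor basal plane has no resolvable gap
  full <- structure3d(transform(site$atoms[1:5, ], serial = 1:5))
  expect_error(place_coordination_waters(full, "CU", 2:5), "gap")
})

test_that("restraint evaluators return zero on conforming geometry", {
  pts <- data.frame(serial = 1:4, name = c("N1", "CU", "N2", "N3"),
                    element = c("N", "CU", "N", "N"), res_name = "X",
                    res_id = 1:4, chain = "A", insert = "", altloc = "",
                    x = c(1, 0, 0, 1), y = c(0, 0, 1, 1), z = 0,
                    occupancy = 1, b_factor = 0, het = TRUE)
  s <- structure3d(pts)
  r <- evaluate_restraints(s, list(
    list(kind = "improper-planarity", atoms = c("1:N1", "2:CU", "3:N2", "4:N3")),
    list(kind = "angle", atoms = c("1:N1", "2:CU", "3:N2"), target = 90)))
  expect_equal(r$deviation, c(0, 0), tolerance = 1e-9)
  expect_equal(r$penalty, c(0, 0), tolerance = 1e-9)
  # out-of-plane atom registers; 109.5 vs 120 target deviates by 10.5
  pts$z[4] <- 0.5
  s2 <- structure3d(pts)
  r2 <- evaluate_restraints(s2, list(
    list(kind = "improper-planarity", atoms = c("1:N1", "2:CU", "3:N2", "4:N3"),
         weight = 2)))
  expect_gt(r2$deviation, 1)
  expect_equal(r2$penalty, 2 * r2$deviation^2)
  tri <- structure3d(data.frame(serial = 1:3, name = c("CU", "O", "H1"),
                                element = c("CU", "O", "H"), res_name = "W",
                                res_id = 1:3, chain = "A", insert = "",
                                altloc = "",
                                x = c(0, 2, 2 + 0.96 * cos(pi * (180 - 109.5) / 180)),
                                y = c(0, 0, 0.96 * sin(pi * (180 - 109.5) / 180)),
                                z = 0, occupancy = 1, b_factor = 0, het = TRUE))
  r3 <- evaluate_restraints(tri, list(
    list(kind = "angle", atoms = c("1:CU", "2:O", "3:H1"), target = 120)))
  expect_equal(r3$deviation, 10.5, tolerance = 1e-6)
})

test_that("placed water hydrogens satisfy the 120-degree metal-O-H restraint", {
  site <- make_ideal_metal_site("square-pyramidal")
  s3 <- structure3d(transform(site$atoms[c(1, 2, 4, 5), ], serial = 1:4))
  out <- place_coordination_waters(s3, "CU", 2:4, hydrogens = TRUE)
  weq_id <- out$atoms$res_id[out$atoms$res_name == "WEQ"][1]
  wax_id <- out$atoms$res_id[out$atoms$res_name == "WAX"][1]
  specs <- unlist(lapply(c(weq_id, wax_id), function(w)
    lapply(c("H1", "H2"), function(h)
      list(kind = "angle", atoms = c("1:CU", sprintf("%d:O", w),
                                     sprintf("%d:%s", w, h)), target = 120))),
    recursive = FALSE)
  r <- evaluate_restraints(out, specs)
  expect_equal(r$deviation, rep(0, 4), tolerance = 1e-9)
})
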