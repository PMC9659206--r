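#' Ideal and interpolated 5-coordinate metal-site fixtures
#'
#' Builds a metal atom at the origin with donor nitrogens at prescribed
#' directions. `"square-pyramidal"` has four basal donors at 90 degree
#' spacing (both trans basal angles 180, so tau = 0) and one apical donor;
#' `"trigonal-bipyramidal"` has two axial donors (180) and three equatorial
#' at 120 (tau = 1); `"tetrahedral"` has four donors at 109.47 degrees.
#' `"interpolated"` morphs one basal trans pair of the square pyramid out of
#' the plane so the realised tau equals `tau_target`: the second-largest
#' angle becomes alpha = 180 - 60 * tau_target while the other trans pair
#' stays at 180 (beta).
#'
#' @param geometry one of `"square-pyramidal"`, `"trigonal-bipyramidal"`,
#'   `"tetrahedral"`, `"interpolated"`.
#' @param bond_length metal-donor distance, angstrom (default 2.0).
#' @param tau_target target Addison tau in \[0, 1\] for `"interpolated"`.
#' @param apical_length optional distinct apical bond length (e.g. 2.5 for a
#'   Jahn-Teller elongated axis); default equal to `bond_length`.
#' @return a [structure3d] with a CU atom and N donors (one residue each).
#' @export
make_ideal_metal_site <- function(geometry = c("square-pyramidal",
                                               "trigonal-bipyramidal",
                                               "tetrahedral", "interpolated"),
                                  bond_length = 2.0, tau_target = NULL,
                                  apical_length = NULL) {
  geometry <- match.arg(geometry)
  if (is.null(apical_length)) apical_length <- bond_length
  dirs <- switch(geometry,
    "square-pyramidal" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                               c(0, -1, 0), c(0, 0, 1)),
    "trigonal-bipyramidal" = rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                                   c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
                                   c(cos(4 * pi / 3), sin(4 * pi / 3), 0)),
    "tetrahedral" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                          c(-1, -1, 1)) / sqrt(3),
    "interpolated" = {
      if (is.null(tau_target) || tau_target < 0 || tau_target > 1)
        stop("interpolated geometry needs tau_target in [0, 1]")
      alpha <- 180 - 60 * tau_target
      half <- deg2rad(alpha / 2)
      rbind(c(1, 0, 0), c(-1, 0, 0),                       # trans pair, beta = 180
            c(0,  sin(half), cos(half)),                   # lifted pair, angle alpha
            c(0, -sin(half), cos(half)),
            c(0, 0, 1))                                    # apical
    })
  lengths <- rep(bond_length, nrow(dirs))
  apical_row <- switch(geometry, "square-pyramidal" = 5, "interpolated" = 5, NA)
  if (!is.na(apical_row)) lengths[apical_row] <- apical_length
  atoms <- data.frame(serial = 1L, name = "CU", element = "CU",
                      res_name = "CU", res_id = 1L, chain = "A", insert = "",
                      altloc = "", x = 0, y = 0, z = 0, occupancy = 1,
                      b_factor = 0, het = TRUE)
  for (i in seq_len(nrow(dirs))) {
    p <- dirs[i, ] * lengths[i]
    atoms <- rbind(atoms, data.frame(serial = i + 1L, name = "N",
                                     element = "N", res_name = "AMN",
                                     res_id = i + 1L, chain = "A", insert = "",
                                     altloc = "", x = p[1], y = p[2], z = p[3],
                                     occupancy = 1, b_factor = 0, het = TRUE))
  }
  structure3d(atoms, NULL, sprintf("synthetic %s metal site", geometry))
}

#' Build an ideal lysine side chain at prescribed chi angles
#'
#' Constructs N, CA, C, O, CB, CG, CD, CE, NZ with ideal bond lengths
#' (C-C 1.53, C-N 1.49, N-CA 1.46 angstrom) and tetrahedral (109.5 degree)
#' bond angles, placing each side-chain atom by internal coordinates so the
#' four chi torsions take exactly the requested values.
#'
#' @param chi numeric vector of chi1..chi4 in degrees.
#' @param res_id residue number for the built residue (default 1).
#' @return a [structure3d] of one LYS residue.
#' @export
make_lys_sidechain <- function(chi, res_id = 1L) {
  stopifnot(length(chi) == 4, all(is.finite(chi)))
  tet <- 109.5
  pos <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0))
  # C placed off-axis to give the chi1 quadruple a reference plane
  pos$C <- place_atom(c(0, 1, 0), pos$N, pos$CA, 1.53, 111, 0)
  pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.23, 120, 180)
  pos$CB <- place_atom(pos$N, pos$C, pos$CA, 1.53, tet, 122)
  pos$CG <- place_atom(pos$N, pos$CA, pos$CB, 1.53, tet, chi[1])
  pos$CD <- place_atom(pos$CA, pos$CB, pos$CG, 1.53, tet, chi[2])
  pos$CE <- place_atom(pos$CB, pos$CG, pos$CD, 1.53, tet, chi[3])
  pos$NZ <- place_atom(pos$CG, pos$CD, pos$CE, 1.49, tet, chi[4])
  atoms <- do.call(rbind, lapply(names(pos), function(nm) {
    data.frame(serial = 0L, name = nm,
               element = substr(sub("[0-9]", "", nm), 1, 1),
               res_name = "LYS", res_id = as.integer(res_id), chain = "A",
               insert = "", altloc = "", x = pos[[nm]][1], y = pos[[nm]][2],
               z = pos[[nm]][3], occupancy = 1, b_factor = 0, het = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  structure3d(atoms, NULL, "synthetic lysine side chain")
}

#' Generate a harmonic-fluctuation synthetic trajectory
#'
#' Statistical stand-in for a production MD run: frame t is the reference
#' plus independent Gaussian displacements, each residue's atoms drawn with
#' that residue's per-coordinate amplitude sigma, optionally followed by a
#' global rigid drift (rotation + translation accumulating per frame). This
#' exercises RMSD/RMSF/B-factor/PCA statistics deterministically; it is a
#' statistical, not physical, surrogate (no inter-atom correlations).
#'
#' @param reference a [structure3d].
#' @param per_residue_sigma per-coordinate fluctuation amplitude in angstrom:
#'   a single value, or a vector named by residue id (unnamed vectors are
#'   matched to residues in order).
#' @param n_frames number of frames.
#' @param seed mandatory RNG seed.
#' @param frame_spacing_ps frame spacing (default 40 ps).
#' @param rigid_drift optional list with any of `axis` (3-vector),
#'   `angle_per_frame` (degrees) and `translation_per_frame` (3-vector,
#'   angstrom), applied cumulatively.
#' @return a [trajectory3d].
#' @export
make_harmonic_traj <- function(reference, per_residue_sigma, n_frames,
                               seed, frame_spacing_ps = 40,
                               rigid_drift = NULL) {
  stopifnot(inherits(reference, "structure3d"), n_frames >= 1,
            all(per_residue_sigma >= 0))
  set.seed(as.integer(seed))
  res <- unique(reference$atoms$res_id)
  sig <- if (length(per_residue_sigma) == 1) {
    stats::setNames(rep(per_residue_sigma, length(res)), res)
  } else if (!is.null(names(per_residue_sigma))) {
    per_residue_sigma
  } else {
    stopifnot(length(per_residue_sigma) == length(res))
    stats::setNames(per_residue_sigma, res)
  }
  atom_sigma <- as.numeric(sig[as.character(reference$atoms$res_id)])
  if (any(is.na(atom_sigma))) stop("per_residue_sigma misses some residues")
  ref <- coords(reference)
  n_at <- nrow(ref)
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    f <- ref + matrix(stats::rnorm(3 * n_at, sd = atom_sigma), ncol = 3)
    if (!is.null(rigid_drift)) {
      ang <- (t - 1) * (rigid_drift$angle_per_frame %||% 0)
      axis <- rigid_drift$axis %||% c(0, 0, 1)
      trans <- (t - 1) * (rigid_drift$translation_per_frame %||% c(0, 0, 0))
      if (ang != 0) f <- rotate_points(f, colMeans(ref), axis, ang)
      f <- sweep(f, 2, trans, "+")
    }
    frames[[t]] <- f
  }
  trajectory3d(reference, frames, frame_spacing_ps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a rotamer-switch synthetic trajectory
#'
#' Rebuilds the side chain of one residue frame by frame following a
#' schedule of rotamer codes (runs of given lengths), with optional Gaussian
#' chi jitter; the backbone and all other residues stay static. Emulates a
#' side chain hopping between stable rotamers during a simulation.
#'
#' @param base a [structure3d] containing a lysine-like residue.
#' @param res_id residue whose side chain is driven.
#' @param schedule data.frame with columns `code` (strings over p/t/m, e.g.
#'   "pttp") and `length` (frames, >= 1).
#' @param jitter Gaussian chi noise SD in degrees (default 0).
#' @param seed mandatory RNG seed.
#' @param frame_spacing_ps frame spacing (default 40 ps).
#' @return a [trajectory3d].
#' @export
make_rotamer_switch_traj <- function(base, res_id, schedule, jitter = 0,
                                     seed = 1, frame_spacing_ps = 40) {
  stopifnot(all(schedule$length >= 1))
  set.seed(as.integer(seed))
  canon <- c(p = 65, t = 180, m = -65)
  frames <- list()
  for (i in seq_len(nrow(schedule))) {
    letters_i <- strsplit(schedule$code[i], "")[[1]]
    if (!all(letters_i %in% names(canon))) stop("bad rotamer code: ",
                                                schedule$code[i])
    target <- canon[letters_i]
    for (k in seq_len(schedule$length[i])) {
      chi <- target + if (jitter > 0) stats::rnorm(length(target), sd = jitter) else 0
      frames[[length(frames) + 1]] <- coords(set_chi(base, res_id, chi))
    }
  }
  trajectory3d(base, frames, frame_spacing_ps)
}

#' Minimal synthetic quinone/copper active-site fixture
#'
#' A toy active site mirroring the arrangement of an LTQ-type amine oxidase:
#' a Cu atom at the origin; three imidazole-like N donors on short stalks
#' filling three basal positions (2.05 angstrom); a water oxygen (Weq)
#' completing the basal square (2.0 angstrom); and a quinone ring whose O4
#' oxoanion sits on the axial (Jahn-Teller) direction at 2.5 angstrom, with
#' a crosslinked lysine-like arm on the ring C2 and a phenyl ring stacked
#' parallel to the quinone. The basal trans angles are built at 174 and 162
#' degrees, so the site's Addison tau is 0.200 by construction.
#'
#' @return a [structure3d] with bond records for the ring and crosslink.
#' @export
make_toy_active_site <- function() {
  rows <- list(); bonds <- list()
  idx <- 0
  add <- function(name, element, res_name, res_id, chain, pos, het = TRUE) {
    idx <<- idx + 1
    rows[[idx]] <<- data.frame(serial = idx, name = name, element = element,
                               res_name = res_name, res_id = as.integer(res_id),
                               chain = chain, insert = "", altloc = "",
                               x = pos[1], y = pos[2], z = pos[3],
                               occupancy = 1, b_factor = 0, het = het)
    idx
  }
  sph <- function(r, polar, azim) {
    r * c(sin(deg2rad(polar)) * cos(deg2rad(azim)),
          sin(deg2rad(polar)) * sin(deg2rad(azim)),
          cos(deg2rad(polar)))
  }
  cu <- add("CU", "CU", "CU", 1, "A", c(0, 0, 0))
  # basal donors: trans pair at polar 93 (angle 174), the other at polar 99
  # (angle 162); tau = (174 - 162)/60 = 0.200
  his_polar <- c(93, 99, 93); his_azim <- c(0, 90, 180)
  for (h in 1:3) {
    n_pos <- sph(2.05, his_polar[h], his_azim[h])
    nd <- add("ND1", "N", "HIS", 10 + h, "A", n_pos, het = FALSE)
    cg <- add("CG", "C", "HIS", 10 + h, "A", n_pos * (2.05 + 1.38) / 2.05,
              het = FALSE)
    bonds[[length(bonds) + 1]] <- c(nd, cg)
  }
  weq <- add("O", "O", "WEQ", 30, "W", sph(2.00, 99, 270))
  # quinone ring: O4 apical at 2.5 A on +z, ring hanging above it
  o4 <- add("O4", "O", "LTQ", 20, "A", c(0, 0, 2.5))
  ring_ctr <- c(0, 0, 2.5 + 1.30)
  ring <- integer(6)
  for (k in 1:6) {
    ang <- deg2rad(60 * (k - 1))
    ring[k] <- add(paste0("C", k), "C", "LTQ", 20, "A",
                   ring_ctr + 1.40 * c(cos(ang), sin(ang), 0))
  }
  # ring bonds C1..C6 cyclic; O4 on C4
  for (k in 1:6) bonds[[length(bonds) + 1]] <- c(ring[k], ring[k %% 6 + 1])
  bonds[[length(bonds) + 1]] <- c(ring[4], o4)
  # crosslinked lysine-like arm on C2: NZ-CE-CD-CG-CB-CA-N chain going away
  arm_dir <- c(cos(deg2rad(60)), sin(deg2rad(60)), 0)
  c2_pos <- ring_ctr + 1.40 * arm_dir
  arm_names <- c("NZ", "CE", "CD", "CG", "CB", "CA", "N")
  arm_el <- c("N", "C", "C", "C", "C", "C", "N")
  prev <- ring[2]
  arm_idx <- integer(0)
  for (k in seq_along(arm_names)) {
    p <- c2_pos + (1.45 * k) * arm_dir + c(0, 0, 0.35 * (k %% 2))
    id <- add(arm_names[k], arm_el[k], "LYS", 40, "A", p, het = FALSE)
    bonds[[length(bonds) + 1]] <- c(prev, id)
    prev <- id
    arm_idx <- c(arm_idx, id)
  }
  # stacked phenyl ring parallel to the quinone, 3.5 A above, small offset
  phe_ctr <- ring_ctr + c(0.8, 0, 3.5)
  phe_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (k in 1:6) {
    ang <- deg2rad(60 * (k - 1) + 30)
    add(phe_names[k], "C", "PHE", 50, "A", phe_ctr + 1.40 * c(cos(ang), sin(ang), 0),
        het = FALSE)
  }
  # distal water, hydrogen-bonded, outside the first shell
  add("O", "O", "WAX", 31, "W", c(0, 0, -3.2))
  structure3d(do.call(rbind, rows), do.call(rbind, bonds),
              "synthetic toy quinone/copper active site")
}
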