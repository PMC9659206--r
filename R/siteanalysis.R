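#' Detect the first coordination sphere of a metal
#'
#' Finds all N, O and S donor atoms within a distance cutoff of a metal atom
#' and records every metal-ligand distance and ligand-metal-ligand angle.
#' The default 2.6 angstrom cutoff covers typical 2.0-2.2 angstrom M-N bonds
#' and an elongated ~2.5 angstrom axial oxygen while excluding second-shell
#' residues at >= 3 angstrom.
#'
#' @param s a [structure3d].
#' @param metal atom index of the metal, or its element symbol (e.g. "CU")
#'   when the structure has exactly one such atom.
#' @param cutoff donor distance cutoff in angstrom (default 2.6).
#' @param donor_elements elements accepted as donors (default N, O, S).
#' @return Object of class `coordination_sphere`: metal index, ligand indices
#'   sorted by distance, `distances` (angstrom), and `lml_angles` (data.frame
#'   of all ligand pairs with their L-M-L angle in degrees).
#' @export
find_coordination_sphere <- function(s, metal, cutoff = 2.6,
                                     donor_elements = c("N", "O", "S")) {
  stopifnot(inherits(s, "structure3d"))
  if (is.character(metal)) {
    hit <- which(toupper(s$atoms$element) == toupper(metal))
    if (length(hit) == 0) stop("no atom of element ", metal)
    if (length(hit) > 1) stop("several atoms of element ", metal,
                              "; pass an atom index")
    metal <- hit
  }
  xyz <- coords(s)
  m <- xyz[metal, ]
  d <- sqrt(rowSums(sweep(xyz, 2, m)^2))
  cand <- which(toupper(s$atoms$element) %in% toupper(donor_elements) &
                  d <= cutoff & seq_len(nrow(xyz)) != metal)
  cand <- cand[order(d[cand])]
  if (!length(cand)) warning("no donor atoms within cutoff: empty coordination sphere")
  ang <- NULL
  if (length(cand) >= 2) {
    pr <- utils::combn(seq_along(cand), 2)
    ang <- data.frame(i = cand[pr[1, ]], j = cand[pr[2, ]],
                      angle = apply(pr, 2, function(p)
                        vec_angle(xyz[cand[p[1]], ], m, xyz[cand[p[2]], ])))
  }
  out <- list(metal = metal, ligands = cand, distances = unname(d[cand]),
              lml_angles = ang, cutoff = cutoff,
              ligand_labels = sprintf("%s%d:%s", s$atoms$res_name[cand],
                                      s$atoms$res_id[cand], s$atoms$name[cand]))
  class(out) <- "coordination_sphere"
  out
}

#' @export
print.coordination_sphere <- function(x, ...) {
  cat(sprintf("coordination_sphere: %d ligands within %.2f A\n",
              length(x$ligands), x$cutoff))
  if (length(x$ligands))
    cat(paste(sprintf("  %-14s %.3f A", x$ligand_labels, x$distances),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Addison parameter (tau) of a 5-coordinate metal site
#'
#' The geometry index tau = (beta - alpha) / 60, where beta >= alpha are the
#' two largest ligand-metal-ligand angles: 0 for an ideal square pyramid
#' (two trans basal angles of 180 degrees), 1 for an ideal trigonal bipyramid
#' (beta = 180 axial, alpha = 120 equatorial). The apical ligand is the one
#' involved in neither beta nor alpha.
#'
#' @param sphere a `coordination_sphere` with exactly 5 ligands.
#' @return Object of class `addison_result`: `tau`, `beta`, `alpha`
#'   (degrees), `apical_ligand` (atom index, NA when every ligand takes part
#'   in beta or alpha), and `label` (`"square-pyramidal"` for tau <= 0.3,
#'   `"trigonal-bipyramidal"` for tau >= 0.7, else `"intermediate"`; the
#'   thresholds are reporting conventions, the numeric tau is authoritative).
#' @export
addison_tau <- function(sphere) {
  stopifnot(inherits(sphere, "coordination_sphere"))
  if (length(sphere$ligands) != 5)
    stop(sprintf("Addison tau is defined for 5-coordination; sphere has %d ligands",
                 length(sphere$ligands)))
  a <- sphere$lml_angles[order(-sphere$lml_angles$angle), ]
  beta <- a$angle[1]; alpha <- a$angle[2]
  involved <- unique(c(a$i[1:2], a$j[1:2]))
  apical <- setdiff(sphere$ligands, involved)
  out <- list(tau = (beta - alpha) / 60, beta = beta, alpha = alpha,
              apical_ligand = if (length(apical) == 1) apical else NA_integer_,
              label = if ((beta - alpha) / 60 <= 0.3) "square-pyramidal"
                      else if ((beta - alpha) / 60 >= 0.7) "trigonal-bipyramidal"
                      else "intermediate")
  class(out) <- "addison_result"
  out
}

#' @export
print.addison_result <- function(x, ...) {
  cat(sprintf("Addison tau = %.3f (beta = %.1f, alpha = %.1f): %s\n",
              x$tau, x$beta, x$alpha, x$label))
  invisible(x)
}

#' Jahn-Teller axis of a coordination sphere
#'
#' Identifies the elongated metal-ligand direction of a (d9 Cu2+-like)
#' complex as the longest first-shell bond, and reports its excess over the
#' mean of the remaining bond lengths.
#'
#' @param sphere a `coordination_sphere` with >= 4 ligands.
#' @param min_elongation excess (angstrom) below which the site is flagged
#'   as having no resolved elongation (default 0.05).
#' @return list with `ligand` (atom index), `distance`, `elongation`
#'   (angstrom over the mean of the others) and `elongated` (logical).
#' @export
jahn_teller_axis <- function(sphere, min_elongation = 0.05) {
  stopifnot(inherits(sphere, "coordination_sphere"))
  if (length(sphere$ligands) < 4) stop("need at least 4 ligands")
  k <- which.max(sphere$distances)
  excess <- sphere$distances[k] - mean(sphere$distances[-k])
  list(ligand = sphere$ligands[k], distance = sphere$distances[k],
       elongation = excess, elongated = excess > min_elongation)
}

# side-chain torsion ladder shared by chi extraction and rebuilding;
# lysine-type chain N-CA-CB-CG-CD-CE-NZ (native or LTQ-crosslinked)
chi_ladder <- function(names_present) {
  quads <- list(c("N", "CA", "CB", "CG"),
                c("CA", "CB", "CG", "CD"),
                c("CB", "CG", "CD", "CE"),
                c("CG", "CD", "CE", "NZ"))
  keep <- vapply(quads, function(q) all(q %in% names_present), logical(1))
  # truncate at the first missing quadruple
  if (any(!keep)) keep[seq_along(keep) >= which(!keep)[1]] <- FALSE
  quads[keep]
}

#' Side-chain chi angles of a lysine-like residue
#'
#' Computes chi1..chi4 from the atom quadruples N-CA-CB-CG, CA-CB-CG-CD,
#' CB-CG-CD-CE and CG-CD-CE-NZ. Missing atoms truncate the list, so a
#' residue lacking CE yields only chi1 and chi2.
#'
#' @param s a [structure3d].
#' @param res_id residue number.
#' @param chain optional chain id to disambiguate.
#' @return numeric vector of chi angles in degrees (possibly length < 4).
#' @export
chi_angles <- function(s, res_id, chain = NULL) {
  a <- s$atoms
  in_res <- a$res_id == res_id & (if (is.null(chain)) TRUE else a$chain == chain)
  quads <- chi_ladder(a$name[in_res])
  if (!length(quads)) return(numeric(0))
  vapply(quads, function(q) {
    p <- lapply(q, function(nm) atom_xyz(s, res_id, nm, chain))
    vec_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
  }, numeric(1))
}

#' Classify a rotamer by nearest canonical chi values
#'
#' Each chi angle maps to the nearest of the three canonical staggered values
#' p = +65, t = 180, m = -65 degrees under circular distance, following the
#' penultimate rotamer library lettering. A state more than `distorted_above`
#' degrees from its nearest canonical value in any chi is flagged distorted.
#'
#' @param chi numeric vector of chi angles, degrees.
#' @param distorted_above deviation (degrees) above which the state is
#'   flagged distorted (default 40).
#' @return Object of class `rotamer_state`: `chi`, `code` (string over
#'   p/t/m), `max_deviation` (degrees) and `distorted` (logical).
#' @export
classify_rotamer <- function(chi, distorted_above = 40) {
  stopifnot(length(chi) >= 1, all(is.finite(chi)))
  canon <- c(p = 65, t = 180, m = -65)
  dev <- vapply(chi, function(x) circ_diff(x, canon), numeric(3))
  pick <- apply(dev, 2, which.min)
  out <- list(chi = chi,
              code = paste(names(canon)[pick], collapse = ""),
              max_deviation = max(dev[cbind(pick, seq_along(chi))]))
  out$distorted <- out$max_deviation > distorted_above
  class(out) <- "rotamer_state"
  out
}

#' @export
print.rotamer_state <- function(x, ...) {
  cat(sprintf("rotamer %s%s (max deviation %.1f deg): chi = %s\n", x$code,
              if (x$distorted) " [distorted]" else "", x$max_deviation,
              paste(sprintf("%.1f", x$chi), collapse = ", ")))
  invisible(x)
}

# ring atom names by residue type; quinone cofactor rings use C1..C6
ring_atom_names <- function(res_name) {
  switch(toupper(res_name),
         PHE = , TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
         HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
         TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
         LTQ = , TPQ = , DPQ = c("C1", "C2", "C3", "C4", "C5", "C6"),
         NULL)
}

#' Aromatic (or quinone) ring stacking geometry between two residues
#'
#' Computes ring centroid distance, interplanar angle from the least-squares
#' ring normals, and the in-plane centroid offset. The pair is called stacked
#' when distance <= `max_distance` and angle <= `max_angle`.
#'
#' @param s a [structure3d].
#' @param res_a,res_b residue numbers of the two ring systems.
#' @param ring_atoms_a,ring_atoms_b optional explicit ring atom names;
#'   by default looked up from the residue name (PHE/TYR/HIS/TRP and the
#'   quinone cofactors LTQ/TPQ/DPQ with ring atoms C1..C6).
#' @param max_distance,max_angle stacking thresholds, 5.5 angstrom and
#'   30 degrees by default.
#' @return Object of class `stacking_contact`: `centroid_distance` (angstrom),
#'   `interplanar_angle` (degrees, folded into \[0, 90\]), `offset` (angstrom,
#'   displacement of centroid b in the plane of ring a) and `is_stacked`.
#' @export
pi_stacking <- function(s, res_a, res_b, ring_atoms_a = NULL, ring_atoms_b = NULL,
                        max_distance = 5.5, max_angle = 30) {
  get_ring <- function(res_id, names_override) {
    rn <- unique(s$atoms$res_name[s$atoms$res_id == res_id])
    nms <- if (!is.null(names_override)) names_override else ring_atom_names(rn[1])
    if (is.null(nms)) stop(sprintf("residue %d (%s) has no known ring", res_id, rn[1]))
    t(vapply(nms, function(n) atom_xyz(s, res_id, n), numeric(3)))
  }
  ra <- get_ring(res_a, ring_atoms_a); rb <- get_ring(res_b, ring_atoms_b)
  pa <- fit_plane(ra); pb <- fit_plane(rb)
  dvec <- pb$centroid - pa$centroid
  ang <- vec_angle(pa$normal, c(0, 0, 0), pb$normal)
  if (ang > 90) ang <- 180 - ang
  perp <- abs(sum(dvec * pa$normal))
  dist <- sqrt(sum(dvec^2))
  out <- list(centroid_distance = dist,
              interplanar_angle = ang,
              offset = sqrt(max(0, dist^2 - perp^2)),
              is_stacked = dist <= max_distance && ang <= max_angle)
  class(out) <- "stacking_contact"
  out
}

#' @export
print.stacking_contact <- function(x, ...) {
  cat(sprintf("ring contact: centroids %.2f A, interplanar %.1f deg, offset %.2f A -> %s\n",
              x$centroid_distance, x$interplanar_angle, x$offset,
              if (x$is_stacked) "stacked" else "not stacked"))
  invisible(x)
}

# Bondi (1964) van der Waals radii, angstrom
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, CU = 1.40, ZN = 1.39, FE = 1.40)

#' Van der Waals contacts between two residues
#'
#' Lists atom pairs whose separation is within `tolerance` of the sum of
#' their Bondi van der Waals radii (gap = distance - r_a - r_b <= tolerance).
#' Hydrogens are excluded by default.
#'
#' @param s a [structure3d].
#' @param res_a,res_b residue numbers.
#' @param tolerance maximum gap in angstrom (default 0.5).
#' @param include_hydrogens include H atoms (default FALSE).
#' @return data.frame of contacts sorted by gap: atom names, indices,
#'   `distance` and `gap` (angstrom).
#' @export
vdw_contacts <- function(s, res_a, res_b, tolerance = 0.5,
                         include_hydrogens = FALSE) {
  a <- s$atoms
  pick <- function(res_id) {
    i <- which(a$res_id == res_id)
    if (!length(i)) stop("residue ", res_id, " not found")
    if (!include_hydrogens) i <- i[toupper(a$element[i]) != "H"]
    i
  }
  ia <- pick(res_a); ib <- pick(res_b)
  xyz <- coords(s)
  grid <- expand.grid(i = ia, j = ib)
  grid$distance <- sqrt(rowSums((xyz[grid$i, , drop = FALSE] -
                                   xyz[grid$j, , drop = FALSE])^2))
  ra <- vdw_radii[toupper(a$element[grid$i])]
  rb <- vdw_radii[toupper(a$element[grid$j])]
  ra[is.na(ra)] <- 1.7; rb[is.na(rb)] <- 1.7   # unknown elements: carbon-like
  grid$gap <- grid$distance - (ra + rb)
  out <- grid[grid$gap <= tolerance, , drop = FALSE]
  out <- out[order(out$gap), , drop = FALSE]
  data.frame(atom_a = a$name[out$i], atom_b = a$name[out$j],
             i = out$i, j = out$j, distance = out$distance, gap = out$gap,
             row.names = NULL)
}

#' Side-chain separation report between two residues
#'
#' Distance report for a residue pair whose functional-group separation is of
#' interest (e.g. the precursor lysine and tyrosine of an LTQ site): the
#' Nzeta-OH distance where those atoms exist, the Nzeta-to-ring-carbon
#' distance, and the minimum side-chain to side-chain heavy-atom distance.
#'
#' @param s a [structure3d].
#' @param lys_res,tyr_res residue numbers of the lysine-like and
#'   tyrosine/quinone-like residue.
#' @return data.frame with one row per available measure (`measure`,
#'   `distance` in angstrom).
#' @export
residue_separation <- function(s, lys_res, tyr_res) {
  a <- s$atoms
  side <- function(res_id) {
    i <- which(a$res_id == res_id &
                 !(a$name %in% c("N", "CA", "C", "O", "OXT")) &
                 toupper(a$element) != "H")
    if (!length(i)) stop("residue ", res_id, " has no side-chain atoms")
    i
  }
  xyz <- coords(s)
  rows <- list()
  has <- function(res_id, nm) any(a$res_id == res_id & a$name == nm)
  if (has(lys_res, "NZ") && has(tyr_res, "OH"))
    rows$nz_oh <- c("NZ-OH", vec_distance(atom_xyz(s, lys_res, "NZ"),
                                          atom_xyz(s, tyr_res, "OH")))
  ring <- ring_atom_names(a$res_name[match(tyr_res, a$res_id)])
  ring <- ring[vapply(ring, function(n) has(tyr_res, n), logical(1))]
  if (has(lys_res, "NZ") && length(ring)) {
    nz <- atom_xyz(s, lys_res, "NZ")
    d <- vapply(ring, function(n) vec_distance(nz, atom_xyz(s, tyr_res, n)),
                numeric(1))
    rows$nz_ring <- c(sprintf("NZ-%s(ring)", names(which.min(d))), min(d))
  }
  ia <- side(lys_res); ib <- side(tyr_res)
  dd <- as.matrix(stats::dist(xyz[c(ia, ib), ]))[seq_along(ia),
                                                 length(ia) + seq_along(ib)]
  rows$min_side <- c("min side-side", min(dd))
  data.frame(measure = vapply(rows, `[`, character(1), 1),
             distance = as.numeric(vapply(rows, `[`, character(1), 2)),
             row.names = NULL)
}
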