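#' Extract backbone and side-chain dihedrals of a segment
#'
#' For each residue in the range, phi (C- N CA C), psi (N CA C N+) and omega
#' (CA- C- N CA) are computed from the standard quadruples; the first residue
#' of a chain has no phi/omega and the last no psi (reported as NA). The
#' side-chain chi list is computed with [chi_angles()] (lysine-type ladder,
#' truncated at the first missing atom).
#'
#' @param s a [structure3d].
#' @param chain chain identifier.
#' @param res_range integer vector of residue numbers (contiguous).
#' @return Object of class `segment_dihedrals`: data.frame `backbone`
#'   (res_id, phi, psi, omega in degrees) and list `chi` keyed by residue.
#' @export
extract_segment_dihedrals <- function(s, chain, res_range) {
  res_range <- sort(as.integer(res_range))
  if (!all(diff(res_range) == 1)) stop("res_range must be contiguous")
  bb <- function(res_id, nm) {
    i <- which(s$atoms$chain == chain & s$atoms$res_id == res_id &
                 s$atoms$name == nm)
    if (length(i) != 1) return(NULL)
    unlist(s$atoms[i, c("x", "y", "z")], use.names = FALSE)
  }
  for (r in res_range) {
    for (nm in c("N", "CA", "C")) {
      if (is.null(bb(r, nm)))
        stop(sprintf("residue %d is missing backbone atom %s", r, nm))
    }
  }
  rows <- lapply(res_range, function(r) {
    phi <- psi <- omega <- NA_real_
    if (!is.null(bb(r - 1, "C")))
      phi <- vec_dihedral(bb(r - 1, "C"), bb(r, "N"), bb(r, "CA"), bb(r, "C"))
    if (!is.null(bb(r + 1, "N")))
      psi <- vec_dihedral(bb(r, "N"), bb(r, "CA"), bb(r, "C"), bb(r + 1, "N"))
    if (!is.null(bb(r - 1, "CA")))
      omega <- vec_dihedral(bb(r - 1, "CA"), bb(r - 1, "C"), bb(r, "N"), bb(r, "CA"))
    data.frame(res_id = r, phi = phi, psi = psi, omega = omega)
  })
  chi <- lapply(res_range, function(r) {
    tryCatch(chi_angles(s, r, chain), error = function(e) numeric(0))
  })
  names(chi) <- res_range
  out <- list(backbone = do.call(rbind, rows), chi = chi)
  class(out) <- "segment_dihedrals"
  out
}

#' @export
print.segment_dihedrals <- function(x, ...) {
  cat("segment_dihedrals:\n")
  print(x$backbone, row.names = FALSE)
  invisible(x)
}

# residue ordering key within a chain (file order of first atom)
residue_order <- function(s, chain) {
  a <- s$atoms
  idx <- which(a$chain == chain)
  unique(a$res_id[idx])
}

# atoms "downstream" of a backbone torsion, assuming atoms are stored in
# chain order. For rotation about bond (p, q) the moving set contains all
# atoms reached from q without passing back through p, approximated here by
# chain position (valid for linear peptide backbones):
#   omega_i (C[i-1]-N[i]):  all atoms of residues >= i
#   phi_i   (N[i]-CA[i]):   residue-i atoms except N (+H), plus residues > i
#   psi_i   (CA[i]-C[i]):   O/OXT of residue i, plus residues > i
downstream_set <- function(s, chain, res_id, which_angle) {
  a <- s$atoms
  on_chain <- a$chain == chain
  later <- on_chain & a$res_id > res_id
  this <- on_chain & a$res_id == res_id
  keep <- switch(which_angle,
    omega = this | later,
    phi = (this & !(a$name %in% c("N", "H", "H1", "H2", "H3"))) | later,
    psi = (this & a$name %in% c("O", "OXT")) | later)
  which(keep)
}

# rotate the structure so the torsion defined by quadruple coordinates
# becomes `target`; `moving` indexes atoms carried by the rotation
set_torsion <- function(s, p1, p2, p3, p4, target, moving, anchor = "upstream") {
  cur <- vec_dihedral(p1, p2, p3, p4)
  delta <- wrap180(target - cur)
  if (abs(delta) < 1e-12) return(s)
  xyz <- coords(s)
  # right-handed rotation of the downstream set about p2->p3 increases the
  # torsion under the standard sign convention
  if (anchor == "upstream") {
    xyz[moving, ] <- rotate_points(xyz[moving, , drop = FALSE], p2, p3 - p2, delta)
  } else {
    still <- setdiff(seq_len(nrow(xyz)), moving)
    xyz[still, ] <- rotate_points(xyz[still, , drop = FALSE], p2, p3 - p2, -delta)
  }
  set_coords(s, xyz)
}

#' Transplant segment dihedrals with torsion-only rebuilding
#'
#' Sets the backbone phi/psi/omega (and, where provided, side-chain chi) of a
#' residue range to the values of a template [segment_dihedrals], by rotating
#' about each backbone bond in turn. Bond lengths and bond angles are
#' untouched: only torsions move. With the default `anchor = "upstream"` the
#' N-terminal side of the segment stays bitwise fixed and atoms distal to the
#' segment ride rigidly with the last rebuilt peptide frame, matching the
#' remodelling of a short internal strand while the rest of the fold stays
#' put; `anchor = "downstream"` fixes the C-terminal side instead.
#'
#' Omega values absent from the template are set to trans (180 degrees), so a
#' template with missing omegas cannot introduce accidental cis peptides.
#'
#' @param target a [structure3d].
#' @param chain chain identifier.
#' @param res_range contiguous residue numbers to rebuild.
#' @param dihedrals a `segment_dihedrals` covering `res_range` (matched
#'   positionally, so a template segment from another protein applies).
#' @param anchor `"upstream"` (default) or `"downstream"`.
#' @param apply_chi also set side-chain chi where the template provides them
#'   (default TRUE).
#' @return the rebuilt [structure3d].
#' @export
transplant_segment_dihedrals <- function(target, chain, res_range, dihedrals,
                                         anchor = c("upstream", "downstream"),
                                         apply_chi = TRUE) {
  anchor <- match.arg(anchor)
  res_range <- sort(as.integer(res_range))
  stopifnot(inherits(dihedrals, "segment_dihedrals"))
  if (nrow(dihedrals$backbone) != length(res_range))
    stop("dihedrals do not cover res_range")
  a <- target$atoms
  # chain-break check: consecutive C-N distances inside the segment
  for (k in seq_len(length(res_range) - 1)) {
    d <- vec_distance(atom_xyz(target, res_range[k], "C", chain),
                      atom_xyz(target, res_range[k + 1], "N", chain))
    if (d > 2.5)
      stop(sprintf("chain break between residues %d and %d (C-N %.2f A)",
                   res_range[k], res_range[k + 1], d))
  }
  s <- target
  order_res <- if (anchor == "upstream") seq_along(res_range) else rev(seq_along(res_range))
  for (k in order_res) {
    r <- res_range[k]
    tmpl <- dihedrals$backbone[k, ]
    g <- function(res_id, nm) atom_xyz(s, res_id, nm, chain)
    has <- function(res_id, nm) {
      any(s$atoms$chain == chain & s$atoms$res_id == res_id & s$atoms$name == nm)
    }
    omega <- if (is.na(tmpl$omega)) 180 else tmpl$omega
    if (has(r - 1, "C") && has(r - 1, "CA")) {
      s <- set_torsion(s, g(r - 1, "CA"), g(r - 1, "C"), g(r, "N"), g(r, "CA"),
                       omega, downstream_set(s, chain, r, "omega"), anchor)
      if (!is.na(tmpl$phi))
        s <- set_torsion(s, g(r - 1, "C"), g(r, "N"), g(r, "CA"), g(r, "C"),
                         tmpl$phi, downstream_set(s, chain, r, "phi"), anchor)
    }
    if (!is.na(tmpl$psi) && has(r + 1, "N"))
      s <- set_torsion(s, g(r, "N"), g(r, "CA"), g(r, "C"), g(r + 1, "N"),
                       tmpl$psi, downstream_set(s, chain, r, "psi"), anchor)
    if (apply_chi && length(dihedrals$chi[[k]]))
      s <- set_chi(s, r, dihedrals$chi[[k]], chain)
  }
  s
}

#' Set side-chain chi angles of a lysine-like residue
#'
#' Rotates the side chain about each chi bond so the torsions take the
#' requested values; atoms distal to each bond (by the N-CA-CB-CG-CD-CE-NZ
#' ladder) move, the backbone does not.
#'
#' @param s a [structure3d].
#' @param res_id residue number.
#' @param chi target chi angles in degrees (length up to 4; only as many as
#'   the residue defines are applied).
#' @param chain optional chain id.
#' @return the updated structure.
#' @export
set_chi <- function(s, res_id, chi, chain = NULL) {
  in_res <- s$atoms$res_id == res_id &
    (if (is.null(chain)) TRUE else s$atoms$chain == chain)
  quads <- chi_ladder(s$atoms$name[in_res])
  n <- min(length(quads), length(chi))
  ladder <- c("CB", "CG", "CD", "CE", "NZ")
  for (k in seq_len(n)) {
    q <- quads[[k]]
    p <- lapply(q, function(nm) atom_xyz(s, res_id, nm, chain))
    distal <- ladder[seq_along(ladder) > k]           # atoms beyond the bond
    moving <- which(in_res & s$atoms$name %in% distal)
    # crosslinked partners hanging off NZ would need graph traversal; side
    # chains handled here end at NZ
    s <- set_torsion(s, p[[1]], p[[2]], p[[3]], p[[4]], chi[k], moving)
  }
  s
}

#' Graft a side-chain template onto a residue
#'
#' Rigidly superposes a template residue onto the target residue using >= 3
#' shared frame atoms (default N, CA, CB), then replaces the target's side
#' chain with the transformed template side chain. The target backbone
#' (N, CA, C, O) is untouched; the residue is renamed to the template's
#' residue name. This is how a quinone cofactor side chain observed in one
#' structure is transplanted onto a tyrosine of another.
#'
#' @param s a [structure3d].
#' @param res_id target residue number.
#' @param template a [structure3d] holding one residue.
#' @param frame_atoms atom names shared by target and template used for the
#'   rigid fit (default `c("N", "CA", "CB")`).
#' @return the edited [structure3d].
#' @export
graft_sidechain_template <- function(s, res_id, template,
                                     frame_atoms = c("N", "CA", "CB")) {
  if (length(frame_atoms) < 3) stop("need at least 3 frame atoms")
  t_res <- template$atoms$res_id[1]
  for (nm in frame_atoms) {
    if (!any(s$atoms$res_id == res_id & s$atoms$name == nm))
      stop(sprintf("target residue %d lacks frame atom %s", res_id, nm))
    if (!any(template$atoms$res_id == t_res & template$atoms$name == nm))
      stop(sprintf("template lacks frame atom %s", nm))
  }
  tgt_frame <- t(vapply(frame_atoms, function(nm) atom_xyz(s, res_id, nm), numeric(3)))
  tpl_frame <- t(vapply(frame_atoms, function(nm) atom_xyz(template, t_res, nm),
                        numeric(3)))
  sup <- superpose(tpl_frame, tgt_frame)
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA")
  keep <- !(s$atoms$res_id == res_id & !(s$atoms$name %in% backbone))
  atoms <- s$atoms[keep, , drop = FALSE]
  side <- template$atoms[!(template$atoms$name %in% backbone), , drop = FALSE]
  if (nrow(side)) {
    side_xyz <- apply_superposition(as.matrix(side[, c("x", "y", "z")]), sup)
    side$x <- side_xyz[, 1]; side$y <- side_xyz[, 2]; side$z <- side_xyz[, 3]
    side$res_id <- res_id
    side$chain <- atoms$chain[match(res_id, atoms$res_id)]
    side$serial <- max(atoms$serial) + seq_len(nrow(side))
    at_res <- which(atoms$res_id == res_id)
    insert_at <- max(at_res)
    atoms <- rbind(atoms[seq_len(insert_at), ], side,
                   if (insert_at < nrow(atoms)) atoms[(insert_at + 1):nrow(atoms), ])
  }
  atoms$res_name[atoms$res_id == res_id] <- template$atoms$res_name[1]
  # bonds cannot be carried across the index change; rebuild from scratch if
  # the caller tracked them
  structure3d(atoms, NULL, s$title)
}

# ---------------------------------------------------------------------------
# Cofactor patches: declarative graph edits (delete/add atoms, bonds, rename)

#' Construct a cofactor patch
#'
#' A patch is a declarative molecular-graph edit: atoms to delete, atoms to
#' add (each with an internal-coordinate or absolute placement rule), bonds
#' to add or delete, and residue renames. Applying a patch changes atom and
#' bond counts by exactly the patch sizes; [invert_patch()] builds the patch
#' that undoes it.
#'
#' @param atoms_deleted data.frame(res_id, name).
#' @param atoms_added data.frame with columns res_id, name, element and a
#'   placement rule: either `x`,`y`,`z` (absolute) or `ref1`,`ref2`,`ref3`
#'   ("res:name" strings), `bond_length`, `bond_angle`, `dihedral`
#'   (internal coordinates, NeRF placement).
#' @param bonds_added,bonds_deleted data.frame(a, b) of "res:name" atom refs.
#' @param renames data.frame(res_id, new_name) residue renames.
#' @return object of class `cofactor_patch`.
#' @export
cofactor_patch <- function(atoms_deleted = NULL, atoms_added = NULL,
                           bonds_added = NULL, bonds_deleted = NULL,
                           renames = NULL) {
  out <- list(atoms_deleted = atoms_deleted, atoms_added = atoms_added,
              bonds_added = bonds_added, bonds_deleted = bonds_deleted,
              renames = renames)
  class(out) <- "cofactor_patch"
  out
}

#' @export
print.cofactor_patch <- function(x, ...) {
  nr <- function(d) if (is.null(d)) 0 else nrow(d)
  cat(sprintf("cofactor_patch: -%d atoms, +%d atoms, -%d bonds, +%d bonds, %d renames\n",
              nr(x$atoms_deleted), nr(x$atoms_added), nr(x$bonds_deleted),
              nr(x$bonds_added), nr(x$renames)))
  invisible(x)
}

parse_atom_ref <- function(ref, s) {
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("bad atom reference: ", ref)
  atom_index(s, as.integer(parts[1]), parts[2])
}

#' Apply a cofactor patch to a structure
#'
#' Deletions are checked against the bond graph: a bond left dangling (one
#' endpoint deleted without the bond being listed in `bonds_deleted`) is an
#' error. Added atoms are placed by their rule; added bonds connect existing
#' or added atoms.
#'
#' @param s a [structure3d].
#' @param patch a [cofactor_patch].
#' @return the edited [structure3d].
#' @export
apply_patch <- function(s, patch) {
  stopifnot(inherits(patch, "cofactor_patch"))
  a <- s$atoms
  del_idx <- integer(0)
  if (!is.null(patch$atoms_deleted) && nrow(patch$atoms_deleted)) {
    del_idx <- vapply(seq_len(nrow(patch$atoms_deleted)), function(i)
      atom_index(s, patch$atoms_deleted$res_id[i], patch$atoms_deleted$name[i]),
      integer(1))
  }
  # delete listed bonds first, then check for dangling ones
  bonds <- s$bonds
  ref_label <- function(i) sprintf("%d:%s", a$res_id[i], a$name[i])
  if (!is.null(patch$bonds_deleted) && nrow(patch$bonds_deleted)) {
    for (i in seq_len(nrow(patch$bonds_deleted))) {
      bi <- parse_atom_ref(patch$bonds_deleted$a[i], s)
      bj <- parse_atom_ref(patch$bonds_deleted$b[i], s)
      hit <- which((bonds[, 1] == min(bi, bj)) & (bonds[, 2] == max(bi, bj)))
      if (!length(hit)) stop(sprintf("bond %s-%s not present",
                                     ref_label(bi), ref_label(bj)))
      bonds <- bonds[-hit, , drop = FALSE]
    }
  }
  if (length(del_idx) && nrow(bonds)) {
    dangling <- which((bonds[, 1] %in% del_idx) != (bonds[, 2] %in% del_idx))
    if (length(dangling))
      stop("deletion leaves dangling bond(s): ",
           paste(sprintf("%s-%s", vapply(bonds[dangling, 1], ref_label, character(1)),
                         vapply(bonds[dangling, 2], ref_label, character(1))),
                 collapse = ", "))
    both <- which((bonds[, 1] %in% del_idx) & (bonds[, 2] %in% del_idx))
    if (length(both)) bonds <- bonds[-both, , drop = FALSE]
  }
  # remap and delete atoms
  if (length(del_idx)) {
    keep <- setdiff(seq_len(nrow(a)), del_idx)
    remap <- match(seq_len(nrow(a)), keep)
    if (nrow(bonds)) bonds <- cbind(remap[bonds[, 1]], remap[bonds[, 2]])
    a <- a[keep, , drop = FALSE]
    rownames(a) <- NULL
  }
  s2 <- structure3d(a, bonds, s$title)
  # add atoms
  if (!is.null(patch$atoms_added) && nrow(patch$atoms_added)) {
    add <- patch$atoms_added
    for (i in seq_len(nrow(add))) {
      if (!is.null(add$x) && is.finite(add$x[i])) {
        pos <- c(add$x[i], add$y[i], add$z[i])
      } else {
        p1 <- coords(s2)[parse_atom_ref(add$ref1[i], s2), ]
        p2 <- coords(s2)[parse_atom_ref(add$ref2[i], s2), ]
        p3 <- coords(s2)[parse_atom_ref(add$ref3[i], s2), ]
        pos <- place_atom(p3, p2, p1, add$bond_length[i], add$bond_angle[i],
                          add$dihedral[i])
      }
      at <- s2$atoms
      row <- data.frame(serial = max(at$serial, 0) + 1L, name = add$name[i],
                        element = add$element[i], res_name = at$res_name[
                          match(add$res_id[i], at$res_id)],
                        res_id = as.integer(add$res_id[i]),
                        chain = at$chain[match(add$res_id[i], at$res_id)],
                        insert = "", altloc = "", x = pos[1], y = pos[2],
                        z = pos[3], occupancy = 1, b_factor = 0, het = TRUE)
      if (is.na(row$res_name)) { row$res_name <- "UNK"; row$chain <- "A" }
      s2 <- structure3d(rbind(at, row), s2$bonds, s2$title)
    }
  }
  # add bonds
  if (!is.null(patch$bonds_added) && nrow(patch$bonds_added)) {
    nb <- t(vapply(seq_len(nrow(patch$bonds_added)), function(i)
      c(parse_atom_ref(patch$bonds_added$a[i], s2),
        parse_atom_ref(patch$bonds_added$b[i], s2)), integer(2)))
    s2$bonds <- normalize_bonds(rbind(s2$bonds, nb))
  }
  if (!is.null(patch$renames) && nrow(patch$renames)) {
    for (i in seq_len(nrow(patch$renames)))
      s2$atoms$res_name[s2$atoms$res_id == patch$renames$res_id[i]] <-
        patch$renames$new_name[i]
  }
  s2
}

#' Invert a cofactor patch
#'
#' Builds the patch that undoes `patch` on the structure it was applied to:
#' added atoms become deletions, deleted atoms are re-added at their original
#' coordinates (recorded from `s_before`), bond edits swap roles, renames
#' revert. `apply_patch(apply_patch(s, p), invert_patch(p, s))` restores the
#' original atom set and bond graph.
#'
#' @param patch a [cofactor_patch].
#' @param s_before the structure the patch was (or will be) applied to.
#' @return the inverse [cofactor_patch].
#' @export
invert_patch <- function(patch, s_before) {
  inv_del <- NULL
  if (!is.null(patch$atoms_added) && nrow(patch$atoms_added))
    inv_del <- patch$atoms_added[, c("res_id", "name")]
  inv_add <- NULL
  if (!is.null(patch$atoms_deleted) && nrow(patch$atoms_deleted)) {
    inv_add <- do.call(rbind, lapply(seq_len(nrow(patch$atoms_deleted)), function(i) {
      idx <- atom_index(s_before, patch$atoms_deleted$res_id[i],
                        patch$atoms_deleted$name[i])
      s_before$atoms[idx, c("res_id", "name", "element", "x", "y", "z")]
    }))
    # restore bonds removed implicitly (both endpoints deleted) or explicitly
  }
  # bonds lost by the patch: explicit deletions plus bonds among deleted atoms
  lost <- patch$bonds_deleted
  if (!is.null(patch$atoms_deleted) && nrow(patch$atoms_deleted) &&
      nrow(s_before$bonds)) {
    del_idx <- vapply(seq_len(nrow(patch$atoms_deleted)), function(i)
      atom_index(s_before, patch$atoms_deleted$res_id[i],
                 patch$atoms_deleted$name[i]), integer(1))
    b <- s_before$bonds
    both <- which((b[, 1] %in% del_idx) & (b[, 2] %in% del_idx))
    if (length(both)) {
      lab <- function(i) sprintf("%d:%s", s_before$atoms$res_id[i],
                                 s_before$atoms$name[i])
      lost <- rbind(lost, data.frame(a = vapply(b[both, 1], lab, character(1)),
                                     b = vapply(b[both, 2], lab, character(1))))
    }
  }
  inv_ren <- NULL
  if (!is.null(patch$renames) && nrow(patch$renames)) {
    inv_ren <- data.frame(res_id = patch$renames$res_id,
                          new_name = vapply(patch$renames$res_id, function(r)
                            s_before$atoms$res_name[match(r, s_before$atoms$res_id)],
                            character(1)))
  }
  cofactor_patch(atoms_deleted = inv_del, atoms_added = inv_add,
                 bonds_added = lost, bonds_deleted = patch$bonds_added,
                 renames = inv_ren)
}

#' Swap a metal atom for another element
#'
#' Replaces the element (and atom name, when it equalled the element symbol)
#' of the unique atom of `from_element`, keeping its coordinates. With more
#' than one such atom, `site` (an atom index) must identify which.
#'
#' @param s a [structure3d].
#' @param from_element,to_element element symbols, e.g. `"ZN"`, `"CU"`.
#' @param site optional atom index when several atoms of `from_element` exist.
#' @return the edited [structure3d].
#' @export
swap_metal <- function(s, from_element, to_element, site = NULL) {
  hit <- which(toupper(s$atoms$element) == toupper(from_element))
  if (!length(hit)) stop("no ", from_element, " atom present")
  if (length(hit) > 1) {
    if (is.null(site)) stop("several ", from_element,
                            " atoms present; specify `site`")
    if (!site %in% hit) stop("`site` is not a ", from_element, " atom")
    hit <- site
  }
  up <- toupper(to_element)
  if (s$atoms$name[hit] == toupper(from_element) ||
      s$atoms$name[hit] == s$atoms$element[hit]) s$atoms$name[hit] <- up
  if (s$atoms$res_name[hit] == toupper(from_element)) s$atoms$res_name[hit] <- up
  s$atoms$element[hit] <- up
  s
}

#' Place equatorial and axial coordination waters
#'
#' Completes a square-pyramidal metal coordination from three basal donors:
#' a water oxygen Weq is placed in the basal least-squares plane, trans to
#' the mean donor direction (filling the open basal position), and Wax along
#' the basal-plane normal. The axial bond is longer than the equatorial one
#' by default (2.40 vs 2.00 angstrom), reflecting the elongated axis of a
#' d9 metal. Optionally hydrogens are added with metal-O-H angles of 120
#' degrees.
#'
#' @param s a [structure3d].
#' @param metal atom index of the metal (or element symbol if unique).
#' @param basal_ligands atom indices of >= 3 basal donors.
#' @param axial_direction optional 3-vector picking the axial side; by
#'   default the side with more room (larger clearance to existing atoms).
#' @param d_eq,d_ax metal-O distances, angstrom (defaults 2.00 and 2.40).
#' @param hydrogens add water hydrogens (default FALSE).
#' @return the structure with residues `HOH` named `WEQ`/`WAX` appended.
#' @export
place_coordination_waters <- function(s, metal, basal_ligands,
                                      axial_direction = NULL,
                                      d_eq = 2.0, d_ax = 2.4,
                                      hydrogens = FALSE) {
  if (is.character(metal)) {
    hit <- which(toupper(s$atoms$element) == toupper(metal))
    if (length(hit) != 1) stop("metal element must match exactly one atom")
    metal <- hit
  }
  if (length(basal_ligands) < 3) stop("need at least 3 basal donors")
  xyz <- coords(s)
  m <- xyz[metal, ]
  donors <- xyz[basal_ligands, , drop = FALSE]
  dirs <- sweep(donors, 2, m)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pl <- fit_plane(donors)
  n <- pl$normal
  # gap direction: opposite the mean donor direction, projected into the plane
  gap <- -colSums(dirs)
  gap <- gap - sum(gap * n) * n
  if (sqrt(sum(gap^2)) < 1e-8)
    stop("no resolvable basal-plane gap (donors symmetric about the metal)")
  gap <- gap / sqrt(sum(gap^2))
  weq <- m + d_eq * gap
  # axial side: given direction, or the freer side
  if (!is.null(axial_direction)) {
    ax <- if (sum(axial_direction * n) >= 0) n else -n
  } else {
    clearance <- function(p) min(sqrt(rowSums(sweep(xyz, 2, p)^2)))
    ax <- if (clearance(m + d_ax * n) >= clearance(m - d_ax * n)) n else -n
  }
  wax <- m + d_ax * ax
  mk_water <- function(res_name, o_pos) {
    res_id <- max(s$atoms$res_id) + if (res_name == "WEQ") 1L else 2L
    rows <- data.frame(serial = 0L, name = "O", element = "O",
                       res_name = res_name, res_id = res_id, chain = "W",
                       insert = "", altloc = "", x = o_pos[1], y = o_pos[2],
                       z = o_pos[3], occupancy = 1, b_factor = 0, het = TRUE)
    if (hydrogens) {
      u <- (o_pos - m) / sqrt(sum((o_pos - m)^2))
      v <- cross3(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
      v <- v / sqrt(sum(v^2))
      # metal-O-H of 120 deg: H direction at 60 deg from the outward radius
      for (k in 1:2) {
        hdir <- cos(deg2rad(60)) * u + (if (k == 1) 1 else -1) * sin(deg2rad(60)) * v
        rows <- rbind(rows, data.frame(serial = 0L, name = paste0("H", k),
                                       element = "H", res_name = res_name,
                                       res_id = res_id, chain = "W", insert = "",
                                       altloc = "", x = o_pos[1] + 0.96 * hdir[1],
                                       y = o_pos[2] + 0.96 * hdir[2],
                                       z = o_pos[3] + 0.96 * hdir[3],
                                       occupancy = 1, b_factor = 0, het = TRUE))
      }
    }
    rows
  }
  new_atoms <- rbind(mk_water("WEQ", weq), mk_water("WAX", wax))
  new_atoms$serial <- max(s$atoms$serial) + seq_len(nrow(new_atoms))
  structure3d(rbind(s$atoms, new_atoms), s$bonds, s$title)
}

#' Evaluate geometric restraints
#'
#' Two restraint kinds mirror the adjustments used when keeping a metal site
#' in shape during refinement: `improper-planarity` (the improper dihedral of
#' four named atoms should be 0, i.e. the atoms coplanar) and `angle` (a
#' three-atom angle should equal a target, e.g. metal-O-H at 120 degrees).
#' Each restraint yields its absolute deviation in degrees and a quadratic
#' penalty `weight * deviation^2`; no minimiser is bundled, so the evaluators
#' can score the output of any external refinement.
#'
#' @param s a [structure3d].
#' @param specs list of restraint specs: each a list with `kind`
#'   (`"improper-planarity"` or `"angle"`), `atoms` (character vector of
#'   "res:name" references; 4 for improper, 3 for angle), `target` (degrees;
#'   0 for planarity) and optional `weight` (default 1).
#' @return data.frame with one row per restraint: `kind`, `deviation`
#'   (degrees) and `penalty`.
#' @export
evaluate_restraints <- function(s, specs) {
  rows <- lapply(specs, function(sp) {
    w <- if (is.null(sp$weight)) 1 else sp$weight
    p <- lapply(sp$atoms, function(r) coords(s)[parse_atom_ref(r, s), ])
    if (sp$kind == "improper-planarity") {
      if (length(p) != 4) stop("planarity restraint needs 4 atoms")
      dev <- abs(wrap180(vec_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]) -
                           (if (is.null(sp$target)) 0 else sp$target)))
    } else if (sp$kind == "angle") {
      if (length(p) != 3) stop("angle restraint needs 3 atoms")
      dev <- abs(vec_angle(p[[1]], p[[2]], p[[3]]) - sp$target)
    } else stop("unknown restraint kind: ", sp$kind)
    data.frame(kind = sp$kind, deviation = dev, penalty = w * dev^2)
  })
  do.call(rbind, rows)
}
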