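#' Read a cofactor patch from its declarative text format
#'
#' One edit per line; `#` starts a comment. Forms:
#' \preformatted{
#' delete <res_id> <atom>
#' add <res_id> <atom> <element> xyz <x> <y> <z>
#' add <res_id> <atom> <element> zmat <res:atom> <res:atom> <res:atom> <length> <angle> <dihedral>
#' bond <res:atom> <res:atom>
#' unbond <res:atom> <res:atom>
#' rename <res_id> <new_residue_name>
#' }
#'
#' @param path file path.
#' @return a [cofactor_patch].
#' @export
read_patch <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  del <- add <- ba <- bd <- ren <- NULL
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    kw <- tolower(f[1])
    if (kw == "delete" && length(f) == 3) {
      del <- rbind(del, data.frame(res_id = as.integer(f[2]), name = f[3]))
    } else if (kw == "add" && length(f) >= 5 && tolower(f[5]) == "xyz") {
      add <- rbind(add, data.frame(res_id = as.integer(f[2]), name = f[3],
                                   element = f[4], x = as.numeric(f[6]),
                                   y = as.numeric(f[7]), z = as.numeric(f[8]),
                                   ref1 = NA, ref2 = NA, ref3 = NA,
                                   bond_length = NA, bond_angle = NA,
                                   dihedral = NA))
    } else if (kw == "add" && length(f) >= 5 && tolower(f[5]) == "zmat") {
      add <- rbind(add, data.frame(res_id = as.integer(f[2]), name = f[3],
                                   element = f[4], x = NA_real_, y = NA_real_,
                                   z = NA_real_, ref1 = f[6], ref2 = f[7],
                                   ref3 = f[8], bond_length = as.numeric(f[9]),
                                   bond_angle = as.numeric(f[10]),
                                   dihedral = as.numeric(f[11])))
    } else if (kw == "bond" && length(f) == 3) {
      ba <- rbind(ba, data.frame(a = f[2], b = f[3]))
    } else if (kw == "unbond" && length(f) == 3) {
      bd <- rbind(bd, data.frame(a = f[2], b = f[3]))
    } else if (kw == "rename" && length(f) == 3) {
      ren <- rbind(ren, data.frame(res_id = as.integer(f[2]), new_name = f[3]))
    } else stop("bad patch line: ", ln)
  }
  cofactor_patch(del, add, ba, bd, ren)
}

#' Write a cofactor patch to its text format
#' @param patch a [cofactor_patch].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path) {
  lines <- character(0)
  if (!is.null(patch$atoms_deleted))
    lines <- c(lines, sprintf("delete %d %s", patch$atoms_deleted$res_id,
                              patch$atoms_deleted$name))
  if (!is.null(patch$atoms_added)) {
    a <- patch$atoms_added
    for (i in seq_len(nrow(a))) {
      lines <- c(lines, if (!is.na(a$x[i]))
        sprintf("add %d %s %s xyz %.4f %.4f %.4f", a$res_id[i], a$name[i],
                a$element[i], a$x[i], a$y[i], a$z[i])
        else sprintf("add %d %s %s zmat %s %s %s %.3f %.2f %.2f", a$res_id[i],
                     a$name[i], a$element[i], a$ref1[i], a$ref2[i], a$ref3[i],
                     a$bond_length[i], a$bond_angle[i], a$dihedral[i]))
    }
  }
  if (!is.null(patch$bonds_deleted))
    lines <- c(lines, sprintf("unbond %s %s", patch$bonds_deleted$a,
                              patch$bonds_deleted$b))
  if (!is.null(patch$bonds_added))
    lines <- c(lines, sprintf("bond %s %s", patch$bonds_added$a,
                              patch$bonds_added$b))
  if (!is.null(patch$renames))
    lines <- c(lines, sprintf("rename %d %s", patch$renames$res_id,
                              patch$renames$new_name))
  writeLines(lines, path)
  invisible(path)
}

#' Canonical cofactor patches for LTQ construction
#'
#' `patch_tpq2hp_to_ltq2hp()` builds the crosslinking edit that turns a
#' quinone-hydrazone residue plus a nearby lysine into the LTQ-2HP adduct:
#' the C2 oxygen of the quinone is removed (giving the dopaquinone-like
#' intermediate) and a new epsilon-N to C2 bond is created (target length
#' 1.40 angstrom, aromatic C-N, recorded in the patch metadata for any
#' downstream relaxation). `patch_ltq2hp_to_ltq()` strips the
#' 2-hydrazinopyridine-derived atoms and restores the carbonyl oxygen at C5,
#' regenerating unmodified LTQ.
#'
#' @param lys_res residue number of the lysine donating the epsilon-amino
#'   group.
#' @param quinone_res residue number of the quinone cofactor residue.
#' @param c2_oxygen name of the C2-bound oxygen to delete (default "O2").
#' @param hyd_atoms atom names derived from 2-hydrazinopyridine to delete
#'   (default `c("N1","N3","C7","C8","C9","C10","C11")`).
#' @return a [cofactor_patch].
#' @name ltq_patches
#' @export
patch_tpq2hp_to_ltq2hp <- function(lys_res, quinone_res, c2_oxygen = "O2") {
  p <- cofactor_patch(
    atoms_deleted = data.frame(res_id = quinone_res, name = c2_oxygen),
    bonds_added = data.frame(a = sprintf("%d:NZ", lys_res),
                             b = sprintf("%d:C2", quinone_res)),
    bonds_deleted = data.frame(a = sprintf("%d:C2", quinone_res),
                               b = sprintf("%d:%s", quinone_res, c2_oxygen)),
    renames = data.frame(res_id = quinone_res, new_name = "LTQ"))
  attr(p, "crosslink_target_length") <- 1.40
  p
}

#' @rdname ltq_patches
#' @export
patch_ltq2hp_to_ltq <- function(quinone_res,
                                hyd_atoms = c("N1", "N3", "C7", "C8", "C9",
                                              "C10", "C11")) {
  cofactor_patch(
    atoms_deleted = data.frame(res_id = quinone_res, name = hyd_atoms),
    atoms_added = data.frame(res_id = quinone_res, name = "O5", element = "O",
                             x = NA_real_, y = NA_real_, z = NA_real_,
                             ref1 = sprintf("%d:C5", quinone_res),
                             ref2 = sprintf("%d:C4", quinone_res),
                             ref3 = sprintf("%d:C3", quinone_res),
                             bond_length = 1.23, bond_angle = 120,
                             dihedral = 180),
    bonds_deleted = data.frame(a = sprintf("%d:C5", quinone_res),
                               b = sprintf("%d:N1", quinone_res)),
    bonds_added = data.frame(a = sprintf("%d:C5", quinone_res),
                             b = sprintf("%d:O5", quinone_res)))
}
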