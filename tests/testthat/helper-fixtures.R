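# Fixtures built in code: ideal peptides, rigid motions, small structures.

# Ideal poly-Ala backbone (N, CA, C per residue) built by internal-coordinate
# chain extension at the given phi/psi/omega.
build_peptide <- function(n, phi, psi, omega = 180) {
  atoms <- NULL
  add <- function(nm, el, rid, p) {
    rbind(atoms, data.frame(serial = 0L, name = nm, element = el,
                            res_name = "ALA", res_id = as.integer(rid),
                            chain = "A", insert = "", altloc = "",
                            x = p[1], y = p[2], z = p[3],
                            occupancy = 1, b_factor = 0, het = FALSE))
  }
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  N <- c(0, 0, 0); CA <- c(1.46, 0, 0)
  C <- ltqdyn:::place_atom(c(0, 1, 0), N, CA, 1.52, 111, 0)
  atoms <- add("N", "N", 1, N); atoms <- add("CA", "C", 1, CA)
  atoms <- add("C", "C", 1, C)
  for (i in 2:n) {
    N2 <- ltqdyn:::place_atom(N, CA, C, 1.33, 116.2, psi[i - 1])
    CA2 <- ltqdyn:::place_atom(CA, C, N2, 1.46, 121.7, omega[i])
    C2 <- ltqdyn:::place_atom(C, N2, CA2, 1.52, 111, phi[i])
    atoms <- add("N", "N", i, N2); atoms <- add("CA", "C", i, CA2)
    atoms <- add("C", "C", i, C2)
    N <- N2; CA <- CA2; C <- C2
  }
  atoms$serial <- seq_len(nrow(atoms))
  structure3d(atoms)
}

# random rigid motion applied to an n x 3 coordinate matrix
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  axis <- stats::rnorm(3); ang <- stats::runif(1, -180, 180)
  tr <- stats::rnorm(3, sd = 5)
  sweep(ltqdyn:::rotate_points(xyz, colMeans(xyz), axis, ang), 2, tr, "+")
}

# quinone + uncrosslinked lysine fixture with a C2-bound oxygen, for patch
# tests (the toy active site minus its crosslink, plus an O2)
make_precursor_fixture <- function() {
  toy <- make_toy_active_site()
  at <- toy$atoms
  c2 <- which(at$name == "C2" & at$res_id == 20)
  nz <- which(at$name == "NZ" & at$res_id == 40)
  b <- toy$bonds
  b <- b[!(b[, 1] == min(c2, nz) & b[, 2] == max(c2, nz)), , drop = FALSE]
  o2 <- at[c2, ]
  o2$serial <- max(at$serial) + 1L; o2$name <- "O2"; o2$element <- "O"
  o2[, c("x", "y", "z")] <- at[c2, c("x", "y", "z")] + c(0, 0, 1.23)
  structure3d(rbind(at, o2), rbind(b, c(c2, nrow(at) + 1L)), toy$title)
}

# all 81 four-letter rotamer codes over {p, t, m}
all_rotamer_codes <- function() {
  g <- expand.grid(a = c("p", "t", "m"), b = c("p", "t", "m"),
                   c = c("p", "t", "m"), d = c("p", "t", "m"),
                   stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}

code_to_chi <- function(code) {
  canon <- c(p = 65, t = 180, m = -65)
  unname(canon[strsplit(code, "")[[1]]])
}
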