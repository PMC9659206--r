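#' Vector geometry kernel
#'
#' Distances, bond angles and dihedral angles on raw 3-vectors, in the units
#' used throughout the package: angstrom and degrees.
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return `vec_distance`: distance in angstrom. `vec_angle`: the a-b-c angle
#'   in degrees, in \[0, 180\]. `vec_dihedral`: the a-b-c-d torsion in degrees,
#'   in (-180, 180\], IUPAC sign convention (clockwise positive looking from
#'   b towards c).
#' @name vec_geometry
NULL

#' @rdname vec_geometry
#' @export
vec_distance <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' @rdname vec_geometry
#' @export
vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length arm in angle")
  cosx <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosx))) * 180 / pi
}

#' @rdname vec_geometry
#' @export
vec_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) == 0 || sum(n2^2) == 0)
    stop("collinear points: dihedral undefined")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap degrees into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# smallest circular separation of two angles in degrees, in [0, 180]
circ_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two coordinate sets with known one-to-one atom
#' correspondence. The singular-value decomposition solution is used with a
#' determinant guard, so a reflection is never returned.
#'
#' @param mobile,ref n x 3 matrices, n >= 3, in correspondence by row.
#' @param weights optional non-negative weights, length n.
#' @return An object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3), and `rmsd` (angstrom; weighted RMS of
#'   residuals). The fitted coordinates are `mobile %*% t(rotation)` plus the
#'   translation, as applied by [apply_superposition()].
#' @export
superpose <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  n <- nrow(mobile)
  if (n != nrow(ref)) stop("coordinate sets differ in length")
  if (n < 3) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) == 0) stop("invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  X <- sweep(mobile, 2, cm); Y <- sweep(ref, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate geometry: superposition undefined")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)          # maps centred mobile onto centred ref
  fitted <- X %*% t(R)
  msd <- sum(w * rowSums((fitted - Y)^2))
  out <- list(rotation = R,
              translation = as.numeric(cr - R %*% cm),
              rmsd = sqrt(max(0, msd)))
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param xyz n x 3 matrix.
#' @param sup a `superposition` from [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Root-mean-square deviation between coordinate sets
#'
#' @param A,B n x 3 matrices in row correspondence.
#' @param fit if TRUE (default) minimise over rigid motions first
#'   ([superpose()]); if FALSE use the coordinates as given.
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return RMSD in the requested unit.
#' @export
rmsd <- function(A, B, fit = TRUE, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in length")
  val <- if (fit) superpose(A, B)$rmsd
         else sqrt(mean(rowSums((A - B)^2)))
  if (units == "nm") val / 10 else val
}

# --- internal-coordinate placement (NeRF) -----------------------------------
# Place a new point at distance `r` from C, making angle `theta` (deg) with
# B-C, and dihedral `phi` (deg) about B-C relative to A. Standard natural
# extension reference frame construction.
place_atom <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear reference atoms in internal-coordinate placement")
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# rotation matrix for rotating by `angle` degrees about the axis through
# point `origin` with direction `axis` (need not be unit length)
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         nrow = 3, byrow = TRUE)
}

# rotate rows of xyz about the axis through `origin` along `axis`
rotate_points <- function(xyz, origin, axis, angle) {
  R <- rotation_about_axis(axis, angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

# least-squares plane through points: returns list(centroid, normal)
fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}
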