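# Independent oracles kept deliberately separate from the implementation:
# a quaternion (Horn) superposition solver and a two-plane-normal dihedral.

# Horn's closed-form absolute-orientation method: the optimal rotation is the
# eigenvector of a 4x4 quaternion matrix. Independent of the SVD route used
# by the package.
quaternion_superpose_oracle <- function(mobile, ref) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(ref, 2, colMeans(ref))
  S <- t(X) %*% Y
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       Syy - Sxx - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       Szz - Sxx - Syy),
    nrow = 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  fitted <- X %*% t(R)
  rms <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rmsd = rms, rotation = R)
}

# dihedral via the two plane normals, sign from the scalar triple product
dihedral_oracle <- function(a, b, c, d) {
  x3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- x3(b - a, c - b); n2 <- x3(c - b, d - c)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(min(1, max(-1, cosphi))) * 180 / pi
  if (sum(x3(n1, n2) * (c - b)) < 0) phi <- -phi
  phi
}

# RMSD series oracle: per-frame Kabsch on fresh centred SVD, no shared code
# with the package path beyond base svd
rmsd_oracle <- function(A, B) {
  X <- sweep(A, 2, colMeans(A)); Y <- sweep(B, 2, colMeans(B))
  sv <- svd(t(X) %*% Y)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((X %*% t(R) - Y)^2)))
}
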