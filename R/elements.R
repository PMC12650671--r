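## Element-level finite element kernels.  Units: N, mm, MPa.
## Hex8: trilinear isoparametric solid, 2x2x2 Gauss quadrature with
## selective reduced integration of the volumetric term for
## near-incompressible materials (anti-locking).  Truss: axial two-node
## element, optionally tension-only.  Beam: 3D two-node shear-deformable
## (Timoshenko) beam with circular section.

hex8_natural <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                         -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
                       8, 3, byrow = TRUE)

hex8_dshape <- function(xi) {
  g <- hex8_natural
  dN <- matrix(0, 8, 3)
  for (i in 1:8) {
    dN[i, 1] <- g[i, 1] * (1 + g[i, 2] * xi[2]) * (1 + g[i, 3] * xi[3]) / 8
    dN[i, 2] <- (1 + g[i, 1] * xi[1]) * g[i, 2] * (1 + g[i, 3] * xi[3]) / 8
    dN[i, 3] <- (1 + g[i, 1] * xi[1]) * (1 + g[i, 2] * xi[2]) * g[i, 3] / 8
  }
  dN
}

## strain-displacement matrix (6 x 24, engineering shear strains) and
## Jacobian determinant at natural point xi
hex8_bmatrix <- function(X, xi) {
  dN <- hex8_dshape(xi)
  J <- t(dN) %*% X           # rows: d(x,y,z)/d(xi_j)
  detJ <- det(J)
  dNx <- dN %*% solve(t(J))  # dN_i/d(x,y,z)
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, by = 3)
  B[1, ix]     <- dNx[, 1]
  B[2, ix + 1] <- dNx[, 2]
  B[3, ix + 2] <- dNx[, 3]
  B[4, ix]     <- dNx[, 2]; B[4, ix + 1] <- dNx[, 1]
  B[5, ix + 1] <- dNx[, 3]; B[5, ix + 2] <- dNx[, 2]
  B[6, ix]     <- dNx[, 3]; B[6, ix + 2] <- dNx[, 1]
  list(B = B, detJ = detJ)
}

hex_jacobian_center <- function(X) {
  det(t(hex8_dshape(c(0, 0, 0))) %*% X)
}

hex_min_jacobian <- function(X) {
  g <- 1 / sqrt(3)
  pts <- rbind(hex8_natural * g, c(0, 0, 0))
  min(apply(pts, 1, function(xi) det(t(hex8_dshape(xi)) %*% X)))
}

iso_dmatrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Hex8 element stiffness
#'
#' 24x24 stiffness of an 8-node trilinear hexahedron (2x2x2 Gauss).
#' For `nu > 0.49` (or when `sri = TRUE`) the volumetric part of the
#' constitutive tensor is integrated with a single central point
#' (selective reduced integration), the standard anti-locking treatment
#' for near-incompressible materials such as the nucleus pulposus.
#'
#' @param X 8 x 3 node coordinates (VTK ordering), mm.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @param sri logical; force/suppress selective reduced integration.
#' @return 24 x 24 symmetric stiffness matrix (N/mm).
#' @export
hex8_stiffness <- function(X, E, nu, sri = nu > 0.49) {
  D <- iso_dmatrix(E, nu)
  m <- c(1, 1, 1, 0, 0, 0)
  Kb <- E / (3 * (1 - 2 * nu))
  Dvol <- Kb * tcrossprod(m)
  Duse <- if (sri) D - Dvol else D
  K <- matrix(0, 24, 24)
  g <- 1 / sqrt(3)
  for (r in 1:8) {
    xi <- hex8_natural[r, ] * g
    bb <- hex8_bmatrix(X, xi)
    if (bb$detJ <= 0) stop("inverted hex element (non-positive Jacobian)")
    K <- K + t(bb$B) %*% Duse %*% bb$B * bb$detJ
  }
  if (sri) {
    b0 <- hex8_bmatrix(X, c(0, 0, 0))
    K <- K + t(b0$B) %*% Dvol %*% b0$B * (8 * b0$detJ)
  }
  (K + t(K)) / 2
}

## centroid stress (6-vector, MPa) of a hex under nodal displacements
hex8_centroid_stress <- function(X, ue, E, nu) {
  b0 <- hex8_bmatrix(X, c(0, 0, 0))
  drop(iso_dmatrix(E, nu) %*% (b0$B %*% ue))
}

## centroid strain (6-vector) of a hex under nodal displacements
hex8_centroid_strain <- function(X, ue) {
  b0 <- hex8_bmatrix(X, c(0, 0, 0))
  drop(b0$B %*% ue)
}

#' Von Mises equivalent stress
#' @param s stress 6-vector (xx, yy, zz, xy, yz, zx) or matrix with 6
#'   columns.
#' @return scalar (or vector) von Mises stress.
#' @export
von_mises <- function(s) {
  if (is.matrix(s)) {
    sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                  (s[, 3] - s[, 1])^2) +
           3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  } else {
    sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2) +
           3 * (s[4]^2 + s[5]^2 + s[6]^2))
  }
}

#' Truss element stiffness
#'
#' Axial two-node element: stiffness `E A / L` along the element axis.
#' Tension-only behaviour is handled by the solver's active-set loop,
#' which drops compressed elements.
#'
#' @param X 2 x 3 node coordinates (mm).
#' @param E Young's modulus (MPa).
#' @param A cross-sectional area (mm^2).
#' @return list with the 6 x 6 stiffness `K`, unit direction `dir`,
#'   length `L` and axial stiffness `k = EA/L`.
#' @export
truss_stiffness <- function(X, E, A) {
  d <- X[2, ] - X[1, ]
  L <- sqrt(sum(d^2))
  if (L < 1e-12) stop("zero-length truss element")
  dir <- d / L
  k <- E * A / L
  dd <- k * tcrossprod(dir)
  K <- rbind(cbind(dd, -dd), cbind(-dd, dd))
  list(K = K, dir = dir, L = L, k = k)
}

#' 3D Timoshenko beam element stiffness (circular section)
#'
#' Standard 12x12 two-node shear-deformable beam with circular section
#' properties derived from the diameter (A = pi d^2/4, I = pi d^4/64,
#' J = 2I) and shear correction factor 6(1+nu)/(7+6nu).
#'
#' @param X 2 x 3 node coordinates (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @param diameter section diameter (mm).
#' @return 12 x 12 stiffness in global coordinates; DOF order
#'   (ux, uy, uz, rx, ry, rz) per node.
#' @export
beam_stiffness <- function(X, E, nu, diameter) {
  d <- X[2, ] - X[1, ]
  L <- sqrt(sum(d^2))
  if (L < 1e-12) stop("zero-length beam element")
  if (diameter <= 0) stop("beam diameter must be > 0")
  A <- pi * diameter^2 / 4
  I <- pi * diameter^4 / 64
  Jt <- 2 * I
  G <- E / (2 * (1 + nu))
  kappa <- 6 * (1 + nu) / (7 + 6 * nu)
  Phi <- 12 * E * I / (kappa * G * A * L^2)

  K <- matrix(0, 12, 12)
  K[1, 1] <- K[7, 7] <- E * A / L
  K[1, 7] <- K[7, 1] <- -E * A / L
  K[4, 4] <- K[10, 10] <- G * Jt / L
  K[4, 10] <- K[10, 4] <- -G * Jt / L
  c1 <- E * I / (L^3 * (1 + Phi))
  ## bending in local x-y plane: dofs v1=2, tz1=6, v2=8, tz2=12
  bxy <- c1 * matrix(c(12, 6 * L, -12, 6 * L,
                       6 * L, (4 + Phi) * L^2, -6 * L, (2 - Phi) * L^2,
                       -12, -6 * L, 12, -6 * L,
                       6 * L, (2 - Phi) * L^2, -6 * L, (4 + Phi) * L^2),
                     4, 4, byrow = TRUE)
  ii <- c(2, 6, 8, 12)
  K[ii, ii] <- K[ii, ii] + bxy
  ## bending in local x-z plane: dofs w1=3, ty1=5, w2=9, ty2=11
  bxz <- c1 * matrix(c(12, -6 * L, -12, -6 * L,
                       -6 * L, (4 + Phi) * L^2, 6 * L, (2 - Phi) * L^2,
                       -12, 6 * L, 12, 6 * L,
                       -6 * L, (2 - Phi) * L^2, 6 * L, (4 + Phi) * L^2),
                     4, 4, byrow = TRUE)
  jj <- c(3, 5, 9, 11)
  K[jj, jj] <- K[jj, jj] + bxz

  ex <- d / L
  ref <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  ey <- ref - sum(ref * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  T <- matrix(0, 12, 12)
  for (b in 0:3) T[3 * b + 1:3, 3 * b + 1:3] <- R
  t(T) %*% K %*% T
}
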