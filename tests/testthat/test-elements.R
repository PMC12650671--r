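# Element kernels: hex8 (patch tests, quadrature oracle), truss, beam

unit_cube <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

test_that("homogeneous uniaxial strain reproduces sigma = E eps", {
  E <- 12000; nu <- 0.3; eps <- 1e-3
  # uniaxial stress state: free lateral contraction -nu*eps
  U <- cbind(-nu * eps * unit_cube[, 1], -nu * eps * unit_cube[, 2],
             eps * unit_cube[, 3])
  ue <- as.vector(t(U))
  s <- spinefe:::hex8_centroid_stress(unit_cube, ue, E, nu)
  expect_equal(s[3] / eps, E, tolerance = 1e-3)  # within 0.1%
  expect_equal(s[1], 0, tolerance = 1e-9)
  expect_equal(von_mises(s), E * eps, tolerance = 1e-6)
})

test_that("rigid motions produce zero force and zero stress", {
  K <- hex8_stiffness(unit_cube, 12000, 0.3)
  u_trans <- rep(c(0.4, -0.2, 0.7), 8)
  expect_lt(max(abs(K %*% u_trans)), 1e-9)
  # small rigid rotation about a random axis
  w <- c(2e-4, -1e-4, 3e-4)
  U <- t(apply(unit_cube, 1, function(r) {
    c(w[2] * r[3] - w[3] * r[2],
      w[3] * r[1] - w[1] * r[3],
      w[1] * r[2] - w[2] * r[1])
  }))
  s <- spinefe:::hex8_centroid_stress(unit_cube, as.vector(t(U)),
                                      12000, 0.3)
  expect_lt(von_mises(s) * 1000, 1e-6)   # kPa
})

test_that("hex8 stiffness matches an independent quadrature oracle", {
  # independent oracle: own shape-function derivatives and a 3x3x3
  # Gauss rule; on affine (parallelepiped) elements both rules are exact
  oracle_K <- function(X, E, nu) {
    gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
    gw <- c(5 / 9, 8 / 9, 5 / 9)
    sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                 c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
    D <- matrix(0, 6, 6); D[1:3, 1:3] <- lam
    diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
    K <- matrix(0, 24, 24)
    for (a in 1:3) for (b in 1:3) for (c3 in 1:3) {
      xi <- c(gp[a], gp[b], gp[c3])
      dN <- matrix(0, 8, 3)
      for (i in 1:8) {
        dN[i, ] <- c(
          sgn[i, 1] * (1 + sgn[i, 2] * xi[2]) * (1 + sgn[i, 3] * xi[3]),
          (1 + sgn[i, 1] * xi[1]) * sgn[i, 2] * (1 + sgn[i, 3] * xi[3]),
          (1 + sgn[i, 1] * xi[1]) * (1 + sgn[i, 2] * xi[2]) * sgn[i, 3]
        ) / 8
      }
      J <- t(dN) %*% X
      dNx <- dN %*% solve(t(J))
      B <- matrix(0, 6, 24)
      for (i in 1:8) {
        c0 <- 3 * (i - 1)
        B[1, c0 + 1] <- dNx[i, 1]; B[2, c0 + 2] <- dNx[i, 2]
        B[3, c0 + 3] <- dNx[i, 3]
        B[4, c0 + 1] <- dNx[i, 2]; B[4, c0 + 2] <- dNx[i, 1]
        B[5, c0 + 2] <- dNx[i, 3]; B[5, c0 + 3] <- dNx[i, 2]
        B[6, c0 + 1] <- dNx[i, 3]; B[6, c0 + 3] <- dNx[i, 1]
      }
      K <- K + gw[a] * gw[b] * gw[c3] * t(B) %*% D %*% B * det(J)
    }
    K
  }
  set.seed(13)
  for (rep in 1:5) {
    A <- diag(3) + matrix(stats::rnorm(9, sd = 0.2), 3, 3)  # affine map
    X <- unit_cube %*% t(A)
    K1 <- hex8_stiffness(X, 3500, 0.25)
    K2 <- oracle_K(X, 3500, 0.25)
    expect_equal(K1, K2, tolerance = 1e-8)
  }
})

test_that("selective reduced integration relieves volumetric locking", {
  Kf <- hex8_stiffness(unit_cube, 1, 0.499, sri = FALSE)
  Ks <- hex8_stiffness(unit_cube, 1, 0.499, sri = TRUE)
  # a bending-like mode must be much softer under SRI
  u <- as.vector(t(cbind(unit_cube[, 3] * (unit_cube[, 1] - 0.5), 0,
                         0 * unit_cube[, 1])))
  expect_lt(drop(u %*% Ks %*% u), drop(u %*% Kf %*% u))
  ev <- eigen(Ks, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < max(ev) * 1e-10), 6)  # exactly the rigid modes
})

test_that("truss follows EA/L and rotates correctly", {
  X <- rbind(c(0, 0, 0), c(10, 0, 0))
  ts <- truss_stiffness(X, 10, 26)       # ISL-like: E=10 MPa, A=26 mm^2
  expect_equal(ts$k * 0.1, 2.6)          # 0.1 mm elongation -> 2.6 N
  set.seed(3)
  for (i in 1:10) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2)) * 12
    X2 <- rbind(c(1, 2, 3), c(1, 2, 3) + d)
    got <- truss_stiffness(X2, 200, 5)$K
    # oracle: rotate the 1D local stiffness into 3D
    dirv <- d / 12
    kl <- 200 * 5 / 12
    dd <- kl * outer(dirv, dirv)
    expect_equal(got, rbind(cbind(dd, -dd), cbind(-dd, dd)),
                 tolerance = 1e-12)
  }
  expect_error(truss_stiffness(rbind(c(0, 0, 0), c(0, 0, 0)), 1, 1),
               "zero-length")
})

test_that("beam cantilever matches the shear-augmented closed form", {
  E <- 110000; nu <- 0.3; d <- 5.5; L <- 100; P <- 50
  nodes <- cbind(seq(0, L, length.out = 9), 0, 0)
  u <- beam_chain_solve(nodes, E, nu, d, c(0, 0, P, 0, 0, 0))
  tip_w <- u[8 * 6 + 3]
  I <- pi * d^4 / 64; A <- pi * d^2 / 4
  G <- E / (2 * (1 + nu)); kappa <- 6 * (1 + nu) / (7 + 6 * nu)
  closed <- P * L^3 / (3 * E * I) + P * L / (kappa * G * A)
  expect_equal(tip_w, closed, tolerance = 0.01 * closed)

  # axial and torsional responses are exact for a single element
  u_ax <- beam_chain_solve(nodes[c(1, 9), ], E, nu, d,
                           c(100, 0, 0, 0, 0, 0))
  expect_equal(u_ax[7], 100 * L / (E * A), tolerance = 1e-10)
  u_tor <- beam_chain_solve(nodes[c(1, 9), ], E, nu, d,
                            c(0, 0, 0, 1000, 0, 0))
  J <- pi * d^4 / 32
  expect_equal(u_tor[10], 1000 * L / (G * J), tolerance = 1e-10)
})

test_that("von Mises handles uniaxial and hydrostatic states", {
  expect_equal(von_mises(c(7, 0, 0, 0, 0, 0)), 7)
  expect_equal(von_mises(c(5, 5, 5, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 1, 0, 0)), sqrt(3))
})
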