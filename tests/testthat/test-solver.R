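# Linear-static solve: linearity, energy, equilibrium, tension-only
# behaviour, incompressibility, and flexion-angle matching

toy_solved <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- assemble_spine(toy_pair_params())
      res <- solve_spine(sp, load_case(moment_nm = 2))
      cache <<- list(sp = sp, res = res)
    }
    cache
  }
})

test_that("zero load gives zero displacement", {
  sp <- toy_solved()$sp
  res0 <- solve_spine(sp, load_case(moment_nm = 0))
  expect_equal(max(abs(res0$U)), 0)
  expect_equal(res0$flexion_deg, 0)
})

test_that("displacements scale linearly on a fixed active set", {
  sp <- toy_solved()$sp
  r2 <- toy_solved()$res
  r4 <- solve_spine(sp, load_case(moment_nm = 4))
  expect_identical(r2$truss_active, r4$truss_active)
  expect_equal(r4$U, 2 * r2$U, tolerance = 1e-9)
})

test_that("strain energy equals external work", {
  res <- toy_solved()$res
  expect_equal(res$strain_energy, res$external_work, tolerance = 1e-6)
})

test_that("reactions at the fixed face balance the applied load", {
  res <- toy_solved()$res
  nf <- length(res$reactions) / 3
  # fixed dofs are stored column-major: x block, y block, z block
  for (c3 in 1:3) {
    r <- sum(res$reactions[(c3 - 1) * nf + seq_len(nf)])
    a <- sum(res$f[seq(c3, length(res$f), by = 3)])
    expect_equal(r + a, 0, tolerance = 1e-8 * max(1, abs(a)))
  }
})

test_that("the terminal active set carries no compressed tension-only member", {
  got <- toy_solved()
  sp <- got$sp; res <- got$res
  sys <- spinefe:::fe_system(sp, sp$config$materials, "inferior_face")
  el <- spinefe:::truss_elongations(sys, res$u_full)
  expect_true(all(el[res$truss_active] >= -1e-8))
  expect_true(all(res$truss_stress_kpa[!res$truss_active] == 0))
  # flexion slackens the anterior longitudinal ligament
  all_idx <- which(sp$truss_info$type == "ALL")
  expect_true(all(!res$truss_active[all_idx]))
  # and some members must genuinely be excluded
  expect_gt(sum(!res$truss_active), 0)
})

test_that("the nucleus behaves as a nearly incompressible fluid core", {
  # At nu = 0.499 a confined nucleus is pressure-dominated, so the
  # per-element volumetric strain is set by p/K_bulk, not by the
  # deviatoric strain (see the methods vignette).  What near
  # incompressibility does guarantee: the stress state is close to
  # hydrostatic, and the net volume change of the core is tiny.
  got <- toy_solved()
  sp <- got$sp; res <- got$res
  nuc <- which(sp$hex_info$mat == "nucleus")
  expect_gt(length(nuc), 0)
  vols <- tr <- q_over_p <- numeric(length(nuc))
  for (k in seq_along(nuc)) {
    e <- nuc[k]; conn <- sp$hex[e, ]
    X <- sp$nodes[conn, ]
    vols[k] <- hex_volume(X)
    eps <- spinefe:::hex8_centroid_strain(X, as.vector(t(res$U[conn, ])))
    tr[k] <- sum(eps[1:3])
    s <- res$hex_sigma[e, ]
    q_over_p[k] <- von_mises(s) / abs(mean(s[1:3]))
  }
  # hydrostatic dominance: von Mises stress well below the pressure
  expect_lt(stats::weighted.mean(q_over_p, vols), 0.5)
  # net volume change of the core is far below unit strain
  expect_lt(abs(sum(vols * tr) / sum(vols)), 1e-3)
})

test_that("rigid-body motion of the whole mesh produces no stress", {
  sp <- toy_solved()$sp
  w <- c(-5 * pi / 180, 0, 0)
  ctr <- colMeans(sp$nodes)
  U <- t(apply(sp$nodes, 1, function(r) {
    rr <- r - ctr
    c(w[2] * rr[3] - w[3] * rr[2],
      w[3] * rr[1] - w[1] * rr[3],
      w[1] * rr[2] - w[2] * rr[1])
  }))
  st <- compute_stresses(sp, U)
  expect_lt(max(st$hex_vm_kpa), 1e-6 * max(1, max(abs(U))) * 1e3)
  # every internal segment ROM is zero, the global rotation is 5 deg
  rot <- vapply(sp$levels, function(lv) {
    ids <- which(sp$node_level == lv)
    -spinefe:::rigid_fit(sp$nodes[ids, ], U[ids, ])$omega[1] * 180 / pi
  }, numeric(1))
  expect_equal(unname(diff(rot)), 0, tolerance = 1e-9)
  expect_equal(unname(rot[1]), 5, tolerance = 1e-9)
})

test_that("a prescribed 3-degree relative rotation is measured as 3.00", {
  sp <- toy_solved()$sp
  up_ids <- which(sp$node_level == "L4")
  ctr <- colMeans(sp$nodes[up_ids, ])
  w <- c(-3 * pi / 180, 0, 0)   # flexion positive convention
  U <- matrix(0, nrow(sp$nodes), 3)
  U[up_ids, ] <- t(apply(sp$nodes[up_ids, ], 1, function(r) {
    rr <- r - ctr
    c(w[2] * rr[3] - w[3] * rr[2],
      w[3] * rr[1] - w[1] * rr[3],
      w[1] * rr[2] - w[2] * rr[1])
  }))
  rot <- vapply(c("L5", "L4"), function(lv) {
    ids <- which(sp$node_level == lv)
    -spinefe:::rigid_fit(sp$nodes[ids, ], U[ids, ])$omega[1] * 180 / pi
  }, numeric(1))
  fake <- structure(list(vertebra_rotation_deg = rot),
                    class = "solve_result")
  sr <- segmental_rom(sp, fake, "L4", "L5")
  expect_equal(sr$rom_deg, 3, tolerance = 1e-9)
  expect_equal(sr$segment, "L4-L5")
})

test_that("flexion-angle matching converges within tolerance", {
  got <- toy_solved()
  target <- got$res$flexion_deg / 2
  m <- match_flexion_angle(got$sp, target)
  expect_lte(abs(m$result$flexion_deg - target), 0.05)
  expect_lte(m$iterations, 3)
  m0 <- match_flexion_angle(got$sp, 0)
  expect_equal(m0$moment_nm, 0)
  expect_equal(m0$iterations, 0L)
})

test_that("a missing fixed set is rejected", {
  sp <- toy_solved()$sp
  expect_error(solve_spine(sp, load_case(fixed_set = "nope")), "empty")
})
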