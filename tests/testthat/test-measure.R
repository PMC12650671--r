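# Cobb/TLK angles, MAE, segmental ROM additivity, stress maxima

planar_params <- function(level, beta, z, theta = 0) {
  vertebra_params(level, c(0, -15, z), c(36, 30, 20), theta_deg = theta,
                  beta_deg = beta, beta_sup_deg = beta,
                  beta_inf_deg = beta)
}

test_that("Cobb angle of a planar toy is the sum of the end tilts", {
  geom <- spine_geometry(list(planar_params("L3", -15, 20),
                              planar_params("T11", 10, 120)))
  expect_equal(cobb_angle(geom, "T11", "L3"), 25, tolerance = 1e-9)
  # invariance to rigid translation and in-plane rotation of the whole
  # geometry is inherited from working on direction vectors
  geom2 <- spine_geometry(list(planar_params("L3", -15 + 7, 20),
                               planar_params("T11", 10 + 7, 120)))
  expect_equal(cobb_angle(geom2, "T11", "L3"), 25, tolerance = 1e-9)
})

test_that("TLK defaults to T10 superior vs L2 inferior", {
  geom <- spine_geometry(list(planar_params("L2", 0, 20, theta = -12.2),
                              planar_params("T10", 0, 200, theta = 8)))
  expect_equal(tlk_angle(geom), 20.2, tolerance = 1e-9)
  geom0 <- spine_geometry(list(planar_params("L2", 0, 20),
                               planar_params("T10", 0, 200)))
  expect_equal(tlk_angle(geom0), 0, tolerance = 1e-12)
})

test_that("TLK matches a brute-force vector-angle oracle on a fixture", {
  gs <- generate_spine(curved_spec(cobb = 40, seed = 6))
  geom <- spine_geometry(gs$truth)
  got <- tlk_angle(geom)
  # oracle: direct arccos on sagittal-projected endplate vectors built
  # from the sampling points
  a <- vertebra_sample_points(gs$truth$params[[match(
    "T10", spine_levels(18))]])
  b <- vertebra_sample_points(gs$truth$params[[match(
    "L2", spine_levels(18))]])
  va <- (a["B", ] - a["A", ])[2:3]
  vb <- (b["D", ] - b["C", ])[2:3]
  want <- acos(abs(sum(va * vb)) /
                 sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(got, gs$truth$true_tlk_deg, tolerance = 1e-6)
})

test_that("axial rotation makes the 3D vector angle exceed projected Cobb", {
  g <- spine_geometry(list(
    planar_params("L3", -15, 20),
    vertebra_params("T11", c(0, -15, 120), c(36, 30, 20), phi_deg = 25,
                    beta_deg = 10, beta_sup_deg = 10, beta_inf_deg = 10)))
  expect_gte(cobb_angle(g, "T11", "L3", projected = FALSE),
             cobb_angle(g, "T11", "L3", projected = TRUE))
})

test_that("MAE is a per-axis mean of absolute differences", {
  set.seed(31)
  a <- matrix(stats::rnorm(18 * 3, sd = 20), 18, 3)
  b <- a + matrix(stats::rnorm(18 * 3, sd = 5), 18, 3)
  got <- mae(a, b)
  expect_equal(unname(got$mae), colMeans(abs(a - b)), ignore_attr = TRUE)
  expect_equal(got$n_levels, 18)
  # symmetry and per-axis triangle inequality
  expect_equal(mae(b, a)$mae, got$mae)
  c3 <- a + matrix(stats::rnorm(18 * 3, sd = 5), 18, 3)
  expect_true(all(mae(a, c3)$mae <= mae(a, b)$mae + mae(b, c3)$mae + 1e-12))
  expect_error(mae(a, b[1:17, ]), "mismatch")
})

test_that("segmental ROM is additive over nested blocks", {
  gs <- generate_spine(straight_spec(n = 4))
  sp <- assemble_spine(gs$truth$params)
  res <- solve_spine(sp, load_case(moment_nm = 1))
  lv <- sp$levels   # L5 L4 L3 L2
  whole <- segmental_rom(sp, res, lv[4], lv[1])$rom_deg
  a <- segmental_rom(sp, res, lv[4], lv[3])$rom_deg
  b <- segmental_rom(sp, res, lv[3], lv[1])$rom_deg
  expect_equal(whole, a + b, tolerance = 1e-6)
  expect_error(segmental_rom(sp, res, "T1", "L5"), "not in model")
})

test_that("stress maxima scan the named group", {
  sp <- assemble_spine(toy_pair_params())
  fake <- list(hex_vm_kpa = rep(42, nrow(sp$hex)),
               truss_stress_kpa = rep(0, nrow(sp$truss)))
  got <- stress_maxima(sp, fake, list(type = "endplate", level = "L5",
                                      side = "sup"))
  expect_equal(got$max_kpa, 42)   # uniform stress -> the uniform value
  expect_true(got$kind == "hex")

  set.seed(17)
  fake2 <- list(hex_vm_kpa = stats::runif(nrow(sp$hex), 0, 100),
                truss_stress_kpa = stats::runif(nrow(sp$truss), 0, 5))
  seg <- "L4-L5"
  got2 <- stress_maxima(sp, fake2, list(type = "annulus", segment = seg))
  # brute-force scan oracle
  ground <- which(sp$hex_info$region == "ground" & sp$hex_info$seg == seg)
  fib <- which(sp$truss_info$type == "fiber" & sp$truss_info$seg == seg)
  want <- max(fake2$hex_vm_kpa[ground], abs(fake2$truss_stress_kpa[fib]))
  expect_equal(got2$max_kpa, want)
  expect_error(stress_maxima(sp, fake2, list(type = "endplate",
                                             level = "T4", side = "sup")),
               "empty")
})
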