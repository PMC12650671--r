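# Synthetic spine generator: calibration, determinism, reference coords

test_that("a straight stack has zero Cobb and zero tilts", {
  gs <- generate_spine(straight_spec(n = 5))
  expect_equal(gs$truth$true_cobb_deg, 0, tolerance = 1e-9)
  geom <- spine_geometry(gs$truth)
  expect_equal(cobb_angle(geom, "L1", "L5"), 0, tolerance = 1e-9)
  for (p in gs$truth$params) {
    expect_equal(p$beta_deg, 0)
    expect_equal(p$beta_sup_deg, 0)
  }
})

test_that("the coronal amplitude calibration hits the Cobb target", {
  gs <- generate_spine(curved_spec(cobb = 52))
  expect_gte(gs$truth$true_cobb_deg, 51.5)
  expect_lte(gs$truth$true_cobb_deg, 52.5)
  # calibration invariant: the generator's closed-form angle agrees with
  # the point-based Cobb measurement on the ground-truth geometry
  geom <- spine_geometry(gs$truth)
  measured <- cobb_angle(geom, gs$truth$cobb_levels[["upper"]],
                         gs$truth$cobb_levels[["lower"]])
  expect_equal(measured, gs$truth$true_cobb_deg, tolerance = 1e-6)
})

test_that("identical spec and seed give byte-identical landmark files", {
  spec <- curved_spec(cobb = 30, noise = 0.5, seed = 9)
  base1 <- tempfile(); base2 <- tempfile()
  write_landmarks(generate_spine(spec)$landmarks, base1)
  write_landmarks(generate_spine(spec)$landmarks, base2)
  for (ext in c(".json", "_pa.csv", "_lat.csv")) {
    expect_identical(readLines(paste0(base1, ext)),
                     readLines(paste0(base2, ext)))
  }
})

test_that("max lateral offset increases strictly with the Cobb target", {
  offs <- vapply(c(10, 30, 50), function(target) {
    gs <- generate_spine(curved_spec(cobb = target))
    max(abs(gs$truth$centerline[, 1]))
  }, numeric(1))
  expect_true(all(diff(offs) > 0))
})

test_that("spec validation rejects bad inputs", {
  expect_error(synthetic_spine_spec(n_vertebrae = 1), "n_vertebrae")
  expect_error(curved_spec(vertebral_heights = c(rep(20, 17), -1)),
               "> 0")
  expect_error(
    synthetic_spine_spec(coronal_curve = list(target_cobb_deg = 20,
                                              span = c("L4", "C3"))),
    "span")
  expect_error(curved_spec(noise = -1), "noise_sd_mm")
})

test_that("reference coordinates exercise the MAE exactly", {
  gs <- generate_spine(curved_spec(cobb = 40))
  model <- t(vapply(gs$truth$params, function(p) p$p_sup_post,
                    numeric(3)))
  rownames(model) <- vapply(gs$truth$params, function(p) p$level,
                            character(1))

  ref0 <- generate_reference_coords(gs$truth, posture_shift = 0,
                                    noise_sd_mm = 0)
  expect_equal(unname(mae(model, ref0)$mae), c(0, 0, 0))

  ref5 <- generate_reference_coords(gs$truth,
                                    posture_shift = c(5, 0, 0))
  expect_equal(unname(mae(model, ref5)$mae), c(5, 0, 0))

  set.seed(21)
  shifts <- matrix(stats::rnorm(18 * 3, sd = 4), 18, 3)
  refr <- generate_reference_coords(gs$truth, posture_shift = shifts,
                                    noise_sd_mm = 1, seed = 5)
  got <- mae(model, refr)$mae
  # brute-force oracle: direct summation of absolute differences
  expect_equal(unname(got), colSums(abs(model - refr)) / 18,
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(generate_reference_coords(gs$truth,
                                         posture_shift = c(1, 2)),
               "mismatch")
})
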