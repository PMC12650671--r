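# Morphing, discs, ligaments, instrumentation and assembly

test_that("identity parameters leave the template unchanged", {
  tpl <- build_template(c(3, 3, 3))
  vp <- vertebra_params("L5", c(0, 0, 0), c(1, 1, 1))
  pv <- morph_and_place(tpl, vp)
  expect_equal(pv$nodes, tpl$nodes, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("doubling Lz doubles every element volume", {
  tpl <- build_template(c(3, 3, 3))
  v1 <- morph_and_place(tpl, vertebra_params("L5", c(0, 0, 0),
                                             c(30, 25, 20)))
  v2 <- morph_and_place(tpl, vertebra_params("L5", c(0, 0, 0),
                                             c(30, 25, 40)))
  vol1 <- vapply(seq_len(nrow(v1$hex)), function(e) {
    hex_volume(v1$nodes[v1$hex[e, ], ])
  }, numeric(1))
  vol2 <- vapply(seq_len(nrow(v2$hex)), function(e) {
    hex_volume(v2$nodes[v2$hex[e, ], ])
  }, numeric(1))
  expect_equal(vol2, 2 * vol1, tolerance = 1e-9)
})

test_that("endplate wedges tilt the endplate planes by the stated angle", {
  tpl <- build_template(c(4, 4, 4))
  vp <- vertebra_params("L3", c(0, 0, 0), c(40, 30, 22),
                        beta_sup_deg = 10, beta_inf_deg = 0)
  pv <- morph_and_place(tpl, vp)
  # plane-fit oracle: regress z on x over the superior rim nodes
  rim <- pv$nodes[pv$attach$rim_sup, ]
  fit <- stats::lm(rim[, 3] ~ rim[, 1] + rim[, 2])
  tilt <- atan(-stats::coef(fit)[["rim[, 1]"]]) * 180 / pi
  expect_equal(tilt, 10, tolerance = 1e-6)
  rim_i <- pv$nodes[pv$attach$rim_inf, ]
  fit_i <- stats::lm(rim_i[, 3] ~ rim_i[, 1] + rim_i[, 2])
  expect_equal(atan(-stats::coef(fit_i)[["rim_i[, 1]"]]) * 180 / pi, 0,
               tolerance = 1e-6)
  # an extreme wedge inverts elements and reports the level
  expect_error(morph_and_place(tpl, vertebra_params(
    "L3", c(0, 0, 0), c(40, 30, 8), beta_sup_deg = 60,
    beta_inf_deg = -60)), "L3")
})

test_that("a parallel 8 mm gap gives 8 mm disc columns throughout", {
  tp <- toy_pair_placed()
  frag <- build_disc(tp$lower, tp$upper, tp$nodes)
  gl <- tp$nodes[as.vector(tp$lower$attach$grid_sup), 3]
  gu <- tp$nodes[as.vector(tp$upper$attach$grid_inf), 3]
  expect_equal(gu - gl, rep(8, length(gl)), tolerance = 1e-9)
  # 3 layers x nx*ny cells
  expect_equal(nrow(frag$hex), 27)
  expect_setequal(unique(frag$hex_info$mat),
                  c("endplate", "nucleus", "ground"))
})

test_that("fiber families sit at +/-30 degrees to the transverse plane", {
  tp <- toy_pair_placed()
  frag <- build_disc(tp$lower, tp$upper, tp$nodes)
  all_nodes <- rbind(tp$nodes, frag$new_nodes)
  ang <- vapply(seq_len(nrow(frag$truss)), function(e) {
    d <- all_nodes[frag$truss[e, 2], ] - all_nodes[frag$truss[e, 1], ]
    atan2(abs(d[3]), sqrt(d[1]^2 + d[2]^2)) * 180 / pi
  }, numeric(1))
  expect_true(all(abs(ang - 30) < 2))
  expect_equal(mean(ang), 30, tolerance = 1e-6)
})

test_that("the nucleus covers the target cross-section area fraction", {
  tp <- toy_pair_placed(resolution = c(6, 6, 3))
  frag <- build_disc(tp$lower, tp$upper, tp$nodes)
  cs <- tp$lower$cross_section
  frac <- sum(cs$areas[frag$nucleus_cells]) / sum(cs$areas)
  expect_gte(frac, 0.42)
  expect_lte(frac, 0.46)
})

test_that("an inverted disc gap is rejected", {
  tpl <- build_template(c(3, 3, 3))
  lower <- morph_and_place(tpl, vertebra_params("L5", c(0, -15, 20),
                                                c(36, 30, 20)), 0L)
  upper <- morph_and_place(tpl, vertebra_params("L4", c(0, -15, 15),
                                                c(36, 30, 20)),
                           nrow(lower$nodes))
  expect_error(build_disc(lower, upper, rbind(lower$nodes, upper$nodes)),
               "negative height|inverted")
})

test_that("ligament counts follow the strand layout", {
  tp <- toy_pair_placed()
  lig <- attach_ligaments(list(tp$lower, tp$upper))
  counts <- table(lig$truss_info$type)
  want <- ligament_strands()
  for (nm in names(want)) {
    expect_equal(unname(counts[[nm]]), unname(want[[nm]]), label = nm)
  }
  expect_error(attach_ligaments(list(tp$lower)), "at least two")
})

test_that("assembly yields one disc fewer than vertebrae", {
  gs <- generate_spine(curved_spec())
  sp <- assemble_spine(gs$truth$params)
  expect_equal(sp$manifest$n_vertebrae, 18)
  expect_equal(sp$manifest$n_discs, 17)
  # 17 segments x 10 strands, at least 7 per segment
  n_lig <- sum(unlist(sp$manifest$truss_by_type[names(ligament_strands())]))
  expect_gte(n_lig, 119)

  sp2 <- assemble_spine(toy_pair_params())
  expect_equal(sp2$manifest$n_discs, 1)
  expect_error(assemble_spine(rev(gs$truth$params)), "caudal to cranial")
  expect_error(assemble_spine(gs$truth$params[1]), "at least two")
})

test_that("a straight stack is mirror-symmetric about the sagittal plane", {
  gs <- generate_spine(straight_spec(n = 3))
  sp <- assemble_spine(gs$truth$params,
                       spine_config(resolution = c(4, 4, 4)))
  key <- function(M) {
    apply(round(M, 6), 1, paste, collapse = ",")
  }
  mirrored <- sp$nodes
  mirrored[, 1] <- -mirrored[, 1]
  expect_true(all(key(mirrored) %in% key(sp$nodes)))
})

test_that("negating coronal parameters reflects the mesh exactly", {
  spec <- synthetic_spine_spec(
    n_vertebrae = 4,
    coronal_curve = list(target_cobb_deg = 30, span = c("L5", "L2")),
    sagittal_profile_deg = rep(0, 4))
  gs <- generate_spine(spec)
  flip <- lapply(gs$truth$params, function(p) {
    vertebra_params(p$level,
                    p$p_sup_post * c(-1, 1, 1), p$lengths,
                    theta_deg = p$theta_deg, phi_deg = -p$phi_deg,
                    beta_deg = -p$beta_deg,
                    beta_sup_deg = -p$beta_sup_deg,
                    beta_inf_deg = -p$beta_inf_deg)
  })
  sp <- assemble_spine(gs$truth$params)
  spf <- assemble_spine(flip)
  mir <- sp$nodes; mir[, 1] <- -mir[, 1]
  key <- function(M) apply(round(M, 6), 1, paste, collapse = ",")
  expect_true(all(key(mir) %in% key(spf$nodes)))
})

test_that("overlapping vertebrae are detected at assembly", {
  p <- toy_pair_params()
  p[[2]]$p_sup_post[3] <- p[[1]]$p_sup_post[3] + 8   # deep overlap
  expect_error(assemble_spine(p), "overlap|negative height")
})

test_that("instrumentation counts match the construct layout", {
  gs <- generate_spine(curved_spec())
  sp <- assemble_spine(gs$truth$params)
  post <- build_instrumentation(sp)
  # 2 bilateral at T10-T11 + 1 unilateral at T12 + 2x4 bilateral L1-L4
  expect_equal(post$manifest$n_screws, 13)
  expect_equal(post$manifest$n_rods, 2)
  expect_equal(post$manifest$n_connectors, 3)

  empty <- instrumentation_spec(levels = character(0),
                                sides = character(0),
                                connector_levels = character(0))
  same <- build_instrumentation(sp, empty)
  expect_equal(same$manifest$n_beam, 0)
  expect_equal(nrow(same$nodes), nrow(sp$nodes))

  bad <- instrumentation_spec(levels = c("T11", "T12"),
                              sides = c("both", "left"),
                              connector_levels = "T12")
  expect_error(build_instrumentation(sp, bad), "unilateral")
  expect_error(build_instrumentation(
    sp, instrumentation_spec(levels = c("T10", "L1"),
                             sides = c("both", "both"),
                             connector_levels = character(0))),
    "contiguous")
})
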