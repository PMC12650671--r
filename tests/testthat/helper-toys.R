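# Small fixtures shared across test files.  All geometry is generated in
# code; nothing is read from disk except files the tests write themselves.

straight_spec <- function(n = 2, noise = 0, seed = 1) {
  synthetic_spine_spec(
    n_vertebrae = n, level_labels = spine_levels(n),
    coronal_curve = list(target_cobb_deg = 0,
                         span = spine_levels(n)[c(1, n)]),
    sagittal_profile_deg = rep(0, n),
    noise_sd_mm = noise, seed = seed
  )
}

curved_spec <- function(cobb = 52, noise = 0, seed = 1, n = 18, ...) {
  synthetic_spine_spec(
    n_vertebrae = n, level_labels = spine_levels(n),
    coronal_curve = list(target_cobb_deg = cobb, span = c("L4", "T9")),
    noise_sd_mm = noise, seed = seed, ...
  )
}

## two stacked unit-ish vertebrae with a parallel 8 mm disc gap
toy_pair_params <- function(Lz = 20, gap = 8) {
  list(
    vertebra_params("L5", c(0, -15, Lz), c(36, 30, Lz)),
    vertebra_params("L4", c(0, -15, 2 * Lz + gap), c(36, 30, Lz))
  )
}

toy_pair_placed <- function(Lz = 20, gap = 8, resolution = c(3, 3, 3)) {
  tpl <- build_template(resolution)
  p <- toy_pair_params(Lz, gap)
  lower <- morph_and_place(tpl, p[[1]], 0L)
  upper <- morph_and_place(tpl, p[[2]], nrow(lower$nodes))
  list(lower = lower, upper = upper,
       nodes = rbind(lower$nodes, upper$nodes))
}

## hex volume by 2x2x2 Gauss integration of the Jacobian determinant
hex_volume <- function(X) {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  sum(apply(pts, 1, function(xi) spinefe:::hex8_bmatrix(X, xi)$detJ))
}

## dense assembly of a chain of beam elements along given nodes
## (6 DOF per node), clamp node 1, apply a tip force/moment vector
beam_chain_solve <- function(nodes, E, nu, diameter, tip_load) {
  n <- nrow(nodes)
  K <- matrix(0, 6 * n, 6 * n)
  for (e in seq_len(n - 1)) {
    Ke <- beam_stiffness(nodes[e:(e + 1), ], E, nu, diameter)
    idx <- c((e - 1) * 6 + 1:6, e * 6 + 1:6)
    K[idx, idx] <- K[idx, idx] + Ke
  }
  f <- numeric(6 * n)
  f[(n - 1) * 6 + 1:6] <- tip_load
  free <- 7:(6 * n)
  u <- numeric(6 * n)
  u[free] <- solve(K[free, free], f[free])
  u
}

table2_rom <- function() {
  list(pre = data.frame(scope = c("C7-T10", "T10-L4", "L4-L5"),
                        value = c(21.52, 14.53, 5.21),
                        stringsAsFactors = FALSE),
       post = data.frame(scope = c("C7-T10", "T10-L4", "L4-L5"),
                         value = c(36.31, 3.06, 2.04),
                         stringsAsFactors = FALSE))
}
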