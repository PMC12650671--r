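## Morph the canonical template to one vertebra's parameters and place
## it in the global frame: anisotropic scaling to the body lengths,
## endplate wedge taper, the Y-X-Z Euler rotation, and translation of
## the superior posterior attachment node onto p_sup_post.

#' Morph and place the template vertebra
#'
#' Scales the canonical extents to `(Lx, Ly, Lz)`, tapers the upper and
#' lower halves of the body by the superior/inferior endplate wedge
#' angles (`beta_sup - beta`, `beta_inf - beta`; linear ramp vanishing
#' at mid-height), applies the Euler chain `(beta, theta, phi)` and
#' translates the superior posterior node onto `p_sup_post`.  All hex
#' Jacobians must remain positive, otherwise an error reports the level
#' and wedge angles.
#'
#' @param tpl a [build_template()] object.
#' @param vp a [vertebra_params()] object.
#' @param id_offset integer added to all node ids (for assembly).
#' @return a `placed_vertebra`: globalized nodes, hexes with regions,
#'   attachment ids, the rotation matrix and the placement point.
#' @export
morph_and_place <- function(tpl, vp, id_offset = 0L) {
  stopifnot(inherits(tpl, "template_vertebra"),
            inherits(vp, "vertebra_params"))
  Lx <- vp$lengths[1]; Ly <- vp$lengths[2]; Lz <- vp$lengths[3]
  nodes <- tpl$nodes
  nodes[, 1] <- nodes[, 1] * Lx
  nodes[, 2] <- nodes[, 2] * Ly
  nodes[, 3] <- nodes[, 3] * Lz

  w_sup <- deg2rad(vp$beta_sup_deg - vp$beta_deg)
  w_inf <- deg2rad(vp$beta_inf_deg - vp$beta_deg)
  ramp_sup <- pmax(0, 1 + 2 * nodes[, 3] / Lz)   # 1 at z = 0, 0 at -Lz/2
  ramp_inf <- pmax(0, -1 - 2 * nodes[, 3] / Lz)  # 1 at z = -Lz
  nodes[, 3] <- nodes[, 3] -
    tan(w_sup) * nodes[, 1] * ramp_sup -
    tan(w_inf) * nodes[, 1] * ramp_inf

  R <- euler_rotation(vp$beta_deg, vp$theta_deg, vp$phi_deg)
  nodes <- nodes %*% t(R)
  nodes <- sweep(nodes, 2, vp$p_sup_post, "+")

  jmin <- min(vapply(seq_len(nrow(tpl$hex)), function(e) {
    hex_min_jacobian(nodes[tpl$hex[e, ], , drop = FALSE])
  }, numeric(1)))
  if (jmin <= 0) {
    stop(sprintf(paste0("level %s: element inverted during morphing ",
                        "(wedge sup %.1f deg, inf %.1f deg)"),
                 vp$level, rad2deg(w_sup), rad2deg(w_inf)))
  }

  attach <- lapply(tpl$attach, function(a) a + id_offset)
  structure(list(level = vp$level, nodes = nodes,
                 hex = tpl$hex + id_offset, hex_region = tpl$hex_region,
                 attach = attach, R = R, p = vp$p_sup_post, params = vp,
                 cross_section = tpl$cross_section,
                 resolution = tpl$resolution, id_offset = id_offset),
            class = "placed_vertebra")
}
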