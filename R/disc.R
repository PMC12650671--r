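## Intervertebral disc builder: thin cartilage endplate layers bonded to
## the facing bony endplates, an annulus ground-substance ring with a
## nucleus pulposus core (target 44% of the cross-section, centred
## slightly posteriorly), and two criss-cross families of tension-only
## fiber trusses on the annulus wall at +/- the configured angle to the
## transverse plane.

## point q on the ring polyline (walked from `start` in direction `dir`)
## whose horizontal (xy) chord distance from p equals `chord`; returns
## the bracketing ring indices, the interpolation parameter and coords
ring_chord_point <- function(p, ring, start, dir, chord) {
  n <- nrow(ring)
  idx <- function(i) ((i - 1) %% n) + 1
  a <- start
  max_steps <- floor(n / 3)
  for (s in seq_len(max_steps)) {
    b <- idx(start + dir * s)
    qa <- ring[a, ]; qb <- ring[b, ]
    w <- qa[1:2] - p[1:2]; d <- qb[1:2] - qa[1:2]
    A <- sum(d^2); B <- 2 * sum(w * d); C <- sum(w^2) - chord^2
    disc <- B^2 - 4 * A * C
    if (disc >= 0 && A > 0) {
      t <- (-B + sqrt(disc)) / (2 * A)
      if (t >= 0 && t <= 1) {
        return(list(a = a, b = b, t = t, coord = qa + t * (qb - qa)))
      }
    }
    a <- b
  }
  ## chord unreachable (tiny ring): clamp to the farthest point walked
  list(a = a, b = a, t = 0, coord = ring[a, ])
}

#' Build one intervertebral disc
#'
#' Connects the superior endplate grid of the caudal vertebra to the
#' inferior endplate grid of the cranial vertebra with three hex layers
#' (cartilage endplate / annulus+nucleus core / cartilage endplate) and
#' adds the criss-cross fiber trusses.  The facing grids must share the
#' template resolution; a negative column height anywhere is an error.
#'
#' @param lower,upper `placed_vertebra` objects (caudal, cranial).
#' @param nodes global node matrix containing the rows referenced by the
#'   two vertebrae's attachment ids.
#' @param cfg a [disc_config()].
#' @return a fragment: `new_nodes`, `hex`, `hex_info`, `truss`,
#'   `truss_info`, `constraints`, `seg` (e.g. `"T9-T10"`).
#' @export
build_disc <- function(lower, upper, nodes, cfg = disc_config()) {
  stopifnot(inherits(lower, "placed_vertebra"),
            inherits(upper, "placed_vertebra"))
  if (!identical(lower$resolution[1:2], upper$resolution[1:2])) {
    stop("facing endplate grids do not match: ", lower$level, " vs ",
         upper$level)
  }
  nx <- lower$resolution[1]; ny <- lower$resolution[2]
  gl <- lower$attach$grid_sup   # (nx+1) x (ny+1) global ids
  gu <- upper$attach$grid_inf
  Pl <- nodes[as.vector(gl), , drop = FALSE]
  Pu <- nodes[as.vector(gu), , drop = FALSE]
  cols <- Pu - Pl
  ## reference direction: outward normal of the lower superior endplate
  normal <- drop(lower$R %*% c(0, 0, 1))
  if (any(cols %*% normal <= 0)) {
    stop("inverted disc between ", lower$level, " and ", upper$level,
         ": negative height")
  }
  seg <- paste0(upper$level, "-", lower$level)

  t1 <- cfg$endplate_frac; t2 <- 1 - cfg$endplate_frac
  base_id <- nrow(nodes)
  n_grid <- (nx + 1) * (ny + 1)
  L1 <- Pl + t1 * cols; L2 <- Pl + t2 * cols
  new_nodes <- rbind(L1, L2)
  id1 <- matrix(base_id + seq_len(n_grid), nx + 1, ny + 1)
  id2 <- matrix(base_id + n_grid + seq_len(n_grid), nx + 1, ny + 1)
  layers <- list(gl, id1, id2, gu)

  ## nucleus cells: greedily grow an elliptical core (centre shifted
  ## posteriorly) until the covered area fraction is as close to the
  ## target as the cell grid allows
  cs <- lower$cross_section
  cy0 <- 0.5 - cfg$nucleus_posterior_shift
  d <- sqrt((cs$centers[, 1] / 0.5)^2 + ((cs$centers[, 2] - cy0) / 0.5)^2)
  ord <- order(d)
  cum <- cumsum(cs$areas[ord]) / sum(cs$areas)
  k <- which.min(abs(cum - cfg$nucleus_area_frac))
  nucleus_cells <- sort(ord[seq_len(k)])

  hexes <- list(); mat <- character(0); region <- character(0)
  sub <- character(0)
  cell <- 0L
  for (j in 0:(ny - 1)) {
    for (i in 0:(nx - 1)) {
      ## cross_section cells were built i-fastest
      cell <- i + j * nx + 1L
      core_mat <- if (cell %in% nucleus_cells) "nucleus" else "ground"
      q <- function(g) c(g[i + 1, j + 1], g[i + 2, j + 1],
                         g[i + 2, j + 2], g[i + 1, j + 2])
      for (l in 1:3) {
        hexes[[length(hexes) + 1L]] <- c(q(layers[[l]]), q(layers[[l + 1]]))
        if (l == 1) {
          mat <- c(mat, "endplate"); region <- c(region, "endplate")
          sub <- c(sub, paste0(lower$level, "_sup"))
        } else if (l == 3) {
          mat <- c(mat, "endplate"); region <- c(region, "endplate")
          sub <- c(sub, paste0(upper$level, "_inf"))
        } else {
          mat <- c(mat, core_mat); region <- c(region, core_mat)
          sub <- c(sub, "")
        }
      }
    }
  }
  hex <- do.call(rbind, hexes)
  hex_info <- data.frame(mat = mat, region = region, sub = sub,
                         level = NA_character_, seg = seg,
                         stringsAsFactors = FALSE)

  ## criss-cross fibers on the annulus wall
  perim <- grid_perimeter_idx(nx, ny)
  all_nodes <- rbind(nodes, new_nodes)
  tan_a <- tan(deg2rad(cfg$fiber_angle_deg))
  truss <- list(); constraints <- list()
  fib_nodes <- list()
  next_id <- base_id + 2 * n_grid
  for (g in 1:3) {
    rb <- as.vector(layers[[g]])[perim]
    rt <- as.vector(layers[[g + 1]])[perim]
    Pb <- all_nodes[rb, , drop = FALSE]
    Pt <- all_nodes[rt, , drop = FALSE]
    for (s in seq_along(rb)) {
      dz <- Pt[s, 3] - Pb[s, 3]
      chord <- max(dz, 1e-9) / tan_a
      for (dir in c(1L, -1L)) {
        cp <- ring_chord_point(Pb[s, ], Pt, s, dir, chord)
        if (cp$t < 1e-9) {
          top_id <- rt[cp$a]
        } else if (cp$t > 1 - 1e-9) {
          top_id <- rt[cp$b]
        } else {
          next_id <- next_id + 1L
          top_id <- next_id
          fib_nodes[[length(fib_nodes) + 1L]] <- cp$coord
          constraints[[length(constraints) + 1L]] <-
            list(slave = top_id, masters = c(rt[cp$a], rt[cp$b]),
                 weights = c(1 - cp$t, cp$t))
        }
        truss[[length(truss) + 1L]] <- c(rb[s], top_id)
      }
    }
  }
  truss <- do.call(rbind, truss)
  truss_info <- data.frame(type = "fiber",
                           family = rep(c("plus", "minus"),
                                        length.out = nrow(truss)),
                           area = cfg$fiber_area_mm2, tension_only = TRUE,
                           seg = seg, stringsAsFactors = FALSE)
  if (length(fib_nodes)) {
    new_nodes <- rbind(new_nodes, do.call(rbind, fib_nodes))
  }
  list(new_nodes = new_nodes, hex = hex, hex_info = hex_info,
       truss = truss, truss_info = truss_info, constraints = constraints,
       seg = seg, nucleus_cells = nucleus_cells)
}
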