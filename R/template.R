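## Parametric template vertebra in a canonical frame: the superior
## posterior midline point sits at the origin, the body occupies the
## unit box x in [-1/2, 1/2], y in [0, 1], z in [-1, 0] (mediolateral,
## posterior-to-anterior, inferior-to-superior), with a superellipse
## cross-section rounding.  Coarse hex blocks for pedicles, laminae,
## spinous and transverse processes attach to the posterior face.

grid_node_id <- function(i, j, k, nx, ny) {
  1L + i + j * (nx + 1L) + k * (nx + 1L) * (ny + 1L)
}

## pull the square cross-section toward a superellipse (rounded
## rectangle); nodes on the x/y axes are unchanged
round_cross_section <- function(x, y, p = 4) {
  xi <- 2 * x
  eta <- 2 * y - 1
  r_box <- pmax(abs(xi), abs(eta))
  r_se <- (abs(xi)^p + abs(eta)^p)^(1 / p)
  f <- ifelse(r_box > 0, r_box / r_se, 1)
  list(x = x * f, y = 0.5 + (y - 0.5) * f)
}

## indices (1-based, into an (nx+1) x (ny+1) grid stored i-fastest) of
## the boundary walked counter-clockwise starting at (0, 0)
grid_perimeter_idx <- function(nx, ny) {
  ij <- rbind(
    cbind(0:nx, 0L),
    cbind(nx, seq_len(ny)),
    cbind((nx - 1L):0L, ny),
    cbind(0L, (ny - 1L):1L)
  )
  ij[, 1] + ij[, 2] * (nx + 1L) + 1L
}

## flip a hex (swap bottom/top faces) if its centre jacobian is negative
orient_hex <- function(conn, nodes) {
  if (hex_jacobian_center(nodes[conn, , drop = FALSE]) < 0) {
    conn[c(5:8, 1:4)]
  } else {
    conn
  }
}

#' Build the parametric template vertebra
#'
#' The vertebral body is an `nx` x `ny` x `nz` hexahedral grid over the
#' canonical unit box with a rounded (superellipse) cross-section; the
#' outer element layer is tagged cortical and the interior cancellous.
#' Coarse posterior blocks (two pedicles, two laminae meeting at the
#' midline, a two-block spinous process and two transverse processes)
#' are extruded from the posterior face and tagged `posterior`.  Named
#' attachment nodes (endplate rim/grid, pedicle node sets, spinous and
#' transverse tips, facet patches, anterior/posterior midline points)
#' support disc, ligament and instrumentation construction.  Node and
#' element counts are deterministic functions of the resolution.
#'
#' @param resolution integer vector `(nx, ny, nz)`, each >= 3 so a
#'   one-element cortical shell encloses at least one cancellous element.
#' @return object of class `template_vertebra` with fields `nodes`
#'   (canonical coordinates), `hex`, `hex_region`, `attach`,
#'   `cross_section` (cell centres/areas for the disc builder) and
#'   `resolution`.
#' @export
build_template <- function(resolution = c(3, 3, 3)) {
  stopifnot(length(resolution) == 3)
  nx <- as.integer(resolution[1]); ny <- as.integer(resolution[2])
  nz <- as.integer(resolution[3])
  if (any(c(nx, ny, nz) < 3)) {
    stop("resolution too small to host a cortical shell (need >= 3)")
  }
  xs <- -0.5 + (0:nx) / nx
  ys <- (0:ny) / ny
  zs <- -1 + (0:nz) / nz
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  rc <- round_cross_section(xs[g$i + 1L], ys[g$j + 1L])
  nodes <- cbind(x = rc$x, y = rc$y, z = zs[g$k + 1L])

  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  hex <- cbind(
    grid_node_id(cells$i,      cells$j,      cells$k,      nx, ny),
    grid_node_id(cells$i + 1L, cells$j,      cells$k,      nx, ny),
    grid_node_id(cells$i + 1L, cells$j + 1L, cells$k,      nx, ny),
    grid_node_id(cells$i,      cells$j + 1L, cells$k,      nx, ny),
    grid_node_id(cells$i,      cells$j,      cells$k + 1L, nx, ny),
    grid_node_id(cells$i + 1L, cells$j,      cells$k + 1L, nx, ny),
    grid_node_id(cells$i + 1L, cells$j + 1L, cells$k + 1L, nx, ny),
    grid_node_id(cells$i,      cells$j + 1L, cells$k + 1L, nx, ny)
  )
  boundary <- cells$i %in% c(0L, nx - 1L) | cells$j %in% c(0L, ny - 1L) |
    cells$k %in% c(0L, nz - 1L)
  hex_region <- ifelse(boundary, "cortical", "cancellous")

  add_nodes <- function(coords) {
    ids <- nrow(nodes) + seq_len(nrow(coords))
    nodes <<- rbind(nodes, coords)
    ids
  }
  new_hexes <- list(); new_regions <- character(0)
  push_hex <- function(conn, region) {
    new_hexes[[length(new_hexes) + 1L]] <<- orient_hex(conn, nodes)
    new_regions <<- c(new_regions, region)
  }

  ped_depth <- 0.30; lam_depth <- 0.25; spin_depth <- 0.30
  lam_halfwidth <- 0.15; tp_len <- 0.30

  ## pedicles: extrude the two upper lateral posterior face cells
  ped <- list(L = list(i = 0L), R = list(i = nx - 1L))
  k0 <- nz - 1L
  midline_lam <- NULL; midline_spin <- NULL
  for (side in c("L", "R")) {
    i0 <- ped[[side]]$i
    front <- c(grid_node_id(i0, 0L, k0, nx, ny),
               grid_node_id(i0 + 1L, 0L, k0, nx, ny),
               grid_node_id(i0, 0L, k0 + 1L, nx, ny),
               grid_node_id(i0 + 1L, 0L, k0 + 1L, nx, ny))
    back <- add_nodes(nodes[front, , drop = FALSE] +
                        matrix(c(0, -ped_depth, 0), 4, 3, byrow = TRUE))
    push_hex(c(front[1], back[1], back[2], front[2],
               front[3], back[3], back[4], front[4]), "posterior")
    ped[[side]]$front <- front
    ped[[side]]$back <- back
    ped[[side]]$set <- c(front, back)
  }

  ## laminae: from each pedicle back face to a midline-adjacent face;
  ## the two midline node columns are shared between sides
  zs2 <- nodes[ped$L$back[c(1, 3)], 3]
  y_lam <- -(ped_depth + lam_depth)
  mid_lam <- add_nodes(cbind(0, y_lam, zs2))
  lam <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    outer <- add_nodes(cbind(sgn * lam_halfwidth, y_lam, zs2))
    back <- if (side == "L") {
      c(outer[1], mid_lam[1], outer[2], mid_lam[2])
    } else {
      c(mid_lam[1], outer[1], mid_lam[2], outer[2])
    }
    front <- ped[[side]]$back  # ordered (i, i+1) x (k, k+1)
    push_hex(c(front[1], front[2], back[2], back[1],
               front[3], front[4], back[4], back[3]), "posterior")
    lam[[side]] <- list(front = front, back = back, outer = outer)
  }

  ## spinous process: extrude both lamina back faces further posteriorly
  y_spin <- y_lam - spin_depth
  mid_spin <- add_nodes(cbind(0, y_spin, zs2))
  spin <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    outer <- add_nodes(cbind(sgn * lam_halfwidth, y_spin, zs2))
    back <- if (side == "L") {
      c(outer[1], mid_spin[1], outer[2], mid_spin[2])
    } else {
      c(mid_spin[1], outer[1], mid_spin[2], outer[2])
    }
    front <- lam[[side]]$back
    push_hex(c(front[1], front[2], back[2], back[1],
               front[3], front[4], back[4], back[3]), "posterior")
    spin[[side]] <- list(back = back, outer = outer)
  }

  ## transverse processes: extrude the outer side face of each pedicle
  tp <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    i_face <- if (side == "L") c(1L, 3L) else c(2L, 4L)
    f_front <- ped[[side]]$front[i_face]   # (k, k+1) on the body face
    f_back <- ped[[side]]$back[i_face]
    face <- c(f_front[1], f_back[1], f_front[2], f_back[2])
    outer <- add_nodes(nodes[face, , drop = FALSE] +
                         matrix(c(sgn * tp_len, 0, 0), 4, 3, byrow = TRUE))
    push_hex(c(face[1], face[2], outer[2], outer[1],
               face[3], face[4], outer[4], outer[3]), "posterior")
    tp[[side]] <- list(outer = outer)
  }

  hex <- rbind(hex, do.call(rbind, new_hexes))
  hex_region <- c(hex_region, new_regions)

  i_mid <- which.min(abs(xs)) - 1L
  ep_grid <- function(k) {
    outer(0:nx, 0:ny, function(i, j) grid_node_id(i, j, k, nx, ny))
  }
  grid_sup <- ep_grid(nz); grid_inf <- ep_grid(0L)
  rim_sup <- grid_sup[grid_perimeter_idx(nx, ny)]
  rim_inf <- grid_inf[grid_perimeter_idx(nx, ny)]

  attach <- list(
    sup_post = grid_node_id(i_mid, 0L, nz, nx, ny),
    post_inf = grid_node_id(i_mid, 0L, 0L, nx, ny),
    ant_sup = grid_node_id(i_mid, ny, nz, nx, ny),
    ant_inf = grid_node_id(i_mid, ny, 0L, nx, ny),
    rim_sup = rim_sup, rim_inf = rim_inf,
    grid_sup = grid_sup, grid_inf = grid_inf,
    ped_L = ped$L$set, ped_R = ped$R$set,
    facet_sup_L = ped$L$back[4], facet_sup_R = ped$R$back[3],
    facet_inf_L = lam$L$outer[1], facet_inf_R = lam$R$outer[1],
    lam_lo_L = lam$L$outer[1], lam_hi_L = lam$L$outer[2],
    lam_lo_R = lam$R$outer[1], lam_hi_R = lam$R$outer[2],
    isl_node = mid_spin[2], spin_tip = mid_spin[1],
    tt_L = tp$L$outer[1], tt_R = tp$R$outer[1],
    ant_row_sup = grid_sup[, ny + 1L], post_row_sup = grid_sup[, 1L]
  )

  ## cross-section cells (at the inferior face) for the disc builder
  cc <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  centers <- matrix(0, nrow(cc), 2); areas <- numeric(nrow(cc))
  for (r in seq_len(nrow(cc))) {
    ids <- c(grid_node_id(cc$i[r], cc$j[r], 0L, nx, ny),
             grid_node_id(cc$i[r] + 1L, cc$j[r], 0L, nx, ny),
             grid_node_id(cc$i[r] + 1L, cc$j[r] + 1L, 0L, nx, ny),
             grid_node_id(cc$i[r], cc$j[r] + 1L, 0L, nx, ny))
    xy <- nodes[ids, 1:2]
    centers[r, ] <- colMeans(xy)
    areas[r] <- polygon_area(xy)
  }

  structure(list(nodes = nodes, hex = hex, hex_region = hex_region,
                 attach = attach,
                 cross_section = list(centers = centers, areas = areas),
                 resolution = c(nx, ny, nz)),
            class = "template_vertebra")
}

#' @export
print.template_vertebra <- function(x, ...) {
  cat("template_vertebra:", nrow(x$nodes), "nodes,", nrow(x$hex),
      "hexes (", sum(x$hex_region == "cortical"), "cortical,",
      sum(x$hex_region == "cancellous"), "cancellous,",
      sum(x$hex_region == "posterior"), "posterior )\n")
  invisible(x)
}

## shoelace area of a planar polygon given as an n x 2 matrix
polygon_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}
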