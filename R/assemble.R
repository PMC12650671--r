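## Spine assembly: morph/place every vertebra, build the 17 discs for 18
## vertebrae, attach ligaments, deduplicate nodes, and record the node
## sets the solver and the measurement code rely on.

#' Assembly configuration
#'
#' @param resolution template vertebra resolution `(nx, ny, nz)`.
#' @param disc a [disc_config()].
#' @param materials a [default_materials()] table.
#' @param merge_tol node-merge tolerance in mm (well below any geometric
#'   feature).
#' @param head_offset_mm posterior offset of the screw head (rod line)
#'   from the pedicle centroid.
#' @param screw_subdiv,rod_subdiv beam elements per screw / per rod span.
#' @return list of class `spine_config`.
#' @export
spine_config <- function(resolution = c(3, 3, 3), disc = disc_config(),
                         materials = default_materials(),
                         merge_tol = 1e-6, head_offset_mm = 15,
                         screw_subdiv = 2L, rod_subdiv = 2L) {
  structure(list(resolution = resolution, disc = disc,
                 materials = materials, merge_tol = merge_tol,
                 head_offset_mm = head_offset_mm,
                 screw_subdiv = as.integer(screw_subdiv),
                 rod_subdiv = as.integer(rod_subdiv)),
            class = "spine_config")
}

## interpenetration test of consecutive vertebral bodies: probe a
## lattice of interior points of the upper body, expressed in the lower
## body's canonical frame
check_interpenetration <- function(placed) {
  fr <- c(0.2, 0.5, 0.8)
  probe0 <- as.matrix(expand.grid(x = fr - 0.5, y = fr, z = -fr))
  for (i in seq_len(length(placed) - 1)) {
    lo <- placed[[i]]; up <- placed[[i + 1]]
    Lu <- up$params$lengths
    pts <- sweep(probe0 %*% diag(Lu) %*% t(up$R), 2, up$p, "+")
    q <- sweep(pts, 2, lo$p) %*% lo$R   # = t(R) applied to rows
    L <- lo$params$lengths
    margin <- 0.1
    inside <- q[, 1] > -L[1] / 2 + margin & q[, 1] < L[1] / 2 - margin &
      q[, 2] > margin & q[, 2] < L[2] - margin &
      q[, 3] > -L[3] + margin & q[, 3] < -margin
    if (any(inside)) {
      stop("vertebrae overlap: ", lo$level, " and ", up$level)
    }
  }
  invisible(TRUE)
}

merge_mesh_nodes <- function(spine, tol) {
  key <- apply(round(spine$nodes / tol), 1, paste, collapse = ",")
  first <- match(key, key)
  if (all(first == seq_along(key))) return(spine)
  keep <- sort(unique(first))
  remap <- integer(length(key))
  remap[keep] <- seq_along(keep)
  map <- remap[first]
  spine$nodes <- spine$nodes[keep, , drop = FALSE]
  relabel <- function(x) {
    if (is.null(x)) return(x)
    if (is.matrix(x)) matrix(map[x], nrow(x), ncol(x)) else map[x]
  }
  spine$hex <- relabel(spine$hex)
  spine$truss <- relabel(spine$truss)
  spine$beam <- relabel(spine$beam)
  spine$node_sets <- lapply(spine$node_sets, relabel)
  spine$constraints <- lapply(spine$constraints, function(cn) {
    cn$slave <- map[cn$slave]; cn$masters <- map[cn$masters]; cn
  })
  spine$node_level <- spine$node_level[keep]
  spine
}

#' Assemble the full spine mesh
#'
#' @param params list of [vertebra_params()], ordered caudal to cranial
#'   (at least two).
#' @param config a [spine_config()].
#' @return object of class `spine_mesh`: global nodes (mm), hex elements
#'   with material/region tags, tension-only trusses (fibers and
#'   ligaments), linear constraints, per-level frames, node sets
#'   (inferior face of the most caudal vertebra, anterior/posterior load
#'   rows of the most cranial one, per-level endplate grids) and a
#'   manifest of counts.
#' @export
assemble_spine <- function(params, config = spine_config()) {
  if (length(params) < 2) stop("need at least two vertebrae")
  z <- vapply(params, function(p) p$p_sup_post[3], numeric(1))
  if (any(diff(z) <= 0)) {
    stop("params must be ordered caudal to cranial (increasing Z)")
  }
  labels <- vapply(params, function(p) p$level, character(1))
  tpl <- build_template(config$resolution)

  placed <- list(); nodes <- NULL
  for (i in seq_along(params)) {
    off <- if (is.null(nodes)) 0L else nrow(nodes)
    pv <- morph_and_place(tpl, params[[i]], id_offset = off)
    placed[[i]] <- pv
    nodes <- rbind(nodes, pv$nodes)
  }
  check_interpenetration(placed)

  node_level <- rep(labels, each = nrow(tpl$nodes))
  hex <- do.call(rbind, lapply(placed, function(p) p$hex))
  hex_info <- do.call(rbind, lapply(placed, function(p) {
    data.frame(mat = p$hex_region, region = p$hex_region, sub = "",
               level = p$level, seg = NA_character_,
               stringsAsFactors = FALSE)
  }))

  truss <- NULL; truss_info <- NULL; constraints <- list()
  for (i in seq_len(length(placed) - 1)) {
    frag <- build_disc(placed[[i]], placed[[i + 1]], nodes, config$disc)
    nodes <- rbind(nodes, frag$new_nodes)
    node_level <- c(node_level, rep(paste0("disc:", frag$seg),
                                    nrow(frag$new_nodes)))
    hex <- rbind(hex, frag$hex)
    hex_info <- rbind(hex_info,
                      data.frame(mat = frag$hex_info$mat,
                                 region = frag$hex_info$region,
                                 sub = frag$hex_info$sub,
                                 level = NA_character_,
                                 seg = frag$seg, stringsAsFactors = FALSE))
    truss <- rbind(truss, frag$truss)
    truss_info <- rbind(truss_info, frag$truss_info)
    constraints <- c(constraints, frag$constraints)
  }

  lig <- attach_ligaments(placed, mats = config$materials)
  truss <- rbind(truss, lig$truss)
  truss_info <- rbind(truss_info, lig$truss_info)

  last <- placed[[length(placed)]]
  node_sets <- list(
    inferior_face = placed[[1]]$attach$grid_inf,
    load_anterior = last$attach$ant_row_sup,
    load_posterior = last$attach$post_row_sup
  )
  for (p in placed) {
    node_sets[[paste0(p$level, "_endplate_sup")]] <- as.vector(p$attach$grid_sup)
    node_sets[[paste0(p$level, "_endplate_inf")]] <- as.vector(p$attach$grid_inf)
    node_sets[[paste0(p$level, "_body")]] <-
      p$id_offset + seq_len(nrow(p$nodes))
  }
  frames <- lapply(placed, function(p) list(R = p$R, p = p$p))
  names(frames) <- labels
  ped_sets <- lapply(placed, function(p) {
    list(L = p$attach$ped_L, R = p$attach$ped_R)
  })
  names(ped_sets) <- labels

  spine <- structure(
    list(nodes = nodes, hex = hex, hex_info = hex_info,
         truss = truss, truss_info = truss_info,
         beam = NULL, beam_info = NULL,
         constraints = constraints, node_sets = node_sets,
         node_level = node_level, levels = labels, frames = frames,
         ped_sets = ped_sets, params = params, config = config),
    class = "spine_mesh")
  spine <- merge_mesh_nodes(spine, config$merge_tol)
  spine$manifest <- mesh_manifest(spine)
  spine
}

#' Counts per element group
#' @param spine a `spine_mesh`.
#' @return named list of counts.
#' @export
mesh_manifest <- function(spine) {
  li <- spine$truss_info
  list(
    n_nodes = nrow(spine$nodes),
    n_vertebrae = length(spine$levels),
    n_discs = length(unique(spine$hex_info$seg[!is.na(spine$hex_info$seg)])),
    n_hex = nrow(spine$hex),
    hex_by_mat = as.list(table(spine$hex_info$mat)),
    n_truss = if (is.null(spine$truss)) 0L else nrow(spine$truss),
    truss_by_type = if (is.null(li)) list() else as.list(table(li$type)),
    n_beam = if (is.null(spine$beam)) 0L else nrow(spine$beam),
    n_screws = if (is.null(spine$beam_info)) 0L else
      length(unique(spine$beam_info$screw_id[spine$beam_info$role == "screw"])),
    n_rods = if (is.null(spine$beam_info)) 0L else
      length(unique(spine$beam_info$rod_id[spine$beam_info$role == "rod"])),
    n_connectors = if (is.null(spine$beam_info)) 0L else
      sum(spine$beam_info$role == "connector"),
    n_constraints = length(spine$constraints)
  )
}

#' @export
print.spine_mesh <- function(x, ...) {
  m <- x$manifest
  cat("spine_mesh:", m$n_vertebrae, "vertebrae,", m$n_discs, "discs |",
      m$n_nodes, "nodes,", m$n_hex, "hexes,", m$n_truss, "trusses,",
      m$n_beam, "beams\n")
  invisible(x)
}
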