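## Geometric and kinematic measures: Cobb and thoracolumbar-kyphosis
## (TLK) angles from endplate sampling lines, per-axis mean absolute
## error against reference coordinates, segmental range of motion from
## rigid-body fits, and stress maxima over named element groups.

#' Endplate sampling geometry from parameters
#'
#' Reconstructs, per level, the eight sampling points (A..H) used by the
#' angle measurements, from the per-vertebra parameters.
#'
#' @param params list of [vertebra_params()] or a `ground_truth`.
#' @return object of class `spine_geometry` (named list of 8 x 3 point
#'   matrices).
#' @export
spine_geometry <- function(params) {
  if (inherits(params, "ground_truth")) params <- params$params
  pts <- lapply(params, vertebra_sample_points)
  names(pts) <- vapply(params, function(p) p$level, character(1))
  structure(pts, class = "spine_geometry")
}

angle_between_lines <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-9 || nb < 1e-9) {
    stop("near-zero projected endplate vector (endplate parallel to the ",
         "projection direction)")
  }
  rad2deg(acos(pmin(1, abs(sum(a * b) / (na * nb)))))
}

level_points <- function(geom, level) {
  P <- geom[[level]]
  if (is.null(P)) stop("level not in geometry: ", level)
  P
}

#' Cobb angle
#'
#' Angle between the coronal-plane projections of the upper end
#' vertebra's superior endplate line (E to F) and the lower end
#' vertebra's inferior endplate line (G to H), in degrees within
#' \[0, 90\].  With `projected = FALSE` the 3D vector angle is returned
#' instead (diagnostic for the projection-vs-3D skew discussion); with
#' axial rotation present the 3D angle is at least the projected one.
#'
#' @param geom a [spine_geometry()].
#' @param upper_level,lower_level end vertebrae of the curve.
#' @param projected project onto the coronal plane (default) or use 3D
#'   vectors.
#' @return angle in degrees.
#' @export
cobb_angle <- function(geom, upper_level, lower_level, projected = TRUE) {
  u <- level_points(geom, upper_level)
  l <- level_points(geom, lower_level)
  a <- u["F", ] - u["E", ]
  b <- l["H", ] - l["G", ]
  if (projected) {
    a <- a[c(1, 3)]; b <- b[c(1, 3)]
  }
  angle_between_lines(a, b)
}

#' Thoracolumbar kyphosis (TLK) angle
#'
#' As [cobb_angle()] but projected onto the sagittal plane, between the
#' upper level's superior endplate line (A to B) and the lower level's
#' inferior endplate line (C to D).  Default levels are the standard
#' thoracolumbar junction definition, T10 superior to L2 inferior.
#'
#' @inheritParams cobb_angle
#' @return angle in degrees.
#' @export
tlk_angle <- function(geom, upper_level = "T10", lower_level = "L2",
                      projected = TRUE) {
  u <- level_points(geom, upper_level)
  l <- level_points(geom, lower_level)
  a <- u["B", ] - u["A", ]
  b <- l["D", ] - l["C", ]
  if (projected) {
    a <- a[2:3]; b <- b[2:3]
  }
  angle_between_lines(a, b)
}

#' Per-axis mean absolute error against reference coordinates
#'
#' Mean over levels of the absolute per-axis coordinate differences
#' between the model's per-vertebra comparison points and a reference
#' (CT-like) coordinate table; the sum of absolute differences is
#' divided by the number of levels.
#'
#' @param model_coords,reference_coords n x 3 matrices with matching
#'   ordered levels (rownames, if present, must agree).
#' @return object of class `mae_result` with `mae` (named X/Y/Z, mm),
#'   `per_level` absolute differences, and `n_levels`.
#' @export
mae <- function(model_coords, reference_coords) {
  if (!all(dim(model_coords) == dim(reference_coords))) {
    stop("level mismatch between model and reference coordinates")
  }
  if (!is.null(rownames(model_coords)) &&
      !is.null(rownames(reference_coords)) &&
      !identical(rownames(model_coords), rownames(reference_coords))) {
    stop("level mismatch between model and reference coordinates")
  }
  ad <- abs(model_coords - reference_coords)
  m <- colMeans(ad)
  names(m) <- c("X", "Y", "Z")
  structure(list(mae = m, per_level = ad, n_levels = nrow(ad)),
            class = "mae_result")
}

#' @export
print.mae_result <- function(x, ...) {
  cat(sprintf("MAE over %d levels: X %.2f mm, Y %.2f mm, Z %.2f mm\n",
              x$n_levels, x$mae[1], x$mae[2], x$mae[3]))
  invisible(x)
}

parse_segment <- function(seg) strsplit(seg, "-", fixed = TRUE)[[1]]

#' Segmental range of motion
#'
#' Sagittal rotation between two levels: each vertebra's rigid-body
#' rotation comes from a least-squares fit of its nodal displacements,
#' and the segment ROM is the difference of the sagittal components
#' (flexion positive).  ROM is additive over nested blocks.
#'
#' @param spine a `spine_mesh`.
#' @param result a `solve_result`.
#' @param levelA,levelB the two levels bounding the segment (either
#'   order; the more cranial minus the more caudal rotation is
#'   returned).
#' @return list of class `segment_rom` with `segment`, `rom_deg`,
#'   `method`.
#' @export
segmental_rom <- function(spine, result, levelA, levelB) {
  rot <- result$vertebra_rotation_deg
  for (lv in c(levelA, levelB)) {
    if (!lv %in% names(rot)) stop("level not in model: ", lv)
  }
  ia <- match(levelA, spine$levels); ib <- match(levelB, spine$levels)
  cranial <- if (ia > ib) levelA else levelB
  caudal <- if (ia > ib) levelB else levelA
  structure(list(segment = paste0(cranial, "-", caudal),
                 rom_deg = rot[[cranial]] - rot[[caudal]],
                 method = "rigid_fit"),
            class = "segment_rom")
}

#' ROM of a segment given by a "upper-lower" label
#' @keywords internal
segment_rom_value <- function(spine, result, seg) {
  lv <- parse_segment(seg)
  segmental_rom(spine, result, lv[1], lv[2])$rom_deg
}

hex_centroids <- function(spine, elems) {
  t(vapply(elems, function(e) {
    colMeans(spine$nodes[spine$hex[e, ], , drop = FALSE])
  }, numeric(3)))
}

#' Stress maximum over a named element group
#'
#' Maximum centroid von Mises stress (kPa) over an endplate or an
#' annulus group, with the argmax element and a side tag
#' (ventral/dorsal, left/right octant relative to the group centroid).
#'
#' @param spine a `spine_mesh`.
#' @param result a `solve_result` (or the output of
#'   [compute_stresses()]).
#' @param scope list: either `list(type = "endplate", level = "T10",
#'   side = "sup")` for the cartilage endplate bonded to that bony
#'   endplate, or `list(type = "annulus", segment = "T9-T10")` for the
#'   segment's annulus ground substance plus fiber set.
#' @return list with `max_kpa`, `element` (id or truss id), `kind`
#'   (`"hex"`/`"truss"`), and `side` tag.
#' @export
stress_maxima <- function(spine, result, scope) {
  hi <- spine$hex_info
  if (scope$type == "endplate") {
    sub <- paste0(scope$level, "_", scope$side)
    elems <- which(hi$region == "endplate" & hi$sub == sub)
    if (!length(elems)) stop("empty element group: endplate ", sub)
    vm <- result$hex_vm_kpa[elems]
    best <- which.max(vm)
    e <- elems[best]
    ctr <- hex_centroids(spine, elems)
    rel <- ctr[best, ] - colMeans(ctr)
    side <- paste0(if (rel[2] >= 0) "ventral" else "dorsal", "-",
                   if (rel[1] >= 0) "left" else "right")
    return(list(max_kpa = vm[best], element = e, kind = "hex",
                side = side))
  }
  if (scope$type == "annulus") {
    elems <- which(hi$region == "ground" & !is.na(hi$seg) &
                     hi$seg == scope$segment)
    ti <- spine$truss_info
    tr <- which(ti$type == "fiber" & ti$seg == scope$segment)
    if (!length(elems) && !length(tr)) {
      stop("empty element group: annulus ", scope$segment)
    }
    vm_hex <- if (length(elems)) result$hex_vm_kpa[elems] else numeric(0)
    vm_tr <- if (length(tr)) abs(result$truss_stress_kpa[tr]) else numeric(0)
    if (length(vm_hex) && (!length(vm_tr) || max(vm_hex) >= max(vm_tr))) {
      best <- which.max(vm_hex)
      e <- elems[best]
      ctr <- hex_centroids(spine, elems)
      rel <- ctr[best, ] - colMeans(ctr)
      side <- paste0(if (rel[2] >= 0) "ventral" else "dorsal", "-",
                     if (rel[1] >= 0) "left" else "right")
      return(list(max_kpa = max(vm_hex), element = e, kind = "hex",
                  side = side))
    }
    best <- which.max(vm_tr)
    return(list(max_kpa = max(vm_tr), element = tr[best], kind = "truss",
                side = NA_character_))
  }
  stop("unknown stress scope type: ", scope$type)
}
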