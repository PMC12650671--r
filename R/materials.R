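## Material configuration.  Solid moduli in MPa, line-element areas in
## mm^2; the solver works in N / mm / MPa throughout and converts to kPa
## only at the reporting boundary.

#' Default material table
#'
#' Linear isotropic properties for the spine model: bone (cortical,
#' cancellous, posterior elements), disc components (nucleus pulposus,
#' annulus ground substance, cartilage endplate), annulus fibers, the
#' seven ligament sets, and the titanium-alloy instrumentation.
#'
#' Solids carry Young's modulus (MPa) and Poisson ratio; line elements
#' (fibers/ligaments) carry Young's modulus and a total cross-sectional
#' area per segment (mm^2) that is divided evenly among the strands the
#' mesher creates for that ligament.  The per-fiber annulus area and the
#' implant modulus are configuration defaults (literature-typical), not
#' taken from the tabulated spine properties.
#'
#' @return a list with data.frames `solids` (name, E, nu) and `lines`
#'   (name, E, area) plus `implant` (name, E, nu).
#' @export
default_materials <- function() {
  solids <- data.frame(
    name = c("cortical", "cancellous", "posterior", "nucleus",
             "ground", "endplate", "implant"),
    E  = c(12000, 100, 3500, 1, 4.2, 24, 110000),
    nu = c(0.3, 0.2, 0.25, 0.499, 0.46, 0.4, 0.3),
    stringsAsFactors = FALSE
  )
  lines <- data.frame(
    name = c("ALL", "PLL", "TL", "LF", "ISL", "SSL", "CL", "fiber"),
    E    = c(7.8, 10, 10, 15, 10, 8, 7.5, 175),
    area = c(24, 14.4, 3.6, 40, 26, 23, 30, 0.5),
    stringsAsFactors = FALSE
  )
  structure(list(solids = solids, lines = lines), class = "material_table")
}

#' Look up a solid material
#' @param mats a material table from [default_materials()].
#' @param name material name.
#' @return list with `E` and `nu`.
#' @keywords internal
solid_material <- function(mats, name) {
  i <- match(name, mats$solids$name)
  if (is.na(i)) stop("unknown solid material: ", name)
  list(E = mats$solids$E[i], nu = mats$solids$nu[i])
}

#' @rdname solid_material
#' @keywords internal
line_material <- function(mats, name) {
  i <- match(name, mats$lines$name)
  if (is.na(i)) stop("unknown line material: ", name)
  list(E = mats$lines$E[i], area = mats$lines$area[i])
}

#' Posterior instrumentation layout
#'
#' Describes a pedicle-screw / rod / transverse-connector construct.
#' The default reproduces a thoracolumbar fusion of T10-L4: bilateral
#' screws at T10, T11 and L1-L4, a unilateral (left) screw at T12, two
#' longitudinal rods, and transverse connectors at T11, L2 and L3.
#' Lumbar screws are 6.6 mm diameter, thoracic screws and rods 5.5 mm,
#' connectors 2 mm.
#'
#' @param levels character vector of instrumented levels (contiguous,
#'   caudal or cranial order).
#' @param sides character vector, one of `"both"`, `"left"`, `"right"`
#'   per level.
#' @param connector_levels levels at which transverse connectors join the
#'   two rods (must have screws on both sides).
#' @param screw_diameter_mm named numeric, diameters for `lumbar` and
#'   `thoracic` screws.
#' @param rod_diameter_mm rod diameter (mm).
#' @param connector_diameter_mm transverse connector diameter (mm).
#' @return an object of class `instrumentation_spec`.
#' @export
instrumentation_spec <- function(levels = c("T10", "T11", "T12", "L1",
                                            "L2", "L3", "L4"),
                                 sides = c("both", "both", "left", "both",
                                           "both", "both", "both"),
                                 connector_levels = c("T11", "L2", "L3"),
                                 screw_diameter_mm = c(lumbar = 6.6,
                                                       thoracic = 5.5),
                                 rod_diameter_mm = 5.5,
                                 connector_diameter_mm = 2) {
  stopifnot(length(levels) == length(sides),
            all(sides %in% c("both", "left", "right")),
            all(screw_diameter_mm > 0), rod_diameter_mm > 0,
            connector_diameter_mm > 0)
  structure(list(levels = levels, sides = sides,
                 connector_levels = connector_levels,
                 screw_diameter_mm = screw_diameter_mm,
                 rod_diameter_mm = rod_diameter_mm,
                 connector_diameter_mm = connector_diameter_mm),
            class = "instrumentation_spec")
}

#' Disc construction configuration
#'
#' @param endplate_frac fraction of the disc height given to each thin
#'   cartilage endplate layer.
#' @param nucleus_area_frac target fraction of the disc cross-section
#'   occupied by the nucleus pulposus (matched as closely as the cell
#'   grid allows).
#' @param nucleus_posterior_shift posterior offset of the nucleus centre
#'   as a fraction of the AP body depth.
#' @param fiber_angle_deg inclination of the criss-cross annulus fiber
#'   families relative to the transverse plane.
#' @param fiber_area_mm2 cross-sectional area per fiber truss.
#' @return list of class `disc_config`.
#' @export
disc_config <- function(endplate_frac = 0.12, nucleus_area_frac = 0.44,
                        nucleus_posterior_shift = 0.08,
                        fiber_angle_deg = 30, fiber_area_mm2 = 0.5) {
  stopifnot(endplate_frac > 0, endplate_frac < 0.5,
            nucleus_area_frac > 0, nucleus_area_frac < 1,
            fiber_angle_deg > 0, fiber_angle_deg < 90)
  structure(list(endplate_frac = endplate_frac,
                 nucleus_area_frac = nucleus_area_frac,
                 nucleus_posterior_shift = nucleus_posterior_shift,
                 fiber_angle_deg = fiber_angle_deg,
                 fiber_area_mm2 = fiber_area_mm2),
            class = "disc_config")
}

#' Ligament strand layout
#'
#' Number of truss strands per ligament type and segment.  The tabulated
#' per-segment area of each ligament is divided evenly among its strands.
#' @return named integer vector.
#' @export
ligament_strands <- function() {
  c(ALL = 1L, PLL = 1L, LF = 2L, ISL = 1L, SSL = 1L, TL = 2L, CL = 2L)
}
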