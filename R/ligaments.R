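## Seven spinal ligament sets as tension-only trusses between named
## attachment nodes of consecutive vertebrae: anterior and posterior
## longitudinal ligaments (ALL, PLL), ligamentum flavum (LF, one strand
## per side), interspinous (ISL) and supraspinous (SSL) ligaments,
## intertransverse ligament (TL, per side) and facet capsular ligaments
## (CL, per side).  The tabulated per-segment area of each ligament is
## divided evenly among its strands.

ligament_connections <- function(lower, upper) {
  u <- upper$attach; l <- lower$attach
  list(
    ALL = list(c(u$ant_inf, l$ant_sup)),
    PLL = list(c(u$post_inf, l$sup_post)),
    LF  = list(c(u$lam_lo_L, l$lam_hi_L), c(u$lam_lo_R, l$lam_hi_R)),
    ISL = list(c(u$spin_tip, l$isl_node)),
    SSL = list(c(u$spin_tip, l$spin_tip)),
    TL  = list(c(u$tt_L, l$tt_L), c(u$tt_R, l$tt_R)),
    CL  = list(c(u$facet_inf_L, l$facet_sup_L),
               c(u$facet_inf_R, l$facet_sup_R))
  )
}

#' Attach the ligament trusses to a sequence of placed vertebrae
#'
#' @param placed list of `placed_vertebra` objects, caudal to cranial.
#' @param strands named integer vector of strands per ligament type (the
#'   layout is fixed by the attachment design; see [ligament_strands()]).
#' @param mats material table supplying per-ligament modulus and total
#'   cross-sectional area.
#' @return fragment with `truss` (node id pairs) and `truss_info`
#'   (type, area per strand, tension-only flag, segment label).
#' @export
attach_ligaments <- function(placed, strands = ligament_strands(),
                             mats = default_materials()) {
  if (length(placed) < 2) {
    stop("ligaments require at least two vertebrae")
  }
  truss <- list(); info <- list()
  for (i in seq_len(length(placed) - 1)) {
    lower <- placed[[i]]; upper <- placed[[i + 1]]
    conns <- ligament_connections(lower, upper)
    seg <- paste0(upper$level, "-", lower$level)
    for (type in names(conns)) {
      pairs <- conns[[type]]
      if (any(vapply(pairs, function(p) any(is.na(p) | is.null(p)),
                     logical(1)))) {
        stop("missing attachment node for ligament ", type,
             " at segment ", seg)
      }
      lm <- line_material(mats, type)
      area <- lm$area / length(pairs)
      for (p in pairs) {
        truss[[length(truss) + 1L]] <- p
        info[[length(info) + 1L]] <-
          data.frame(type = type, family = "", area = area,
                     tension_only = TRUE, seg = seg,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(truss = do.call(rbind, truss), truss_info = do.call(rbind, info))
}
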