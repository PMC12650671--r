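## Posterior instrumentation: pedicle screws as beam chains from an
## anchor node at the pedicle centroid (kinematically tied to the eight
## pedicle-region nodes) to a screw-head node on the rod line; rods as
## beam chains through the ipsilateral screw heads; transverse
## connectors as single beams between the two rods at the stated levels.

#' Add pedicle-screw/rod instrumentation to a spine mesh
#'
#' @param spine a `spine_mesh` from [assemble_spine()].
#' @param ispec an [instrumentation_spec()]; an empty spec (no levels)
#'   returns the mesh unchanged.
#' @return the spine with beam elements, head/anchor nodes and rigid
#'   couplings added; the manifest is updated.
#' @export
build_instrumentation <- function(spine, ispec = instrumentation_spec()) {
  stopifnot(inherits(spine, "spine_mesh"),
            inherits(ispec, "instrumentation_spec"))
  if (length(ispec$levels) == 0) return(spine)
  idx <- match(ispec$levels, spine$levels)
  if (anyNA(idx)) {
    stop("instrumented levels not in spine: ",
         paste(ispec$levels[is.na(idx)], collapse = ", "))
  }
  if (!all(diff(sort(idx)) == 1)) {
    stop("instrumented levels must be contiguous")
  }
  for (cl in ispec$connector_levels) {
    i <- match(cl, ispec$levels)
    if (is.na(i)) stop("connector level ", cl, " is not instrumented")
    if (ispec$sides[i] != "both") {
      stop("connector at ", cl, " requires screws on both sides; ",
           "unilateral side unspecified where needed")
    }
  }

  nodes <- spine$nodes
  node_level <- spine$node_level
  constraints <- spine$constraints
  beams <- list(); binfo <- list()
  add_node <- function(p, tag) {
    nodes <<- rbind(nodes, matrix(p, 1, 3))
    node_level <<- c(node_level, tag)
    nrow(nodes)
  }
  add_beam_chain <- function(a, b, nseg, role, dia, level, side, ids) {
    prev <- a
    pa <- nodes[a, ]; pb <- nodes[b, ]
    for (s in seq_len(nseg)) {
      nxt <- if (s == nseg) b else {
        add_node(pa + (pb - pa) * s / nseg, "instr")
      }
      beams[[length(beams) + 1L]] <<- c(prev, nxt)
      binfo[[length(binfo) + 1L]] <<-
        data.frame(role = role, diameter = dia, mat = "implant",
                   level = level, side = side,
                   screw_id = ids[1], rod_id = ids[2],
                   stringsAsFactors = FALSE)
      prev <- nxt
    }
  }

  heads <- list(L = list(), R = list())
  screw_id <- 0L
  ord <- order(idx)
  for (j in ord) {
    lv <- ispec$levels[j]
    side_spec <- ispec$sides[j]
    sides <- if (side_spec == "both") c("L", "R") else
      c(left = "L", right = "R")[[side_spec]]
    dia <- if (startsWith(lv, "L")) ispec$screw_diameter_mm[["lumbar"]] else
      ispec$screw_diameter_mm[["thoracic"]]
    for (sd in sides) {
      ped <- spine$ped_sets[[lv]][[sd]]
      centroid <- colMeans(spine$nodes[ped, , drop = FALSE])
      anchor <- add_node(centroid, "instr")
      constraints[[length(constraints) + 1L]] <-
        list(slave = anchor, masters = ped,
             weights = rep(1 / length(ped), length(ped)))
      post_dir <- spine$frames[[lv]]$R %*% c(0, -1, 0)
      head <- add_node(centroid + spine$config$head_offset_mm * drop(post_dir),
                       "instr")
      screw_id <- screw_id + 1L
      add_beam_chain(anchor, head, spine$config$screw_subdiv, "screw",
                     dia, lv, sd, c(screw_id, NA))
      heads[[sd]][[lv]] <- head
    }
  }

  rod_id <- 0L
  for (sd in c("L", "R")) {
    hs <- unlist(heads[[sd]])
    if (length(hs) >= 2) {
      rod_id <- rod_id + 1L
      for (s in seq_len(length(hs) - 1)) {
        add_beam_chain(hs[s], hs[s + 1], spine$config$rod_subdiv, "rod",
                       ispec$rod_diameter_mm, NA_character_, sd,
                       c(NA, rod_id))
      }
    }
  }
  for (cl in ispec$connector_levels) {
    add_beam_chain(heads$L[[cl]], heads$R[[cl]], 1L, "connector",
                   ispec$connector_diameter_mm, cl, "both", c(NA, NA))
  }

  spine$nodes <- nodes
  spine$node_level <- node_level
  spine$constraints <- constraints
  spine$beam <- rbind(spine$beam, do.call(rbind, beams))
  spine$beam_info <- rbind(spine$beam_info, do.call(rbind, binfo))
  spine$instrumentation <- ispec
  spine$manifest <- mesh_manifest(spine)
  spine
}
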