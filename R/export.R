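## Mesh export: VTK XML unstructured grid (.vtu, ascii) with cell-data
## material ids plus an embedded JSON tag lookup, and Abaqus .inp with
## one element set / solid section block per material tag.  Both
## round-trip node and per-tag element counts through the matching
## importers.

mesh_cell_tables <- function(spine) {
  kinds <- c(rep("hex", if (is.null(spine$hex)) 0 else nrow(spine$hex)),
             rep("truss", if (is.null(spine$truss)) 0 else
               nrow(spine$truss)),
             rep("beam", if (is.null(spine$beam)) 0 else
               nrow(spine$beam)))
  mats <- c(spine$hex_info$mat,
            if (!is.null(spine$truss_info)) spine$truss_info$type,
            if (!is.null(spine$beam_info)) spine$beam_info$role)
  list(kinds = kinds, mats = mats)
}

#' Export a spine mesh
#'
#' @param spine a `spine_mesh` (must be non-empty).
#' @param format `"vtu"` (VTK XML unstructured grid) or `"inp"`
#'   (Abaqus cards).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_mesh <- function(spine, format = c("vtu", "inp"), path) {
  format <- match.arg(format)
  if (is.null(spine[["nodes"]]) || nrow(spine[["nodes"]]) == 0 ||
      is.null(spine[["hex"]]) || nrow(spine[["hex"]]) == 0) {
    stop("cannot export an empty mesh")
  }
  if (format == "vtu") write_vtu(spine, path) else write_inp(spine, path)
  invisible(path)
}

write_vtu <- function(spine, path) {
  ct <- mesh_cell_tables(spine)
  tags <- sort(unique(ct$mats))
  mat_id <- match(ct$mats, tags) - 1L
  conn <- c(if (!is.null(spine$hex)) as.vector(t(spine$hex)) - 1L,
            if (!is.null(spine$truss)) as.vector(t(spine$truss)) - 1L,
            if (!is.null(spine$beam)) as.vector(t(spine$beam)) - 1L)
  sizes <- ifelse(ct$kinds == "hex", 8L, 2L)
  offsets <- cumsum(sizes)
  types <- ifelse(ct$kinds == "hex", 12L, 3L)
  n <- nrow(spine$nodes)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" ',
    'byte_order="LittleEndian">')
  w("<!-- spinefe-tags ",
    jsonlite::toJSON(list(tags = tags), auto_unbox = TRUE), " -->")
  w("<UnstructuredGrid>")
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n,
            length(types)))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" ',
    'format="ascii">')
  writeLines(apply(spine$nodes, 1, function(r) {
    paste(sprintf("%.9g", r), collapse = " ")
  }), con)
  w("</DataArray></Points>")
  w("<Cells>")
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(conn, collapse = " "), con)
  w("</DataArray>")
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(offsets, collapse = " "), con)
  w("</DataArray>")
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(types, collapse = " "), con)
  w("</DataArray>")
  w("</Cells>")
  w("<CellData>")
  w('<DataArray type="Int32" Name="mat_id" format="ascii">')
  writeLines(paste(mat_id, collapse = " "), con)
  w("</DataArray>")
  w("</CellData>")
  w("</Piece>")
  w("</UnstructuredGrid>")
  w("</VTKFile>")
}

#' Import a .vtu file written by [export_mesh()]
#'
#' @param path a `.vtu` path.
#' @return list with `nodes`, `conn` cell list, `kind` per cell and
#'   `mat` tag per cell.
#' @export
import_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  comment <- xml2::xml_find_first(doc, "//comment()")
  txt <- xml2::xml_text(comment)
  tags <- jsonlite::fromJSON(sub("^\\s*spinefe-tags\\s*", "", txt))$tags
  get_arr <- function(name, type = "numeric") {
    node <- xml2::xml_find_first(
      doc, sprintf("//*[local-name()='DataArray'][@Name='%s']", name))
    vals <- scan(text = xml2::xml_text(node), quiet = TRUE)
    vals
  }
  pts_node <- xml2::xml_find_first(
    doc, "//*[local-name()='Points']/*[local-name()='DataArray']")
  pts <- matrix(scan(text = xml2::xml_text(pts_node), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  connectivity <- get_arr("connectivity") + 1L
  offsets <- get_arr("offsets")
  types <- get_arr("types")
  mat_id <- get_arr("mat_id") + 1L
  starts <- c(1, utils::head(offsets, -1) + 1)
  conn <- lapply(seq_along(offsets), function(i) {
    connectivity[starts[i]:offsets[i]]
  })
  list(nodes = pts, conn = conn,
       kind = ifelse(types == 12, "hex", "line"),
       mat = tags[mat_id])
}

write_inp <- function(spine, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("*HEADING")
  w("spinefe parameterized spine export")
  w("*NODE")
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(spine$nodes)),
                     spine$nodes[, 1], spine$nodes[, 2], spine$nodes[, 3]),
             con)
  eid <- 0L
  mats <- spine$config$materials
  for (m in sort(unique(spine$hex_info$mat))) {
    el <- which(spine$hex_info$mat == m)
    w(sprintf("*ELEMENT, TYPE=C3D8, ELSET=MAT_%s", m))
    writeLines(vapply(el, function(e) {
      eid <<- eid + 1L
      paste(c(eid, spine$hex[e, ]), collapse = ", ")
    }, character(1)), con)
  }
  if (!is.null(spine$truss)) {
    for (m in sort(unique(spine$truss_info$type))) {
      el <- which(spine$truss_info$type == m)
      w(sprintf("*ELEMENT, TYPE=T3D2, ELSET=LINE_%s", m))
      writeLines(vapply(el, function(e) {
        eid <<- eid + 1L
        paste(c(eid, spine$truss[e, ]), collapse = ", ")
      }, character(1)), con)
    }
  }
  if (!is.null(spine$beam)) {
    for (m in sort(unique(spine$beam_info$role))) {
      el <- which(spine$beam_info$role == m)
      w(sprintf("*ELEMENT, TYPE=B31, ELSET=BEAM_%s", m))
      writeLines(vapply(el, function(e) {
        eid <<- eid + 1L
        paste(c(eid, spine$beam[e, ]), collapse = ", ")
      }, character(1)), con)
    }
  }
  for (m in sort(unique(spine$hex_info$mat))) {
    sm <- solid_material(mats, m)
    w(sprintf("*SOLID SECTION, ELSET=MAT_%s, MATERIAL=%s", m, m))
    w(sprintf("*MATERIAL, NAME=%s", m))
    w("*ELASTIC")
    w(sprintf("%.9g, %.9g", sm$E, sm$nu))
  }
  if (!is.null(spine$truss)) {
    for (m in sort(unique(spine$truss_info$type))) {
      lm <- line_material(mats, m)
      area <- spine$truss_info$area[match(m, spine$truss_info$type)]
      w(sprintf("*SOLID SECTION, ELSET=LINE_%s, MATERIAL=%s", m, m))
      w(sprintf("%.9g", area))
      w(sprintf("*MATERIAL, NAME=%s", m))
      w("*ELASTIC")
      w(sprintf("%.9g", lm$E))
    }
  }
}

#' Import an Abaqus .inp written by [export_mesh()]
#'
#' @param path an `.inp` path.
#' @return list with `n_nodes`, named element counts per ELSET and the
#'   number of section blocks.
#' @export
import_inp <- function(path) {
  lines <- readLines(path)
  n_nodes <- 0L
  elsets <- list()
  current <- NULL
  mode <- ""
  for (ln in lines) {
    if (startsWith(ln, "*")) {
      up <- toupper(ln)
      if (startsWith(up, "*NODE")) {
        mode <- "node"; current <- NULL
      } else if (startsWith(up, "*ELEMENT")) {
        mode <- "elem"
        current <- sub(".*ELSET=([^,]+).*", "\\1", ln)
        if (is.null(elsets[[current]])) elsets[[current]] <- 0L
      } else {
        mode <- ""
      }
      next
    }
    if (mode == "node") n_nodes <- n_nodes + 1L
    if (mode == "elem") elsets[[current]] <- elsets[[current]] + 1L
  }
  list(n_nodes = n_nodes, elsets = elsets,
       n_sections = sum(grepl("^\\*SOLID SECTION", toupper(lines))))
}
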