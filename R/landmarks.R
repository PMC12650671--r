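## Calibrated biplanar landmark sets.  The PA view encodes (X, Z), the
## lateral view (Y, Z); after calibration (mm/px scale per view) and
## registration (shared vertical origin) the vertical coordinate of the
## same anatomical point must agree across views within a tolerance.

#' Construct a calibrated landmark set
#'
#' @param points data.frame with columns `level`, `point`, `view`
#'   (`"pa"` or `"lat"`), `u_mm`, `v_mm` (calibrated millimetres).
#' @param scale named numeric, mm/px calibration per view (stored as
#'   provenance; `points` are already in mm).
#' @param v_offset named numeric, vertical registration offset per view
#'   that was subtracted to share a common vertical origin.
#' @param levels ordered level labels (caudal to cranial); defaults to
#'   the order of first appearance.
#' @param v_tol_mm tolerance for cross-view vertical agreement of the
#'   same anatomical point.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, scale = c(pa = 1, lat = 1),
                         v_offset = c(pa = 0, lat = 0),
                         levels = unique(points$level), v_tol_mm = 5) {
  need <- c("level", "point", "view", "u_mm", "v_mm")
  if (!all(need %in% names(points))) {
    stop("landmark points need columns: ", paste(need, collapse = ", "))
  }
  if (any(scale <= 0)) stop("non-positive view scale")
  if (!all(points$view %in% c("pa", "lat"))) {
    stop("views must be 'pa' or 'lat'")
  }
  missing <- character(0)
  for (lv in levels) {
    for (vw in c("pa", "lat")) {
      if (!any(points$level == lv & points$view == vw)) {
        missing <- c(missing, paste0(lv, "/", ifelse(vw == "lat",
                                                     "lateral", "PA")))
      }
    }
  }
  if (length(missing)) {
    stop("landmark set is missing levels/views: ",
         paste(missing, collapse = ", "))
  }
  pa <- points[points$view == "pa", ]
  lat <- points[points$view == "lat", ]
  key <- function(d) paste(d$level, d$point)
  shared <- intersect(key(pa), key(lat))
  dv <- abs(pa$v_mm[match(shared, key(pa))] -
              lat$v_mm[match(shared, key(lat))])
  if (length(dv) && max(dv) > v_tol_mm) {
    stop(sprintf(paste0("vertical coordinates disagree across views by up ",
                        "to %.2f mm (tolerance %.2f mm); check view ",
                        "registration"), max(dv), v_tol_mm))
  }
  structure(list(points = points[order(match(points$level, levels),
                                       points$view, points$point), ],
                 scale = scale, v_offset = v_offset, levels = levels,
                 v_tol_mm = v_tol_mm),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", length(x$levels), "levels,",
      nrow(x$points), "view points\n")
  invisible(x)
}

#' Write a landmark set to JSON and per-view CSV files
#'
#' Writes `<base>.json` (schema-versioned, with calibration metadata and
#' raw pixel coordinates) plus `<base>_pa.csv` and `<base>_lat.csv`
#' (columns `level`, `point_id`, `u_mm`, `v_mm`).
#'
#' @param lms a [landmark_set()].
#' @param base path prefix (without extension).
#' @return invisibly, the three file paths written.
#' @export
write_landmarks <- function(lms, base) {
  stopifnot(inherits(lms, "landmark_set"))
  json_path <- paste0(base, ".json")
  fmt <- function(x) as.numeric(sprintf("%.9g", x))
  pts <- lms$points
  px_u <- pts$u_mm / lms$scale[pts$view]
  px_v <- (pts$v_mm + lms$v_offset[pts$view]) / lms$scale[pts$view]
  payload <- list(
    schema = "spinefe-landmarks-1",
    levels = lms$levels,
    views = list(
      pa = list(scale_mm_per_px = fmt(lms$scale[["pa"]]),
                v_offset_mm = fmt(lms$v_offset[["pa"]])),
      lat = list(scale_mm_per_px = fmt(lms$scale[["lat"]]),
                 v_offset_mm = fmt(lms$v_offset[["lat"]]))
    ),
    v_tol_mm = fmt(lms$v_tol_mm),
    points = data.frame(level = pts$level, point = pts$point,
                        view = pts$view, u_px = fmt(px_u), v_px = fmt(px_v),
                        stringsAsFactors = FALSE)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  csv_paths <- character(2)
  for (i in seq_along(c("pa", "lat"))) {
    vw <- c("pa", "lat")[i]
    d <- pts[pts$view == vw, c("level", "point", "u_mm", "v_mm")]
    names(d) <- c("level", "point_id", "u_mm", "v_mm")
    d$u_mm <- fmt(d$u_mm); d$v_mm <- fmt(d$v_mm)
    csv_paths[i] <- paste0(base, "_", vw, ".csv")
    utils::write.csv(d, csv_paths[i], row.names = FALSE, quote = FALSE)
  }
  invisible(c(json_path, csv_paths))
}

#' Read a landmark set
#'
#' Reads the JSON schema written by [write_landmarks()], applies the
#' per-view mm/px calibration and vertical registration offsets, and
#' validates completeness (every level present in both views) and
#' cross-view vertical agreement.  Missing levels or views are a hard
#' error naming the gaps.
#'
#' @param path path to a `.json` landmark file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema) || !startsWith(raw$schema, "spinefe-landmarks")) {
    stop("not a spinefe landmark file (missing schema): ", path)
  }
  scale <- c(pa = raw$views$pa$scale_mm_per_px,
             lat = raw$views$lat$scale_mm_per_px)
  v_offset <- c(pa = raw$views$pa$v_offset_mm,
                lat = raw$views$lat$v_offset_mm)
  if (any(scale <= 0)) stop("non-positive view scale in ", path)
  pts <- raw$points
  pts$u_mm <- pts$u_px * scale[pts$view]
  pts$v_mm <- pts$v_px * scale[pts$view] - v_offset[pts$view]
  pts <- pts[, c("level", "point", "view", "u_mm", "v_mm")]
  landmark_set(pts, scale = scale, v_offset = v_offset,
               levels = raw$levels,
               v_tol_mm = if (!is.null(raw$v_tol_mm)) raw$v_tol_mm else 5)
}

#' Read a landmark set from two per-view CSV files
#'
#' @param pa_csv,lat_csv per-view CSV files with columns `level`,
#'   `point_id`, `u_mm`, `v_mm` (already calibrated).
#' @param levels optional ordered level labels.
#' @param v_tol_mm cross-view vertical agreement tolerance (mm).
#' @return a [landmark_set()].
#' @export
read_landmarks_csv <- function(pa_csv, lat_csv, levels = NULL, v_tol_mm = 5) {
  rd <- function(path, vw) {
    if (!file.exists(path)) stop("landmark file not found: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    data.frame(level = d$level, point = d$point_id, view = vw,
               u_mm = d$u_mm, v_mm = d$v_mm, stringsAsFactors = FALSE)
  }
  pts <- rbind(rd(pa_csv, "pa"), rd(lat_csv, "lat"))
  if (is.null(levels)) levels <- unique(pts$level)
  landmark_set(pts, levels = levels, v_tol_mm = v_tol_mm)
}
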