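## Per-vertebra parameter extraction from calibrated biplanar landmarks.
## The PA view contributes X, the lateral view Y, and the two views'
## vertical coordinates are fused (averaged) into Z, so each sampling
## point is recovered in 3D before angles and lengths are measured.

fuse_level_points <- function(lms, level) {
  pts <- lms$points[lms$points$level == level, ]
  pa <- pts[pts$view == "pa", ]
  lat <- pts[pts$view == "lat", ]
  names3 <- intersect(pa$point, lat$point)
  out <- matrix(NA_real_, length(names3), 3,
                dimnames = list(names3, c("x", "y", "z")))
  out[, 1] <- pa$u_mm[match(names3, pa$point)]
  out[, 2] <- lat$u_mm[match(names3, lat$point)]
  out[, 3] <- (pa$v_mm[match(names3, pa$point)] +
                 lat$v_mm[match(names3, lat$point)]) / 2
  out
}

#' Extract per-vertebra parameters from a landmark set
#'
#' For each level, the eight sampling points are fused to 3D and the
#' placement parameters are recovered: the superior posterior point is
#' point A; the anterior (A to B) and vertical (C to A) midline
#' directions give two columns of the rotation matrix (and the Ly, Lz
#' body lengths), the third column follows from right-handedness, and
#' the Euler tilts (beta, theta, phi) are decomposed from the rotation.
#' Lx and the endplate coronal tilts come from the lateral rim points
#' (E, F superior; G, H inferior) expressed in the recovered body frame.
#'
#' The transverse tilt phi defaults to the geometric value recovered
#' from the fused points; pass `nash_moe` to override it with the
#' pedicle-shadow based grading instead (the radiographic practice when
#' true 3D points are not available).
#'
#' @param lms a [landmark_set()].
#' @param nash_moe optional named list/vector of Nash-Moe grades (0, "I"
#'   .. "IV") or pedicle offset ratios in \[0, 1\] per level; converted
#'   via [nash_moe_to_phi()].
#' @param nash_moe_table lookup table passed on to [nash_moe_to_phi()].
#' @return list of [vertebra_params()], one per level, caudal to cranial.
#' @export
extract_params <- function(lms, nash_moe = NULL,
                           nash_moe_table = nash_moe_table_default()) {
  stopifnot(inherits(lms, "landmark_set"))
  lapply(lms$levels, function(lv) {
    P <- fuse_level_points(lms, lv)
    need <- c("A", "B", "C", "D", "E", "F", "G", "H")
    if (!all(need %in% rownames(P))) {
      stop("level ", lv, ": missing sampling points ",
           paste(setdiff(need, rownames(P)), collapse = ", "))
    }
    v_y <- P["B", ] - P["A", ]
    v_z <- P["A", ] - P["C", ]
    Ly <- sqrt(sum(v_y^2)); Lz <- sqrt(sum(v_z^2))
    if (Ly < 1e-9 || Lz < 1e-9) {
      stop("level ", lv, ": degenerate (coincident) landmark pair")
    }
    col2 <- v_y / Ly; col3 <- v_z / Lz
    col1 <- c(col2[2] * col3[3] - col2[3] * col3[2],
              col2[3] * col3[1] - col2[1] * col3[3],
              col2[1] * col3[2] - col2[2] * col3[1])
    col1 <- col1 / sqrt(sum(col1^2))
    R <- cbind(col1, col2, col3)
    ang <- euler_angles_from_rotation(R)

    d_sup <- P["F", ] - P["E", ]
    d_inf <- P["H", ] - P["G", ]
    if (sqrt(sum(d_sup^2)) < 1e-9 || sqrt(sum(d_inf^2)) < 1e-9) {
      stop("level ", lv, ": degenerate (coincident) landmark pair")
    }
    Lx <- sum(d_sup * col1)
    if (Lx <= 0) stop("level ", lv, ": endplate rim points reversed")
    w_sup <- rad2deg(atan2(-sum(d_sup * col3), sum(d_sup * col1)))
    w_inf <- rad2deg(atan2(-sum(d_inf * col3), sum(d_inf * col1)))

    phi <- ang[["phi_deg"]]
    if (!is.null(nash_moe)) {
      if (is.null(nash_moe[[lv]])) {
        stop("nash_moe override missing level ", lv)
      }
      phi <- nash_moe_to_phi(nash_moe[[lv]], table = nash_moe_table)
    }
    vertebra_params(level = lv, p_sup_post = P["A", ],
                    lengths = c(Lx, Ly, Lz),
                    theta_deg = ang[["theta_deg"]], phi_deg = phi,
                    beta_deg = ang[["beta_deg"]],
                    beta_sup_deg = ang[["beta_deg"]] + w_sup,
                    beta_inf_deg = ang[["beta_deg"]] + w_inf)
  })
}

#' Default Nash-Moe grade to transverse-rotation table
#'
#' Mapping from the Nash-Moe pedicle-shadow grade (0 to IV) to a
#' transverse rotation angle in degrees.  The mapping is not part of the
#' measured landmark data; it is an editable configuration table with
#' literature-typical defaults, and any report should state the table
#' used.
#'
#' @return data.frame with columns `grade` and `phi_deg`.
#' @export
nash_moe_table_default <- function() {
  data.frame(grade = c("0", "I", "II", "III", "IV"),
             phi_deg = c(0, 5, 15, 25, 35), stringsAsFactors = FALSE)
}

#' Convert a Nash-Moe grade or pedicle offset ratio to a rotation angle
#'
#' Grades map directly through the table.  A numeric pedicle offset
#' ratio in \[0, 1\] is binned into five equal-width grade bins
#' (boundaries belong to the lower bin) and interpolated linearly within
#' the bin between the adjacent grade angles (the last bin is flat).
#'
#' @param grade_or_offset a grade (`0`, `"0"`, `"I"` .. `"IV"`) or a
#'   numeric offset ratio in \[0, 1\].
#' @param table lookup table as from [nash_moe_table_default()].
#' @return transverse rotation angle phi in degrees.
#' @export
nash_moe_to_phi <- function(grade_or_offset,
                            table = nash_moe_table_default()) {
  g <- grade_or_offset
  ang <- table$phi_deg
  ## grades as roman-numeral strings (or integer 2..4); numeric values in
  ## [0, 1] are pedicle offset ratios
  if (is.numeric(g) && g > 1 && g %in% 2:4) g <- table$grade[g + 1]
  if (is.character(g)) {
    i <- match(g, table$grade)
    if (is.na(i)) stop("unknown Nash-Moe grade: ", g)
    return(ang[i])
  }
  x <- as.numeric(g)
  if (is.na(x) || x < 0 || x > 1) {
    stop("pedicle offset ratio must lie in [0, 1]")
  }
  nb <- length(ang) - 1           # 4 interpolation bins + flat tail
  width <- 1 / (nb + 1)           # five equal-width grade bins
  bin <- ceiling(x / width)       # boundary -> lower bin
  bin <- max(1, min(nb + 1, bin))
  lo <- (bin - 1) * width
  t <- (x - lo) / width
  a0 <- ang[bin]
  a1 <- if (bin < length(ang)) ang[bin + 1] else ang[bin]
  a0 + t * (a1 - a0)
}

#' Export a parameter table to CSV
#'
#' One row per level, columns exactly the [vertebra_params()] fields.
#'
#' @param params list of [vertebra_params()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_params_csv <- function(params, path) {
  utils::write.csv(params_table(params), path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter table from CSV
#' @param path CSV written by [write_params_csv()].
#' @return list of [vertebra_params()].
#' @export
read_params_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    vertebra_params(level = d$level[i],
                    p_sup_post = c(d$x_mm[i], d$y_mm[i], d$z_mm[i]),
                    lengths = c(d$Lx_mm[i], d$Ly_mm[i], d$Lz_mm[i]),
                    theta_deg = d$theta_deg[i], phi_deg = d$phi_deg[i],
                    beta_deg = d$beta_deg[i],
                    beta_sup_deg = d$beta_sup_deg[i],
                    beta_inf_deg = d$beta_inf_deg[i])
  })
}
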