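## Synthetic scoliotic-spine fixtures: biplanar landmark sets with known
## ground-truth per-vertebra parameters, plus CT-like reference
## coordinates.  The generator is first-class, tested code: every
## downstream stage of the pipeline is exercised against its truth
## channel without any clinical data.

#' Standard level labels, caudal to cranial
#'
#' @param n number of vertebrae (2..18); the full spine is L5 to C7.
#' @return character vector of length `n`.
#' @export
spine_levels <- function(n = 18) {
  all <- c("L5", "L4", "L3", "L2", "L1", paste0("T", 12:1), "C7")
  stopifnot(n >= 2, n <= length(all))
  all[seq_len(n)]
}

#' Per-vertebra placement parameters
#'
#' The parameter set that places one vertebra: the superior posterior
#' point, body lengths along the three axes, the sagittal (theta),
#' transverse (phi) and frontal-plane (beta) tilts, and the coronal
#' tilts of the superior/inferior endplates.  `beta` is the mean of the
#' two endplate tilts; the residual difference is applied as an endplate
#' wedge during morphing.
#'
#' @param level level label, e.g. `"T10"`.
#' @param p_sup_post numeric length 3, superior posterior point (mm).
#' @param lengths numeric length 3, body lengths (Lx, Ly, Lz) in mm.
#' @param theta_deg,phi_deg,beta_deg tilt angles in degrees.
#' @param beta_sup_deg,beta_inf_deg coronal endplate tilts in degrees.
#' @return object of class `vertebra_params`.
#' @export
vertebra_params <- function(level, p_sup_post, lengths, theta_deg = 0,
                            phi_deg = 0,
                            beta_deg = mean(c(beta_sup_deg, beta_inf_deg)),
                            beta_sup_deg = 0, beta_inf_deg = 0) {
  stopifnot(length(p_sup_post) == 3, length(lengths) == 3,
            all(is.finite(p_sup_post)), all(lengths > 0))
  ang <- c(theta_deg, phi_deg, beta_deg, beta_sup_deg, beta_inf_deg)
  if (any(abs(ang) >= 90)) {
    stop("vertebra_params: tilt angles must satisfy |angle| < 90 degrees")
  }
  structure(list(level = level, p_sup_post = as.numeric(p_sup_post),
                 lengths = as.numeric(lengths), theta_deg = theta_deg,
                 phi_deg = phi_deg, beta_deg = beta_deg,
                 beta_sup_deg = beta_sup_deg, beta_inf_deg = beta_inf_deg),
            class = "vertebra_params")
}

#' Convert a list of vertebra_params to a data.frame
#' @param params list of [vertebra_params()] objects.
#' @return data.frame with one row per level.
#' @export
params_table <- function(params) {
  do.call(rbind, lapply(params, function(p) {
    data.frame(level = p$level,
               x_mm = p$p_sup_post[1], y_mm = p$p_sup_post[2],
               z_mm = p$p_sup_post[3],
               Lx_mm = p$lengths[1], Ly_mm = p$lengths[2],
               Lz_mm = p$lengths[3],
               theta_deg = p$theta_deg, phi_deg = p$phi_deg,
               beta_deg = p$beta_deg, beta_sup_deg = p$beta_sup_deg,
               beta_inf_deg = p$beta_inf_deg,
               stringsAsFactors = FALSE)
  }))
}

#' Named sampling points of one vertebra in model coordinates
#'
#' Eight anatomical sampling points on the vertebral body, in the global
#' frame: A superior-posterior midline (the reference point), B
#' superior-anterior midline, C/D the inferior counterparts, E/F the
#' left/right superior endplate rim at mid-depth, G/H the inferior ones.
#' Wedge (endplate-tilt) taper is applied before the Euler rotation, so
#' the midline points are wedge-free while E-H carry the endplate tilts.
#'
#' @param vp a [vertebra_params()] object.
#' @return 8 x 3 matrix with rownames A..H (mm).
#' @export
vertebra_sample_points <- function(vp) {
  Lx <- vp$lengths[1]; Ly <- vp$lengths[2]; Lz <- vp$lengths[3]
  w_sup <- deg2rad(vp$beta_sup_deg - vp$beta_deg)
  w_inf <- deg2rad(vp$beta_inf_deg - vp$beta_deg)
  pts <- rbind(
    A = c(0, 0, 0),
    B = c(0, Ly, 0),
    C = c(0, 0, -Lz),
    D = c(0, Ly, -Lz),
    E = c(-Lx / 2, Ly / 2, tan(w_sup) * Lx / 2),
    F = c(Lx / 2, Ly / 2, -tan(w_sup) * Lx / 2),
    G = c(-Lx / 2, Ly / 2, -Lz + tan(w_inf) * Lx / 2),
    H = c(Lx / 2, Ly / 2, -Lz - tan(w_inf) * Lx / 2)
  )
  out <- euler_transform(pts, vp$beta_deg, vp$theta_deg, vp$phi_deg)
  sweep(out, 2, vp$p_sup_post, "+")
}

default_vertebral_heights <- function(labels) {
  ifelse(startsWith(labels, "L"), 22, ifelse(labels == "C7", 15, 18))
}

default_body_widths <- function(n) seq(42, 24, length.out = n)
default_body_depths <- function(n) seq(33, 16, length.out = n)

default_sagittal_profile <- function(labels) {
  ## kyphosis above the thoracolumbar junction, lordosis below, with a
  ## linear transition from L2 to T10 (thoracolumbar kyphosis of 20.2
  ## degrees between the T10 superior and L2 inferior endplates)
  idx <- seq_along(labels)
  i_l2 <- match("L2", labels)
  i_t10 <- match("T10", labels)
  if (is.na(i_l2) || is.na(i_t10)) return(rep(0, length(labels)))
  stats::approx(x = c(1, i_l2, i_t10, length(labels)),
                y = c(-12.2, -12.2, 8, 8), xout = idx)$y
}

#' Specification of a synthetic scoliotic spine
#'
#' The stated world of the fixture generator: a single thoracolumbar
#' coronal curve (Lenke-5-like, default target Cobb angle 52 degrees,
#' raised-cosine lateral offset spanning L4-T9), a sagittal
#' kyphosis/lordosis profile, optional per-level axial rotation and
#' endplate wedging, and isotropic Gaussian digitization noise on the
#' projected landmarks.
#'
#' @param n_vertebrae number of vertebrae, caudal to cranial (default 18,
#'   L5 to C7).
#' @param level_labels level names; defaults to [spine_levels()].
#' @param vertebral_heights per-level body heights Lz (mm); defaults 22
#'   lumbar / 18 thoracic / 15 at C7.
#' @param disc_heights disc heights between consecutive levels (mm),
#'   length `n_vertebrae - 1`; default 8.
#' @param body_widths,body_depths per-level Lx / Ly (mm).
#' @param coronal_curve list with `target_cobb_deg` and `span` (the two
#'   levels bounding the raised-cosine lateral offset).
#' @param sagittal_profile_deg per-level sagittal tilt theta (degrees).
#' @param axial_rotation_deg per-level transverse tilt phi (degrees).
#' @param endplate_wedge_deg n x 2 matrix of (superior, inferior) endplate
#'   wedge angles relative to the body coronal tilt (degrees).
#' @param noise_sd_mm standard deviation of landmark digitization noise.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return object of class `synthetic_spine_spec`.
#' @export
synthetic_spine_spec <- function(n_vertebrae = 18,
                                 level_labels = spine_levels(n_vertebrae),
                                 vertebral_heights =
                                   default_vertebral_heights(level_labels),
                                 disc_heights = rep(8, n_vertebrae - 1),
                                 body_widths = default_body_widths(n_vertebrae),
                                 body_depths = default_body_depths(n_vertebrae),
                                 coronal_curve = list(target_cobb_deg = 52,
                                                      span = c("L4", "T9")),
                                 sagittal_profile_deg =
                                   default_sagittal_profile(level_labels),
                                 axial_rotation_deg = rep(0, n_vertebrae),
                                 endplate_wedge_deg =
                                   matrix(0, n_vertebrae, 2),
                                 noise_sd_mm = 0, seed = 1L) {
  if (n_vertebrae < 2) stop("n_vertebrae must be >= 2")
  stopifnot(length(level_labels) == n_vertebrae,
            length(vertebral_heights) == n_vertebrae,
            length(disc_heights) == n_vertebrae - 1,
            length(body_widths) == n_vertebrae,
            length(body_depths) == n_vertebrae,
            length(sagittal_profile_deg) == n_vertebrae,
            length(axial_rotation_deg) == n_vertebrae,
            nrow(endplate_wedge_deg) == n_vertebrae)
  if (any(vertebral_heights <= 0) || any(disc_heights <= 0) ||
      any(body_widths <= 0) || any(body_depths <= 0)) {
    stop("all heights and body dimensions must be > 0")
  }
  if (coronal_curve$target_cobb_deg < 0) stop("target_cobb_deg must be >= 0")
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0")
  if (!all(coronal_curve$span %in% level_labels)) {
    stop("coronal curve span levels outside the level range: ",
         paste(setdiff(coronal_curve$span, level_labels), collapse = ", "))
  }
  structure(list(n_vertebrae = n_vertebrae, level_labels = level_labels,
                 vertebral_heights = vertebral_heights,
                 disc_heights = disc_heights, body_widths = body_widths,
                 body_depths = body_depths, coronal_curve = coronal_curve,
                 sagittal_profile_deg = sagittal_profile_deg,
                 axial_rotation_deg = axial_rotation_deg,
                 endplate_wedge_deg = endplate_wedge_deg,
                 noise_sd_mm = noise_sd_mm, seed = as.integer(seed)),
            class = "synthetic_spine_spec")
}

## projected coronal angle of an endplate line for a vertebra rotated by
## (beta, theta, phi) whose endplate carries a wedge w relative to beta.
## This closed form is deliberately independent of the point-based angle
## measurement used by cobb_angle(): psi = beta + w, and the rotated
## endplate direction is Rz(phi) Rx(theta) (cos psi, 0, -sin psi).
projected_coronal_angle <- function(beta_deg, wedge_deg, theta_deg, phi_deg) {
  psi <- deg2rad(beta_deg + wedge_deg)
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  dx <- cos(ph) * cos(psi) - sin(ph) * sin(th) * sin(psi)
  dz <- -cos(th) * sin(psi)
  rad2deg(atan2(-dz, dx))
}

projected_sagittal_angle <- function(theta_deg, phi_deg) {
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  rad2deg(atan2(sin(th), cos(ph) * cos(th)))
}

## raised-cosine lateral offset profile (single-apex, Lenke-5-like)
raised_cosine_offset <- function(z, z_lo, z_hi, amplitude) {
  out <- numeric(length(z))
  inside <- z >= z_lo & z <= z_hi
  out[inside] <- amplitude * 0.5 *
    (1 - cos(2 * pi * (z[inside] - z_lo) / (z_hi - z_lo)))
  out
}

raised_cosine_slope <- function(z, z_lo, z_hi, amplitude) {
  out <- numeric(length(z))
  inside <- z >= z_lo & z <= z_hi
  out[inside] <- amplitude * pi / (z_hi - z_lo) *
    sin(2 * pi * (z[inside] - z_lo) / (z_hi - z_lo))
  out
}

#' Generate a synthetic scoliotic spine
#'
#' Stacks vertebrae along the vertical axis, imposes a raised-cosine
#' lateral (coronal) offset whose amplitude is calibrated by 1D root
#' finding so the ground-truth Cobb angle meets the requested target
#' within 0.5 degrees, projects each vertebra's sampling points to the
#' PA view (X, Z) and lateral view (Y, Z), and adds isotropic Gaussian
#' digitization noise.  Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spine_spec()].
#' @return list with elements `landmarks` (a `landmark_set`) and `truth`
#'   (a `ground_truth` with per-vertebra parameters, true Cobb/TLK angles
#'   and their end levels, and centerline points).
#' @export
generate_spine <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spine_spec"))
  set.seed(spec$seed)
  n <- spec$n_vertebrae
  labels <- spec$level_labels
  Lz <- spec$vertebral_heights
  z_inf <- cumsum(c(0, (Lz + c(spec$disc_heights, 0))[-n]))
  z_sup <- z_inf + Lz
  z_mid <- (z_inf + z_sup) / 2

  span_idx <- match(spec$coronal_curve$span, labels)
  z_lo <- z_inf[min(span_idx)]
  z_hi <- z_sup[max(span_idx)]

  wedge <- spec$endplate_wedge_deg
  theta <- spec$sagittal_profile_deg
  phi <- spec$axial_rotation_deg

  cobb_of_amplitude <- function(A) {
    beta <- rad2deg(atan(raised_cosine_slope(z_mid, z_lo, z_hi, A)))
    a_sup <- projected_coronal_angle(beta, wedge[, 1], theta, phi)
    a_inf <- projected_coronal_angle(beta, wedge[, 2], theta, phi)
    up <- which.min(a_sup); lo <- which.max(a_inf)
    list(cobb = a_sup[up] - a_inf[lo], upper = up, lower = lo)
  }

  target <- spec$coronal_curve$target_cobb_deg
  base <- abs(cobb_of_amplitude(0)$cobb)
  if (target <= base + 1e-9) {
    A <- 0
  } else {
    A_hi <- 10
    while (abs(cobb_of_amplitude(A_hi)$cobb) < target && A_hi < 1e4) {
      A_hi <- A_hi * 2
    }
    A <- stats::uniroot(function(a) abs(cobb_of_amplitude(a)$cobb) - target,
                        c(0, A_hi), tol = 1e-10)$root
  }

  beta <- rad2deg(atan(raised_cosine_slope(z_mid, z_lo, z_hi, A)))
  x_off <- raised_cosine_offset(z_sup, z_lo, z_hi, A)

  params <- lapply(seq_len(n), function(i) {
    vertebra_params(
      level = labels[i],
      p_sup_post = c(x_off[i], -spec$body_depths[i] / 2, z_sup[i]),
      lengths = c(spec$body_widths[i], spec$body_depths[i], Lz[i]),
      theta_deg = theta[i], phi_deg = phi[i], beta_deg = beta[i],
      beta_sup_deg = beta[i] + wedge[i, 1],
      beta_inf_deg = beta[i] + wedge[i, 2]
    )
  })

  cb <- cobb_of_amplitude(A)
  tlk <- NA_real_; tlk_levels <- c(NA_character_, NA_character_)
  if (all(c("T10", "L2") %in% labels)) {
    i_t10 <- match("T10", labels); i_l2 <- match("L2", labels)
    tlk <- abs(projected_sagittal_angle(theta[i_t10], phi[i_t10]) -
                 projected_sagittal_angle(theta[i_l2], phi[i_l2]))
    tlk_levels <- c("T10", "L2")
  }

  centerline <- t(vapply(params, function(p) {
    p$p_sup_post + euler_transform(c(0, p$lengths[2] / 2, -p$lengths[3] / 2),
                                   p$beta_deg, p$theta_deg, p$phi_deg)
  }, numeric(3)))
  rownames(centerline) <- labels

  truth <- structure(
    list(params = params,
         true_cobb_deg = abs(cb$cobb),
         cobb_levels = c(upper = labels[cb$upper], lower = labels[cb$lower]),
         true_tlk_deg = tlk,
         tlk_levels = c(upper = tlk_levels[1], lower = tlk_levels[2]),
         centerline = centerline,
         amplitude_mm = A),
    class = "ground_truth")

  rows <- do.call(rbind, lapply(params, function(p) {
    pts <- vertebra_sample_points(p)
    data.frame(level = p$level, point = rep(rownames(pts), 2),
               view = rep(c("pa", "lat"), each = nrow(pts)),
               u_mm = c(pts[, 1], pts[, 2]),
               v_mm = c(pts[, 3], pts[, 3]),
               stringsAsFactors = FALSE)
  }))
  if (spec$noise_sd_mm > 0) {
    rows$u_mm <- rows$u_mm + stats::rnorm(nrow(rows), 0, spec$noise_sd_mm)
    rows$v_mm <- rows$v_mm + stats::rnorm(nrow(rows), 0, spec$noise_sd_mm)
  }
  lms <- landmark_set(rows, scale = c(pa = 1, lat = 1),
                      v_offset = c(pa = 0, lat = 0),
                      levels = labels,
                      v_tol_mm = max(5, 8 * spec$noise_sd_mm))
  list(landmarks = lms, truth = truth)
}

#' CT-like reference coordinates for validation
#'
#' Returns one 3D point per vertebra (the superior posterior point, the
#' same anatomical landmark the model comparison uses), offset by a
#' posture shift plus optional Gaussian noise.  Emulates the systematic
#' standing-vs-supine posture discrepancy between radiograph-derived
#' models and CT reconstructions; used to exercise the MAE validation.
#'
#' @param truth a `ground_truth` from [generate_spine()].
#' @param posture_shift scalar, length-3 vector, or n x 3 matrix of
#'   per-level offsets (mm).
#' @param noise_sd_mm Gaussian noise standard deviation (mm).
#' @param seed integer seed.
#' @return n x 3 matrix of reference coordinates with level rownames.
#' @export
generate_reference_coords <- function(truth, posture_shift = 0,
                                      noise_sd_mm = 0, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  pts <- t(vapply(truth$params, function(p) p$p_sup_post, numeric(3)))
  rownames(pts) <- vapply(truth$params, function(p) p$level, character(1))
  n <- nrow(pts)
  if (is.matrix(posture_shift)) {
    if (nrow(posture_shift) != n || ncol(posture_shift) != 3) {
      stop("posture_shift matrix must be ", n, " x 3")
    }
    shift <- posture_shift
  } else if (length(posture_shift) %in% c(1, 3)) {
    shift <- matrix(posture_shift, n, 3, byrow = TRUE)
  } else {
    stop("posture_shift length mismatch with truth")
  }
  set.seed(as.integer(seed))
  noise <- if (noise_sd_mm > 0) {
    matrix(stats::rnorm(3 * n, 0, noise_sd_mm), n, 3)
  } else {
    0
  }
  pts + shift + noise
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$params), "vertebrae;",
      sprintf("Cobb %.2f deg (%s/%s)", x$true_cobb_deg,
              x$cobb_levels[1], x$cobb_levels[2]),
      if (!is.na(x$true_tlk_deg)) {
        sprintf("; TLK %.2f deg", x$true_tlk_deg)
      } else "", "\n")
  invisible(x)
}
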