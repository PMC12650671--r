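## Linear-static solver.  Sparse symmetric assembly over translational
## DOFs (plus rotational DOFs on beam-connected nodes), linear
## multi-point constraints eliminated through a sparse transformation
## matrix, and an active-set iteration for the tension-only trusses:
## solve, deactivate compressed tension-only elements, re-solve until
## the active set is stable.

#' Flexion load case
#'
#' The inferior face of the most caudal vertebra is fixed; a flexion
#' moment about the mediolateral (X) axis is applied to the most cranial
#' vertebra as an equal-and-opposite vertical force couple on its
#' anterior and posterior superior-endplate node rows (this avoids
#' rotational DOFs on the solid mesh).  When `match_target_deg` is set
#' the load magnitude is iterated until the total flexion angle matches.
#'
#' @param moment_nm applied flexion moment (Nm).
#' @param fixed_set,anterior_set,posterior_set node-set names in the
#'   spine mesh.
#' @param match_target_deg optional total-flexion target (degrees).
#' @param tol_deg matching tolerance (degrees).
#' @return list of class `load_case`.
#' @export
load_case <- function(moment_nm = 10, fixed_set = "inferior_face",
                      anterior_set = "load_anterior",
                      posterior_set = "load_posterior",
                      match_target_deg = NULL, tol_deg = 0.05) {
  stopifnot(moment_nm >= 0)
  structure(list(moment_nm = moment_nm, fixed_set = fixed_set,
                 anterior_set = anterior_set,
                 posterior_set = posterior_set,
                 match_target_deg = match_target_deg, tol_deg = tol_deg),
            class = "load_case")
}

## DOF numbering, cached element matrices and the constraint/fixation
## reduction operator
fe_system <- function(spine, mats, fixed_set) {
  n <- nrow(spine$nodes)
  tdof <- matrix(seq_len(3 * n), n, 3, byrow = TRUE)
  ndof <- 3L * n
  rdof <- matrix(NA_integer_, n, 3)
  if (!is.null(spine$beam)) {
    bn <- sort(unique(as.vector(spine$beam)))
    rdof[bn, ] <- matrix(ndof + seq_len(3 * length(bn)), length(bn), 3,
                         byrow = TRUE)
    ndof <- ndof + 3L * length(bn)
  }

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  push <- function(dofs, Ke) {
    idx <- length(trip_i) + 1L
    trip_i[[idx]] <<- rep(dofs, times = length(dofs))
    trip_j[[idx]] <<- rep(dofs, each = length(dofs))
    trip_x[[idx]] <<- as.vector(Ke)
  }
  for (e in seq_len(nrow(spine$hex))) {
    conn <- spine$hex[e, ]
    sm <- solid_material(mats, spine$hex_info$mat[e])
    Ke <- hex8_stiffness(spine$nodes[conn, , drop = FALSE], sm$E, sm$nu)
    push(as.vector(t(tdof[conn, , drop = FALSE])), Ke)
  }
  if (!is.null(spine$beam)) {
    for (e in seq_len(nrow(spine$beam))) {
      conn <- spine$beam[e, ]
      sm <- solid_material(mats, spine$beam_info$mat[e])
      Ke <- beam_stiffness(spine$nodes[conn, , drop = FALSE], sm$E, sm$nu,
                           spine$beam_info$diameter[e])
      dofs <- c(tdof[conn[1], ], rdof[conn[1], ],
                tdof[conn[2], ], rdof[conn[2], ])
      push(dofs, Ke)
    }
  }
  base_trip <- list(i = unlist(trip_i), j = unlist(trip_j),
                    x = unlist(trip_x))

  trusses <- NULL; truss_trip <- NULL
  if (!is.null(spine$truss)) {
    trusses <- lapply(seq_len(nrow(spine$truss)), function(e) {
      conn <- spine$truss[e, ]
      lm <- line_material(mats, spine$truss_info$type[e])
      ts <- truss_stiffness(spine$nodes[conn, , drop = FALSE], lm$E,
                            spine$truss_info$area[e])
      list(dofs = c(tdof[conn[1], ], tdof[conn[2], ]), K = ts$K,
           dir = ts$dir, L = ts$L, k = ts$k,
           A = spine$truss_info$area[e], nodes = conn,
           tension_only = spine$truss_info$tension_only[e])
    })
    truss_trip <- list(
      i = unlist(lapply(trusses, function(tr) rep(tr$dofs, times = 6))),
      j = unlist(lapply(trusses, function(tr) rep(tr$dofs, each = 6))),
      x = unlist(lapply(trusses, function(tr) as.vector(tr$K)))
    )
  }

  fixed_nodes <- spine$node_sets[[fixed_set]]
  if (is.null(fixed_nodes) || length(fixed_nodes) == 0) {
    stop("fixed node set '", fixed_set, "' is empty")
  }
  fixed_dofs <- as.vector(tdof[fixed_nodes, ])

  slaves <- vapply(spine$constraints, function(cn) as.integer(cn$slave),
                   integer(1))
  slave_dofs <- if (length(slaves)) as.vector(tdof[slaves, ]) else integer(0)
  drop_dofs <- unique(c(fixed_dofs, slave_dofs))
  keep <- setdiff(seq_len(ndof), drop_dofs)
  col_of <- integer(ndof)
  col_of[keep] <- seq_along(keep)

  ti <- keep; tj <- seq_along(keep); tx <- rep(1, length(keep))
  for (cn in spine$constraints) {
    for (c3 in 1:3) {
      sd <- tdof[cn$slave, c3]
      md <- tdof[cn$masters, c3]
      ok <- !(md %in% fixed_dofs)
      if (any(ok)) {
        ti <- c(ti, rep(sd, sum(ok)))
        tj <- c(tj, col_of[md[ok]])
        tx <- c(tx, cn$weights[ok])
      }
    }
  }
  T <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(ndof, length(keep)))

  list(ndof = ndof, tdof = tdof, rdof = rdof, base_trip = base_trip,
       trusses = trusses, truss_trip = truss_trip, T = T,
       fixed_dofs = fixed_dofs, fixed_nodes = fixed_nodes,
       n_reduced = length(keep))
}

fe_assemble_K <- function(sys, active) {
  i <- sys$base_trip$i; j <- sys$base_trip$j; x <- sys$base_trip$x
  if (!is.null(sys$truss_trip) && any(active)) {
    sel <- rep(active, each = 36)
    i <- c(i, sys$truss_trip$i[sel])
    j <- c(j, sys$truss_trip$j[sel])
    x <- c(x, sys$truss_trip$x[sel])
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(sys$ndof, sys$ndof))
}

fe_load_vector <- function(spine, sys, lc) {
  f <- numeric(sys$ndof)
  if (lc$moment_nm == 0) return(f)
  ant <- spine$node_sets[[lc$anterior_set]]
  post <- spine$node_sets[[lc$posterior_set]]
  lever <- abs(mean(spine$nodes[ant, 2]) - mean(spine$nodes[post, 2]))
  if (lever < 1e-9) stop("zero lever arm between load node sets")
  Fz <- lc$moment_nm * 1000 / lever    # Nm -> N mm
  f[sys$tdof[ant, 3]] <- f[sys$tdof[ant, 3]] - Fz / length(ant)
  f[sys$tdof[post, 3]] <- f[sys$tdof[post, 3]] + Fz / length(post)
  f
}

truss_elongations <- function(sys, u) {
  vapply(sys$trusses, function(tr) {
    du <- u[tr$dofs[4:6]] - u[tr$dofs[1:3]]
    sum(du * tr$dir)
  }, numeric(1))
}

#' Solve a spine model under a load case
#'
#' Assembles the sparse symmetric system, eliminates multi-point
#' constraints and fixed DOFs, and iterates the tension-only active set
#' (cap 50 iterations; a cycling active set is resolved by freezing the
#' intersection of the cycle states).  The terminal active set carries
#' no compressed tension-only members.
#'
#' @param spine a `spine_mesh`.
#' @param lc a [load_case()].
#' @param mats material table (defaults to the mesh's own).
#' @return object of class `solve_result`: nodal displacements (mm),
#'   per-element centroid von Mises stresses (kPa), truss axial stresses
#'   (kPa) and active flags, per-vertebra sagittal rotations and total
#'   flexion angle (degrees, flexion positive), strain energy vs
#'   external work, reactions at the fixed set, and an iteration log.
#' @export
solve_spine <- function(spine, lc = load_case(),
                        mats = spine$config$materials) {
  sys <- fe_system(spine, mats, lc$fixed_set)
  f <- fe_load_vector(spine, sys, lc)
  n_tr <- length(sys$trusses)
  active <- rep(TRUE, n_tr)
  frozen <- rep(FALSE, n_tr)
  seen <- character(0)
  log <- list()
  u <- numeric(sys$ndof)
  for (it in seq_len(50)) {
    K <- fe_assemble_K(sys, active)
    Kr <- Matrix::forceSymmetric(Matrix::crossprod(sys$T, K %*% sys$T))
    fr <- as.numeric(Matrix::crossprod(sys$T, f))
    ur <- tryCatch(
      as.numeric(Matrix::solve(Matrix::Cholesky(Kr, perm = TRUE),
                               fr, system = "A")),
      error = function(e) {
        stop(errorCondition(paste0("singular system (under-constrained ",
                                   "model?): ", conditionMessage(e)),
                            class = c("spinefe_solver_error", "error",
                                      "condition")))
      })
    u <- as.numeric(sys$T %*% ur)
    if (n_tr == 0) {
      log[[it]] <- list(it = it, active = 0L, changed = 0L)
      break
    }
    elong <- truss_elongations(sys, u)
    tension_only <- vapply(sys$trusses, `[[`, logical(1), "tension_only")
    want <- !tension_only | elong >= -1e-12
    want[frozen] <- FALSE
    changed <- sum(want != active)
    log[[it]] <- list(it = it, active = sum(active), changed = changed)
    if (changed == 0) break
    state <- paste(as.integer(want), collapse = "")
    if (state %in% seen) {
      ## oscillation: damp by freezing the members that keep cycling out
      frozen <- frozen | (!want & active) | (want & !active & elong < 0)
      want <- want & !frozen
      seen <- character(0)
    }
    seen <- c(seen, paste(as.integer(active), collapse = ""))
    active <- want
    if (it == 50) {
      stop(errorCondition(
        "tension-only active set did not stabilize in 50 iterations",
        class = c("spinefe_solver_error", "error", "condition")))
    }
  }

  res <- fe_postprocess(spine, sys, u, f, active, mats)
  res$iterations <- log
  res$load_case <- lc
  res
}

## small-rotation rigid-body fit of a node cloud: u ~ t + omega x r
rigid_fit <- function(coords, disp) {
  rc <- colMeans(coords)
  rho <- sweep(coords, 2, rc)
  uc <- colMeans(disp)
  du <- sweep(disp, 2, uc)
  M <- diag(3) * sum(rho^2) - crossprod(rho)
  b <- c(sum(rho[, 2] * du[, 3] - rho[, 3] * du[, 2]),
         sum(rho[, 3] * du[, 1] - rho[, 1] * du[, 3]),
         sum(rho[, 1] * du[, 2] - rho[, 2] * du[, 1]))
  omega <- solve(M, b)
  list(t = uc, omega = omega)
}

fe_postprocess <- function(spine, sys, u, f, active, mats) {
  n <- nrow(spine$nodes)
  U <- matrix(u[as.vector(t(sys$tdof))], n, 3, byrow = TRUE)

  hex_sigma <- matrix(0, nrow(spine$hex), 6)
  for (e in seq_len(nrow(spine$hex))) {
    conn <- spine$hex[e, ]
    sm <- solid_material(mats, spine$hex_info$mat[e])
    ue <- as.vector(t(U[conn, , drop = FALSE]))
    hex_sigma[e, ] <- hex8_centroid_stress(
      spine$nodes[conn, , drop = FALSE], ue, sm$E, sm$nu)
  }
  hex_vm_kpa <- von_mises(hex_sigma) * 1000

  truss_stress_kpa <- numeric(0)
  if (length(sys$trusses)) {
    elong <- truss_elongations(sys, u)
    force <- ifelse(active, vapply(sys$trusses, `[[`, numeric(1), "k") *
                      elong, 0)
    truss_stress_kpa <- force /
      vapply(sys$trusses, `[[`, numeric(1), "A") * 1000
  }

  rot <- vapply(spine$levels, function(lv) {
    ids <- which(spine$node_level == lv)
    -rad2deg(rigid_fit(spine$nodes[ids, , drop = FALSE],
                       U[ids, , drop = FALSE])$omega[1])
  }, numeric(1))
  names(rot) <- spine$levels

  K <- fe_assemble_K(sys, active)
  residual <- as.numeric(K %*% u) - f
  reactions <- residual[sys$fixed_dofs]
  strain_energy <- 0.5 * sum(u * as.numeric(K %*% u))
  external_work <- 0.5 * sum(f * u)

  structure(list(U = U, u_full = u, f = f,
                 hex_sigma = hex_sigma, hex_vm_kpa = hex_vm_kpa,
                 truss_stress_kpa = truss_stress_kpa,
                 truss_active = active,
                 vertebra_rotation_deg = rot,
                 flexion_deg = rot[[length(rot)]],
                 strain_energy = strain_energy,
                 external_work = external_work,
                 reactions = reactions),
            class = "solve_result")
}

#' Recompute per-element von Mises stresses from displacements
#'
#' Centroid-evaluated strain to stress to von Mises for solids (kPa);
#' axial stress for trusses (zero for inactive tension-only members).
#' Useful for prescribed displacement fields in verification tests.
#'
#' @param spine a `spine_mesh`.
#' @param result a `solve_result`, or a displacement matrix (n x 3 mm).
#' @param mats material table.
#' @return list with `hex_vm_kpa` and `truss_stress_kpa`.
#' @export
compute_stresses <- function(spine, result,
                             mats = spine$config$materials) {
  U <- if (inherits(result, "solve_result")) result$U else result
  sig <- matrix(0, nrow(spine$hex), 6)
  for (e in seq_len(nrow(spine$hex))) {
    conn <- spine$hex[e, ]
    sm <- solid_material(mats, spine$hex_info$mat[e])
    ue <- as.vector(t(U[conn, , drop = FALSE]))
    sig[e, ] <- hex8_centroid_stress(spine$nodes[conn, , drop = FALSE],
                                     ue, sm$E, sm$nu)
  }
  truss_kpa <- numeric(0)
  if (!is.null(spine$truss)) {
    truss_kpa <- vapply(seq_len(nrow(spine$truss)), function(e) {
      conn <- spine$truss[e, ]
      lm <- line_material(mats, spine$truss_info$type[e])
      d <- spine$nodes[conn[2], ] - spine$nodes[conn[1], ]
      L <- sqrt(sum(d^2))
      el <- sum((U[conn[2], ] - U[conn[1], ]) * d / L)
      s <- lm$E * el / L
      if (spine$truss_info$tension_only[e] && s < 0) 0 else s * 1000
    }, numeric(1))
  }
  list(hex_vm_kpa = von_mises(sig) * 1000, hex_sigma = sig,
       truss_stress_kpa = truss_kpa)
}

#' Match the total flexion angle by scaling the load
#'
#' Secant iteration on the load magnitude until the total flexion angle
#' (sagittal rigid-fit rotation of the most cranial vertebra relative to
#' the fixed base) matches `target_deg` within `tol_deg`.  Because the
#' tension-only active set is invariant under positive load scaling, the
#' iteration converges in at most two solves for this model class.
#'
#' @param spine a `spine_mesh` (typically instrumented).
#' @param target_deg target total flexion (degrees, > 0 unless 0 for the
#'   trivial no-load case).
#' @param tol_deg angle tolerance (degrees, default 0.05).
#' @param lc template load case (its magnitude is the starting guess).
#' @param mats material table.
#' @return list with `result` (a `solve_result`), `moment_nm` (matched
#'   load magnitude) and `iterations`.
#' @export
match_flexion_angle <- function(spine, target_deg, tol_deg = 0.05,
                                lc = load_case(),
                                mats = spine$config$materials) {
  if (target_deg == 0) {
    lc$moment_nm <- 0
    return(list(result = solve_spine(spine, lc, mats), moment_nm = 0,
                iterations = 0L))
  }
  stopifnot(target_deg > 0)
  m <- if (lc$moment_nm > 0) lc$moment_nm else 1
  res <- NULL
  for (it in seq_len(30)) {
    lc$moment_nm <- m
    res <- solve_spine(spine, lc, mats)
    a <- res$flexion_deg
    if (abs(a - target_deg) <= tol_deg) {
      return(list(result = res, moment_nm = m, iterations = it))
    }
    if (a <= 0) {
      stop(errorCondition("model does not flex under the applied couple",
                          class = c("spinefe_solver_error", "error",
                                    "condition")))
    }
    m <- m * target_deg / a
  }
  stop(errorCondition(
    "flexion-angle matching did not converge in 30 iterations",
    class = c("spinefe_solver_error", "error", "condition")))
}
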