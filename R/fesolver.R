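#' Material-point protocol driver
#'
#' Evaluates the constitutive law along a prescribed deformation-gradient
#' history: per step it returns the fibre stretch, second Piola-Kirchhoff
#' and Cauchy stresses, the von Mises stress and the effective Green
#' strain. This is the verification driver for the stress, tangent and
#' injury models at a single material point.
#'
#' @param F_history list of 3x3 deformation gradients, one per step.
#' @param a0 reference unit fibre direction.
#' @param params a \code{\link{material_params}}.
#' @param times optional per-step times (ms) carried through to the output.
#' @return data.frame with one row per step: \code{step}, \code{time},
#'   \code{lambda}, \code{J}, S and T components (columns \code{S11..S23},
#'   \code{T11..T23}), \code{von_mises}, \code{eps_eff}, and the
#'   fibre-direction component \code{S_fibre = a0' S a0}.
#' @export
run_protocol <- function(F_history, a0 = c(1, 0, 0), params = muscle_params(),
                         times = seq_along(F_history)) {
  rows <- lapply(seq_along(F_history), function(i) {
    st <- deformation_state(F_history[[i]], a0)
    S <- second_pk(st, params)
    T <- cauchy(st, S)
    E <- green_strain(st$F)
    data.frame(step = i, time = times[i], lambda = st$lambda, J = st$J,
               S11 = S[1, 1], S22 = S[2, 2], S33 = S[3, 3],
               S12 = S[1, 2], S13 = S[1, 3], S23 = S[2, 3],
               T11 = T[1, 1], T22 = T[2, 2], T33 = T[3, 3],
               T12 = T[1, 2], T13 = T[1, 3], T23 = T[2, 3],
               von_mises = von_mises(T), eps_eff = effective_strain(E),
               S_fibre = as.numeric(st$a0 %*% S %*% st$a0))
  })
  do.call(rbind, rows)
}

#' Load case for the static FE solver
#'
#' @param dirichlet data.frame with columns \code{node}, \code{dof} (1..3)
#'   and \code{value} (prescribed displacement, mm).
#' @param body_force length-3 acceleration vector (mm/ms^2) applied as
#'   rho0 * g per unit reference volume, or NULL.
#' @param density reference density (g/mm^3) used with \code{body_force}.
#' @param nodal_loads data.frame with columns \code{node}, \code{dof},
#'   \code{value} (force, N-consistent units), or NULL.
#' @param ramp_steps number of equal load increments.
#' @return object of class \code{load_case}.
#' @export
load_case <- function(dirichlet, body_force = NULL, density = 1e-3,
                      nodal_loads = NULL, ramp_steps = 10L) {
  stopifnot(is.data.frame(dirichlet),
            all(c("node", "dof", "value") %in% names(dirichlet)))
  structure(list(dirichlet = dirichlet, body_force = body_force,
                 density = density, nodal_loads = nodal_loads,
                 ramp_steps = as.integer(ramp_steps)),
            class = "load_case")
}

# per-element reference shape-function gradients and volumes
.element_gradients <- function(mesh) {
  ne <- nrow(mesh$elements)
  grads <- vector("list", ne)
  vols <- numeric(ne)
  for (e in seq_len(ne)) {
    X <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    Dm <- t(X[2:4, , drop = FALSE] - matrix(X[1, ], 3, 3, byrow = TRUE))
    vols[e] <- det(Dm) / 6
    Dmi <- solve(Dm)
    # barycentric coords of nodes 2..4 satisfy X - X1 = Dm %*% lambda, so
    # grad lambda_a = rows of Dm^-1; node 1 closes partition of unity
    grads[[e]] <- rbind(-colSums(Dmi), Dmi)
  }
  list(grads = grads, vols = vols)
}

# element internal force (12-vector) and tangent stiffness (12x12)
.element_force_stiffness <- function(F, S, CC, grad, vol) {
  P <- F %*% S                               # first Piola-Kirchhoff
  fint <- vol * (grad %*% t(P))              # 4 x 3, rows per node
  # A_iJkL = delta_ik S_JL + F_iM CC_MJLQ F_kQ (two-point tangent dP/dF);
  # FCm[i, N, O, P] = F_iM CC[M, N, O, P]
  A <- array(0, c(3, 3, 3, 3))
  Cm <- CC; dim(Cm) <- c(3, 27)
  FCm <- F %*% Cm; dim(FCm) <- c(3, 3, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    # block B_ik[J, L] = d_ik S_JL + sum_Q FCm[i, J, L, Q] F_kQ
    blk <- matrix(0, 3, 3)
    for (J in 1:3) for (L in 1:3)
      blk[J, L] <- sum(FCm[i, J, L, ] * F[k, ])
    if (i == k) blk <- blk + S
    A[i, , k, ] <- blk
  }
  K <- matrix(0, 12, 12)
  for (a in 1:4) for (b in 1:4) {
    # K_block[i,k] = vol * grad[a,J] A[i,J,k,L] grad[b,L]
    blk <- matrix(0, 3, 3)
    for (i in 1:3) for (k in 1:3)
      blk[i, k] <- grad[a, ] %*% A[i, , k, ] %*% grad[b, ]
    K[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- vol * blk
  }
  list(fint = as.numeric(t(fint)), K = K)
}

#' Static total-Lagrangian FE solve on a tetrahedral mesh
#'
#' Newton iterations on the static balance of linear momentum (inertia
#' dropped): single-point-integrated linear tetrahedra, exact consistent
#' tangent, Dirichlet conditions by elimination, optional body force, and
#' equal load-increment ramping. Convergence when the residual norm falls
#' below \code{tol} times the external-force norm (or an absolute floor for
#' pure-Dirichlet cases).
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param materials named list of \code{\link{material_params}} keyed by part
#'   label, or a single \code{material_params} for all parts.
#' @param load a \code{\link{load_case}}.
#' @param fibre_field optional \code{\link{element_fibre_field}}; elements
#'   without a direction fall back to global x (irrelevant at gamma = 1).
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration cap per increment.
#' @param verbose print per-iteration residuals.
#' @return list with \code{displacements} (n_nodes x 3, mm), per-element
#'   \code{stress} (n_elem x 6 Cauchy components), \code{von_mises},
#'   \code{eps_eff}, \code{F} (list), \code{reactions} (n_nodes x 3),
#'   \code{converged}, \code{residual_history}.
#' @export
solve_static <- function(mesh, materials, load, fibre_field = NULL,
                         tol = 1e-8, max_iter = 30L, verbose = FALSE) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(load, "load_case"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements); ndof <- 3L * nn
  if (inherits(materials, "material_params")) {
    mats <- rep(list(materials), ne)
  } else {
    mats <- lapply(mesh$part_labels, function(p) {
      m <- materials[[p]]
      if (is.null(m)) stop(sprintf("no material for part '%s'", p))
      m
    })
  }
  a0s <- matrix(1, ne, 3) * rep(c(1, 0, 0), each = ne)
  if (!is.null(fibre_field)) {
    ok <- !is.na(fibre_field$directions[, 1])
    a0s[ok, ] <- fibre_field$directions[ok, , drop = FALSE]
  }
  eg <- .element_gradients(mesh)
  # external force vector at full load
  fext <- numeric(ndof)
  if (!is.null(load$body_force)) {
    bf <- load$density * as.numeric(load$body_force)
    for (e in seq_len(ne)) {
      nodes <- mesh$elements[e, ]
      share <- eg$vols[e] / 4
      for (a in 1:4)
        fext[(3 * nodes[a] - 2):(3 * nodes[a])] <-
          fext[(3 * nodes[a] - 2):(3 * nodes[a])] + share * bf
    }
  }
  if (!is.null(load$nodal_loads))
    for (r in seq_len(nrow(load$nodal_loads))) {
      i <- 3L * (load$nodal_loads$node[r] - 1L) + load$nodal_loads$dof[r]
      fext[i] <- fext[i] + load$nodal_loads$value[r]
    }
  bc_idx <- 3L * (load$dirichlet$node - 1L) + load$dirichlet$dof
  if (anyDuplicated(bc_idx)) stop("duplicate Dirichlet constraints")
  # well-posedness: the constrained dofs must span all 6 rigid modes
  # (3 translations + 3 infinitesimal rotations about the centroid)
  ctr <- colMeans(mesh$nodes)
  rot_basis <- list(function(p) c(0, -p[3], p[2]),
                    function(p) c(p[3], 0, -p[1]),
                    function(p) c(-p[2], p[1], 0))
  Rc <- vapply(seq_len(nrow(load$dirichlet)), function(r) {
    nd <- load$dirichlet$node[r]; dof <- load$dirichlet$dof[r]
    p <- mesh$nodes[nd, ] - ctr
    c(as.numeric(dof == 1:3), vapply(rot_basis, function(f) f(p)[dof], 1))
  }, numeric(6))
  if (nrow(load$dirichlet) < 6L || qr(t(Rc))$rank < 6L)
    stop("singular system: check that the Dirichlet set removes all rigid modes")
  bc_val <- load$dirichlet$value
  free <- setdiff(seq_len(ndof), bc_idx)
  u <- numeric(ndof)
  res_hist <- numeric(0)
  converged <- TRUE
  elem_dofs <- matrix(0L, ne, 12)
  for (a in 1:4) elem_dofs[, (3 * a - 2):(3 * a)] <-
    cbind(3L * mesh$elements[, a] - 2L, 3L * mesh$elements[, a] - 1L,
          3L * mesh$elements[, a])
  assemble <- function(u) {
    fint <- numeric(ndof)
    trip_i <- vector("list", ne); trip_j <- vector("list", ne)
    trip_x <- vector("list", ne)
    U <- matrix(u, nn, 3, byrow = TRUE)
    for (e in seq_len(ne)) {
      grad <- eg$grads[[e]]
      Ue <- U[mesh$elements[e, ], , drop = FALSE]
      F <- diag(3) + t(Ue) %*% grad
      st <- deformation_state(F, a0s[e, ])
      S <- second_pk(st, mats[[e]])
      CC <- material_tangent(st, mats[[e]])
      ek <- .element_force_stiffness(F, S, CC, grad, eg$vols[e])
      dofs <- elem_dofs[e, ]
      fint[dofs] <- fint[dofs] + ek$fint
      trip_i[[e]] <- rep(dofs, times = 12)
      trip_j[[e]] <- rep(dofs, each = 12)
      trip_x[[e]] <- as.numeric(ek$K)
    }
    K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(ndof, ndof))
    list(fint = fint, K = K)
  }
  ref_norm <- max(sqrt(sum(fext^2)), 1e-12)
  for (inc in seq_len(load$ramp_steps)) {
    frac <- inc / load$ramp_steps
    u[bc_idx] <- frac * bc_val
    fext_inc <- frac * fext
    for (it in seq_len(max_iter)) {
      asm <- assemble(u)
      r <- asm$fint - fext_inc
      rn <- sqrt(sum(r[free]^2))
      res_hist <- c(res_hist, rn)
      scale <- if (sqrt(sum(fext^2)) > 1e-12) frac * ref_norm else
        max(sqrt(sum(asm$fint[bc_idx]^2)), 1)
      if (verbose) message(sprintf("inc %d it %d residual %.3e", inc, it, rn))
      if (rn < tol * scale) break
      Kff <- Matrix::forceSymmetric(asm$K[free, free, drop = FALSE])
      rigid_msg <- "singular system: check that the Dirichlet set removes all rigid modes"
      du <- tryCatch(as.numeric(Matrix::solve(Kff, r[free])),
                     error = function(e) stop(rigid_msg))
      if (any(!is.finite(du))) stop(rigid_msg)
      u[free] <- u[free] - du
      if (it == max_iter) {
        warning(sprintf("Newton did not converge in increment %d (residual %.3e)",
                        inc, rn))
        converged <- FALSE
      }
    }
  }
  # recover element fields and reactions at the converged state
  asm <- assemble(u)
  U <- matrix(u, nn, 3, byrow = TRUE)
  stress <- matrix(0, ne, 6); vm <- numeric(ne); eps <- numeric(ne)
  Flist <- vector("list", ne)
  for (e in seq_len(ne)) {
    Ue <- U[mesh$elements[e, ], , drop = FALSE]
    F <- diag(3) + t(Ue) %*% eg$grads[[e]]
    st <- deformation_state(F, a0s[e, ])
    T <- cauchy(st, second_pk(st, mats[[e]]))
    stress[e, ] <- c(T[1, 1], T[2, 2], T[3, 3], T[1, 2], T[1, 3], T[2, 3])
    vm[e] <- von_mises(T)
    eps[e] <- effective_strain(green_strain(F))
    Flist[[e]] <- F
  }
  reactions <- matrix(0, nn, 3)
  rvec <- asm$fint - fext
  reactions[cbind(load$dirichlet$node, load$dirichlet$dof)] <- rvec[bc_idx]
  list(displacements = U, stress = stress, von_mises = vm, eps_eff = eps,
       F = Flist, reactions = reactions, converged = converged,
       residual_history = res_hist)
}

#' Export a solved state as legacy VTK for inspection
#'
#' Writes the deformed mesh with per-element Cauchy stress, von Mises
#' stress, effective strain and (optionally) injury flags as CELL_DATA.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param solution result of \code{\link{solve_static}}.
#' @param path output path.
#' @param injured optional per-element logical flags.
#' @export
write_solution_vtk <- function(mesh, solution, path, injured = NULL) {
  dm <- tet_mesh(mesh$nodes + solution$displacements, mesh$elements,
                 mesh$part_labels)
  cd <- list(von_mises = solution$von_mises, eps_eff = solution$eps_eff,
             stress = cbind(solution$stress[, c(1, 4, 5)],
                            solution$stress[, c(4, 2, 6)],
                            solution$stress[, c(5, 6, 3)]))
  if (!is.null(injured)) cd$injured <- as.numeric(injured)
  write_mesh(dm, path, dialect = "vtk", cell_data = cd)
}

#' Mesh-refinement convergence study of the volume-normalised stress
#'
#' Solves the same load case on a family of meshes and reports the
#' volume-normalised von Mises stress per refinement level together with
#' the relative change between consecutive levels; the change between the
#' two finest levels is the usual convergence criterion.
#'
#' @param meshes list of \code{\link{tet_mesh}}, coarse to fine.
#' @param make_load function(mesh) -> \code{\link{load_case}} building the
#'   equivalent load case per mesh.
#' @param materials as in \code{\link{solve_static}}.
#' @param ... passed to \code{\link{solve_static}}.
#' @return data.frame with \code{level}, \code{n_elements},
#'   \code{sigma_bar} (MPa) and \code{rel_change_percent} vs the previous
#'   level.
#' @export
convergence_study <- function(meshes, make_load, materials, ...) {
  sb <- vapply(seq_along(meshes), function(i) {
    sol <- solve_static(meshes[[i]], materials, make_load(meshes[[i]]), ...)
    normalised_stress(meshes[[i]], sol$von_mises)
  }, 1)
  rel <- c(NA, 100 * abs(diff(sb)) / utils::head(sb, -1))
  data.frame(level = seq_along(meshes),
             n_elements = vapply(meshes, function(m) nrow(m$elements), 1L),
             sigma_bar = sb, rel_change_percent = rel)
}
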