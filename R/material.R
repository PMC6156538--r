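#' Transversely isotropic hyperelastic soft-tissue parameters
#'
#' Parameter set for the muscle/fat constitutive law: a compressible
#' Mooney-Rivlin-type isotropic matrix (coefficients c1, c2 and bulk
#' modulus k, all MPa) plus an additive fibre contribution along the
#' reference fibre direction with a passive stretch-driven part (c3 in MPa,
#' dimensionless exponent c4) and an active contraction part (peak stress
#' s_max in MPa at optimal fibre stretch lambda_opt, bell shape set by
#' dw_asc/dw_dsc and exponents nu_asc/nu_dsc). The binary switch gamma
#' removes the fibre contribution entirely (gamma = 1: isotropic tissue such
#' as fat/skin); activation alpha in [0, 1] scales the active part.
#'
#' The default values are the published muscle set; \code{skin_fat_params()}
#' returns the same set with gamma = 1.
#'
#' @param c1,c2 isotropic matrix coefficients (MPa).
#' @param bulk_k bulk modulus (MPa); the quasi-incompressibility penalty.
#' @param c3 passive fibre coefficient (MPa).
#' @param c4 passive fibre exponent (dimensionless).
#' @param s_max peak active fibre stress (MPa).
#' @param dw_asc,dw_dsc widths of the ascending/descending active branches.
#' @param nu_asc,nu_dsc exponents of the ascending/descending branches.
#' @param lambda_opt optimal fibre stretch (> 1).
#' @param gamma fibre switch: 0 = fibrous, 1 = isotropic only.
#' @param alpha activation level in [0, 1].
#' @return an object of class \code{material_params}.
#' @export
material_params <- function(c1 = 2.5e-6, c2 = 6e-3, bulk_k = 0.1,
                            c3 = 1e-3, c4 = 6, s_max = 0.1,
                            dw_asc = 0.15, dw_dsc = 0.16,
                            nu_asc = 2, nu_dsc = 4, lambda_opt = 1.3,
                            gamma = 0, alpha = 0) {
  stopifnot(s_max >= 0, lambda_opt > 1, alpha >= 0, alpha <= 1,
            gamma %in% c(0, 1), bulk_k >= 0)
  structure(list(c1 = c1, c2 = c2, bulk_k = bulk_k, c3 = c3, c4 = c4,
                 s_max = s_max, dw_asc = dw_asc, dw_dsc = dw_dsc,
                 nu_asc = nu_asc, nu_dsc = nu_dsc, lambda_opt = lambda_opt,
                 gamma = gamma, alpha = alpha),
            class = "material_params")
}

#' @rdname material_params
#' @export
muscle_params <- function(alpha = 0) material_params(gamma = 0, alpha = alpha)

#' @rdname material_params
#' @export
skin_fat_params <- function() material_params(gamma = 1, alpha = 0)

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf(paste0("<material_params> c1=%g c2=%g k=%g MPa | c3=%g c4=%g | ",
                     "s_max=%g @ lambda_opt=%g | gamma=%d alpha=%g\n"),
              x$c1, x$c2, x$bulk_k, x$c3, x$c4, x$s_max, x$lambda_opt,
              x$gamma, x$alpha))
  invisible(x)
}

#' Read material parameter blocks from a flat key-value config file
#'
#' Format: \code{[block_name]} headers followed by \code{key = value} lines;
#' blank lines and \code{#} comments ignored. Unknown keys are rejected.
#'
#' @param path config file path.
#' @return named list of \code{\link{material_params}}.
#' @export
read_material_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); cur <- NULL; kv <- list()
  flush <- function(cur, kv, out) {
    if (is.null(cur)) return(out)
    known <- names(formals(material_params))
    bad <- setdiff(names(kv), known)
    if (length(bad)) stop(sprintf("unknown material key(s) in [%s]: %s",
                                  cur, paste(bad, collapse = ", ")))
    out[[cur]] <- do.call(material_params, kv)
    out
  }
  for (s in lines) {
    if (startsWith(s, "[")) {
      out <- flush(cur, kv, out)
      cur <- gsub("^\\[|\\]$", "", s); kv <- list()
    } else {
      p <- strsplit(s, "=")[[1]]
      if (length(p) != 2L) stop(sprintf("malformed config line: '%s'", s))
      kv[[trimws(p[1])]] <- as.numeric(trimws(p[2]))
    }
  }
  flush(cur, kv, out)
}

#' Deformation state derived from a deformation gradient
#'
#' Computes the kinematic quantities the constitutive law consumes: right
#' and left Cauchy-Green tensors C and b, J = det F, the isotropic
#' invariants I1, I2, I3 of C, and — given a reference fibre direction a0 —
#' the structural tensor M = a0 (x) a0, the fourth invariant I4 = M : C and
#' the fibre stretch Lambda = sqrt(I4).
#'
#' @param F 3x3 deformation gradient with det F > 0.
#' @param a0 reference unit fibre direction (default e1).
#' @return an object of class \code{deformation_state}.
#' @export
deformation_state <- function(F, a0 = c(1, 0, 0)) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (J <= 0) stop("deformation gradient must have positive determinant")
  a0 <- a0 / sqrt(sum(a0^2))
  C <- crossprod(F)
  M <- tcrossprod(a0)
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  I3 <- det(C)
  I4 <- sum(M * C)
  structure(list(F = F, a0 = a0, C = C, b = tcrossprod(F), J = J, M = M,
                 I1 = I1, I2 = I2, I3 = I3, I4 = I4, lambda = sqrt(I4),
                 Cinv = solve(C)),
            class = "deformation_state")
}

# scalar coefficients of the isotropic stress
.iso_coefs <- function(st, pr) {
  I3m13 <- st$I3^(-1 / 3); I3m23 <- st$I3^(-2 / 3)
  list(B1 = 2 * pr$c1 * I3m13 + 2 * pr$c2 * I3m23 * st$I1,
       B2 = -2 * pr$c2 * I3m23,
       B3 = -(2 / 3) * pr$c1 * I3m13 * st$I1 - (4 / 3) * pr$c2 * I3m23 * st$I2)
}

#' Isotropic part of the second Piola-Kirchhoff stress
#'
#' Compressible isotropic matrix stress
#' S_iso = B1 I + B2 C + B3 C^-1 + k (J - 1) J C^-1 with
#' B1 = 2 c1 I3^(-1/3) + 2 c2 I3^(-2/3) I1, B2 = -2 c2 I3^(-2/3),
#' B3 = -(2/3) c1 I3^(-1/3) I1 - (4/3) c2 I3^(-2/3) I2. At F = I the
#' coefficients cancel (B1 + B2 + B3 = 0), so the reference configuration
#' is stress-free for every parameter set.
#'
#' @param state a \code{\link{deformation_state}}.
#' @param params a \code{\link{material_params}}.
#' @return symmetric 3x3 stress (MPa).
#' @export
iso_stress <- function(state, params) {
  co <- .iso_coefs(state, params)
  co$B1 * diag(3) + co$B2 * state$C +
    (co$B3 + params$bulk_k * (state$J - 1) * state$J) * state$Cinv
}

# scalar fibre stress s(Lambda) such that S_aniso = (1-gamma) s M,
# and its derivative ds/dLambda
.fibre_scalar <- function(lam, pr, branch = c("both", "pas", "act")) {
  branch <- match.arg(branch)
  s_pas <- ds_pas <- 0
  if (lam >= 1) {
    s_pas <- pr$c3 * (lam^pr$c4 - 1) / lam^2
    ds_pas <- pr$c3 * ((pr$c4 - 2) * lam^(pr$c4 - 3) + 2 * lam^(-3))
  }
  if (lam <= pr$lambda_opt) { dw <- pr$dw_asc; nu <- pr$nu_asc }
  else { dw <- pr$dw_dsc; nu <- pr$nu_dsc }
  u <- (lam / pr$lambda_opt - 1) / dw
  env <- exp(-abs(u)^nu)
  s_act <- pr$s_max / lam^2 * env
  denv <- -nu * abs(u)^(nu - 1) * sign(u) / (dw * pr$lambda_opt) * env
  ds_act <- pr$s_max * (-2 * lam^(-3) * env + lam^(-2) * denv)
  switch(branch,
         both = list(s = s_pas + pr$alpha * s_act,
                     ds = ds_pas + pr$alpha * ds_act),
         pas = list(s = s_pas, ds = ds_pas),
         act = list(s = s_act, ds = ds_act))
}

#' Anisotropic (fibre) part of the second Piola-Kirchhoff stress
#'
#' Two-branch fibre stress along the structural tensor M = a0 (x) a0:
#' the passive part c3 (Lambda^c4 - 1) / Lambda^2 switches on at
#' Lambda = 1; the active part s_max / Lambda^2 times an exponential
#' envelope peaks at Lambda = lambda_opt, with separate ascending and
#' descending branch widths and exponents. The whole contribution is gated
#' by (1 - gamma) and the active part scaled by alpha.
#'
#' @inheritParams iso_stress
#' @param part \code{"both"} (default), \code{"pas"} or \code{"act"}
#'   (ungated components for inspection; the gating (1 - gamma) and alpha
#'   apply only to \code{"both"}).
#' @return symmetric 3x3 stress (MPa).
#' @export
aniso_stress <- function(state, params, part = c("both", "pas", "act")) {
  part <- match.arg(part)
  if (part == "both" && params$gamma == 1) return(matrix(0, 3, 3))
  fs <- .fibre_scalar(state$lambda, params, branch = part)
  g <- if (part == "both") (1 - params$gamma) else 1
  g * fs$s * state$M
}

#' Total second Piola-Kirchhoff stress
#'
#' S = S_iso + (1 - gamma) (S_pas + alpha S_act).
#'
#' @inheritParams iso_stress
#' @return symmetric 3x3 stress (MPa).
#' @export
second_pk <- function(state, params) {
  iso_stress(state, params) + aniso_stress(state, params)
}

#' Cauchy stress by push-forward
#'
#' T = J^-1 F S F'.
#'
#' @param state a \code{\link{deformation_state}}.
#' @param S second Piola-Kirchhoff stress (3x3); computed from
#'   \code{params} if missing.
#' @param params a \code{\link{material_params}} (used when S is missing).
#' @return symmetric 3x3 Cauchy stress (MPa).
#' @export
cauchy <- function(state, S = NULL, params = NULL) {
  if (is.null(S)) S <- second_pk(state, params)
  state$F %*% S %*% t(state$F) / state$J
}

# fourth-order tensor helpers: 3x3x3x3 arrays
.t4_outer <- function(A, B) {             # (A (x) B)_ijkl = A_ij B_kl
  outer(A, B)
}
.t4_sym_id <- local({
  I <- diag(3)
  arr <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    arr[i, j, k, l] <- (I[i, k] * I[j, l] + I[i, l] * I[j, k]) / 2
  arr
})
# -(d C^-1 / d C): (Ci o Ci)_ijkl = (Ci_ik Ci_jl + Ci_il Ci_jk)/2
.t4_odot <- function(A) {
  arr <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    arr[i, j, k, l] <- (A[i, k] * A[j, l] + A[i, l] * A[j, k]) / 2
  arr
}

#' Material elasticity tangent
#'
#' The fourth-order material tangent C_MNOP = 2 dS/dC, assembled in closed
#' form from the invariant derivatives of the isotropic part and the scalar
#' fibre-stress derivative of the anisotropic part. It carries major and
#' both minor symmetries.
#'
#' @inheritParams iso_stress
#' @return numeric array 3x3x3x3 (MPa).
#' @export
material_tangent <- function(state, params) {
  C <- state$C; Ci <- state$Cinv; I <- diag(3)
  I3 <- state$I3; I1 <- state$I1; I2 <- state$I2; J <- state$J
  c1 <- params$c1; c2 <- params$c2; k <- params$bulk_k
  I3m13 <- I3^(-1 / 3); I3m23 <- I3^(-2 / 3)
  co <- .iso_coefs(state, params)
  # dB/dC as 3x3 matrices
  dB1 <- -(2 / 3) * c1 * I3m13 * Ci +
    2 * c2 * (-(2 / 3) * I3m23 * I1 * Ci + I3m23 * I)
  dB2 <- (4 / 3) * c2 * I3m23 * Ci
  dB3 <- -(2 / 3) * c1 * (-(1 / 3) * I3m13 * I1 * Ci + I3m13 * I) -
    (4 / 3) * c2 * (-(2 / 3) * I3m23 * I2 * Ci + I3m23 * (I1 * I - C))
  pen <- k * (J - 1) * J                    # penalty coefficient on C^-1
  dpen <- k * (I3 - J / 2) * Ci             # d[k(I3 - sqrt(I3))]/dC
  CC <- .t4_outer(I, dB1) + .t4_outer(C, dB2) + co$B2 * .t4_sym_id +
    .t4_outer(Ci, dB3 + dpen) - (co$B3 + pen) * .t4_odot(Ci)
  CC <- 2 * CC
  if (params$gamma != 1) {
    fs <- .fibre_scalar(state$lambda, params)
    # d s / d I4 = (ds/dLambda) / (2 Lambda)
    dsdI4 <- fs$ds / (2 * state$lambda)
    CC <- CC + (1 - params$gamma) * 2 * dsdI4 * .t4_outer(state$M, state$M)
  }
  CC
}

#' Spatial elasticity tangent (push-forward)
#'
#' B_ijkl = J^-1 F_iM F_jN F_kO F_lP C_MNOP; the J^-1 factor makes it the
#' tangent conjugate to the Cauchy stress.
#'
#' @param state a \code{\link{deformation_state}}.
#' @param C_mat material tangent from \code{\link{material_tangent}}; computed
#'   from \code{params} if missing.
#' @param params a \code{\link{material_params}}.
#' @return numeric array 3x3x3x3 (MPa).
#' @export
spatial_tangent <- function(state, C_mat = NULL, params = NULL) {
  if (is.null(C_mat)) C_mat <- material_tangent(state, params)
  # flatten index pairs column-major: (M, N) -> M + 3 (N - 1); then the
  # pair-wise push-forward matrix is the Kronecker product F (x) F
  C2 <- C_mat; dim(C2) <- c(9, 9)
  W <- state$F %x% state$F
  B <- W %*% C2 %*% t(W) / state$J
  dim(B) <- c(3, 3, 3, 3)
  B
}

#' Von Mises stress of a Cauchy stress tensor
#'
#' sqrt(3/2) times the Frobenius norm of the stress deviator.
#'
#' @param T symmetric 3x3 Cauchy stress (MPa).
#' @return scalar von Mises stress (MPa).
#' @export
von_mises <- function(T) {
  dev <- T - mean(diag(T)) * diag(3)
  sqrt(1.5 * sum(dev * dev))
}
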