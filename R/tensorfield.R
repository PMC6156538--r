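#' Per-voxel diffusion tensor field
#'
#' Holds the fitted symmetric 3x3 diffusion tensor per voxel (mm^2/s), the
#' fractional anisotropy, the principal eigenvector, and a valid-voxel mask.
#'
#' @param tensors numeric array \code{nx x ny x nz x 6}; the 6 unique tensor
#'   components ordered (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @param fa numeric array of fractional anisotropy values in [0, 1].
#' @param e1 array \code{nx x ny x nz x 3} of principal unit eigenvectors.
#' @param mask logical array of valid voxels.
#' @param voxel_size physical spacing (mm).
#' @return an object of class \code{tensor_field}.
#' @export
tensor_field <- function(tensors, fa, e1, mask, voxel_size = c(1, 1, 1)) {
  d <- dim(mask)
  stopifnot(length(d) == 3L, identical(dim(tensors), c(d, 6L)),
            identical(dim(fa), d), identical(dim(e1), c(d, 3L)))
  structure(list(tensors = tensors, fa = fa, e1 = e1, mask = mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<tensor_field> %dx%dx%d, %d masked voxels, FA range [%.3f, %.3f]\n",
              d[1], d[2], d[3], sum(x$mask),
              min(x$fa[x$mask]), max(x$fa[x$mask])))
  invisible(x)
}

.tensor_vec_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves for the symmetric tensor D minimising
#' || ln(S/S0) + b g' D g ||^2 over the gradient scheme (mono-exponential
#' signal model). Requires at least 6 non-collinear diffusion directions and
#' a b = 0 volume. Voxels with non-positive signal are masked out.
#'
#' @param stack a \code{\link{dwi_stack}} containing b0 and diffusion-weighted
#'   volumes.
#' @return a \code{\link{tensor_field}}.
#' @export
fit_tensor <- function(stack) {
  stopifnot(inherits(stack, "dwi_stack"))
  is_b0 <- stack$bvals == 0
  if (!any(is_b0)) stop("a b = 0 volume is required")
  dw <- which(!is_b0)
  if (length(dw) < 6L) stop("at least 6 diffusion directions are required")
  G <- stack$bvecs[dw, , drop = FALSE]
  A <- -stack$bvals[dw] *
    cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
          2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  if (qr(A)$rank < 6L) stop("gradient scheme is rank-deficient (collinear directions)")
  d <- dim(stack$volumes[[1]])
  nvox <- prod(d)
  S0 <- Reduce(`+`, stack$volumes[is_b0]) / sum(is_b0)
  Smat <- vapply(stack$volumes[dw], as.numeric, numeric(nvox))  # nvox x ndir
  mask <- as.numeric(S0) > 0 & apply(Smat > 0, 1L, all)
  Y <- matrix(0, nvox, length(dw))
  Y[mask, ] <- log(Smat[mask, , drop = FALSE] / as.numeric(S0)[mask])
  # one normal-equation solve applied to every voxel at once
  Dcoef <- t(qr.solve(A, t(Y)))                       # nvox x 6
  fa <- numeric(nvox); e1 <- matrix(0, nvox, 3)
  for (i in which(mask)) {
    Dm <- .tensor_vec_to_mat(Dcoef[i, ])
    eg <- eigen(Dm, symmetric = TRUE)
    fa[i] <- .fa_from_eigenvalues(eg$values)
    e1[i, ] <- eg$vectors[, 1]
  }
  tensor_field(array(Dcoef, c(d, 6L)), array(fa, d), array(e1, c(d, 3L)),
               array(mask, d), voxel_size = stack$voxel_size)
}

.fa_from_eigenvalues <- function(lam) {
  mb <- mean(lam)
  den <- sum(lam^2)
  if (den <= 0) return(0)
  min(1, max(0, sqrt(1.5 * sum((lam - mb)^2) / den)))
}

#' Fractional anisotropy of a diffusion tensor
#'
#' Standard eigenvalue-dispersion measure, clipped to [0, 1]: 0 for
#' isotropic diffusion, 1 for purely linear diffusion.
#'
#' @param tensor symmetric 3x3 matrix, or a length-6 component vector
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @return scalar FA in [0, 1].
#' @export
fractional_anisotropy <- function(tensor) {
  if (is.matrix(tensor)) D <- tensor else D <- .tensor_vec_to_mat(tensor)
  .fa_from_eigenvalues(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
}

#' Ordered fibre strand
#'
#' An ordered polyline of 3D points (mm), consecutively numbered from 1.
#'
#' @param points numeric matrix (n x 3), n >= 2.
#' @param id integer strand label.
#' @return an object of class \code{fibre_strand}.
#' @export
fibre_strand <- function(points, id = 1L) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(nrow(points) >= 2L)
  structure(list(points = points, id = as.integer(id)), class = "fibre_strand")
}

#' Deterministic streamline tracking along the principal eigenvector
#'
#' Bidirectional Euler integration of the principal-eigenvector field from
#' each seed, with hemisphere sign continuity (each step's direction is
#' flipped to have non-negative dot product with the previous step).
#' Tracking stops on mask exit, FA below \code{fa_stop}, or turning angle
#' above \code{max_angle_deg}. Strands shorter than \code{min_length_mm}
#' are discarded.
#'
#' @param field a \code{\link{tensor_field}}.
#' @param seeds matrix (n x 3) of seed positions in mm (voxel centres at
#'   (i-0.5)*voxel_size).
#' @param step_mm Euler step length (mm); must be positive.
#' @param min_length_mm minimum strand length (mm) to keep.
#' @param fa_stop FA stopping threshold (0 disables, as in muscle work).
#' @param max_angle_deg maximal turning angle per step (degrees).
#' @return list of \code{\link{fibre_strand}} objects.
#' @export
track_streamlines <- function(field, seeds, step_mm = 1, min_length_mm = 10,
                              fa_stop = 0, max_angle_deg = 60) {
  stopifnot(inherits(field, "tensor_field"))
  if (step_mm <= 0) stop("step_mm must be positive")
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  cos_max <- cos(max_angle_deg * pi / 180)
  d <- dim(field$mask)
  vs <- field$voxel_size
  vox_of <- function(p) {
    v <- floor(p / vs) + 1L
    if (any(v < 1L) || any(v > d)) NULL else v
  }
  dir_at <- function(p) {
    v <- vox_of(p)
    if (is.null(v) || !field$mask[v[1], v[2], v[3]]) return(NULL)
    if (field$fa[v[1], v[2], v[3]] < fa_stop) return(NULL)
    field$e1[v[1], v[2], v[3], ]
  }
  march <- function(p0, sgn) {
    pts <- list(); p <- p0
    dir0 <- dir_at(p0)
    if (is.null(dir0)) return(NULL)
    prev <- sgn * dir0
    max_steps <- ceiling(4 * sum(d * vs) / step_mm)
    for (s in seq_len(max_steps)) {
      dr <- dir_at(p)
      if (is.null(dr)) break
      if (sum(dr * prev) < 0) dr <- -dr          # hemisphere continuity
      if (sum(dr * prev) < cos_max && s > 1L) break
      p <- p + step_mm * dr
      if (is.null(vox_of(p))) break
      pts[[length(pts) + 1L]] <- p
      prev <- dr
    }
    if (length(pts)) do.call(rbind, pts) else NULL
  }
  strands <- list()
  for (i in seq_len(nrow(seeds))) {
    p0 <- seeds[i, ]
    if (is.null(dir_at(p0))) next
    fwd <- march(p0, +1)
    bwd <- march(p0, -1)
    pts <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0, 1), fwd)
    if (nrow(pts) < 2L) next
    len <- sum(sqrt(rowSums(diff(pts)^2)))
    if (len < min_length_mm) next
    strands[[length(strands) + 1L]] <- fibre_strand(pts, id = length(strands) + 1L)
  }
  strands
}

#' Bundle of fibre strands belonging to one muscle
#'
#' @param name muscle label.
#' @param strands list of \code{\link{fibre_strand}} objects with unique ids.
#' @return an object of class \code{fibre_bundle}.
#' @export
fibre_bundle <- function(name, strands) {
  ids <- vapply(strands, function(s) s$id, 1L)
  if (anyDuplicated(ids)) stop("strand ids must be unique within a bundle")
  structure(list(name = name, strands = strands), class = "fibre_bundle")
}

#' @export
print.fibre_bundle <- function(x, ...) {
  cat(sprintf("<fibre_bundle> '%s': %d strands\n", x$name, length(x$strands)))
  invisible(x)
}

#' Bundle strands passing through an axis-aligned cropping box
#'
#' A strand is included iff at least one of its points lies inside the
#' closed box.
#'
#' @param strands list of \code{\link{fibre_strand}} objects.
#' @param box numeric matrix 2 x 3: row 1 the lower corner, row 2 the upper
#'   corner (mm).
#' @param name muscle label for the resulting bundle.
#' @return a \code{\link{fibre_bundle}}.
#' @export
crop_bundle <- function(strands, box, name = "bundle") {
  box <- matrix(as.numeric(box), 2, 3)
  inside <- vapply(strands, function(s) {
    any(s$points[, 1] >= box[1, 1] & s$points[, 1] <= box[2, 1] &
        s$points[, 2] >= box[1, 2] & s$points[, 2] <= box[2, 2] &
        s$points[, 3] >= box[1, 3] & s$points[, 3] <= box[2, 3])
  }, TRUE)
  fibre_bundle(name, strands[inside])
}

#' Rasterise a fibre bundle into a binary volume
#'
#' A voxel is marked TRUE iff any strand point falls inside it.
#'
#' @param bundle a \code{\link{fibre_bundle}}.
#' @param dim length-3 integer grid size.
#' @param voxel_size physical spacing (mm).
#' @return logical array of the given dimension.
#' @export
bundle_to_mask <- function(bundle, dim, voxel_size = c(1, 1, 1)) {
  mask <- array(FALSE, dim = dim)
  for (s in bundle$strands) {
    v <- floor(sweep(s$points, 2L, voxel_size, `/`)) + 1L
    ok <- v[, 1] >= 1 & v[, 1] <= dim[1] & v[, 2] >= 1 & v[, 2] <= dim[2] &
          v[, 3] >= 1 & v[, 3] <= dim[3]
    mask[v[ok, , drop = FALSE]] <- TRUE
  }
  mask
}

#' Read / write fibre strands in a plain whitespace text format
#'
#' One row per point: \code{strand_id point_index x y z}. Point indices are
#' consecutive from 1 within each strand.
#'
#' @param strands list of \code{\link{fibre_strand}} objects.
#' @param path file path.
#' @return \code{read_strands} returns a list of strands.
#' @export
write_strands <- function(strands, path) {
  rows <- lapply(strands, function(s)
    data.frame(id = s$id, idx = seq_len(nrow(s$points)),
               x = s$points[, 1], y = s$points[, 2], z = s$points[, 3]))
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_strands
#' @export
read_strands <- function(path) {
  df <- utils::read.table(path, col.names = c("id", "idx", "x", "y", "z"))
  lapply(split(df, df$id), function(g) {
    g <- g[order(g$idx), ]
    fibre_strand(as.matrix(g[, c("x", "y", "z")]), id = g$id[1])
  })
}
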