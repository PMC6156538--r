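#' Linear tetrahedral mesh
#'
#' Nodes in mm, 4-node connectivity (0-based internally would invite
#' off-by-one churn in R; connectivity is 1-based here and converted at file
#' boundaries where a dialect requires otherwise). Element node ordering
#' follows the convention that the signed volume
#' det(x2-x1, x3-x1, x4-x1)/6 is positive; negative-volume elements are
#' repaired by swapping nodes 3 and 4 with a warning.
#'
#' @param nodes numeric matrix (n_nodes x 3), coordinates in mm.
#' @param elements integer matrix (n_elem x 4), 1-based node indices.
#' @param part_labels character or integer vector, one label per element
#'   (muscle name / fat / bone / ...).
#' @return an object of class \code{tet_mesh}.
#' @export
tet_mesh <- function(nodes, elements, part_labels = rep("part", nrow(elements))) {
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  elements <- matrix(as.integer(elements), ncol = 4)
  if (any(elements < 1L) || any(elements > nrow(nodes)))
    stop("element connectivity indices out of range")
  stopifnot(length(part_labels) == nrow(elements))
  vol <- .tet_volumes(nodes, elements)
  neg <- vol < 0
  if (any(neg)) {
    warning(sprintf("repaired %d negative-volume elements by node swap", sum(neg)))
    elements[neg, c(3L, 4L)] <- elements[neg, c(4L, 3L)]
    vol <- abs(vol)
  }
  if (any(vol == 0)) stop("degenerate (zero-volume) elements present")
  structure(list(nodes = nodes, elements = elements,
                 part_labels = part_labels), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets, parts: %s\n",
              nrow(x$nodes), nrow(x$elements),
              paste(unique(x$part_labels), collapse = ", ")))
  invisible(x)
}

.tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 2], , drop = FALSE] - nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 3], , drop = FALSE] - nodes[elements[, 1], , drop = FALSE]
  d <- nodes[elements[, 4], , drop = FALSE] - nodes[elements[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Element centroids and volumes
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @return list with \code{centroids} (n_elem x 3, mm) and \code{volumes}
#'   (mm^3).
#' @export
element_centroids_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  cen <- (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
          mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
  list(centroids = matrix(cen, ncol = 3),
       volumes = .tet_volumes(mesh$nodes, mesh$elements))
}

#' Bounding-box diagonal of a mesh subset
#'
#' Length L of the diagonal of the axis-aligned bounding box of the nodes
#' used by the selected elements; the length scale of the radial-basis
#' fibre-field smoothing kernel.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param element_ids elements defining the subset (default: all).
#' @return scalar L in mm.
#' @export
bounding_box_diagonal <- function(mesh, element_ids = seq_len(nrow(mesh$elements))) {
  nd <- unique(as.vector(mesh$elements[element_ids, , drop = FALSE]))
  pts <- mesh$nodes[nd, , drop = FALSE]
  sqrt(sum((apply(pts, 2L, max) - apply(pts, 2L, min))^2))
}

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 proper orthogonal matrix (det = 1).
#' @param translation length-3 vector (mm).
#' @return an object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be proper orthogonal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a \code{\link{rigid_transform}}.
#' @param points matrix (n x 3).
#' @return transformed points (n x 3).
#' @export
apply_transform <- function(transform, points) {
  sweep(points %*% t(transform$rotation), 2L, transform$translation, `+`)
}

# closed-form least-squares rigid fit (Kabsch) of paired point sets
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP: alternate nearest-neighbour pairing of source points
#' to target points with a closed-form least-squares rigid fit until the RMS
#' pairing distance changes by less than \code{tol}. The RMS objective is
#' non-increasing across iterations.
#'
#' @param source matrix (n x 3) of points to move.
#' @param target matrix (m x 3) of fixed points.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the RMS pairing distance (mm).
#' @return a \code{\link{rigid_transform}} mapping source onto target, with
#'   attributes \code{rms} (final RMS distance) and \code{iterations}.
#' @export
icp_register <- function(source, target, max_iter = 100L, tol = 1e-10) {
  source <- matrix(as.numeric(source), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  if (nrow(source) < 3L || nrow(target) < 3L)
    stop("at least 3 points required in each cloud")
  for (pts in list(source, target)) {
    sv <- svd(sweep(pts, 2L, colMeans(pts)))$d
    if (sv[2] <= 1e-12 * max(sv[1], 1))
      stop("degenerate (collinear) point cloud")
  }
  R <- diag(3); tr <- c(0, 0, 0)
  moved <- source
  rms_prev <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    # brute-force nearest neighbours (desk-scale clouds)
    d2 <- outer(rowSums(moved^2), rowSums(target^2), `+`) -
      2 * tcrossprod(moved, target)
    nn <- max.col(-d2, ties.method = "first")
    fit <- .kabsch(source, target[nn, , drop = FALSE])
    R <- fit$R; tr <- fit$t
    moved <- sweep(source %*% t(R), 2L, tr, `+`)
    rms <- sqrt(mean(rowSums((moved - target[nn, , drop = FALSE])^2)))
    if (abs(rms_prev - rms) < tol || it >= max_iter) break
    rms_prev <- rms
  }
  out <- rigid_transform(R, tr)
  attr(out, "rms") <- rms
  attr(out, "iterations") <- it
  out
}

# --- 3D binary morphology + separable Gaussian blur (array-shift based) ---

.shift3 <- function(a, s) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1]) - s[1], 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) - s[2], 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) - s[3], 1L), d[3])
  # out-of-range positions become FALSE/0, not clamped copies
  out <- a[ix, iy, iz, drop = FALSE]
  if (s[1] > 0) out[seq_len(min(s[1], d[1])), , ] <- 0
  if (s[1] < 0) out[d[1] + 1L - seq_len(min(-s[1], d[1])), , ] <- 0
  if (s[2] > 0) out[, seq_len(min(s[2], d[2])), ] <- 0
  if (s[2] < 0) out[, d[2] + 1L - seq_len(min(-s[2], d[2])), ] <- 0
  if (s[3] > 0) out[, , seq_len(min(s[3], d[3]))] <- 0
  if (s[3] < 0) out[, , d[3] + 1L - seq_len(min(-s[3], d[3]))] <- 0
  out
}

.dilate3 <- function(mask, steps) {
  m <- mask
  for (i in seq_len(steps)) {
    acc <- m
    for (ax in 1:3) for (sg in c(-1L, 1L)) {
      s <- integer(3); s[ax] <- sg
      acc <- acc | .shift3(m, s)
    }
    m <- acc
  }
  m
}

.erode3 <- function(mask, steps) !.dilate3(!mask, steps)

.gauss_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  out <- a
  for (ax in 1:3) {
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      s <- integer(3); s[ax] <- j - r - 1L
      acc <- acc + k[j] * .shift3(out, s)
    }
    out <- acc
  }
  out
}

#' Morphological + Gaussian smoothing of a binary mask
#'
#' The surface-smoothing step applied to segmentation masks before meshing:
#' dilate, blur the indicator with a Gaussian, re-threshold, and erode back
#' by the same number of steps. The symmetric dilate/erode pair makes the
#' pipeline approximately volume-preserving on convex bodies; the relative
#' volume change is reported and should stay below 0.2 percent with the
#' defaults.
#'
#' @param mask logical 3D array.
#' @param dilation_steps number of 6-neighbourhood dilation (and final
#'   erosion) passes.
#' @param gaussian_sigma Gaussian standard deviation in voxels.
#' @param threshold indicator threshold after blurring.
#' @return smoothed logical mask with attribute \code{volume_change}
#'   (relative, signed) and \code{volume_change_percent}.
#' @export
smooth_mask <- function(mask, dilation_steps = 1L, gaussian_sigma = 1,
                        threshold = 0.5) {
  stopifnot(length(dim(mask)) == 3L)
  v0 <- sum(mask)
  if (v0 == 0L) {
    out <- mask
    attr(out, "volume_change") <- 0
    attr(out, "volume_change_percent") <- 0
    return(out)
  }
  m <- .dilate3(mask != 0, dilation_steps)
  m <- .gauss_blur3(m * 1, gaussian_sigma) >= threshold
  m <- .erode3(m, dilation_steps)
  v1 <- sum(m)
  attr(m, "volume_change") <- (v1 - v0) / v0
  attr(m, "volume_change_percent") <- 100 * abs(v1 - v0) / v0
  m
}
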