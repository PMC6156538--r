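#' Built-in gradient scheme: 12 directions on the unit sphere
#'
#' A fixed 12-direction scheme (golden-spiral layout, well spread, none
#' collinear) matching the acquisition geometry of a 12-direction
#' b = 0/700 s/mm^2 protocol.
#'
#' @return 12 x 3 matrix of unit vectors.
#' @export
gradient_scheme_12 <- function() {
  i <- seq_len(12)
  z <- (2 * i - 1) / 12 - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# unit fibre direction of a pattern at physical position p (mm)
.pattern_direction <- function(pattern, p, centre, pitch = 20) {
  if (pattern == "axial") return(c(0, 0, 1))
  if (pattern == "helical") {
    d <- p - centre
    v <- c(-d[2], d[1], pitch / (2 * pi))
    n <- sqrt(sum(v^2))
    if (n < 1e-12) return(c(0, 0, 1))
    return(v / n)
  }
  stop(sprintf("unknown fibre pattern '%s'", pattern))
}

#' Synthetic diffusion-weighted phantom with known ground truth
#'
#' Generates DWI signals from the mono-exponential tensor model
#' S = S0 exp(-b g' D g), with D built from a prescribed fibre pattern
#' (axial, or helical with given pitch) and axially symmetric eigenvalues
#' (defaults lambda_par = 1.8e-3, lambda_perp = 0.3e-3 mm^2/s, typical for
#' muscle). Rician noise of level \code{rician_sigma} is added
#' magnitude-wise under the given seed. The ground-truth tensor field is
#' returned alongside so every downstream fit/track step has an oracle.
#'
#' @param shape length-3 voxel grid size.
#' @param fibre_pattern \code{"axial"} or \code{"helical"}.
#' @param pitch helix pitch (mm per turn) when helical.
#' @param bval diffusion weighting (s/mm^2).
#' @param bvecs gradient directions (n x 3); default the built-in
#'   12-direction scheme.
#' @param voxel_size mm spacing.
#' @param s0 unweighted signal level.
#' @param lambda_par,lambda_perp tensor eigenvalues (mm^2/s).
#' @param rician_sigma Rician noise level (signal units); 0 for noiseless.
#' @param n_acquisitions repeats per direction (all identically distributed).
#' @param n_b0 number of b = 0 volumes.
#' @param seed RNG seed for the noise.
#' @return list with \code{stack} (a \code{\link{dwi_stack}}) and
#'   \code{truth} (a \code{\link{tensor_field}}).
#' @export
make_dwi_phantom <- function(shape = c(12, 12, 12), fibre_pattern = "axial",
                             pitch = 20, bval = 700,
                             bvecs = gradient_scheme_12(),
                             voxel_size = c(3.2, 3.2, 3),
                             s0 = 100, lambda_par = 1.8e-3,
                             lambda_perp = 0.3e-3, rician_sigma = 0,
                             n_acquisitions = 1L, n_b0 = 1L, seed = 1L) {
  set.seed(seed)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  nvox <- prod(shape)
  centre <- shape * voxel_size / 2
  idx <- arrayInd(seq_len(nvox), shape)
  pos <- sweep(idx - 0.5, 2L, voxel_size, `*`)
  tens <- matrix(0, nvox, 6)
  e1 <- matrix(0, nvox, 3)
  fa_true <- .fa_from_eigenvalues(c(lambda_par, lambda_perp, lambda_perp))
  for (v in seq_len(nvox)) {
    a <- .pattern_direction(fibre_pattern, pos[v, ], centre, pitch)
    D <- lambda_perp * diag(3) + (lambda_par - lambda_perp) * tcrossprod(a)
    tens[v, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    e1[v, ] <- a
  }
  rician <- function(clean) {
    if (rician_sigma <= 0) return(clean)
    n1 <- array(stats::rnorm(nvox, sd = rician_sigma), shape)
    n2 <- array(stats::rnorm(nvox, sd = rician_sigma), shape)
    sqrt((clean + n1)^2 + n2^2)
  }
  vols <- list(); bv <- numeric(0); gv <- NULL; acq <- integer(0)
  for (r in seq_len(n_b0)) {
    vols[[length(vols) + 1L]] <- rician(array(s0, shape))
    bv <- c(bv, 0); gv <- rbind(gv, c(0, 0, 0)); acq <- c(acq, r)
  }
  for (r in seq_len(n_acquisitions)) for (gi in seq_len(nrow(bvecs))) {
    g <- bvecs[gi, ]
    quad <- tens[, 1] * g[1]^2 + tens[, 2] * g[2]^2 + tens[, 3] * g[3]^2 +
      2 * (tens[, 4] * g[1] * g[2] + tens[, 5] * g[1] * g[3] +
           tens[, 6] * g[2] * g[3])
    clean <- array(s0 * exp(-bval * quad), shape)
    vols[[length(vols) + 1L]] <- rician(clean)
    bv <- c(bv, bval); gv <- rbind(gv, g); acq <- c(acq, r)
  }
  truth <- tensor_field(array(tens, c(shape, 6L)),
                        array(fa_true, shape), array(e1, c(shape, 3L)),
                        array(TRUE, shape), voxel_size)
  list(stack = dwi_stack(vols, bv, gv, voxel_size, acq), truth = truth)
}

#' Structured tetrahedral cylinder mesh
#'
#' Builds a structured hexahedral grid over the cylinder (a square
#' cross-section grid mapped onto the disc by the standard elliptical
#' square-to-disc map, extruded along z) and splits each hexahedron into 6
#' tetrahedra. Boundary nodes lie exactly on the cylinder surface, so the
#' mesh volume converges to pi r^2 L from below under refinement.
#'
#' @param radius cylinder radius (mm).
#' @param length cylinder length along z (mm).
#' @param target_edge target element edge length (mm); sets the grid
#'   density.
#' @param part part label for all elements.
#' @return a \code{\link{tet_mesh}}.
#' @export
make_cylinder_mesh <- function(radius, length, target_edge = radius / 4,
                               part = "muscle") {
  n <- max(2L, as.integer(round(2 * radius / target_edge)))
  nz <- max(2L, as.integer(round(length / target_edge)))
  # grid on [-1, 1]^2 mapped to the unit disc, scaled by radius
  s <- seq(-1, 1, length.out = n + 1L)
  nodes <- NULL
  nid <- array(0L, c(n + 1L, n + 1L, nz + 1L))
  coords <- matrix(0, (n + 1L)^2 * (nz + 1L), 3)
  cnt <- 0L
  for (kz in 0:nz) for (j in seq_len(n + 1L)) for (i in seq_len(n + 1L)) {
    x <- s[i]; y <- s[j]
    u <- x * sqrt(1 - y^2 / 2); v <- y * sqrt(1 - x^2 / 2)
    cnt <- cnt + 1L
    coords[cnt, ] <- c(radius * u, radius * v, length * kz / nz)
    nid[i, j, kz + 1L] <- cnt
  }
  hex_tets <- rbind(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
                    c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))
  elems <- matrix(0L, 6L * n * n * nz, 4)
  ec <- 0L
  for (kz in seq_len(nz)) for (j in seq_len(n)) for (i in seq_len(n)) {
    c000 <- nid[i, j, kz];         c100 <- nid[i + 1L, j, kz]
    c010 <- nid[i, j + 1L, kz];    c110 <- nid[i + 1L, j + 1L, kz]
    c001 <- nid[i, j, kz + 1L];    c101 <- nid[i + 1L, j, kz + 1L]
    c011 <- nid[i, j + 1L, kz + 1L]; c111 <- nid[i + 1L, j + 1L, kz + 1L]
    corners <- c(c000, c100, c010, c110, c001, c101, c011, c111)
    for (t in 1:6) {
      ec <- ec + 1L
      elems[ec, ] <- corners[hex_tets[t, ]]
    }
  }
  suppressWarnings(tet_mesh(coords, elems, rep(part, nrow(elems))))
}

#' Wrap a volume into a mosaic image
#'
#' Inverse companion of \code{\link{assemble_stack}} for phantom building:
#' \code{make_mosaic} then \code{assemble_stack} is the identity.
#'
#' @param volume 3D array.
#' @param grid_n tiles per row/column.
#' @return a \code{\link{mosaic_image}}.
#' @export
make_mosaic <- function(volume, grid_n) flatten_to_mosaic(volume, grid_n)

#' Synthetic fibre strands
#'
#' Generates ordered, consecutively numbered strands following a simple
#' pattern: straight lines along z ("axial") or helices of given pitch.
#'
#' @param pattern \code{"axial"} or \code{"helical"}.
#' @param n_strands number of strands.
#' @param n_points points per strand.
#' @param extent length-3 domain size (mm).
#' @param pitch helix pitch (mm) for the helical pattern.
#' @param seed RNG seed for strand placement.
#' @return list of \code{\link{fibre_strand}}.
#' @export
make_strands <- function(pattern = "axial", n_strands = 10L, n_points = 20L,
                         extent = c(50, 50, 50), pitch = 20, seed = 1L) {
  set.seed(seed)
  strands <- vector("list", n_strands)
  for (s in seq_len(n_strands)) {
    if (pattern == "axial") {
      x0 <- stats::runif(1, 0.2, 0.8) * extent[1]
      y0 <- stats::runif(1, 0.2, 0.8) * extent[2]
      z <- seq(0.05, 0.95, length.out = n_points) * extent[3]
      pts <- cbind(x0, y0, z)
    } else if (pattern == "helical") {
      r0 <- stats::runif(1, 0.15, 0.4) * min(extent[1:2])
      ph0 <- stats::runif(1, 0, 2 * pi)
      z <- seq(0.05, 0.95, length.out = n_points) * extent[3]
      th <- ph0 + 2 * pi * z / pitch
      pts <- cbind(extent[1] / 2 + r0 * cos(th),
                   extent[2] / 2 + r0 * sin(th), z)
    } else stop(sprintf("unknown pattern '%s'", pattern))
    strands[[s]] <- fibre_strand(pts, id = s)
  }
  strands
}

#' Synthetic binary masks
#'
#' @param shape length-3 grid size.
#' @param primitive \code{"sphere"}, \code{"cylinder"} or \code{"cube"}.
#' @param radius primitive radius (voxels; half-edge for the cube).
#' @param length cylinder length along z (voxels).
#' @param centre primitive centre (voxels; default grid centre).
#' @return logical 3D array.
#' @export
make_mask <- function(shape = c(64, 64, 64),
                      primitive = c("sphere", "cylinder", "cube"),
                      radius = min(shape) / 4, length = shape[3] / 2,
                      centre = shape / 2) {
  primitive <- match.arg(primitive)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  d <- sweep(idx - 0.5, 2L, centre)
  inside <- switch(primitive,
    sphere = rowSums(d^2) <= radius^2,
    cylinder = (d[, 1]^2 + d[, 2]^2 <= radius^2) & abs(d[, 3]) <= length / 2,
    cube = apply(abs(d) <= radius, 1L, all))
  array(inside, shape)
}
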