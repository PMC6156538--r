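#' Mosaic-format scan image
#'
#' A single 2D image tiling all slices of a 3D acquisition in an
#' \code{grid_n} x \code{grid_n} grid of tiles. Tiles are traversed
#' column-first (down the k-axis) when stacking into a volume, so the slice
#' index of tile (k, l) is m = N (l - 1) + k with 1-based indices.
#'
#' @param pixels numeric matrix of size \code{grid_n*tile_rows} x
#'   \code{grid_n*tile_cols}.
#' @param grid_n tiles per row/column of the mosaic (N).
#' @param n_slices number of populated tiles; trailing tiles (in column-first
#'   order) are unused. If \code{NULL}, trailing all-zero tiles are dropped.
#' @return an object of class \code{mosaic_image}.
#' @export
mosaic_image <- function(pixels, grid_n, n_slices = NULL) {
  pixels <- as.matrix(pixels)
  stopifnot(grid_n >= 1)
  if (nrow(pixels) %% grid_n != 0L || ncol(pixels) %% grid_n != 0L)
    stop(sprintf("pixel grid %d x %d not divisible by grid_n = %d",
                 nrow(pixels), ncol(pixels), grid_n))
  tile_rows <- nrow(pixels) %/% grid_n
  tile_cols <- ncol(pixels) %/% grid_n
  n_tiles <- grid_n^2
  if (is.null(n_slices)) {
    # drop trailing all-zero tiles (column-first order)
    n_slices <- n_tiles
    while (n_slices > 1L) {
      tile <- .mosaic_tile(pixels, grid_n, tile_rows, tile_cols, n_slices)
      if (any(tile != 0)) break
      n_slices <- n_slices - 1L
    }
  }
  if (n_slices > n_tiles)
    stop(sprintf("n_slices = %d exceeds grid capacity %d", n_slices, n_tiles))
  structure(list(pixels = pixels, grid_n = as.integer(grid_n),
                 tile_rows = tile_rows, tile_cols = tile_cols,
                 n_slices = as.integer(n_slices)),
            class = "mosaic_image")
}

# tile m (1-based, column-first): k = row index, l = column index
.mosaic_tile <- function(pixels, grid_n, tile_rows, tile_cols, m) {
  k <- (m - 1L) %% grid_n + 1L
  l <- (m - 1L) %/% grid_n + 1L
  pixels[(k - 1L) * tile_rows + seq_len(tile_rows),
         (l - 1L) * tile_cols + seq_len(tile_cols), drop = FALSE]
}

#' @export
print.mosaic_image <- function(x, ...) {
  cat(sprintf("<mosaic_image> %dx%d grid, %dx%d px tiles, %d slices\n",
              x$grid_n, x$grid_n, x$tile_rows, x$tile_cols, x$n_slices))
  invisible(x)
}

#' Assemble a 3D volume from a mosaic image
#'
#' Stacks the mosaic tiles into a 3D volume. Tiles are traversed
#' column-first: tile (k, l) becomes slice m = N (l - 1) + k (1-based).
#'
#' @param mosaic a \code{\link{mosaic_image}}.
#' @return numeric array \code{tile_rows x tile_cols x n_slices}.
#' @export
assemble_stack <- function(mosaic) {
  stopifnot(inherits(mosaic, "mosaic_image"))
  vol <- array(0, dim = c(mosaic$tile_rows, mosaic$tile_cols, mosaic$n_slices))
  for (m in seq_len(mosaic$n_slices))
    vol[, , m] <- .mosaic_tile(mosaic$pixels, mosaic$grid_n,
                               mosaic$tile_rows, mosaic$tile_cols, m)
  vol
}

#' Flatten a 3D volume back into mosaic layout
#'
#' Inverse of \code{\link{assemble_stack}}; unused trailing tiles are zero.
#'
#' @param volume 3D array.
#' @param grid_n tiles per row/column; must satisfy grid_n^2 >= n_slices.
#' @return a \code{\link{mosaic_image}}.
#' @export
flatten_to_mosaic <- function(volume, grid_n) {
  d <- dim(volume)
  stopifnot(length(d) == 3L, grid_n^2 >= d[3])
  px <- matrix(0, grid_n * d[1], grid_n * d[2])
  for (m in seq_len(d[3])) {
    k <- (m - 1L) %% grid_n + 1L
    l <- (m - 1L) %/% grid_n + 1L
    px[(k - 1L) * d[1] + seq_len(d[1]), (l - 1L) * d[2] + seq_len(d[2])] <-
      volume[, , m]
  }
  mosaic_image(px, grid_n, n_slices = d[3])
}

#' Diffusion-weighted image stack
#'
#' A collection of 3D volumes sharing one grid, each tagged with a b-value
#' (s/mm^2), a unit gradient direction, and an acquisition repeat index.
#'
#' @param volumes list of 3D arrays of identical dimension.
#' @param bvals numeric vector of b-values, one per volume.
#' @param bvecs matrix (n_volumes x 3) of gradient directions; rows are unit
#'   vectors, or zero for b = 0 volumes.
#' @param voxel_size length-3 physical voxel spacing in mm.
#' @param acquisition_id integer repeat index per volume.
#' @return an object of class \code{dwi_stack}.
#' @export
dwi_stack <- function(volumes, bvals, bvecs, voxel_size = c(1, 1, 1),
                      acquisition_id = rep(1L, length(volumes))) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  d <- dim(volumes[[1]])
  stopifnot(length(d) == 3L)
  for (v in volumes) if (!identical(dim(v), d))
    stop("all volumes in a dwi_stack must share the same shape")
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  stopifnot(length(bvals) == length(volumes), nrow(bvecs) == length(volumes),
            length(voxel_size) == 3L)
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) bvecs[bad, ] <- bvecs[bad, , drop = FALSE] / nrm[bad]
  bvecs[bvals == 0, ] <- 0
  structure(list(volumes = volumes, bvals = as.numeric(bvals), bvecs = bvecs,
                 voxel_size = as.numeric(voxel_size),
                 acquisition_id = as.integer(acquisition_id)),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat(sprintf("<dwi_stack> %d volumes of %dx%dx%d, b in {%s} s/mm^2\n",
              length(x$volumes), d[1], d[2], d[3],
              paste(sort(unique(x$bvals)), collapse = ", ")))
  invisible(x)
}

#' Average repeated acquisitions of a DWI stack
#'
#' Collapses repeated acquisitions to one mean volume per unique gradient
#' direction plus one mean b = 0 volume, reducing the Rician noise variance.
#' For 4 acquisitions of 12 directions plus 12 b0 repeats (60 volumes) this
#' yields 13 volumes.
#'
#' @param stack a \code{\link{dwi_stack}} with per-volume acquisition tags.
#' @return a \code{\link{dwi_stack}} with one volume per direction (+ b0).
#' @export
average_acquisitions <- function(stack) {
  stopifnot(inherits(stack, "dwi_stack"))
  key <- ifelse(stack$bvals == 0, "b0",
                paste(round(stack$bvecs[, 1], 6), round(stack$bvecs[, 2], 6),
                      round(stack$bvecs[, 3], 6)))
  groups <- split(seq_along(key), key)
  # same direction acquired with different b-values means the acquisitions
  # carry different gradient tables
  for (g in groups)
    if (length(unique(stack$bvals[g])) != 1L)
      stop("inconsistent gradient tables across acquisitions")
  ord <- order(vapply(groups, min, 1L))  # keep first-appearance order
  groups <- groups[ord]
  vols <- lapply(groups, function(g) {
    v <- stack$volumes[[g[1]]]
    if (length(g) > 1L) for (i in g[-1]) v <- v + stack$volumes[[i]]
    v / length(g)
  })
  idx1 <- vapply(groups, `[`, 1L, 1L)
  dwi_stack(unname(vols), stack$bvals[idx1],
            stack$bvecs[idx1, , drop = FALSE], stack$voxel_size,
            acquisition_id = rep(1L, length(vols)))
}

#' Local-PCA denoising with Rician bias correction
#'
#' A sliding-window local principal component analysis across the diffusion
#' dimension: for each spatial patch the patch-by-volume data matrix is
#' decomposed, eigencomponents whose variance falls below the noise
#' threshold tau = 2.3 sigma^2 are suppressed, overlapping reconstructions
#' are averaged, and the Rician bias of magnitude data is removed via
#' m_corrected = sqrt(max(m^2 - 2 sigma^2, 0)).
#'
#' This is a deliberately compact variant of overcomplete local-PCA
#' denoising: one pass, hard eigenvalue threshold, uniform patch
#' aggregation.
#'
#' @param stack a \code{\link{dwi_stack}} with at least 2 volumes.
#' @param patch_radius half-width of the cubic patch (patch edge
#'   \code{2*patch_radius+1} voxels).
#' @param noise_sigma Rician noise level (same units as the signal); must be
#'   positive.
#' @param threshold_factor eigenvalue threshold multiplier tau / sigma^2.
#' @return a denoised \code{\link{dwi_stack}} of identical shape.
#' @export
denoise_local_pca <- function(stack, patch_radius = 1L, noise_sigma,
                              threshold_factor = 2.3) {
  stopifnot(inherits(stack, "dwi_stack"))
  if (length(stack$volumes) < 2L)
    stop("local PCA needs at least 2 volumes")
  if (!is.numeric(noise_sigma) || noise_sigma <= 0)
    stop("noise_sigma must be positive")
  d <- dim(stack$volumes[[1]])
  nv <- length(stack$volumes)
  X <- vapply(stack$volumes, identity, stack$volumes[[1]])  # d1 x d2 x d3 x nv
  acc <- array(0, dim = c(d, nv))
  wts <- array(0, dim = d)
  r <- as.integer(patch_radius)
  tau <- threshold_factor * noise_sigma^2
  step <- max(1L, r)  # overlapping but strided aggregation
  xs <- unique(c(seq(1L, max(1L, d[1] - 2L * r), by = step), max(1L, d[1] - 2L * r)))
  ys <- unique(c(seq(1L, max(1L, d[2] - 2L * r), by = step), max(1L, d[2] - 2L * r)))
  zs <- unique(c(seq(1L, max(1L, d[3] - 2L * r), by = step), max(1L, d[3] - 2L * r)))
  for (x0 in xs) for (y0 in ys) for (z0 in zs) {
    ix <- x0:min(d[1], x0 + 2L * r)
    iy <- y0:min(d[2], y0 + 2L * r)
    iz <- z0:min(d[3], z0 + 2L * r)
    P <- matrix(X[ix, iy, iz, ], nrow = length(ix) * length(iy) * length(iz),
                ncol = nv)
    mu <- colMeans(P)
    Pc <- sweep(P, 2L, mu)
    np <- nrow(P)
    sv <- svd(Pc, nu = min(np, nv), nv = nv)
    lam <- sv$d^2 / max(1L, np - 1L)       # component variances
    keep <- lam > tau
    if (!all(keep)) {
      k <- sum(keep)
      rec <- if (k == 0L) matrix(0, np, nv) else
        sv$u[, seq_len(k), drop = FALSE] %*%
          (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
      P <- sweep(rec, 2L, mu, `+`)
    }
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, ] + array(P, c(length(ix), length(iy), length(iz), nv))
    wts[ix, iy, iz] <- wts[ix, iy, iz] + 1
  }
  den <- acc / array(wts, c(d, nv))
  # Rician bias correction on magnitudes: E[m^2] = A^2 + 2 sigma^2
  den <- sqrt(pmax(den^2 - 2 * noise_sigma^2, 0)) * sign(den)
  vols <- lapply(seq_len(nv), function(i) array(den[, , , i], d))
  dwi_stack(vols, stack$bvals, stack$bvecs, stack$voxel_size,
            stack$acquisition_id)
}

#' Read / write a DWI stack as NIfTI + FSL-style gradient tables
#'
#' The volumes are stored as a single 4D NIfTI-1 file; b-values and gradient
#' directions go to sidecar text files \code{<stem>.bval} (one row) and
#' \code{<stem>.bvec} (three rows), the FSL convention.
#'
#' @param stack a \code{\link{dwi_stack}}.
#' @param path path of the \code{.nii} (or \code{.nii.gz}) file.
#' @return \code{write_nifti} returns \code{path} invisibly;
#'   \code{read_nifti} returns a \code{\link{dwi_stack}}.
#' @export
write_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "dwi_stack"))
  d <- dim(stack$volumes[[1]])
  arr <- array(unlist(stack$volumes, use.names = FALSE),
               c(d, length(stack$volumes)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(stack$voxel_size, 1)
  RNifti::writeNifti(img, path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  writeLines(paste(format(stack$bvals, scientific = FALSE), collapse = " "),
             paste0(stem, ".bval"))
  writeLines(apply(t(stack$bvecs), 1L, paste, collapse = " "),
             paste0(stem, ".bvec"))
  invisible(path)
}

#' @rdname write_nifti
#' @param path path of the NIfTI file to read.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop(sprintf("expected a 3D/4D NIfTI, got %dD", length(d)))
  arr <- array(as.numeric(img), d)
  vols <- lapply(seq_len(d[4]), function(i) array(arr[, , , i], d[1:3]))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  bvf <- paste0(stem, ".bval"); gvf <- paste0(stem, ".bvec")
  if (file.exists(bvf) && file.exists(gvf)) {
    bvals <- scan(bvf, quiet = TRUE)
    bvecs <- t(matrix(scan(gvf, quiet = TRUE), nrow = 3, byrow = TRUE))
  } else {
    bvals <- rep(0, d[4]); bvecs <- matrix(0, d[4], 3)
  }
  vox <- RNifti::pixdim(img)[1:3]
  dwi_stack(vols, bvals, bvecs, voxel_size = vox)
}
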