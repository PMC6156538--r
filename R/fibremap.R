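#' Per-element fibre direction field
#'
#' One unit direction per mesh element (or NA for elements with no fibre
#' information), plus the number of contributing strands.
#'
#' @param directions numeric matrix (n_elem x 3); rows are unit vectors or
#'   all-NA for missing elements.
#' @param source_counts integer vector of contributing strand counts.
#' @return an object of class \code{element_fibre_field}.
#' @export
element_fibre_field <- function(directions,
                                source_counts = rep(0L, nrow(directions))) {
  directions <- matrix(as.numeric(directions), ncol = 3)
  have <- !is.na(directions[, 1])
  nrm <- sqrt(rowSums(directions[have, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-9))
    directions[have, ] <- directions[have, , drop = FALSE] / nrm
  structure(list(directions = directions,
                 source_counts = as.integer(source_counts)),
            class = "element_fibre_field")
}

#' @export
print.element_fibre_field <- function(x, ...) {
  cat(sprintf("<element_fibre_field> %d elements, %d with directions\n",
              nrow(x$directions), sum(!is.na(x$directions[, 1]))))
  invisible(x)
}

# barycentric coordinates of points wrt one tet; boundary counts as inside
.points_in_tet <- function(points, verts, tol = 1e-9) {
  Tm <- t(verts[2:4, , drop = FALSE]) - verts[1, ]
  rel <- sweep(points, 2L, verts[1, ])
  lam <- t(solve(Tm, t(rel)))
  l1 <- 1 - rowSums(lam)
  lam[, 1] >= -tol & lam[, 2] >= -tol & lam[, 3] >= -tol & l1 >= -tol
}

#' Runs of consecutively numbered strand points inside one element
#'
#' Finds the maximal runs of consecutive points of a strand that lie inside
#' a given tetrahedron (point-in-tet decided by barycentric coordinates;
#' boundary counts as inside). Each run contributes one trend line to the
#' element's effective fibre direction.
#'
#' @param strand a \code{\link{fibre_strand}}.
#' @param mesh a \code{\link{tet_mesh}}.
#' @param element element index.
#' @return list of integer vectors, each the point indices of one run
#'   (possibly empty list).
#' @export
strand_segments_in_element <- function(strand, mesh, element) {
  verts <- mesh$nodes[mesh$elements[element, ], , drop = FALSE]
  inside <- .points_in_tet(strand$points, verts)
  if (!any(inside)) return(list())
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) starts[i]:ends[i])
}

#' Total-least-squares line of best fit through points
#'
#' Principal axis of the centred point set, sign-aligned with the traversal
#' direction of the points (last minus first point).
#'
#' @param points numeric matrix (n x 3), n >= 2.
#' @return unit direction vector (length 3).
#' @export
line_of_best_fit <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2L) stop("at least 2 points required")
  if (nrow(points) == 2L) {
    g <- points[2, ] - points[1, ]
    return(g / sqrt(sum(g^2)))
  }
  ctr <- sweep(points, 2L, colMeans(points))
  g <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  trav <- points[nrow(points), ] - points[1, ]
  if (sum(g * trav) < 0) g <- -g
  g / sqrt(sum(g^2))
}

#' Effective fibre direction of an element from its strand runs
#'
#' Weighted sum of the run trend lines with weights w_s = n_s^2 / sum n_s^2
#' where n_s is the number of points in run s. Because fibre directions are
#' axial (sign-free), the trend lines are hemisphere-aligned to the longest
#' run's direction before summing, and the result is normalised to unit
#' length.
#'
#' @param directions matrix (n_runs x 3) of run trend lines g_s.
#' @param counts integer vector of run point counts n_s.
#' @return list with \code{direction} (unit 3-vector, or NA if no runs) and
#'   \code{weights}.
#' @export
effective_direction <- function(directions, counts) {
  if (length(counts) == 0L)
    return(list(direction = rep(NA_real_, 3), weights = numeric(0)))
  directions <- matrix(as.numeric(directions), ncol = 3)
  w <- counts^2 / sum(counts^2)
  ref <- directions[which.max(counts), ]
  flip <- as.numeric(directions %*% ref) < 0
  directions[flip, ] <- -directions[flip, , drop = FALSE]
  f <- colSums(w * directions)
  nf <- sqrt(sum(f^2))
  if (nf == 0) return(list(direction = rep(NA_real_, 3), weights = w))
  list(direction = f / nf, weights = w)
}

#' Map fibre strands of a bundle onto mesh elements
#'
#' For every element of the selected part, finds all runs of consecutive
#' strand points inside it, fits a trend line per run, and combines them
#' into the element's effective fibre direction.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param bundle a \code{\link{fibre_bundle}} (or plain list of strands).
#' @param part restrict to elements with this part label (default: all).
#' @return an \code{\link{element_fibre_field}} over all mesh elements;
#'   elements outside \code{part} or without fibre points are NA.
#' @export
map_fibres_to_elements <- function(mesh, bundle, part = NULL) {
  strands <- if (inherits(bundle, "fibre_bundle")) bundle$strands else bundle
  ne <- nrow(mesh$elements)
  eids <- if (is.null(part)) seq_len(ne) else which(mesh$part_labels == part)
  dirs <- matrix(NA_real_, ne, 3)
  cnts <- integer(ne)
  # spatial prefilter: element bounding boxes
  lo <- hi <- matrix(0, ne, 3)
  for (j in 1:3) {
    xs <- matrix(mesh$nodes[mesh$elements, j], ne, 4)
    lo[, j] <- apply(xs, 1L, min); hi[, j] <- apply(xs, 1L, max)
  }
  for (e in eids) {
    run_dirs <- list(); run_n <- integer(0); n_strands <- 0L
    for (s in strands) {
      p <- s$points
      if (all(p[, 1] < lo[e, 1]) || all(p[, 1] > hi[e, 1]) ||
          all(p[, 2] < lo[e, 2]) || all(p[, 2] > hi[e, 2]) ||
          all(p[, 3] < lo[e, 3]) || all(p[, 3] > hi[e, 3])) next
      runs <- strand_segments_in_element(s, mesh, e)
      if (!length(runs)) next
      n_strands <- n_strands + 1L
      for (r in runs) {
        if (length(r) < 2L) next  # a single point defines no trend line
        run_dirs[[length(run_dirs) + 1L]] <- line_of_best_fit(p[r, , drop = FALSE])
        run_n <- c(run_n, length(r))
      }
    }
    if (length(run_n)) {
      ed <- effective_direction(do.call(rbind, run_dirs), run_n)
      dirs[e, ] <- ed$direction
      cnts[e] <- n_strands
    }
  }
  element_fibre_field(dirs, cnts)
}

#' Gaussian radial-basis smoothing of an element fibre field
#'
#' Replaces each element's direction by the kernel-weighted vector sum over
#' all elements carrying a direction,
#' \deqn{\tilde f(x_i) = \mathrm{norm}\sum_e \phi(x_i, x_e, p)\, f(x_e),
#'   \quad \phi = \exp(-(p \|x_i - x_e\| / L)^2),}
#' with L the bounding-box diagonal of the muscle. Elements with missing
#' directions receive interpolated values; contributions are
#' hemisphere-aligned to the strongest-weight contributor before summation
#' (fibre directions are axial), and the output is normalised to unit
#' length. Applied per part when \code{part} is given.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param field an \code{\link{element_fibre_field}}.
#' @param p kernel sharpness; larger p narrows the neighbourhood
#'   (default 20).
#' @param part restrict smoothing to elements of this part (default: all
#'   elements form one domain).
#' @param density_scaled if TRUE, p is rescaled by
#'   (n_elem / 1000)^(1/3), an optional mode making the kernel width follow
#'   mesh density.
#' @param L kernel length scale (mm); defaults to the axis-aligned
#'   bounding-box diagonal of the smoothed domain. Pass a fixed value to
#'   make the operation independent of the domain's orientation.
#' @return a smoothed \code{\link{element_fibre_field}}.
#' @export
smooth_fibre_field <- function(mesh, field, p = 20, part = NULL,
                               density_scaled = FALSE, L = NULL) {
  stopifnot(inherits(field, "element_fibre_field"))
  ne <- nrow(mesh$elements)
  stopifnot(nrow(field$directions) == ne)
  eids <- if (is.null(part)) seq_len(ne) else which(mesh$part_labels == part)
  cv <- element_centroids_volumes(mesh)
  X <- cv$centroids[eids, , drop = FALSE]
  if (is.null(L)) L <- bounding_box_diagonal(mesh, eids)
  dirs <- field$directions
  have <- which(!is.na(dirs[eids, 1]))
  if (!length(have)) return(field)
  peff <- if (density_scaled) p * (length(eids) / 1000)^(1 / 3) else p
  Fsrc <- dirs[eids[have], , drop = FALSE]
  Xsrc <- X[have, , drop = FALSE]
  out <- dirs
  for (ii in seq_along(eids)) {
    d2 <- rowSums(sweep(Xsrc, 2L, X[ii, ])^2)
    w <- exp(-(peff^2 / L^2) * d2)
    ref <- Fsrc[which.max(w), ]
    contrib <- Fsrc
    flip <- as.numeric(contrib %*% ref) < 0
    contrib[flip, ] <- -contrib[flip, , drop = FALSE]
    f <- colSums(w * contrib)
    nf <- sqrt(sum(f^2))
    if (nf > 0) out[eids[ii], ] <- f / nf
  }
  element_fibre_field(out, pmax(field$source_counts,
                                as.integer(!is.na(out[, 1]))))
}

#' Export mesh + fibre field as LS-DYNA *ELEMENT_SOLID_ORTHO cards
#'
#' Writes a keyword deck with \code{*NODE} and one
#' \code{*ELEMENT_SOLID_ORTHO} card per element: the connectivity line
#' (8-wide integer fields, tets in degenerate 8-node form), then the fibre
#' direction a and an auto-generated orthogonal second axis d on two
#' 16-wide float lines. Elements without a direction get the documented
#' fallback axis (global x, or y where x is parallel) and a warning.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param field an \code{\link{element_fibre_field}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_element_solid_ortho <- function(mesh, field, path) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(field, "element_fibre_field"))
  ne <- nrow(mesh$elements)
  stopifnot(nrow(field$directions) == ne)
  dirs <- field$directions
  missing <- is.na(dirs[, 1])
  if (any(missing)) {
    warning(sprintf("%d elements lack a fibre direction; using fallback axis",
                    sum(missing)))
    dirs[missing, ] <- rep(c(1, 0, 0), each = sum(missing))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("*KEYWORD", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%8d%16.8f%16.8f%16.8f", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT_SOLID_ORTHO", con)
  pid <- as.integer(factor(mesh$part_labels))
  for (e in seq_len(ne)) {
    el <- mesh$elements[e, ]
    a <- dirs[e, ]
    # orthogonal second axis: remove a-component from the seed axis
    seed <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    dvec <- seed - sum(seed * a) * a
    dvec <- dvec / sqrt(sum(dvec^2))
    writeLines(sprintf("%8d%8d%8d%8d%8d%8d%8d%8d%8d%8d",
                       e, pid[e], el[1], el[2], el[3], el[4],
                       el[4], el[4], el[4], el[4]), con)
    writeLines(sprintf("%16.8f%16.8f%16.8f", a[1], a[2], a[3]), con)
    writeLines(sprintf("%16.8f%16.8f%16.8f", dvec[1], dvec[2], dvec[3]), con)
  }
  writeLines("*END", con)
  invisible(path)
}

#' Read back an *ELEMENT_SOLID_ORTHO deck
#'
#' Independent parser used to round-trip ortho exports: returns the mesh,
#' the per-element a axes and the per-element d axes.
#'
#' @param path keyword file path.
#' @return list with \code{mesh}, \code{a} (n_elem x 3), \code{d}
#'   (n_elem x 3).
#' @export
read_element_solid_ortho <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\$", lines)]
  inode <- which(toupper(lines) == "*NODE")
  iortho <- which(toupper(lines) == "*ELEMENT_SOLID_ORTHO")
  if (!length(inode) || !length(iortho)) stop("missing *NODE or *ELEMENT_SOLID_ORTHO")
  kw <- grep("^\\*", lines)
  nend <- min(kw[kw > inode[1]]) - 1L
  nd <- t(vapply(lines[(inode[1] + 1):nend], function(s)
    as.numeric(c(substr(s, 1, 8), substr(s, 9, 24), substr(s, 25, 40),
                 substr(s, 41, 56))), numeric(4)))
  oend <- kw[kw > iortho[1]]
  oend <- if (length(oend)) min(oend) - 1L else length(lines)
  block <- lines[(iortho[1] + 1):oend]
  stopifnot(length(block) %% 3L == 0L)
  ne <- length(block) %/% 3L
  conn <- matrix(0L, ne, 4); a <- d <- matrix(0, ne, 3); pid <- integer(ne)
  for (i in seq_len(ne)) {
    l1 <- block[3 * i - 2]
    f <- as.numeric(substring(l1, seq(1, 73, by = 8), seq(8, 80, by = 8)))
    pid[i] <- f[2]; conn[i, ] <- f[3:6]
    a[i, ] <- as.numeric(substring(block[3 * i - 1], c(1, 17, 33), c(16, 32, 48)))
    d[i, ] <- as.numeric(substring(block[3 * i], c(1, 17, 33), c(16, 32, 48)))
  }
  list(mesh = tet_mesh(nd[, 2:4], conn, part_labels = as.character(pid)),
       a = a, d = d)
}
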