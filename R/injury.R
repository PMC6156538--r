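#' Effective strain of a Green strain tensor
#'
#' The scalar strain intensity feeding the deep-tissue-injury criterion:
#' eps_eff = sqrt((2/3) eps : eps), the full tensor contraction of the
#' symmetric Green-Lagrange strain E = (F'F - I)/2.
#'
#' @param E symmetric 3x3 Green strain tensor.
#' @return scalar effective strain (dimensionless).
#' @export
effective_strain <- function(E) {
  sqrt((2 / 3) * sum(E * E))
}

#' Green strain from a deformation gradient
#' @param F 3x3 deformation gradient.
#' @return symmetric 3x3 Green-Lagrange strain E = (F'F - I)/2.
#' @export
green_strain <- function(F) {
  (crossprod(matrix(as.numeric(F), 3, 3)) - diag(3)) / 2
}

#' Strain-time injury threshold (critical strain sigmoid)
#'
#' Boltzmann-type sigmoid giving the critical effective strain beyond which
#' muscle cells die after sustained loading time t:
#' eps_crit(t) = K / (1 + exp(beta (t - t0))) + C. Tissue tolerates
#' eps_eff up to K + C at short times and only C after long loading; the
#' midpoint of the decay sits at t0.
#'
#' @param t loading time in ms (vectorised). Time is measured from load
#'   onset.
#' @param K sigmoid step height (default 0.268).
#' @param t0 sigmoid midpoint time in ms (default 9.78e6).
#' @param beta decay rate in 1/ms (default 5.83e-7).
#' @param C late-time asymptote (default 0.332).
#' @return critical strain values, same length as \code{t}.
#' @export
critical_strain <- function(t, K = 0.268, t0 = 9.78e6, beta = 5.83e-7,
                            C = 0.332) {
  K / (1 + exp(pmin(beta * (t - t0), 700))) + C
}

#' Injury state of a tracked element set
#'
#' @param injured logical matrix (n_elements x n_times): flag history.
#' @param times evaluation instants (ms).
#' @param damage_fraction percent of tracked volume injured at each time.
#' @return object of class \code{injury_state}.
#' @export
injury_state <- function(injured, times, damage_fraction) {
  stopifnot(ncol(injured) == length(times),
            length(damage_fraction) == length(times))
  structure(list(injured = injured, times = as.numeric(times),
                 damage_fraction = as.numeric(damage_fraction)),
            class = "injury_state")
}

#' @export
print.injury_state <- function(x, ...) {
  cat(sprintf("<injury_state> %d elements over %d instants; final damage %.3f%%\n",
              nrow(x$injured), length(x$times),
              x$damage_fraction[length(x$damage_fraction)]))
  invisible(x)
}

#' Classify elements as injured or healthy over a strain history
#'
#' An element is flagged injured at the first instant where its effective
#' strain exceeds the critical strain eps_crit(t); the flag is irreversible
#' (cell death does not heal within the analysis window).
#'
#' @param strain_history numeric matrix (n_elements x n_times) of eps_eff
#'   values.
#' @param times evaluation instants (ms), measured from load onset.
#' @param volumes optional per-element volumes (mm^3) for the damage
#'   fraction; defaults to equal volumes.
#' @param ... sigmoid constants passed to \code{\link{critical_strain}}.
#' @return an \code{\link{injury_state}}.
#' @export
classify_injury <- function(strain_history, times,
                            volumes = rep(1, nrow(strain_history)), ...) {
  strain_history <- as.matrix(strain_history)
  stopifnot(ncol(strain_history) == length(times),
            length(volumes) == nrow(strain_history))
  crit <- critical_strain(times, ...)
  exceed <- sweep(strain_history, 2L, crit, `>`)
  # irreversible: injured once exceeded at any earlier instant
  injured <- t(apply(exceed, 1L, cummax)) > 0
  if (length(times) == 1L) injured <- matrix(exceed[, 1], ncol = 1)
  dmg <- 100 * as.numeric(volumes %*% injured) / sum(volumes)
  injury_state(injured, times, dmg)
}

#' Damage volume fraction of tracked mesh parts
#'
#' Percent of the tracked parts' volume whose elements are flagged injured,
#' per evaluation instant. Tracks muscle parts by default.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param injured logical matrix (n_tracked x n_times) or vector, rows
#'   matching \code{tracked_elements}.
#' @param tracked_parts part labels to include in the total volume
#'   (default: all parts whose label contains "muscle", else all).
#' @return numeric vector, percent in [0, 100] per instant.
#' @export
damage_volume_fraction <- function(mesh, injured, tracked_parts = NULL) {
  if (is.null(tracked_parts)) {
    tracked_parts <- unique(grep("muscle", mesh$part_labels, value = TRUE,
                                 ignore.case = TRUE))
    if (!length(tracked_parts)) tracked_parts <- unique(mesh$part_labels)
  }
  sel <- mesh$part_labels %in% tracked_parts
  v <- element_centroids_volumes(mesh)$volumes[sel]
  injured <- as.matrix(injured)
  stopifnot(nrow(injured) == sum(sel))
  100 * as.numeric(v %*% injured) / sum(v)
}

#' Volume-normalised von Mises stress
#'
#' sigma_bar = (1/V) sum_e sigma_e v_e: the element-volume-weighted mean
#' von Mises stress used as the mesh-convergence metric.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param von_mises_stress per-element von Mises stress (MPa).
#' @param element_ids elements to include (default: all).
#' @return scalar sigma_bar (MPa).
#' @export
normalised_stress <- function(mesh, von_mises_stress,
                              element_ids = seq_len(nrow(mesh$elements))) {
  v <- element_centroids_volumes(mesh)$volumes[element_ids]
  stopifnot(length(von_mises_stress) == length(v))
  sum(von_mises_stress * v) / sum(v)
}

#' Write a damage-fraction time series as CSV
#' @param state an \code{\link{injury_state}}.
#' @param path output CSV path.
#' @export
write_damage_series <- function(state, path) {
  utils::write.csv(data.frame(time_ms = state$times,
                              damage_percent = state$damage_fraction),
                   path, row.names = FALSE)
  invisible(path)
}
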