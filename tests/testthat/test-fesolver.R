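test_that("material-point protocols report zero stress for identity histories", {
  out <- run_protocol(rep(list(diag(3)), 4), params = muscle_params())
  expect_true(all(abs(out[, grep("^[ST]", names(out))]) < 1e-14))
  expect_true(all(out$eps_eff == 0))
  expect_equal(out$lambda, rep(1, 4))
})

test_that("a fibre-stretch ramp peaks at s_max when scaled by lambda^2", {
  # isolate the active law: isotropic and passive coefficients off
  pr <- material_params(c1 = 0, c2 = 0, bulk_k = 0, c3 = 0, alpha = 1)
  lams <- seq(1, 1.3, length.out = 7)
  Fh <- lapply(lams, function(l) diag(c(l, 1 / sqrt(l), 1 / sqrt(l))))
  out <- run_protocol(Fh, a0 = c(1, 0, 0), params = pr)
  expect_equal(out$lambda, lams, tolerance = 1e-12)
  expect_equal(max(out$lambda^2 * out$S_fibre), 0.1, tolerance = 1e-12)
  # cross-fibre stretch with passive-only muscle: fibre stays unstretched,
  # passive fibre stress zero, isotropic part matches the energy oracle
  prm <- muscle_params()
  Fc <- diag(c(1, 1.15, 1))
  st <- deformation_state(Fc, c(1, 0, 0))
  expect_equal(aniso_stress(st, prm)[1, 1], 0)
  expect_equal(second_pk(st, prm), second_pk_fd(st$C, c(1, 0, 0), prm),
               tolerance = 1e-5)
})

test_that("zero load produces zero displacement and stress", {
  m <- cube_mesh(2L, 2)
  bot <- which(m$nodes[, 3] < 1e-9)
  lc <- load_case(data.frame(node = rep(bot, each = 3),
                             dof = rep(1:3, length(bot)), value = 0),
                  ramp_steps = 1L)
  sol <- solve_static(m, skin_fat_params(), lc)
  expect_true(sol$converged)
  expect_equal(max(abs(sol$displacements)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sol$stress)), 0, tolerance = 1e-10)
})

test_that("the FE patch test reproduces the material-point stress exactly", {
  m <- cube_mesh(3L, 2)
  Fh <- matrix(c(1.04, 0.02, 0, 0.01, 0.98, 0.015, 0, 0.01, 1.03), 3, 3)
  # affine Dirichlet data on every boundary node
  faces <- rbind(m$elements[, c(1, 2, 3)], m$elements[, c(1, 2, 4)],
                 m$elements[, c(1, 3, 4)], m$elements[, c(2, 3, 4)])
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  bnodes <- sort(unique(as.vector(faces[key %in% names(which(table(key) == 1)), ])))
  expect_lt(length(bnodes), nrow(m$nodes))    # interior nodes exist
  disp <- m$nodes[bnodes, ] %*% t(Fh - diag(3))
  lc <- load_case(data.frame(node = rep(bnodes, 3),
                             dof = rep(1:3, each = length(bnodes)),
                             value = as.numeric(disp)), ramp_steps = 1L)
  pr <- skin_fat_params()
  sol <- solve_static(m, pr, lc, tol = 1e-10)
  expect_true(sol$converged)
  st <- deformation_state(Fh)
  Tref <- cauchy(st, second_pk(st, pr))
  ref <- c(Tref[1, 1], Tref[2, 2], Tref[3, 3], Tref[1, 2], Tref[1, 3],
           Tref[2, 3])
  expect_lt(max(abs(sweep(sol$stress, 2, ref))), 1e-8)
  # Newton converges superlinearly: log-residual drops accelerate
  r <- sol$residual_history
  r <- r[r > 1e-14]
  if (length(r) >= 3) {
    rates <- diff(log(r))
    expect_gt(rates[length(rates)] / rates[1], 1.5)
  }
})

test_that("reaction forces balance the applied body load", {
  m <- make_cylinder_mesh(4, 8, 2)
  bot <- which(m$nodes[, 3] < 1e-9)
  g <- c(0, 0, -9.81e-3)                    # gravity, mm/ms^2
  rho <- 1e-3                               # g/mm^3
  lc <- load_case(data.frame(node = rep(bot, each = 3),
                             dof = rep(1:3, length(bot)), value = 0),
                  body_force = g, density = rho, ramp_steps = 2L)
  sol <- solve_static(m, skin_fat_params(), lc, tol = 1e-10)
  expect_true(sol$converged)
  V <- sum(element_centroids_volumes(m)$volumes)
  weight <- rho * V * 9.81e-3
  expect_equal(sum(sol$reactions[, 3]), weight, tolerance = 1e-6)
})

test_that("quasi-incompressibility holds with a stiffened bulk modulus", {
  m <- make_cylinder_mesh(5, 6, 2.5)
  pr <- material_params(gamma = 1, bulk_k = 1)   # 10x the default penalty
  # frictionless platens: only the axial dof of the end faces is driven, so
  # the response is near-homogeneous and the volume change is material,
  # not an end-constraint artefact
  z <- m$nodes[, 3]
  bot <- which(z < 1e-9); top <- which(z > 6 - 1e-9)
  ctr <- which.min(rowSums(m$nodes[, 1:2]^2) + z^2)   # pin rigid modes
  xpin <- which.max(m$nodes[, 1] * (z < 1e-9))
  dir <- rbind(data.frame(node = bot, dof = 3L, value = 0),
               data.frame(node = top, dof = 3L, value = -0.05 * 6),
               data.frame(node = ctr, dof = 1:2, value = 0),
               data.frame(node = xpin, dof = 2L, value = 0))
  sol <- solve_static(m, pr, load_case(dir, ramp_steps = 2L), tol = 1e-8)
  expect_true(sol$converged)
  def <- tet_mesh(m$nodes + sol$displacements, m$elements, m$part_labels)
  v0 <- sum(element_centroids_volumes(m)$volumes)
  v1 <- sum(abs(fibremech:::.tet_volumes(def$nodes, def$elements)))
  expect_lt(100 * abs(v1 - v0) / v0, 0.5)
})

test_that("the solution is invariant under node renumbering", {
  m <- cube_mesh(2L, 4)
  set.seed(60)
  perm <- sample(nrow(m$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- tet_mesh(m$nodes[perm, ], matrix(inv[m$elements], ncol = 4),
                 m$part_labels)
  mk <- function(mesh) axial_compression_load(mesh, 0.03, ramp_steps = 1L)
  s1 <- solve_static(m, skin_fat_params(), mk(m), tol = 1e-10)
  s2 <- solve_static(m2, skin_fat_params(), mk(m2), tol = 1e-10)
  expect_equal(normalised_stress(m, s1$von_mises),
               normalised_stress(m2, s2$von_mises), tolerance = 1e-8)
  expect_equal(s1$displacements[perm[5], ], s2$displacements[5, ],
               tolerance = 1e-8)
})

test_that("rigid-body-mode deficiencies are diagnosed", {
  m <- cube_mesh(2L, 2)
  # constraining a single dof leaves rigid modes
  lc <- load_case(data.frame(node = 1L, dof = 3L, value = 0.01),
                  ramp_steps = 1L)
  expect_error(suppressWarnings(solve_static(m, skin_fat_params(), lc)),
               "rigid")
})

test_that("uniform-stress refinement keeps the normalised stress constant", {
  Fh <- diag(c(0.97, 1.01, 1.02))
  mk <- function(mesh) {
    faces <- rbind(mesh$elements[, c(1, 2, 3)], mesh$elements[, c(1, 2, 4)],
                   mesh$elements[, c(1, 3, 4)], mesh$elements[, c(2, 3, 4)])
    key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
    bn <- sort(unique(as.vector(faces[key %in% names(which(table(key) == 1)), ])))
    disp <- mesh$nodes[bn, ] %*% t(Fh - diag(3))
    load_case(data.frame(node = rep(bn, 3), dof = rep(1:3, each = length(bn)),
                         value = as.numeric(disp)), ramp_steps = 1L)
  }
  meshes <- list(cube_mesh(2L, 2), cube_mesh(3L, 2))
  cs <- convergence_study(meshes, mk, skin_fat_params(), tol = 1e-10)
  expect_equal(cs$sigma_bar[1], cs$sigma_bar[2], tolerance = 1e-8)
  # single level: trivial pass-through
  one <- convergence_study(meshes[1], mk, skin_fat_params(), tol = 1e-10)
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$rel_change_percent))
  # solution export for standard viewers parses back as a mesh
  sol <- solve_static(meshes[[1]], skin_fat_params(), mk(meshes[[1]]))
  pv <- file.path(tempdir(), "sol.vtk")
  write_solution_vtk(meshes[[1]], sol, pv,
                     injured = rep(FALSE, nrow(meshes[[1]]$elements)))
  expect_s3_class(read_mesh(pv, "vtk"), "tet_mesh")
})
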