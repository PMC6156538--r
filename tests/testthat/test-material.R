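test_that("the reference configuration is stress-free for passive parameter sets", {
  st <- deformation_state(diag(3), c(0, 0, 1))
  for (pr in list(muscle_params(), skin_fat_params(),
                  material_params(c1 = 3e-4, c2 = 1e-2, bulk_k = 0.5,
                                  c3 = 5e-3, c4 = 4, lambda_opt = 1.2)))
    expect_equal(second_pk(st, pr), matrix(0, 3, 3), tolerance = 1e-15)
  # coefficient cancellation B1 + B2 * 1 + B3 = 0 at the identity
  expect_equal(iso_stress(st, muscle_params()), matrix(0, 3, 3),
               tolerance = 1e-15)
  expect_equal(cauchy(st, params = skin_fat_params()), matrix(0, 3, 3),
               tolerance = 1e-15)
})

test_that("pure dilation recovers the bulk penalty on the diagonal", {
  pr <- skin_fat_params()
  J <- 1.2
  st <- deformation_state(J^(1 / 3) * diag(3))
  S <- iso_stress(st, pr)
  # symbolic evaluation: isochoric part vanishes, leaving
  # k (J - 1) J * C^-1 with C = J^(2/3) I
  expect_equal(S, pr$bulk_k * (J - 1) * J * J^(-2 / 3) * diag(3),
               tolerance = 1e-12)
})

test_that("stress matches the finite-difference strain-energy oracle", {
  set.seed(40)
  a0 <- c(2, 1, 0.5); a0 <- a0 / sqrt(sum(a0^2))
  cases <- list(
    list(F = diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1))), pr = muscle_params()),
    list(F = matrix(c(1, 0, 0, 0.25, 1, 0, 0, 0, 1), 3, 3),
         pr = skin_fat_params()),                     # simple shear, fat
    list(F = diag(3) + 0.08 * matrix(rnorm(9), 3, 3), pr = muscle_params())
  )
  for (cs in cases) {
    st <- deformation_state(cs$F, a0)
    S_fd <- second_pk_fd(st$C, a0, cs$pr)
    expect_equal(second_pk(st, cs$pr), S_fd, tolerance = 1e-5)
  }
})

test_that("fibre stress branches follow the printed two-branch law", {
  pr <- muscle_params(alpha = 1)
  a0 <- c(1, 0, 0)
  mk <- function(lam) deformation_state(diag(c(lam, 1, 1)), a0)
  # compressed fibre: passive part exactly zero
  expect_equal(aniso_stress(mk(0.95), pr, part = "pas"), matrix(0, 3, 3))
  # at optimal stretch the exponential is 1: Lambda^2 S_act = s_max
  lam <- pr$lambda_opt
  Sact <- aniso_stress(mk(lam), pr, part = "act")
  expect_equal(lam^2 * Sact[1, 1], pr$s_max, tolerance = 1e-12)
  # passive fibre component vs the scalar formula at Lambda = 1.2
  Spas <- aniso_stress(mk(1.2), pr, part = "pas")
  expect_equal(Spas[1, 1], pr$c3 * (1.2^pr$c4 - 1) / 1.2^2, tolerance = 1e-12)
  # gamma = 1 kills the fibre contribution entirely
  stf <- mk(1.2)
  expect_equal(second_pk(stf, skin_fat_params()),
               iso_stress(stf, skin_fat_params()), tolerance = 1e-15)
})

test_that("fibre stress is continuous across both branch switches", {
  pr <- muscle_params(alpha = 0.8)
  a0 <- c(1, 0, 0)
  s_at <- function(lam)
    aniso_stress(deformation_state(diag(c(lam, 1, 1)), a0), pr)[1, 1]
  eps <- 1e-9
  expect_equal(s_at(1 - eps), s_at(1 + eps), tolerance = 1e-6)
  lo <- pr$lambda_opt
  expect_equal(s_at(lo - eps), s_at(lo + eps), tolerance = 1e-6)
  # both active branches equal s_max / lambda_opt^2 at the optimum
  sact <- aniso_stress(deformation_state(diag(c(lo, 1, 1)), a0),
                       muscle_params(alpha = 1), part = "act")[1, 1]
  expect_equal(sact, pr$s_max / lo^2, tolerance = 1e-12)
})

test_that("stress is frame-indifferent", {
  set.seed(41)
  pr <- muscle_params(alpha = 0.5)
  a0 <- c(0, 1, 0)
  F <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
  S <- second_pk(deformation_state(F, a0), pr)
  for (i in 1:5) {
    Q <- random_rotation()
    expect_equal(second_pk(deformation_state(Q %*% F, a0), pr), S,
                 tolerance = 1e-9)
  }
})

test_that("the analytic tangent matches central differences of S", {
  set.seed(42)
  a0 <- c(1, 1, 1) / sqrt(3)
  pr <- muscle_params(alpha = 0.7)
  h <- 1e-6
  for (rep in 1:5) {
    F <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
    if (det(F) < 0.3) next
    st <- deformation_state(F, a0)
    CC <- material_tangent(st, pr)
    scale <- max(abs(CC))
    for (k in 1:3) for (l in k:3) {
      dC <- matrix(0, 3, 3)
      if (k == l) dC[k, k] <- h else dC[k, l] <- dC[l, k] <- h / 2
      fd <- (second_pk(state_from_C(st$C + dC, a0), pr) -
             second_pk(state_from_C(st$C - dC, a0), pr)) / h
      expect_lt(max(abs(CC[, , k, l] - fd)) / scale, 1e-6)
    }
  }
})

test_that("the tangent carries major and minor symmetries", {
  set.seed(43)
  st <- deformation_state(diag(3) + 0.1 * matrix(rnorm(9), 3, 3), c(1, 0, 0))
  for (pr in list(skin_fat_params(), muscle_params(alpha = 1))) {
    CC <- material_tangent(st, pr)
    expect_equal(CC, aperm(CC, c(3, 4, 1, 2)), tolerance = 1e-12)  # major
    expect_equal(CC, aperm(CC, c(2, 1, 3, 4)), tolerance = 1e-12)  # minor
    expect_equal(CC, aperm(CC, c(1, 2, 4, 3)), tolerance = 1e-12)
  }
})

test_that("the spatial tangent at the identity is isotropic with positive shear", {
  st <- deformation_state(diag(3))
  B <- spatial_tangent(st, params = skin_fat_params())
  # at F = I the push-forward is the material tangent itself
  expect_equal(B, material_tangent(st, skin_fat_params()), tolerance = 1e-12)
  # shear-direction components positive (shear modulus ~ 2(c1 + c2))
  expect_gt(B[1, 2, 1, 2], 0)
  expect_equal(B[1, 2, 1, 2], B[2, 3, 2, 3], tolerance = 1e-12)
  expect_equal(B[1, 1, 1, 1], B[2, 2, 2, 2], tolerance = 1e-12)
})

test_that("von Mises stress follows the deviator-norm formula", {
  expect_equal(von_mises(diag(c(5, 5, 5))), 0)
  expect_equal(von_mises(diag(c(3, 0, 0))), 3)
  set.seed(44)
  A <- matrix(rnorm(9), 3, 3); T <- (A + t(A)) / 2
  dev <- T - diag(3) * sum(diag(T)) / 3
  expect_equal(von_mises(T), sqrt(1.5 * sum(dev^2)), tolerance = 1e-12)
})

test_that("material config files round trip and reject unknown keys", {
  cfg <- read_material_config(system.file("extdata", "materials.cfg",
                                          package = "fibremech"))
  expect_named(cfg, c("muscle", "skin_fat", "liner"))
  expect_equal(cfg$muscle$s_max, 0.1)
  expect_equal(cfg$muscle$lambda_opt, 1.3)
  expect_equal(cfg$skin_fat$gamma, 1)
  expect_equal(cfg$liner$c1, 0.33)
  bad <- file.path(tempdir(), "bad.cfg")
  writeLines(c("[x]", "c1 = 1", "c9 = 2"), bad)
  expect_error(read_material_config(bad), "unknown material key")
})

test_that("deformation states reject non-invertible gradients", {
  expect_error(deformation_state(diag(c(1, 1, 0))), "positive determinant")
  st <- deformation_state(diag(c(1.2, 0.9, 1)), c(1, 0, 0))
  expect_equal(st$lambda, 1.2)
  expect_equal(st$I4, 1.44)
  expect_equal(st$J, 1.2 * 0.9)
})
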