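test_that("strand runs inside an element are maximal consecutive stretches", {
  big <- suppressWarnings(tet_mesh(10 * unit_tet()$nodes, matrix(1:4, 1), "m"))
  inside <- fibre_strand(rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1)), 1L)
  runs <- strand_segments_in_element(inside, big, 1L)
  expect_length(runs, 1L)
  expect_identical(runs[[1]], 1:3)
  # in-out-in: brute-force barycentric classification oracle
  pts <- rbind(c(1, 1, 1), c(2, 2, 2), c(20, 20, 20), c(30, 1, 1),
               c(1, 1, 2), c(2, 1, 1))
  s <- fibre_strand(pts, 2L)
  runs2 <- strand_segments_in_element(s, big, 1L)
  oracle <- apply(pts, 1L, function(p) all(p >= 0) && sum(p) <= 10)
  expect_identical(oracle, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_length(runs2, 2L)
  expect_identical(runs2, list(1:2, 5:6))
  # no points inside -> empty
  far <- fibre_strand(rbind(c(50, 50, 50), c(51, 50, 50)), 3L)
  expect_length(strand_segments_in_element(far, big, 1L), 0L)
  # boundary counts as inside
  onface <- fibre_strand(rbind(c(0, 0, 0), c(10, 0, 0)), 4L)
  expect_length(strand_segments_in_element(onface, big, 1L), 1L)
})

test_that("total-least-squares trend lines align with the traversal direction", {
  pts <- cbind(seq(0, 5, by = 1), seq(0, 10, by = 2), 0)
  g <- line_of_best_fit(pts)
  expect_equal(g, c(1, 2, 0) / sqrt(5), tolerance = 1e-12)
  # reversed traversal flips the sign
  expect_equal(line_of_best_fit(pts[6:1, ]), -g, tolerance = 1e-12)
  # two points: normalised difference vector
  expect_equal(line_of_best_fit(rbind(c(0, 0, 0), c(0, 0, 2))), c(0, 0, 1))
  # noisy line recovered within 1 degree
  set.seed(30)
  axis <- c(1, 1, 1) / sqrt(3)
  t <- seq(0, 1, length.out = 50)
  noisy <- outer(t, axis) + matrix(rnorm(150, sd = 0.01), ncol = 3)
  ang <- acos(min(1, abs(sum(line_of_best_fit(noisy) * axis)))) * 180 / pi
  expect_lt(ang, 1)
  expect_error(line_of_best_fit(matrix(1:3, 1)), "at least 2")
})

test_that("effective directions use squared-count weights that sum to one", {
  # n = (3, 1) -> weights (0.9, 0.1), the printed weight formula
  ed <- effective_direction(rbind(c(1, 0, 0), c(0, 1, 0)), c(3L, 1L))
  expect_equal(ed$weights, c(0.9, 0.1))
  expect_equal(sum(ed$weights), 1)
  expect_equal(ed$direction,
               c(0.9, 0.1, 0) / sqrt(0.9^2 + 0.1^2), tolerance = 1e-12)
  # single run passes through
  one <- effective_direction(matrix(c(0, 0, 1), 1), 5L)
  expect_equal(one$direction, c(0, 0, 1))
  # antiparallel equal runs resolve to the common axis, not zero
  anti <- effective_direction(rbind(c(1, 0, 0), c(-1, 0, 0)), c(4L, 4L))
  expect_equal(abs(anti$direction), c(1, 0, 0))
  # property: weights sum to 1 for random run sets
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    dirs <- matrix(rnorm(3 * k), k)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ed <- effective_direction(dirs, sample(1:9, k, replace = TRUE))
    expect_equal(sum(ed$weights), 1, tolerance = 1e-12)
    expect_equal(sum(ed$direction^2), 1, tolerance = 1e-9)
  }
  # no runs -> missing flag
  expect_true(all(is.na(effective_direction(matrix(0, 0, 3), integer(0))$direction)))
})

test_that("fibre mapping assigns axial strands an axial element direction", {
  m <- cube_mesh(2L, 10)
  strands <- make_strands("axial", n_strands = 6L, n_points = 30L,
                          extent = c(10, 10, 10), seed = 32L)
  field <- map_fibres_to_elements(m, fibre_bundle("muscle", strands))
  have <- !is.na(field$directions[, 1])
  expect_gt(sum(have), 0)
  expect_true(all(abs(field$directions[have, 3]) > 1 - 1e-9))
})

test_that("radial-basis smoothing equals the brute-force kernel sum", {
  m <- cube_mesh(2L, 10)
  ne <- nrow(m$elements)
  set.seed(33)
  dirs <- matrix(rnorm(3 * ne), ne)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # hemisphere-normalise the fixture so sign flips do not enter the oracle
  ref0 <- dirs[1, ]
  flip <- as.numeric(dirs %*% ref0) < 0
  dirs[flip, ] <- -dirs[flip, ]
  field <- element_fibre_field(dirs, rep(1L, ne))
  p <- 4                                    # wide kernel: all weights matter
  sm <- smooth_fibre_field(m, field, p = p)
  cv <- element_centroids_volumes(m)
  L <- bounding_box_diagonal(m)
  for (i in c(1L, 17L, ne)) {
    num <- c(0, 0, 0)
    wmax <- -1; ref <- NULL
    for (e in seq_len(ne)) {
      w <- exp(-(p * sqrt(sum((cv$centroids[i, ] - cv$centroids[e, ])^2)) / L)^2)
      if (w > wmax) { wmax <- w; ref <- dirs[e, ] }
    }
    for (e in seq_len(ne)) {
      w <- exp(-(p * sqrt(sum((cv$centroids[i, ] - cv$centroids[e, ])^2)) / L)^2)
      d <- dirs[e, ]
      if (sum(d * ref) < 0) d <- -d
      num <- num + w * d
    }
    expect_equal(sm$directions[i, ], num / sqrt(sum(num^2)), tolerance = 1e-12)
  }
})

test_that("smoothing a constant field is the identity and fills gaps", {
  m <- cube_mesh(2L, 10)
  ne <- nrow(m$elements)
  const <- matrix(rep(c(0, 0, 1), each = ne), ne)
  sm <- smooth_fibre_field(m, element_fibre_field(const), p = 20)
  expect_equal(sm$directions, const, tolerance = 1e-12)
  # one missing element surrounded by the constant field gets filled
  holey <- const; holey[5, ] <- NA
  sm2 <- smooth_fibre_field(m, element_fibre_field(holey), p = 20)
  expect_equal(sm2$directions[5, ], c(0, 0, 1), tolerance = 1e-9)
  expect_false(anyNA(sm2$directions))
})

test_that("smoothing commutes with global rotations", {
  m <- cube_mesh(2L, 8)
  ne <- nrow(m$elements)
  set.seed(34)
  dirs <- matrix(rnorm(3 * ne), ne)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # the kernel length scale is held fixed: the default axis-aligned
  # bounding-box diagonal is itself orientation-dependent
  L <- bounding_box_diagonal(m)
  sm <- smooth_fibre_field(m, element_fibre_field(dirs), p = 10, L = L)
  Q <- random_rotation()
  mrot <- tet_mesh(m$nodes %*% t(Q), m$elements, m$part_labels)
  smrot <- smooth_fibre_field(mrot, element_fibre_field(dirs %*% t(Q)),
                              p = 10, L = L)
  expect_equal(smrot$directions, sm$directions %*% t(Q), tolerance = 1e-9)
  # a grid-aligned quarter turn preserves the default length scale too
  Qz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mrot2 <- tet_mesh(m$nodes %*% t(Qz), m$elements, m$part_labels)
  smrot2 <- smooth_fibre_field(mrot2, element_fibre_field(dirs %*% t(Qz)),
                               p = 10)
  expect_equal(smrot2$directions,
               smooth_fibre_field(m, element_fibre_field(dirs),
                                  p = 10)$directions %*% t(Qz),
               tolerance = 1e-9)
})

test_that("ortho-card export round trips through the independent parser", {
  m <- unit_tet()
  field <- element_fibre_field(matrix(c(0.6, 0.8, 0), 1))
  path <- file.path(tempdir(), "ortho.k")
  export_element_solid_ortho(m, field, path)
  back <- read_element_solid_ortho(path)
  expect_equal(back$mesh$nodes, m$nodes, tolerance = 1e-7)
  expect_identical(back$mesh$elements, m$elements)
  expect_equal(back$a[1, ], c(0.6, 0.8, 0), tolerance = 1e-7)
  # second axis is unit and orthogonal to a
  expect_equal(sum(back$d[1, ]^2), 1, tolerance = 1e-6)
  expect_lt(abs(sum(back$a[1, ] * back$d[1, ])), 1e-6)
  # missing direction falls back with a warning
  expect_warning(
    export_element_solid_ortho(m, element_fibre_field(matrix(NA_real_, 1, 3)),
                               path), "fallback")
  back2 <- read_element_solid_ortho(path)
  expect_equal(back2$a[1, ], c(1, 0, 0))
})
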