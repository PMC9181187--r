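test_that("two symmetric centers split the field into equal halves", {
  field <- field_rect()
  m <- tessellate(cbind(c(300, 635), c(374, 374)), field)
  expect_equal(m$areas_um2, rep(935 * 748 / 2, 2))
  expect_equal(m$adjacency, list(2L, 1L))
})

test_that("interior hexagonal-lattice cells have the closed-form area", {
  # lattice phase s/4 keeps ideal lattice sites off the field border, so
  # every edge-deficient cell visibly touches the wall and is excluded as
  # a boundary cell
  s <- 21.49
  field <- field_rect()
  xs <- seq(s / 4, field$width_um - 1e-9, by = s)
  ys <- seq(s * sqrt(3) / 4, field$height_um - 1e-9, by = s * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
    cbind(xs + (r %% 2) * s / 2, ys[r])
  }))
  pts <- pts[pts[, 1] > 0 & pts[, 1] < field$width_um, ]
  m <- tessellate(pts, field)
  interior <- which(!m$boundary)
  expect_gt(length(interior), 100)
  expect_equal(m$areas_um2[interior],
               rep(sqrt(3) / 2 * s^2, length(interior)),
               tolerance = 1e-6)
  mm <- morphometry(m)
  expect_equal(mm$cv_area, 0, tolerance = 1e-9)
  expect_equal(mm$hexagonality, 1.0)
})

test_that("input validation names offending center indices", {
  field <- field_rect()
  expect_error(tessellate(cbind(c(100, 100, 2000), c(100, 400, 400)), field),
               "indices: 3")
  expect_error(tessellate(cbind(c(100, 100), c(100, 100)), field),
               "duplicate")
  expect_error(tessellate(cbind(100, 100)[0, , drop = FALSE], field),
               "at least one")
})

test_that("tessellation tiles the field and adjacency is symmetric", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(c(5, 20, 80, 200), 1)
    m <- random_mosaic(n)
    expect_equal(sum(m$areas_um2), 935 * 748, tolerance = 1e-6)
    amat <- adjacency_to_matrix(m$adjacency)
    expect_true(identical(amat, t(amat)))
    expect_false(any(diag(amat)))
    # every center inside its own polygon
    own <- vapply(seq_len(n), function(i) {
      point_in_polygon(m$centers[i, 1], m$centers[i, 2], m$polygons[[i]])
    }, TRUE)
    expect_true(all(own))
  }
})

test_that("adjacency matches the sampled-bisector oracle on random fields", {
  set.seed(5)
  for (rep in 1:3) {
    m <- random_mosaic(50)
    expect_identical(adjacency_to_matrix(m$adjacency),
                     oracle_adjacency(m$centers, m$field))
  }
})

test_that("morphometry handles degenerate and jittered inputs", {
  field <- field_rect()
  m1 <- tessellate(cbind(400, 300), field)
  expect_error(morphometry(m1, interior_only = TRUE), "interior")
  mm <- morphometry(m1, interior_only = FALSE)
  expect_equal(mm$cv_area, 0)

  # polymegethism grows with jitter (20 seeds each)
  cv_at <- function(sig) {
    mean(vapply(1:20, function(seed) {
      cfg <- generator_config(target_ecd = 2500, jitter_sigma = sig,
                              seed = seed,
                              field = field_rect(935 / 2, 748 / 2),
                              nx = 640, ny = 512)
      morphometry(generate_mosaic(cfg)$mosaic)$cv_area
    }, 1))
  }
  expect_lt(cv_at(2), cv_at(6))
})

test_that("contiguous_groups partitions like the closure oracle", {
  expect_identical(contiguous_groups(integer(0), list(integer(0))), list())
  adj <- list(integer(0), integer(0))
  expect_identical(contiguous_groups(c(1, 2), adj), list(1L, 2L))
  expect_error(contiguous_groups(3, adj), "unknown")

  set.seed(12)
  for (rep in 1:25) {
    m <- random_mosaic(sample(10:40, 1))
    n <- nrow(m$centers)
    members <- sample(n, sample(0:n, 1))
    expect_identical(contiguous_groups(members, m$adjacency),
                     oracle_components(members, m$adjacency))
  }
})
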