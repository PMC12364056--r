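test_that("facet_persistent_number counts facets spanning both scales", {
  bc <- facet_barcode(c(1, 2, 10))
  expect_identical(facet_persistent_number(bc, i = 1, t = 1, t2 = 8), 1L)
  expect_identical(facet_persistent_number(bc, i = 0, t = 0, t2 = 1), 1L)
  expect_error(facet_persistent_number(bc, 0, t = 2, t2 = 1), "t <= t2")
  # diagonal reduces to a census of alive facets
  set.seed(31)
  for (rep in 1:20) {
    pts <- random_points(sample(2:10, 1))
    b <- facet_barcode(pts)
    t <- sample(0:15, 1)
    fac <- facets_at_scale(pts, t)
    dims <- fac[, "last"] - fac[, "first"]
    for (i in 0:3)
      expect_identical(facet_persistent_number(b, i, t, t),
                       sum(dims == i))
  }
})

test_that("facet_count_curve matches the worked example and conventions", {
  bc <- facet_barcode(c(1, 2, 10))
  M <- facet_count_curve(bc, grid = c(0, 1, 8, 9), dmax = 3)
  expect_equal(unname(M[1, ]), c(3, 1, 0, 0))
  expect_equal(unname(M[2, ]), c(0, 1, 2, 0))
  expect_equal(unname(M[3, ]), c(0, 0, 0, 1))
  # degenerate inputs
  expect_equal(facet_count_curve(NULL, 0:3, 2),
               matrix(0, 2, 4, dimnames = list(c("F0", "F1"), 0:3)))
  single <- facet_count_curve(facet_barcode(5), 0:3, 3)
  expect_equal(unname(single[1, ]), rep(1, 4))
  expect_equal(sum(single[-1, ]), 0)
})

test_that("overflow bucket accumulates facets of dimension >= dmax - 1", {
  pts <- 1:6  # at t = 5 the full 5-simplex is the only facet
  bc <- facet_barcode(pts)
  M <- facet_count_curve(bc, grid = 5, dmax = 3)
  expect_equal(unname(M[, 1]), c(0, 0, 1))
  set.seed(32)
  for (rep in 1:10) {
    p <- random_points(sample(4:10, 1), span = 20L)
    t <- sample(0:20, 1)
    full <- facet_count_curve(facet_barcode(p), t, dmax = 12)
    cut <- facet_count_curve(facet_barcode(p), t, dmax = 3)
    expect_equal(sum(full), sum(cut))
    expect_equal(unname(cut[3, 1]), sum(full[3:12, 1]))
  }
})

test_that("graded_betti_j1 agrees with the Hochster subset-sum oracle", {
  expect_identical(graded_betti_j1(c(1, 2, 10), t = 1, i = 1), 2L)
  expect_identical(graded_betti_j1(c(0, 10, 20), t = 5, i = 2), 2L)
  set.seed(33)
  for (rep in 1:100) {
    pts <- random_points(sample(2:8, 1), span = 20L)
    t <- sample(0:(max(pts) - min(pts) + 1), 1)
    i <- sample(1:3, 1)
    expect_identical(graded_betti_j1(pts, t, i),
                     hochster_betti(pts, t, i, 1))
  }
  # a simplex has trivial resolution beyond position 0
  pts <- random_points(5)
  for (i in 1:4)
    expect_identical(graded_betti_j1(pts, max(pts) - min(pts), i), 0L)
})

test_that("persistent_graded_betti obeys the structural identities", {
  set.seed(34)
  for (rep in 1:25) {
    pts <- random_points(sample(2:8, 1), span = 20L)
    t2 <- sample(0:20, 1)
    t <- sample(0:t2, 1)
    expect_identical(persistent_graded_betti(pts, t, t2, 0, 0), 1L)
    for (i in 1:3) {
      expect_identical(persistent_graded_betti(pts, t, t2, i, 0), 0L)
      for (j in 2:4)
        expect_identical(persistent_graded_betti(pts, t, t2, i, j), 0L)
    }
    expect_identical(persistent_graded_betti(pts, t, t2, 0, 1), 0L)
  }
  expect_identical(persistent_graded_betti(c(1, 2, 10), 1, 1, 1, 1), 2L)
  expect_error(persistent_graded_betti(c(1, 2), 3, 1, 1, 1), "t <= t2")
})

test_that("fast persistent j=1 route matches union-find component ranks", {
  set.seed(35)
  for (rep in 1:100) {
    pts <- random_points(sample(2:8, 1), span = 20L)
    t2 <- sample(0:(max(pts) - min(pts) + 1), 1)
    t <- sample(0:t2, 1)
    i <- sample(1:3, 1)
    expect_identical(
      persistent_graded_betti(pts, t, t2, i, 1, method = "fast"),
      persistent_graded_betti(pts, t, t2, i, 1, method = "oracle"))
  }
})

test_that("f <-> h transforms match the worked examples and invert exactly", {
  expect_equal(unname(h_from_f(c(1, 3, 1))), c(1, 1, -1))
  expect_equal(unname(h_from_f(c(1, 7), d = 1)), c(1, 6))
  expect_equal(unname(h_from_f(c(1, 3, 3, 1))), c(1, 0, 0, 0))
  expect_equal(unname(f_from_h(c(1, 1, -1))), c(1, 3, 1))
  d <- 4
  expect_equal(unname(f_from_h(c(1, 0, 0, 0, 0), d)), choose(d, 0:d))
  expect_error(h_from_f(c(2, 3)), "f_\\{-1\\}")
  set.seed(36)
  for (rep in 1:100) {
    f <- random_f_vector()
    d <- length(f) - 1L
    expect_equal(unname(f_from_h(h_from_f(f, d), d)), unname(f))
  }
})

test_that("persistent h-vector reduces to the classical one on the diagonal", {
  set.seed(37)
  for (rep in 1:50) {
    pts <- random_points(sample(2:9, 1), span = 25L)
    t <- sample(0:(max(pts) - min(pts) + 1), 1)
    expect_equal(unname(persistent_h_vector(pts, t, t)),
                 unname(h_vector_at_scale(pts, t)))
    expect_equal(unname(persistent_f_vector(pts, t, t)),
                 unname(f_vector_at_scale(pts, t)))
  }
})

test_that("persistent h is 1 in degree 0 and trivial on a full simplex", {
  set.seed(38)
  for (rep in 1:20) {
    pts <- random_points(sample(2:9, 1), span = 25L)
    t2 <- sample(0:25, 1)
    t <- sample(0:t2, 1)
    h <- persistent_h_vector(pts, t, t2)
    expect_equal(unname(h[1]), 1)
    f <- persistent_f_vector(pts, t, t2)
    expect_equal(unname(f[1]), 1)
  }
  pts <- c(2, 4, 9, 11)
  span <- max(pts) - min(pts)
  h <- persistent_h_vector(pts, 0, span)
  expect_equal(unname(h), c(1, rep(0, length(h) - 1)))
  expect_error(persistent_h_vector(pts, 5, 2), "t <= t2")
})
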