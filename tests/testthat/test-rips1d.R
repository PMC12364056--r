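test_that("facets_at_scale matches the worked examples", {
  f1 <- facets_at_scale(c(1, 2, 10), 1)
  expect_identical(intervals_as_sets(f1), list(1:2, 3L))
  f0 <- facets_at_scale(c(1, 2, 10), 0)
  expect_identical(intervals_as_sets(f0), list(1L, 2L, 3L))
  expect_identical(nrow(facets_at_scale(numeric(0), 3)), 0L)
  expect_error(facets_at_scale(c(1, 1, 2), 1), "strictly increasing")
})

test_that("facets_at_scale agrees with brute-force maximal subsets", {
  set.seed(11)
  for (rep in 1:100) {
    pts <- random_points(sample(2:10, 1))
    t <- sample(0:(max(pts) - min(pts) + 2), 1)
    fast <- intervals_as_sets(facets_at_scale(pts, t))
    brute <- facets_bruteforce(pts, t)
    expect_identical(fast, brute)
  }
})

test_that("facet minima are distinct and increasing at every scale", {
  set.seed(12)
  for (rep in 1:50) {
    pts <- random_points(sample(2:12, 1), span = 30L)
    for (t in c(0, 1, 3, 7, 15)) {
      fac <- facets_at_scale(pts, t)
      expect_false(anyDuplicated(fac[, "first"]) > 0)
      expect_false(is.unsorted(fac[, "first"], strictly = TRUE))
      # union of runs covers all indices
      expect_setequal(unlist(intervals_as_sets(fac)), seq_along(pts))
    }
  }
})

test_that("facet_barcode matches the worked example and a grid scan", {
  bc <- facet_barcode(c(1, 2, 10))
  key <- sprintf("%d-%d", bc$first, bc$last)
  expect_setequal(key, c("1-1", "2-2", "3-3", "1-2", "2-3", "1-3"))
  get <- function(k) bc[key == k, c("birth", "death")]
  expect_equal(unlist(get("1-1")), c(birth = 0, death = 1))
  expect_equal(unlist(get("2-2")), c(birth = 0, death = 1))
  expect_equal(unlist(get("3-3")), c(birth = 0, death = 8))
  expect_equal(unlist(get("1-2")), c(birth = 1, death = 9))
  expect_equal(unlist(get("2-3")), c(birth = 8, death = 9))
  expect_equal(unlist(get("1-3")), c(birth = 9, death = Inf))
  expect_true(all(bc$birth < bc$death))

  single <- facet_barcode(5)
  expect_identical(nrow(single), 1L)
  expect_equal(single$birth, 0)
  expect_equal(single$death, Inf)
})

test_that("barcode life intervals reproduce facets_at_scale on a fine grid", {
  set.seed(13)
  for (rep in 1:30) {
    pts <- random_points(sample(2:10, 1), span = 25L)
    bc <- facet_barcode(pts)
    # every vertex interval appears exactly once (no resurrection)
    expect_false(anyDuplicated(paste(bc$first, bc$last)) > 0)
    for (t in seq(0, max(pts) - min(pts) + 1, by = 0.5)) {
      alive <- bc[bc$birth <= t & bc$death > t, c("first", "last")]
      alive <- alive[order(alive$first), , drop = FALSE]
      expect_identical(as.matrix(alive),
                       matrix(facets_at_scale(pts, t),
                              ncol = 2, dimnames = dimnames(as.matrix(alive))))
    }
  }
})

test_that("f_vector_at_scale matches brute-force subset counting", {
  expect_equal(unname(f_vector_at_scale(c(1, 2, 10), 1)), c(1, 3, 1))
  expect_equal(unname(f_vector_at_scale(c(1, 2, 10), 9)), c(1, 3, 3, 1))
  set.seed(14)
  for (rep in 1:100) {
    pts <- random_points(sample(2:10, 1))
    t <- sample(0:(max(pts) - min(pts) + 1), 1)
    f <- f_vector_at_scale(pts, t)
    simplices <- rips_complex_bruteforce(pts, t)
    sizes <- table(factor(lengths(simplices), levels = 1:(length(f) - 1)))
    expect_equal(unname(f), c(1, as.numeric(sizes)))
    # vertices only at t = 0; f_0 constant in t
    expect_equal(unname(f_vector_at_scale(pts, 0)), c(1, length(pts)))
    expect_equal(unname(f[2]), length(pts))
  }
})

test_that("component_count counts gap-separated clusters, monotone in t", {
  expect_identical(component_count(c(1, 2, 10), 1), 2L)
  expect_identical(component_count(c(1, 2, 10), 8), 1L)
  expect_identical(component_count(3, 0), 1L)
  expect_identical(component_count(numeric(0), 1), 0L)
  set.seed(15)
  for (rep in 1:20) {
    pts <- random_points(sample(2:12, 1))
    counts <- vapply(0:12, function(t) component_count(pts, t), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("1-D Rips complexes have vanishing homology in degrees >= 1", {
  set.seed(16)
  for (rep in 1:40) {
    pts <- random_points(sample(2:8, 1), span = 20L)
    t <- sample(0:(max(pts) - min(pts) + 1), 1)
    cx <- rips_complex_bruteforce(pts, t)
    for (q in 1:3) expect_identical(reduced_betti(cx, q), 0L)
    # degree 0 reduced homology counts components minus one
    expect_identical(reduced_betti(cx, 0), component_count(pts, t) - 1L)
  }
})
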