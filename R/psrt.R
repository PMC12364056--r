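# Persistent Stanley-Reisner invariants on 1-D Vietoris-Rips
# filtrations: facet persistent numbers, persistent graded Betti
# numbers (via the degree-shift-one collapse special to the line),
# and the classical / persistent f- and h-vector transforms.
#
# All Betti/f/h computation is exact integer arithmetic.  The
# closed-form routes are derived (not quoted) results; the oracle
# module provides the brute-force counterparts every one of them is
# tested against.

#' Facet persistent number
#'
#' Number of dimension-`i` facets whose life interval `[birth, death)`
#' contains both scales: `birth <= t` and `death > t2`.  On the
#' diagonal `t == t2` this is a census of alive dimension-`i` facets.
#'
#' @param barcode Result of [facet_barcode()].
#' @param i Facet dimension.
#' @param t,t2 Scales with `t <= t2`.
#' @return Integer count.
#' @export
#' @examples
#' facet_persistent_number(facet_barcode(c(1, 2, 10)), i = 1, t = 1, t2 = 8)
facet_persistent_number <- function(barcode, i, t, t2 = t) {
  if (t > t2) .stopf("facet_persistent_number: need t <= t2")
  sum(barcode$dim == i & barcode$birth <= t & barcode$death > t2)
}

#' Facet-count curves over a filtration grid
#'
#' Entry `(i, r)` counts alive facets of dimension `i - 1` at scale
#' `grid[r]`; facets of dimension `>= dmax - 1` are accumulated into the
#' last row (overflow bucket), so every curve matrix has exactly `dmax`
#' rows regardless of how dense the point cloud is.
#'
#' @param barcode Result of [facet_barcode()] (or `NULL` for an empty
#'   position set).
#' @param grid Increasing vector of scales.
#' @param dmax Number of dimension rows (`>= 1`).
#' @return `dmax x length(grid)` numeric matrix.
#' @export
facet_count_curve <- function(barcode, grid, dmax) {
  stopifnot(dmax >= 1, length(grid) >= 1, !is.unsorted(grid))
  out <- matrix(0, dmax, length(grid),
                dimnames = list(paste0("F", seq_len(dmax) - 1L), grid))
  if (is.null(barcode) || nrow(barcode) == 0L) return(out)
  dims <- pmin(barcode$dim, dmax - 1L)
  for (r in seq_along(grid)) {
    alive <- barcode$birth <= grid[r] & barcode$death > grid[r]
    out[, r] <- tabulate(dims[alive] + 1L, nbins = dmax)
  }
  out
}

#' Graded Betti numbers in degree shift one (1-D closed form)
#'
#' Computes `beta_{i,i+1}` of the Stanley-Reisner ring of the Rips
#' complex at scale `t` in polynomial time.  Via Hochster's identity the
#' value is a sum over vertex pairs `a < b` at distance `> t` of
#' `C(n - (b - a + 1), i - 1)`: each such pair, taken consecutive inside
#' an `(i+1)`-subset, contributes one extra connected component, and the
#' remaining `i - 1` vertices may be chosen freely outside the enclosed
#' index interval.
#'
#' @param points Strictly increasing numeric vector.
#' @param t Scale, `t >= 0`.
#' @param i Homological index, `i >= 1`.
#' @return Integer.
#' @export
#' @examples
#' graded_betti_j1(c(1, 2, 10), t = 1, i = 1)  # 2
graded_betti_j1 <- function(points, t, i) {
  points <- .check_points(points)
  stopifnot(t >= 0, i >= 1)
  n <- length(points)
  if (n < 2L) return(0L)
  total <- 0
  for (a in seq_len(n - 1L)) {
    far <- which(points[(a + 1L):n] - points[a] > t) + a
    if (length(far) > 0L)
      total <- total + sum(.choose0(n - (far - a + 1L), i - 1L))
  }
  as.integer(total)
}

#' Persistent graded Betti number of a 1-D Rips filtration
#'
#' For filtrations of 1-D point clouds all higher reduced homology of
#' induced subcomplexes vanishes, so the only nonzero entries sit in
#' degree shift one (`j = 1`) besides the structural `beta_{0,0} = 1`.
#' Because the vertex set is fixed, the induced map on degree-0 reduced
#' homology of every induced subcomplex is surjective, hence the
#' persistent `j = 1` value equals the static value at the later scale
#' `t2`.  That collapse is a derived shortcut; `method = "oracle"`
#' recomputes the value by brute-force persistent component ranks
#' instead (small inputs only).
#'
#' @param points Strictly increasing numeric vector.
#' @param t,t2 Scales with `t <= t2`.
#' @param i,j Homological index and degree shift, both `>= 0`.
#' @param method `"fast"` (closed form, default) or `"oracle"`
#'   (brute-force subset sum; guarded input size).
#' @return Integer.
#' @export
#' @examples
#' persistent_graded_betti(c(1, 2, 10), t = 1, t2 = 8, i = 0, j = 0)  # 1
persistent_graded_betti <- function(points, t, t2, i, j,
                                    method = c("fast", "oracle")) {
  method <- match.arg(method)
  if (t > t2) .stopf("persistent_graded_betti: need t <= t2")
  stopifnot(i >= 0, j >= 0)
  if (j == 0L) return(if (i == 0L) 1L else 0L)
  if (i == 0L || j >= 2L || i > i + j) return(0L)
  # j == 1, i >= 1
  if (method == "fast") return(graded_betti_j1(points, t2, i))
  points <- .check_points(points)
  n <- length(points)
  if (n > 14L) .stopf("oracle path limited to n <= 14 points")
  if (n < i + 1L) return(0L)
  subsets <- combn(n, i + 1L)
  total <- 0L
  for (c in seq_len(ncol(subsets)))
    total <- total + persistent_component_rank(points, subsets[, c], t, t2)
  total
}

#' h-vector from an f-vector
#'
#' `h_m = sum_{j=0}^{m} (-1)^(m-j) C(d-j, m-j) f_{j-1}` for
#' `m = 0, ..., d`, with `f_{-1} = 1` and the zero-outside-range
#' binomial convention.
#'
#' @param f Numeric vector `(f_{-1}, f_0, ..., f_{d-1})`; `f[1]` must
#'   be 1.
#' @param d The parameter `d = dim + 1` (defaults to `length(f) - 1`).
#' @return Numeric vector `(h_0, ..., h_d)`.
#' @export
#' @examples
#' h_from_f(c(1, 3, 1))  # 1 1 -1
h_from_f <- function(f, d = length(f) - 1L) {
  if (length(f) < 1L || f[1] != 1)
    .stopf("malformed f-vector: f_{-1} must equal 1")
  h <- vapply(0:d, function(m) {
    j <- 0:m
    fj <- ifelse(j + 1L <= length(f), f[pmin(j + 1L, length(f))], 0)
    sum((-1)^(m - j) * .choose0(d - j, m - j) * fj)
  }, numeric(1))
  names(h) <- paste0("h", 0:d)
  h
}

#' f-vector from an h-vector (inverse transform)
#'
#' `f_{m-1} = sum_{i=0}^{m} C(d-i, m-i) h_i` for `m = 0, ..., d`.
#'
#' @param h Numeric vector `(h_0, ..., h_d)`; `h[1]` must be 1.
#' @param d The parameter `d = dim + 1` (defaults to `length(h) - 1`).
#' @return Numeric vector `(f_{-1}, ..., f_{d-1})`.
#' @export
#' @examples
#' f_from_h(c(1, 1, -1))  # 1 3 1
f_from_h <- function(h, d = length(h) - 1L) {
  if (length(h) < 1L || h[1] != 1)
    .stopf("malformed h-vector: h_0 must equal 1")
  f <- vapply(0:d, function(m) {
    i <- 0:m
    hi <- ifelse(i + 1L <= length(h), h[pmin(i + 1L, length(h))], 0)
    sum(.choose0(d - i, m - i) * hi)
  }, numeric(1))
  names(f) <- paste0("f", (0:d) - 1L)
  f
}

#' Persistent h-vector between two filtration levels
#'
#' `h_m(t, t') = alpha_0^m + sum_{j=1}^{m} alpha_j^m (-1)^(j-1)
#' beta_{j-1,j}(t, t')` with
#' `alpha_j^m = C(n - d + m - j - 1, m - j)`, `n` the number of points
#' and `d = dim(complex at t') + 1`.  Always has `h_0 = 1`; on the
#' diagonal `t == t2` it reproduces the classical h-vector.
#'
#' @inheritParams persistent_graded_betti
#' @return Numeric vector `(h_0, ..., h_d)`.
#' @export
persistent_h_vector <- function(points, t, t2, method = c("fast", "oracle")) {
  method <- match.arg(method)
  if (t > t2) .stopf("persistent_h_vector: need t <= t2")
  points <- .check_points(points)
  n <- length(points)
  if (n == 0L) return(c(h0 = 1))
  d <- max(.run_ends(points, t2) - seq_len(n) + 1L)  # dim(Delta^{t2}) + 1
  beta <- vapply(seq_len(d), function(j)
    persistent_graded_betti(points, t, t2, i = j - 1L, j = 1L,
                            method = method), numeric(1))
  h <- vapply(0:d, function(m) {
    val <- .choose0(n - d + m - 1L, m)  # alpha_0^m
    if (m >= 1L) {
      j <- 1:m
      alpha <- .choose0(n - d + m - j - 1L, m - j)
      val <- val + sum(alpha * (-1)^(j - 1L) * beta[j])
    }
    val
  }, numeric(1))
  names(h) <- paste0("h", 0:d)
  h
}

#' Persistent f-vector between two filtration levels
#'
#' Inverse binomial transform of [persistent_h_vector()] with the same
#' `d`.  Off-diagonal values may be non-integer or negative; they are
#' emitted as computed.
#'
#' @inheritParams persistent_h_vector
#' @return Numeric vector `(f_{-1}, ..., f_{d-1})`.
#' @export
persistent_f_vector <- function(points, t, t2, method = c("fast", "oracle")) {
  h <- persistent_h_vector(points, t, t2, method = method)
  f_from_h(h, d = length(h) - 1L)
}
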