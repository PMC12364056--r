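# Exact Vietoris-Rips machinery for 1-D point clouds.
#
# On the real line the Rips complex at scale t has simplices exactly the
# point subsets of diameter <= t (closed condition), and every facet
# (maximal simplex) is a maximal run of consecutive sorted points.  A
# facet is uniquely determined by its minimal element, which makes all
# face counting closed-form.  These fast paths are validated against the
# brute-force oracle module in the test suite.

.check_points <- function(points) {
  if (length(points) == 0L) return(numeric(0))
  if (is.unsorted(points, strictly = TRUE))
    .stopf("points must be strictly increasing (ties are not allowed)")
  as.numeric(points)
}

# Largest index j with x_j <= x_a + t, for every start a (vectorized).
.run_ends <- function(points, t) {
  findInterval(points + t, points)
}

#' Facets of the 1-D Vietoris-Rips complex at one scale
#'
#' Two points are adjacent at scale `t` iff their distance is at most
#' `t`; facets are the maximal runs of consecutive sorted points of
#' diameter at most `t`.
#'
#' @param points Strictly increasing numeric vector.
#' @param t Scale (radius), `t >= 0`.
#' @return Two-column integer matrix `(first, last)` of index intervals
#'   into `points`, in increasing order of minimal vertex.  Zero rows
#'   for empty input.
#' @export
#' @examples
#' facets_at_scale(c(1, 2, 10), 1)  # {1,2} and {10}
facets_at_scale <- function(points, t) {
  points <- .check_points(points)
  stopifnot(t >= 0)
  n <- length(points)
  if (n == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("first", "last"))))
  ends <- .run_ends(points, t)
  keep <- c(TRUE, ends[-1L] > ends[-n])
  cbind(first = which(keep), last = ends[keep])
}

#' Facet barcode of a 1-D Vietoris-Rips filtration
#'
#' Every contiguous index interval `[a, b]` of the sorted points is a
#' facet precisely for scales in the half-open interval
#' `[birth, death)`, with `birth = x_b - x_a` and
#' `death = min(x_{b+1} - x_a, x_b - x_{a-1})` (`Inf` when neither
#' neighbour exists, i.e. the full point set).  A facet is alive at its
#' birth scale and dead at its death scale.
#'
#' @param points Strictly increasing numeric vector, `n >= 1`.
#' @return A data frame with columns `first`, `last` (index interval),
#'   `dim` (simplex dimension `last - first`), `birth`, `death`,
#'   ordered by `(birth, first)`.
#' @export
#' @examples
#' facet_barcode(c(1, 2, 10))
facet_barcode <- function(points) {
  points <- .check_points(points)
  n <- length(points)
  if (n == 0L) .stopf("facet_barcode needs at least one point")
  a <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  b <- unlist(lapply(seq_len(n), function(i) i:n), use.names = FALSE)
  birth <- points[b] - points[a]
  right <- ifelse(b < n, points[pmin(b + 1L, n)] - points[a], Inf)
  left <- ifelse(a > 1L, points[b] - points[pmax(a - 1L, 1L)], Inf)
  death <- pmin(right, left)
  keep <- birth < death
  out <- data.frame(first = a[keep], last = b[keep], dim = b[keep] - a[keep],
                    birth = birth[keep], death = death[keep])
  out[order(out$birth, out$first), , drop = FALSE]
}

#' f-vector of the 1-D Vietoris-Rips complex at one scale
#'
#' `f_i` counts the `(i+1)`-subsets of diameter at most `t`.  Each such
#' subset lies in the maximal run of its minimal element, so with run
#' lengths `L_a`, `f_i = sum_a C(L_a - 1, i)` -- no subset enumeration.
#'
#' @param points Strictly increasing numeric vector.
#' @param t Scale, `t >= 0`.
#' @param dmax Optional cap: report only `f_{-1} .. f_{dmax-1}`.
#' @return Numeric vector `(f_{-1}, f_0, ..., f_{d-1})` with
#'   `f_{-1} = 1` (empty face).
#' @export
#' @examples
#' f_vector_at_scale(c(1, 2, 10), 1)  # 1 3 1
f_vector_at_scale <- function(points, t, dmax = NULL) {
  points <- .check_points(points)
  stopifnot(t >= 0)
  n <- length(points)
  if (n == 0L) return(1)
  L <- .run_ends(points, t) - seq_len(n) + 1L
  d <- max(L)  # d_t = dim + 1
  top <- if (is.null(dmax)) d else min(d, dmax)
  f <- c(1, vapply(seq_len(top), function(m) sum(.choose0(L - 1L, m - 1L)),
                   numeric(1)))
  names(f) <- paste0("f", seq_along(f) - 2L)
  f
}

#' Classical h-vector at one scale
#'
#' Binomial transform of [f_vector_at_scale()] with `d = dim + 1`.
#'
#' @inheritParams f_vector_at_scale
#' @return Numeric vector `(h_0, ..., h_d)`.
#' @export
h_vector_at_scale <- function(points, t) {
  f <- f_vector_at_scale(points, t)
  h_from_f(f, d = length(f) - 1L)
}

#' Number of connected components at one scale
#'
#' `1 +` the number of consecutive gaps exceeding `t`; 0 for an empty
#' point set.
#'
#' @inheritParams f_vector_at_scale
#' @return Integer count.
#' @export
#' @examples
#' component_count(c(1, 2, 10), 1)  # 2
component_count <- function(points, t) {
  points <- .check_points(points)
  stopifnot(t >= 0)
  n <- length(points)
  if (n == 0L) return(0L)
  1L + sum(diff(points) > t)
}

# Alive facet counts per dimension at a single scale, with dimensions
# >= dmax - 1 accumulated into the last bucket.  Fast path used by the
# featurizer; equals a census of facet_barcode intervals alive at t.
.facet_counts_at_scale <- function(points, t, dmax) {
  n <- length(points)
  out <- numeric(dmax)
  if (n == 0L) return(out)
  ends <- .run_ends(points, t)
  keep <- c(TRUE, ends[-1L] > ends[-n])
  dims <- (ends - seq_len(n))[keep]
  dims <- pmin(dims, dmax - 1L)
  tab <- tabulate(dims + 1L, nbins = dmax)
  as.numeric(tab)
}

#' Export a facet barcode as TSV
#'
#' Columns: facet-min, facet-max (point values), dim, birth, death.
#'
#' @param barcode Result of [facet_barcode()].
#' @param points The point cloud the barcode was computed from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_tsv <- function(barcode, points, path) {
  out <- data.frame(facet_min = points[barcode$first],
                    facet_max = points[barcode$last],
                    dim = barcode$dim,
                    birth = barcode$birth,
                    death = barcode$death)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
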