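# Brute-force reference implementations used to validate the
# closed-form fast paths: maximal-subset facet enumeration, GF(2)
# simplicial homology via boundary-matrix ranks, Hochster subset-sums,
# and union-find persistent component ranks.  Exponential in the number
# of vertices; a hard guard keeps them honest test fixtures.

.ORACLE_MAX_N <- 14L

.guard_n <- function(n) {
  if (n > .ORACLE_MAX_N)
    .stopf("oracle guard: %d vertices exceeds the n <= %d limit",
           n, .ORACLE_MAX_N)
}

#' Brute-force Vietoris-Rips complex on a 1-D point cloud
#'
#' Enumerates every nonempty subset of diameter at most `t`.  Test
#' oracle only; exponential in `length(points)`.
#'
#' @param points Strictly increasing numeric vector (guarded size).
#' @param t Scale, `t >= 0`.
#' @return List of integer index vectors (the simplices, all faces
#'   included), each sorted increasing.
#' @export
rips_complex_bruteforce <- function(points, t) {
  points <- .check_points(points)
  n <- length(points)
  .guard_n(n)
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (points[idx[length(idx)]] - points[idx[1L]] <= t)
      out[[length(out) + 1L]] <- idx
  }
  out
}

#' Brute-force facet enumeration
#'
#' Maximal subsets of diameter at most `t`, by filtering the full
#' subset enumeration.  Independent of the run-based fast path.
#'
#' @inheritParams rips_complex_bruteforce
#' @return List of sorted integer index vectors (the facets), ordered
#'   by minimal element.
#' @export
facets_bruteforce <- function(points, t) {
  simplices <- rips_complex_bruteforce(points, t)
  keys <- vapply(simplices, paste, character(1), collapse = ",")
  maximal <- vapply(seq_along(simplices), function(i) {
    s <- simplices[[i]]
    !any(vapply(simplices, function(o)
      length(o) > length(s) && all(s %in% o), logical(1)))
  }, logical(1))
  out <- simplices[maximal]
  out[order(vapply(out, min, numeric(1)))]
}

# Downward closure of a set of simplices (list of sorted integer
# vectors) into a deduplicated list.
.close_complex <- function(simplices) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(s) {
    key <- paste(s, collapse = ",")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <<- s
  }
  for (s in simplices) {
    m <- length(s)
    for (mask in seq_len(2^m - 1L)) {
      add(s[which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)])
    }
  }
  out
}

# GF(2) rank by Gaussian elimination; m is a 0/1 matrix.
.gf2_rank <- function(m) {
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L) return(0L)
  m <- m %% 2L
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(m))) {
    piv <- which(m[row:nrow(m), col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) m[c(row, piv), ] <- m[c(piv, row), ]
    hits <- which(m[, col] == 1L)
    hits <- hits[hits != row]
    if (length(hits) > 0L)
      m[hits, ] <- (m[hits, , drop = FALSE] +
                      matrix(m[row, ], length(hits), ncol(m),
                             byrow = TRUE)) %% 2L
    rank <- rank + 1L
    row <- row + 1L
    if (row > nrow(m)) break
  }
  rank
}

#' Reduced simplicial Betti number over GF(2)
#'
#' Dimension of the degree-`q` reduced homology of a small simplicial
#' complex, by rank-nullity on GF(2) boundary matrices (the augmented
#' chain complex, so `q = 0` counts components minus one).
#'
#' @param simplices List of sorted integer vertex vectors; closed under
#'   faces or not (the downward closure is taken).  The empty list is
#'   the void complex (all reduced Betti numbers 0 by convention here).
#' @param q Homological degree, `q >= 0`.
#' @return Integer dimension.
#' @export
#' @examples
#' hollow <- list(c(1, 2), c(2, 3), c(1, 3))
#' reduced_betti(hollow, 1)  # 1 (a circle)
reduced_betti <- function(simplices, q) {
  stopifnot(q >= 0)
  if (length(simplices) == 0L) return(0L)
  cx <- .close_complex(simplices)
  verts <- sort(unique(unlist(cx)))
  .guard_n(length(verts))
  by_dim <- split(cx, vapply(cx, length, integer(1)) - 1L)
  faces_of_dim <- function(d) {
    fs <- by_dim[[as.character(d)]]
    if (is.null(fs)) list() else fs
  }
  keyed <- function(fs) vapply(fs, paste, character(1), collapse = ",")
  # boundary matrix from dimension d faces to dimension d-1 faces (GF(2))
  boundary <- function(d) {
    hi <- faces_of_dim(d)
    if (d == 0L) {  # augmentation: every vertex maps to the empty face
      return(matrix(1L, nrow = 1L, ncol = length(hi)))
    }
    lo <- faces_of_dim(d - 1L)
    if (length(hi) == 0L)
      return(matrix(0L, nrow = max(1L, length(lo)), ncol = 0L))
    lo_idx <- setNames(seq_along(lo), keyed(lo))
    m <- matrix(0L, nrow = length(lo), ncol = length(hi))
    for (cc in seq_along(hi)) {
      s <- hi[[cc]]
      for (drop in seq_along(s))
        m[lo_idx[[paste(s[-drop], collapse = ",")]], cc] <- 1L
    }
    m
  }
  nq <- length(faces_of_dim(q))
  if (nq == 0L) return(0L)
  rank_q <- .gf2_rank(boundary(q))
  rank_q1 <- .gf2_rank(boundary(q + 1L))
  nq - rank_q - rank_q1
}

# Induced subcomplex of the 1-D Rips complex at scale t on vertex
# subset W (indices into points): all subsets of W with diameter <= t.
.induced_rips <- function(points, W, t) {
  W <- sort(W)
  m <- length(W)
  out <- list()
  for (mask in seq_len(2^m - 1L)) {
    idx <- W[which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)]
    if (points[idx[length(idx)]] - points[idx[1L]] <= t)
      out[[length(out) + 1L]] <- idx
  }
  out
}

#' Hochster subset-sum evaluation of graded Betti numbers
#'
#' Exact evaluation of `beta_{i,i+j}` of the Stanley-Reisner ring of
#' the 1-D Rips complex at scale `t`: the sum over vertex subsets `W`
#' of size `i + j` of the reduced Betti number of the induced
#' subcomplex in degree `j - 1`.  Exponential; test oracle only.
#'
#' @param points Strictly increasing numeric vector (guarded size).
#' @param t Scale.
#' @param i Homological index, `i >= 1`.
#' @param j Degree shift, `j >= 1`.
#' @return Integer.
#' @export
hochster_betti <- function(points, t, i, j) {
  points <- .check_points(points)
  stopifnot(i >= 1, j >= 1)
  n <- length(points)
  .guard_n(n)
  size <- i + j
  if (n < size) return(0L)
  subsets <- combn(n, size)
  total <- 0L
  for (cc in seq_len(ncol(subsets))) {
    sub <- .induced_rips(points, subsets[, cc], t)
    total <- total + reduced_betti(sub, j - 1L)
  }
  total
}

#' Persistent rank on reduced degree-0 homology of an induced subcomplex
#'
#' Rank of the map induced by inclusion from scale `t` to `t2` on the
#' reduced degree-0 homology of the subcomplex induced on `W`, computed
#' by union-find merge tracking: components of `W` at `t` are merged
#' into components at `t2`; the reduced rank is the number of distinct
#' images minus one.
#'
#' @param points Strictly increasing numeric vector.
#' @param W Integer indices into `points` (the vertex subset).
#' @param t,t2 Scales with `t <= t2`.
#' @return Integer rank.
#' @export
persistent_component_rank <- function(points, W, t, t2) {
  if (t > t2) .stopf("persistent_component_rank: need t <= t2")
  points <- .check_points(points)
  W <- sort(unique(as.integer(W)))
  stopifnot(all(W >= 1L), all(W <= length(points)))
  if (length(W) == 0L) return(0L)
  x <- points[W]
  comp_at <- function(s) cumsum(c(1L, diff(x) > s))  # component id per vertex
  c1 <- comp_at(t)
  c2 <- comp_at(t2)
  # image of each t-component under the merge into t2-components
  image <- unique(c2[!duplicated(c1)])
  max(0L, length(image) - 1L)
}
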