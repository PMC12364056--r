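# Weighted algebraic distances between sequence representations.
# Per feature type the distance is a weighted Euclidean metric
# d = sqrt( sum_k sum_i a_{k,i} ||v1_{k,i} - v2_{k,i}||^2 ), with the
# inner norm taken over the (kmer x radius) block of dimension i; the
# composite distance is the sum of the per-type metrics (f-curves,
# h-curves, facet curves), each term a metric, hence so is the sum.

#' Weighting scheme for the algebraic distance
#'
#' `uniform`: `a_{k,i} = 1`; `per_k`: `a_{k,i} = 1 / 2^(k-1)` (the
#' default); `per_k_dim`: `a_{k,i} = 1 / 2^(i*K + k - 1)` with `K` the
#' maximum k-mer window considered.  With a single fixed k, `per_k` is
#' a global rescaling and cannot change any nearest-neighbor ranking.
#'
#' @param name One of `"uniform"`, `"per_k"`, `"per_k_dim"`.
#' @param K Maximum k-mer window (only used by `per_k_dim`; defaults to
#'   the k the weights are evaluated at).
#' @return An object of class `cakl_weights`.
#' @export
weight_scheme <- function(name = c("per_k", "uniform", "per_k_dim"),
                          K = NULL) {
  name <- match.arg(name)
  structure(list(name = name, K = K), class = "cakl_weights")
}

# a_{k,i} for vectors of k and i
.weight_value <- function(scheme, k, i) {
  switch(scheme$name,
         uniform = rep(1, length(i)),
         per_k = rep_len(1 / 2^(k - 1), length(i)),
         per_k_dim = {
           K <- if (is.null(scheme$K)) max(k) else scheme$K
           1 / 2^(i * K + k - 1)
         })
}

#' Weighted algebraic distance between two representation vectors
#'
#' @param v1,v2 Representation vectors from [sequence_representation()]
#'   built under the same configuration.
#' @param config The shared [feature_config()].
#' @param scheme A [weight_scheme()].
#' @param k K-mer length of the representations (defaults to
#'   `config$k`).
#' @param sqrt_total Apply the final square root (default `TRUE`; the
#'   rooted form is the metric, the unrooted form is the plain weighted
#'   sum of squares).
#' @return Nonnegative real; 0 iff the vectors coincide.
#' @export
weighted_distance <- function(v1, v2, config, scheme = weight_scheme(),
                              k = config$k, sqrt_total = TRUE) {
  if (length(v1) != length(v2))
    .stopf("representation layouts differ: lengths %d vs %d",
           length(v1), length(v2))
  map <- feature_index_map(config)
  if (nrow(map) != length(v1))
    .stopf("representation length %d does not match config layout %d",
           length(v1), nrow(map))
  w <- .weight_value(scheme, k, map$dim)
  total <- sum(w * (v1 - v2)^2)
  if (sqrt_total) sqrt(total) else total
}

#' Composite algebraic distance across feature types
#'
#' Sum of the per-type weighted distances over the feature types
#' present in the configuration (f-vector curves, h-vector curves,
#' facet-count curves).  With only facet curves enabled this is the
#' facet-curve distance alone.
#'
#' @inheritParams weighted_distance
#' @return Nonnegative real.
#' @export
composite_distance <- function(v1, v2, config, scheme = weight_scheme(),
                               k = config$k) {
  if (length(v1) != length(v2))
    .stopf("representation layouts differ: lengths %d vs %d",
           length(v1), length(v2))
  map <- feature_index_map(config)
  if (nrow(map) != length(v1))
    .stopf("representation length %d does not match config layout %d",
           length(v1), nrow(map))
  total <- 0
  for (ty in config$feature_types) {
    at <- map$type == ty
    w <- .weight_value(scheme, k, map$dim[at])
    total <- total + sqrt(sum(w * (v1[at] - v2[at])^2))
  }
  total
}

#' Pairwise composite distance matrix
#'
#' @param features A `cakl_features` object ([cakl_featurize()]) with
#'   at least two sequences.
#' @param scheme A [weight_scheme()].
#' @return Symmetric numeric matrix with zero diagonal; dimnames are
#'   the sequence ids.
#' @export
cakl_distance_matrix <- function(features, scheme = weight_scheme()) {
  stopifnot(inherits(features, "cakl_features"))
  x <- features$x
  if (nrow(x) < 2L) .stopf("need at least 2 sequences for a distance matrix")
  map <- features$map
  k <- features$config$k
  n <- nrow(x)
  D <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (ty in features$config$feature_types) {
    at <- map$type == ty
    w <- .weight_value(scheme, k, map$dim[at])
    scaled <- x[, at, drop = FALSE] *
      matrix(sqrt(w), n, sum(at), byrow = TRUE)
    D <- D + as.matrix(dist(scaled))
  }
  D
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param D Symmetric matrix with id dimnames.
#' @param path Output path.
#' @param format `"tsv"` (square, with header ids) or `"phylip"`
#'   (square PHYLIP).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- cbind(id = rownames(D), as.data.frame(D))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D)))
      writeLines(paste(c(formatC(rownames(D)[i], width = -10),
                         format(D[i, ], digits = 10)), collapse = " "), con)
  }
  invisible(path)
}

#' Read a square TSV distance matrix written by [write_distance_matrix()]
#'
#' @param path Input path.
#' @return Symmetric numeric matrix with id dimnames.
#' @export
read_distance_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  D <- as.matrix(tab[, -1, drop = FALSE])
  mode(D) <- "numeric"
  dimnames(D) <- list(ids, ids)
  D
}
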