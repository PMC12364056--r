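# Assembly of per-k-mer invariant curves into the fixed-length
# algebraic representation of a sequence.  Layout: k-mers in
# enumerate_kmers() order, then feature type, then dimension row, then
# grid radius (dimension-major within a type block).  The layout is a
# function of the configuration alone, so representations built under
# one configuration are always comparable coordinate-by-coordinate.

#' Featurization configuration
#'
#' Collects every parameter that fixes the representation layout.
#' Curves are sampled on the diagonal `r = r'` of the filtration.
#'
#' @param k K-mer length (default 4, the value used for classification
#'   tasks).
#' @param alphabet Ordered alphabet (default DNA).
#' @param r_max Largest filtration radius of the sampling grid.
#' @param r_step Grid step (integer radii by default: occurrence
#'   positions are integers, so every birth/death value is an integer).
#' @param dmax Number of dimension rows per curve; facets of dimension
#'   `>= dmax - 1` fall into the last (overflow) row.
#' @param feature_types Subset of `c("facet", "fvec", "hvec")`; the
#'   facet-count curves are the production default.
#' @param normalize Divide curves by the number of k-mer windows
#'   (`N - k + 1`); off by default (raw counts).
#' @return An object of class `cakl_config`.
#' @export
feature_config <- function(k = 4L, alphabet = c("A", "C", "G", "T"),
                           r_max = 50, r_step = 1, dmax = 5L,
                           feature_types = "facet", normalize = FALSE) {
  stopifnot(k >= 1, dmax >= 1, r_max >= 0, r_step > 0,
            length(feature_types) >= 1,
            all(feature_types %in% c("facet", "fvec", "hvec")),
            !anyDuplicated(feature_types))
  grid <- seq(0, r_max, by = r_step)
  structure(list(k = as.integer(k), alphabet = alphabet, grid = grid,
                 dmax = as.integer(dmax), feature_types = feature_types,
                 normalize = isTRUE(normalize)),
            class = "cakl_config")
}

#' @export
print.cakl_config <- function(x, ...) {
  cat(sprintf(
    "cakl feature config: k=%d, |alphabet|=%d, grid [%g, %g] step %g,",
    x$k, length(x$alphabet), min(x$grid), max(x$grid),
    if (length(x$grid) > 1) x$grid[2] - x$grid[1] else 0),
    sprintf("dmax=%d, types={%s}, normalize=%s\n",
            x$dmax, paste(x$feature_types, collapse = ","), x$normalize))
  invisible(x)
}

# Short fingerprint of a config, embedded in exports so that stages of
# a pipeline can refuse mismatched inputs.
.config_fingerprint <- function(config) {
  paste(config$k, paste(config$alphabet, collapse = ""),
        min(config$grid), max(config$grid), length(config$grid),
        config$dmax, paste(config$feature_types, collapse = "+"),
        config$normalize, sep = "|")
}

# Curve block for one feature type on one position set: a
# dmax x |grid| matrix.
.type_block <- function(positions, type, config) {
  grid <- config$grid
  dmax <- config$dmax
  if (length(positions) == 0L)
    return(matrix(0, dmax, length(grid)))
  if (type == "facet") {
    m <- vapply(grid, function(t)
      .facet_counts_at_scale(positions, t, dmax), numeric(dmax))
    return(matrix(m, dmax, length(grid)))
  }
  m <- matrix(0, dmax, length(grid))
  for (r in seq_along(grid)) {
    f <- f_vector_at_scale(positions, grid[r])
    v <- if (type == "fvec") f[-1L] else h_from_f(f, d = length(f) - 1L)
    ln <- min(length(v), dmax)
    m[seq_len(ln), r] <- v[seq_len(ln)]
  }
  m
}

#' Feature block for one k-mer position set
#'
#' Concatenates, per feature type in configuration order, the
#' dimension-major flattening of the type's curve matrix (dimension
#' rows, then grid radii).  For `"fvec"`/`"hvec"` the entries are
#' `f_0 .. f_{dmax-1}` resp. `h_0 .. h_{dmax-1}` per radius,
#' zero-padded.  An empty position set yields an all-zero block.
#'
#' @param positions Sorted integer occurrence positions (may be empty).
#' @param config A [feature_config()].
#' @return Numeric vector of length
#'   `length(feature_types) * dmax * length(grid)`.
#' @export
kmer_feature_vector <- function(positions, config) {
  blocks <- lapply(config$feature_types, function(ty)
    as.vector(t(.type_block(positions, ty, config))))
  unlist(blocks, use.names = FALSE)
}

#' Algebraic representation of one sequence
#'
#' The concatenation of [kmer_feature_vector()] blocks over all k-mers
#' in [enumerate_kmers()] order.  Depends only on the pairwise gaps of
#' each k-mer's occurrence positions, hence is invariant under global
#' translation of the sequence.
#'
#' @param seq Normalized sequence string.
#' @param config A [feature_config()].
#' @return Numeric vector of length
#'   `|alphabet|^k * length(feature_types) * dmax * length(grid)`.
#' @export
sequence_representation <- function(seq, config) {
  kmers <- enumerate_kmers(config$k, config$alphabet)
  pos <- .all_kmer_positions(seq, config$k, config$alphabet)
  block_len <- length(config$feature_types) * config$dmax *
    length(config$grid)
  out <- numeric(length(kmers) * block_len)
  scale <- 1
  if (config$normalize) {
    nwin <- nchar(seq) - config$k + 1L
    scale <- if (nwin > 0L) 1 / nwin else 1
  }
  for (x in names(pos)) {
    at <- match(x, kmers)
    out[(at - 1L) * block_len + seq_len(block_len)] <-
      kmer_feature_vector(pos[[x]], config) * scale
  }
  out
}

#' Index map of the representation layout
#'
#' One row per coordinate of [sequence_representation()], naming the
#' `(kmer, type, dim, radius)` it holds.
#'
#' @param config A [feature_config()].
#' @return Data frame with columns `kmer`, `type`, `dim`, `radius`.
#' @export
feature_index_map <- function(config) {
  kmers <- enumerate_kmers(config$k, config$alphabet)
  data.frame(
    kmer = rep(kmers, each = length(config$feature_types) *
                 config$dmax * length(config$grid)),
    type = rep(rep(config$feature_types,
                   each = config$dmax * length(config$grid)),
               times = length(kmers)),
    dim = rep(rep(seq_len(config$dmax) - 1L, each = length(config$grid)),
              times = length(kmers) * length(config$feature_types)),
    radius = rep(config$grid, times = length(kmers) *
                   length(config$feature_types) * config$dmax))
}

#' Featurize a set of sequences
#'
#' @param seqs Named character vector of normalized sequences (as from
#'   [read_fasta()]).
#' @param config A [feature_config()].
#' @return An object of class `cakl_features`: list with `x` (matrix,
#'   one row per sequence), `map` (the [feature_index_map()]), and
#'   `config`.
#' @export
cakl_featurize <- function(seqs, config = feature_config()) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  x <- t(vapply(seqs, sequence_representation, config = config,
                FUN.VALUE = numeric(length(config$alphabet)^config$k *
                                      length(config$feature_types) *
                                      config$dmax * length(config$grid))))
  rownames(x) <- names(seqs)
  structure(list(x = x, map = feature_index_map(config), config = config),
            class = "cakl_features")
}

#' @export
print.cakl_features <- function(x, ...) {
  cat(sprintf("cakl features: %d sequences x %d coordinates\n",
              nrow(x$x), ncol(x$x)))
  print(x$config)
  invisible(x)
}

#' Export a feature matrix as TSV
#'
#' Header columns are named `kmer.type.dim.radius`; a sidecar
#' `<path>.meta` records the configuration fingerprint.
#'
#' @param features A `cakl_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  cols <- with(features$map, paste(kmer, type, dim, radius, sep = "."))
  tab <- as.data.frame(features$x)
  names(tab) <- cols
  tab <- cbind(id = rownames(features$x), tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("fingerprint\t", .config_fingerprint(features$config)),
               paste0("k\t", features$config$k),
               paste0("dmax\t", features$config$dmax),
               paste0("types\t",
                      paste(features$config$feature_types, collapse = ","))),
             paste0(path, ".meta"))
  invisible(path)
}
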