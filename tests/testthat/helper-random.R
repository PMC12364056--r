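# Shared generators for property-style tests.

# Random strictly increasing integer point cloud with n points drawn
# from 1..span.
random_points <- function(n, span = 40L) {
  sort(sample.int(span, n))
}

# Random valid f-vector: the classical f-vector of a random 1-D Rips
# complex at a random scale (guarantees validity without constructing
# one by hand).
random_f_vector <- function(nmax = 8L) {
  pts <- random_points(sample(2:nmax, 1))
  t <- sample(0:(max(pts) - min(pts)), 1)
  f_vector_at_scale(pts, t)
}

# Random DNA sequence.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Facet index intervals as a canonical list of sorted vectors, for
# comparison against the brute-force facet enumeration.
intervals_as_sets <- function(mat) {
  lapply(seq_len(nrow(mat)), function(i) mat[i, 1]:mat[i, 2])
}
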