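# UPGMA tree inference and monophyly purity scoring.
#
# UPGMA is implemented directly so the tie rule is fully specified:
# among pairs at the minimal distance, the pair whose (sorted) cluster
# ids -- each cluster identified by its lexicographically smallest leaf
# -- is smallest is merged first.  The result is returned as an ape
# "phylo" object and cross-checked against average-linkage clustering
# in the test suite.

#' UPGMA tree from a distance matrix
#'
#' Iteratively merges the closest pair of clusters under size-weighted
#' arithmetic-average linkage; the merge node sits at height
#' `distance / 2`, giving an ultrametric rooted tree.
#'
#' @param D Symmetric nonnegative matrix with zero diagonal and id
#'   dimnames, `n >= 2`.
#' @return A rooted ultrametric tree of class `phylo` (ape).
#' @export
#' @examples
#' D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' ape::write.tree(upgma(D))  # ((a:1,b:1):3,c:4);
upgma <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D)
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (nrow(D) < 2L) .stopf("UPGMA needs at least 2 leaves")
  if (any(is.na(D)) || any(!is.finite(D)))
    .stopf("distance matrix contains NA/NaN/Inf entries")
  if (any(D < 0)) .stopf("distance matrix contains negative entries")
  if (max(abs(D - t(D))) > 1e-9) .stopf("distance matrix is not symmetric")
  ids <- rownames(D)
  n <- nrow(D)
  active <- seq_len(n)
  size <- rep(1L, n)
  height <- rep(0, n)
  newick <- ids
  minlab <- ids  # lexicographic tie key of each cluster
  W <- D
  while (length(active) > 1L) {
    # locate the minimal off-diagonal distance among active clusters
    sub <- W[active, active, drop = FALSE]
    diag(sub) <- Inf
    mval <- min(sub)
    hits <- which(sub - mval <= 0, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    key1 <- pmin(minlab[active[hits[, 1]]], minlab[active[hits[, 2]]])
    key2 <- pmax(minlab[active[hits[, 1]]], minlab[active[hits[, 2]]])
    pick <- order(key1, key2)[1L]
    i <- active[hits[pick, 1]]
    j <- active[hits[pick, 2]]
    if (minlab[j] < minlab[i]) { tmp <- i; i <- j; j <- tmp }
    h <- mval / 2
    # new cluster reuses slot i
    newick_i <- sprintf("(%s:%.12g,%s:%.12g)",
                        newick[i], h - height[i], newick[j], h - height[j])
    merged_size <- size[i] + size[j]
    rest <- setdiff(active, c(i, j))
    if (length(rest) > 0L) {
      upd <- (size[i] * W[i, rest] + size[j] * W[j, rest]) / merged_size
      W[i, rest] <- upd
      W[rest, i] <- upd
    }
    newick[i] <- newick_i
    size[i] <- merged_size
    height[i] <- h
    minlab[i] <- min(minlab[i], minlab[j])
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

#' Serialize a tree to a Newick string
#'
#' Branch lengths included, terminated by `';'`; leaf names needing
#' quoting are quoted.
#'
#' @param tree A `phylo` object.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Purity of a partition
#'
#' For a partition of `n` elements into blocks of the given sizes,
#' `purity = sum (|S_i| / n)^2`: 1 for a single block, `1/n` for all
#' singletons, strictly below 1 for any finite split.
#'
#' @param block_sizes Positive integer block sizes.
#' @param n Total number of elements; must equal `sum(block_sizes)`.
#' @return Purity in `(0, 1]`.
#' @export
#' @examples
#' partition_purity(c(9, 1), 10)  # 0.82
partition_purity <- function(block_sizes, n = sum(block_sizes)) {
  if (length(block_sizes) == 0L || any(block_sizes <= 0))
    .stopf("block sizes must be positive")
  if (sum(block_sizes) != n)
    .stopf("block sizes sum to %d, not n = %d", sum(block_sizes), n)
  sum((block_sizes / n)^2)
}

# Per-node leaf census on a rooted phylo tree: for every node, the
# number of descendant tips and the number carrying each label.
.node_label_counts <- function(tree, labels) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  missing <- setdiff(tree$tip.label, names(labels))
  if (length(missing) > 0L)
    .stopf("unlabeled leaf/leaves: %s", paste(missing, collapse = ", "))
  lv <- unique(unname(labels[tree$tip.label]))
  counts <- matrix(0L, nnode, length(lv), dimnames = list(NULL, lv))
  counts[cbind(seq_len(ntip), match(labels[tree$tip.label], lv))] <- 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    counts[parent, ] <- counts[parent, ] + counts[child, ]
  }
  counts
}

#' Purity of one label on a rooted tree
#'
#' Marks each node pure iff all descendant leaves carry `label`; the
#' maximal pure nodes (pure nodes whose parent is absent or not pure)
#' partition the label's leaves into blocks, and the purity of that
#' partition is returned.  1 means the label is monophyletic.
#'
#' @param tree Rooted `phylo` tree.
#' @param labels Named character vector mapping every tip label to a
#'   class.
#' @param label The class to score.
#' @return List with `purity`, `blocks` (block sizes) and `n` (leaves
#'   with the label).
#' @export
label_purity <- function(tree, labels, label) {
  counts <- .node_label_counts(tree, labels)
  if (!label %in% colnames(counts))
    .stopf("label '%s' absent from the tree", label)
  total <- rowSums(counts)
  pure <- counts[, label] == total & total > 0L
  parent <- rep(NA_integer_, nrow(counts))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  maximal <- pure & (is.na(parent) | !pure[ifelse(is.na(parent), 1L, parent)])
  blocks <- total[maximal]
  n <- sum(counts[seq_along(tree$tip.label), label])
  list(purity = partition_purity(blocks, n), blocks = unname(blocks), n = n)
}

#' Average purity across all labels
#'
#' Unweighted mean of [label_purity()] over the distinct labels.
#'
#' @inheritParams label_purity
#' @return Object of class `cakl_purity`: list with `per_label`
#'   (data frame: label, n, num_blocks, purity) and `average`.
#' @export
avg_purity <- function(tree, labels) {
  lv <- sort(unique(unname(labels[tree$tip.label])))
  rows <- lapply(lv, function(l) {
    p <- label_purity(tree, labels, l)
    data.frame(label = l, n = p$n, num_blocks = length(p$blocks),
               purity = p$purity)
  })
  per_label <- do.call(rbind, rows)
  structure(list(per_label = per_label,
                 average = mean(per_label$purity)),
            class = "cakl_purity")
}

#' @export
print.cakl_purity <- function(x, ...) {
  print(x$per_label, row.names = FALSE)
  cat(sprintf("average purity: %.6g over %d labels\n",
              x$average, nrow(x$per_label)))
  invisible(x)
}

#' Write a purity report as TSV
#'
#' One row per label plus a trailing summary line.
#'
#' @param purity A `cakl_purity` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_purity_tsv <- function(purity, path) {
  write.table(purity$per_label, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("# average_purity\t%.10g\n", purity$average),
      file = path, append = TRUE)
  invisible(path)
}
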