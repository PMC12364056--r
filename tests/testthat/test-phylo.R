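make_D <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  m
}

test_that("upgma reproduces the hand-computed 3-leaf tree", {
  D <- make_D(matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3), c("a", "b", "c"))
  tree <- upgma(D)
  expect_identical(write_newick(tree), "((a:1,b:1):3,c:4);")
  # 2 leaves at distance d -> two branches of d/2
  D2 <- make_D(matrix(c(0, 5, 5, 0), 2, 2), c("x", "y"))
  expect_identical(write_newick(upgma(D2)), "(x:2.5,y:2.5);")
  expect_error(upgma(make_D(matrix(c(0, NA, NA, 0), 2, 2), c("x", "y"))),
               "NA")
  expect_error(upgma(make_D(matrix(c(0, -1, -1, 0), 2, 2), c("x", "y"))),
               "negative")
})

test_that("equal distances collapse deterministically via the id tie rule", {
  ids <- c("d", "b", "c", "a")
  D <- make_D(matrix(4, 4, 4) - diag(4, 4), ids)
  t1 <- upgma(D)
  t2 <- upgma(D[rev(ids), rev(ids)])
  expect_identical(write_newick(t1), write_newick(t2))
  # all heights equal: every leaf sits at depth distance/2
  depths <- ape::node.depth.edgelength(t1)[seq_along(ids)]
  expect_equal(depths, rep(2, 4))
  # first merge joins the lexicographically smallest pair, a and b
  expect_true(grepl("(a:2,b:2)", write_newick(t1), fixed = TRUE))
})

test_that("upgma agrees with average-linkage clustering on random input", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 3), n)
    D <- as.matrix(dist(pts))  # generic: ties have probability zero
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    ours <- upgma(D)
    ref <- phangorn::upgma(as.dist(D))
    expect_equal(ape::cophenetic.phylo(ours)[rownames(D), rownames(D)],
                 ape::cophenetic.phylo(ref)[rownames(D), rownames(D)],
                 tolerance = 1e-8)
  }
})

test_that("upgma trees are ultrametric and round-trip through Newick", {
  set.seed(72)
  fam <- simulate_families(n_families = 2, per_family = 4, length = 150,
                           substitution_rate = 0.05, seed = 72)
  feats <- cakl_featurize(fam$seqs, feature_config(k = 1, r_max = 20))
  tree <- upgma(cakl_distance_matrix(feats))
  expect_true(ape::is.ultrametric(tree, tol = 1e-9))
  back <- ape::read.tree(text = write_newick(tree))
  expect_identical(sort(back$tip.label), sort(tree$tip.label))
  ids <- sort(tree$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[ids, ids],
               ape::cophenetic.phylo(tree)[ids, ids], tolerance = 1e-9)
})

test_that("partition_purity matches the closed-form extremes", {
  n <- 10
  expect_equal(partition_purity(n, n), 1)
  expect_equal(partition_purity(rep(1, n), n), 1 / n)
  expect_equal(partition_purity(c(9, 1), 10), 0.82)
  expect_equal(partition_purity(c(9, 1), 10), 1 - 2 * (n - 1) / n^2)
  expect_lt(partition_purity(c(9, 1), 10), 1)
  expect_equal(partition_purity(c(5, 5), 10), 0.5)
  expect_error(partition_purity(c(3, 3), 10), "sum")
  expect_error(partition_purity(integer(0), 0), "positive")
})

test_that("label_purity finds maximal pure subtrees", {
  # monophyletic label -> purity 1
  tree <- ape::read.tree(text = "(((a1:1,a2:1):1,(a3:1,a4:1):1):1,(b1:1,b2:1):2);")
  labels <- c(a1 = "A", a2 = "A", a3 = "A", a4 = "A", b1 = "B", b2 = "B")
  pa <- label_purity(tree, labels, "A")
  expect_equal(pa$purity, 1)
  expect_equal(pa$blocks, 4)
  # caterpillar A,A,B,A: blocks {A,A} and {A} -> 5/9
  cat_tree <- ape::read.tree(text = "(((x1:1,x2:1):1,x3:2):1,x4:3);")
  cat_labels <- c(x1 = "A", x2 = "A", x3 = "B", x4 = "A")
  pc <- label_purity(cat_tree, cat_labels, "A")
  expect_equal(pc$purity, (2 / 3)^2 + (1 / 3)^2)
  expect_setequal(pc$blocks, c(2, 1))
  # fully interleaved label -> all singleton blocks, purity 1/n
  alt <- ape::read.tree(text = "(((y1:1,z1:1):1,(y2:1,z2:1):1):1,(y3:1,z3:1):2);")
  alt_labels <- setNames(rep(c("Y", "Z"), 3),
                         c("y1", "z1", "y2", "z2", "y3", "z3"))
  expect_equal(label_purity(alt, alt_labels, "Y")$purity, 1 / 3)
  expect_error(label_purity(tree, labels[-1], "A"), "a1")
  expect_error(label_purity(tree, labels, "Q"), "absent")
})

test_that("avg_purity averages unweighted across labels", {
  # one monophyletic label, one split into equal halves -> mean 0.75
  tree <- ape::read.tree(
    text = "(((m1:1,m2:1):1,(s1:1,s2:1):1):1,((s3:1,s4:1):1,(m3:1,m4:1):1):1);")
  labels <- c(m1 = "M", m2 = "M", s1 = "S", s2 = "S",
              s3 = "S", s4 = "S", m3 = "X", m4 = "X")
  p <- avg_purity(tree, labels)
  expect_equal(p$per_label$purity[p$per_label$label == "M"], 1)
  expect_equal(p$per_label$purity[p$per_label$label == "S"], 0.5)
  expect_equal(p$per_label$purity[p$per_label$label == "X"], 1)
  expect_equal(p$average, mean(c(1, 0.5, 1)))
  # single label on all leaves -> 1
  one <- setNames(rep("L", 8), names(labels))
  expect_equal(avg_purity(tree, one)$average, 1)
  # report writer emits one row per label plus a summary line
  path <- withr::local_tempfile(fileext = ".tsv")
  write_purity_tsv(p, path)
  lines <- readLines(path)
  expect_length(lines, 1 + 3 + 1)
  expect_match(lines[5], "average_purity")
})
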