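additive4 <- function() {
  labs <- c("A", "B", "C", "D")
  matrix(c(0, 3, 5, 6,
           3, 0, 6, 7,
           5, 6, 0, 7,
           6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
}

test_that("nj_build reproduces the additive 4-taxon tree exactly", {
  tr <- nj_build(additive4())
  expect_identical(split_keys(tr), "C|D")  # AB|CD topology
  # pendant edges A:1 B:2 C:3 D:4, internal 1
  co <- ape::cophenetic.phylo(tr)
  expect_equal(unname(co[c("A", "B", "C", "D"), c("A", "B", "C", "D")]),
               unname(additive4()), tolerance = 1e-12)
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(1, 1, 2, 3, 4), tolerance = 1e-12)
})

test_that("nj_build handles the small and degenerate contracts", {
  # 3 taxa: unique star topology, three-point formulas
  labs <- c("x", "y", "z")
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3, dimnames = list(labs, labs))
  tr3 <- nj_build(d3)
  expect_equal(ape::Ntip(tr3), 3L)
  co <- ape::cophenetic.phylo(tr3)
  expect_equal(unname(co[labs, labs]), unname(d3), tolerance = 1e-12)

  # all-zero matrix: some tree, all edge lengths 0
  labs5 <- letters[1:5]
  d0 <- matrix(0, 5, 5, dimnames = list(labs5, labs5))
  tr0 <- nj_build(d0)
  expect_setequal(tr0$tip.label, labs5)
  expect_true(all(tr0$edge.length == 0))

  # n = 2: single-edge tree with a warning
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(tr2 <- nj_build(d2), "2 labels")
  expect_equal(ape::cophenetic.phylo(tr2)["a", "b"], 4)

  # undefined entries are fatal and name the pair
  dna <- additive4(); dna["A", "B"] <- dna["B", "A"] <- NA
  err <- expect_error(nj_build(dna), class = "undefined_distance_error")
  expect_match(conditionMessage(err), "A / B")
})

test_that("nj_build is consistent on additive inputs and matches ape::nj", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    tr <- ape::unroot(tr)
    D <- ape::cophenetic.phylo(tr)
    out <- nj_build(D)
    expect_identical(split_keys(out), split_keys(tr))
    co <- ape::cophenetic.phylo(out)
    expect_lt(max(abs(co[rownames(D), colnames(D)] - D)), 1e-9)
    # independent oracle on the same matrix
    expect_identical(split_keys(out), split_keys(ape::nj(D)))
  }
})

two_cluster_lib <- function() {
  # two clusters of 4, separated by 20 diagnostic transition columns
  base <- strrep("ACGT", 30)                       # 120 bp backbone
  block_a <- strrep("A", 20); block_b <- strrep("G", 20)
  mutate1 <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  cl_a <- vapply(1:4, function(i) mutate1(paste0(base, block_a), i, "T"), character(1))
  cl_b <- vapply(1:4, function(i) mutate1(paste0(base, block_b), i + 8, "T"), character(1))
  make_lib(rep(c("S a", "S b"), each = 4), c(cl_a, cl_b),
           ids = sprintf("t%02d", 1:8))
}

test_that("bootstrap_support recovers a clean central split at 100%", {
  lib <- two_cluster_lib()
  tr <- bootstrap_support(lib, replicates = 100, seed = 5, min_overlap = 50)
  keys <- barcodeaudit:::tree_splits(tr)
  central <- paste(sort(sprintf("t%02d", 5:8)), collapse = "|")
  expect_true(central %in% keys)
  sup <- as.numeric(tr$node.label[match(central, keys)])
  expect_equal(sup, 100)
  sups <- suppressWarnings(as.numeric(tr$node.label))
  sups <- sups[!is.na(sups)]
  expect_true(all(sups >= 0 & sups <= 100))
})

test_that("bootstrap supports are deterministic and label-order invariant", {
  lib <- two_cluster_lib()
  t1 <- bootstrap_support(lib, replicates = 25, seed = 9, min_overlap = 50)
  t2 <- bootstrap_support(lib, replicates = 25, seed = 9, min_overlap = 50)
  expect_identical(t1$node.label, t2$node.label)

  rev_lib <- subset_library(lib, rev(lib$records$specimen_id))
  rev_lib$records <- rev_lib$records[rev(seq_len(nrow(rev_lib$records))), ]
  t3 <- bootstrap_support(rev_lib, replicates = 25, seed = 9, min_overlap = 50)
  m1 <- stats::setNames(t1$node.label, barcodeaudit:::tree_splits(t1))
  m3 <- stats::setNames(t3$node.label, barcodeaudit:::tree_splits(t3))
  shared <- intersect(names(m1)[!is.na(names(m1))], names(m3)[!is.na(names(m3))])
  expect_identical(m1[shared], m3[shared])

  # replicates = 1: supports are 0 or 100 only
  tr1 <- bootstrap_support(lib, replicates = 1, seed = 2, min_overlap = 50)
  sups <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sups[!is.na(sups)] %in% c(0, 100)))
})

test_that("midpoint_root places the root at half the diameter", {
  cherry <- ape::read.tree(text = "(a:1,b:3);")
  r <- midpoint_root(cherry)
  D <- ape::dist.nodes(r)
  root <- length(r$tip.label) + 1L
  expect_equal(D[root, which(r$tip.label == "b")], 2.0)
  expect_equal(D[root, which(r$tip.label == "a")], 2.0)

  tr <- nj_build(additive4())
  r4 <- midpoint_root(tr)
  D4 <- ape::dist.nodes(r4)
  root4 <- length(r4$tip.label) + 1L
  expect_equal(D4[root4, which(r4$tip.label == "B")], 3.5)
  expect_equal(D4[root4, which(r4$tip.label == "D")], 3.5)

  # symmetric quartet: root lands on the central edge
  sym <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rs <- midpoint_root(sym)
  ks <- split_keys(rs)
  expect_true(any(vapply(ks, function(k) k %in% c("c|d", "a|b"), logical(1))))
  Ds <- ape::dist.nodes(rs)
  roots <- length(rs$tip.label) + 1L
  expect_equal(unname(Ds[roots, 1:4]), rep(2, 4))
})

test_that("midpoint rooting preserves bipartitions and warns on zero trees", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::unroot(ape::rtree(10))
    r <- midpoint_root(tr)
    expect_identical(split_keys(r), split_keys(tr))
  }
  z <- ape::read.tree(text = "((a:0,b:0):0,c:0,d:0);")
  expect_warning(rz <- midpoint_root(z), "zero")
  expect_true(ape::is.rooted(rz))
})
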