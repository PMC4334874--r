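additive_4taxon <- function() {
  # tree ((A:1,B:2):1,(C:3,D:4)) scaled into [0,1]
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- 3; m["A", "C"] <- 5; m["A", "D"] <- 6
  m["B", "C"] <- 6; m["B", "D"] <- 7; m["C", "D"] <- 7
  m <- (m + t(m)) / 10
  m
}

test_that("NJ recovers topology and branch lengths on additive input", {
  m <- additive_4taxon()
  tree <- build_tree(m)
  expect_s3_class(tree, "phylo")
  bp <- tree_bipartitions(tree)
  expect_equal(length(bp), 1)
  expect_equal(bp[[1]], c("C", "D")) # canonical side: the one without "A"
  # path lengths reproduce the input exactly (NJ is exact on additive data)
  paths <- as.matrix(ape::cophenetic.phylo(tree))[rownames(m), colnames(m)]
  expect_equal(paths, m, tolerance = 1e-10)
  expect_true(all(tree$edge.length >= 0))
  expect_error(build_tree(m[1:2, 1:2]), "at least 3")
})

test_that("NJ matches exhaustive 4-taxon least squares on noisy-additive data", {
  # the three unrooted 4-taxon topologies, fitted by ordinary least squares
  ls_topology <- function(m) {
    labs <- rownames(m)
    combos <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    resid <- vapply(combos, function(cb) {
      X <- matrix(0, nrow(pairs), 5)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        for (tx in c(i, j)) X[r, which(cb == tx)] <- 1
        if ((i %in% cb[1:2]) != (j %in% cb[1:2])) X[r, 5] <- 1
      }
      sum(lm.fit(X, m[pairs])$residuals^2)
    }, numeric(1))
    cb <- combos[[which.min(resid)]]
    sort(labs[cb[1:2]])
  }
  canon <- function(s, labs)
    if (labs[1] %in% s) sort(setdiff(labs, s)) else sort(s)
  withr::local_seed(60)
  hits <- 0; n_trials <- 50
  for (t in seq_len(n_trials)) {
    tr0 <- ape::rtree(4, br = function(k) runif(k, 0.05, 0.5))
    m0 <- as.matrix(ape::cophenetic.phylo(tr0))
    labs <- sort(rownames(m0)); m0 <- m0[labs, labs]
    noise <- matrix(0, 4, 4)
    noise[upper.tri(noise)] <- runif(6, -0.02, 0.02)
    m <- pmax(m0 + noise + t(noise), 0); diag(m) <- 0
    m <- m / max(m) * 0.9
    dimnames(m) <- list(labs, labs)
    bp <- tree_bipartitions(build_tree(m))
    if (length(bp) == 1 &&
        identical(canon(bp[[1]], labs), canon(ls_topology(m), labs)))
      hits <- hits + 1
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("on ultrametric input NJ bipartitions equal the dendrogram's", {
  withr::local_seed(61)
  x <- matrix(rnorm(16), 8)
  hc <- hclust(dist(x), method = "single")
  m <- as.matrix(cophenetic(hc))
  m <- m / max(m) / 2
  labs <- sprintf("t%d", 1:8)
  dimnames(m) <- list(labs, labs)
  hc$labels <- labs
  nj_bp <- tree_bipartitions(build_tree(m))
  dend_bp <- tree_bipartitions(ape::as.phylo(hc))
  expect_true(setequal(nj_bp, dend_bp))
})

test_that("BME+NNI and NJ agree on near-additive input", {
  withr::local_seed(62)
  for (t in 1:5) {
    tr0 <- ape::rtree(6, br = function(k) runif(k, 0.05, 0.4))
    m0 <- as.matrix(ape::cophenetic.phylo(tr0))
    labs <- sort(rownames(m0)); m0 <- m0[labs, labs]
    noise <- matrix(0, 6, 6)
    noise[upper.tri(noise)] <- runif(15, -0.01, 0.01)
    m <- pmax(m0 + noise + t(noise), 0); diag(m) <- 0
    m <- m / max(m) * 0.9
    dimnames(m) <- list(labs, labs)
    expect_true(setequal(tree_bipartitions(build_tree(m, "bme")),
                         tree_bipartitions(build_tree(m, "nj"))))
  }
})

test_that("outgroup rooting places the root on the separating branch", {
  m <- additive_4taxon()
  tree <- build_tree(m)
  rt <- root_with_outgroup(tree, "D")
  expect_true(ape::is.rooted(rt))
  expect_true(is_monophyletic(rt, c("A", "B", "C")))
  rt2 <- root_with_outgroup(tree, c("C", "D"))
  expect_true(is_monophyletic(rt2, c("A", "B")))
  expect_true(is_monophyletic(rt2, c("C", "D")))
  expect_error(root_with_outgroup(tree, LETTERS[1:4]), "proper")
  expect_error(root_with_outgroup(tree, "Z"), "unknown")
  # {A, C} spans the internal branch: not a clade
  expect_error(root_with_outgroup(tree, c("A", "C")), "not monophyletic")
})

test_that("monophyly testing is exact on known topologies", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tree, c("A", "B")))
  expect_true(is_monophyletic(tree, c("C", "D")))
  expect_false(is_monophyletic(tree, c("A", "C")))
  expect_true(is_monophyletic(tree, "A"))
  expect_error(is_monophyletic(tree, c("A", "Q")), "unknown")
})

test_that("planted groups are monophyletic in simulated trees", {
  withr::local_seed(63)
  hier <- calibrate_hierarchy(n_species = 2, strains_per_group = 3)
  sim <- simulate_taxon_set(sim_config(seed = 77, ancestor_length = 15000,
                                       hierarchy = hier))
  tree <- build_tree(gbdp_pairwise(sim$genomes)$distances)
  sp <- sim$truth$partitions$species
  groups <- split(names(sp), as.integer(sp))
  for (g in groups) {
    rt <- root_with_outgroup(tree, setdiff(tree$tip.label, g))
    expect_true(is_monophyletic(rt, g))
  }
})

test_that("support counting: identical replicates give 100, 2 of 4 give 50", {
  m <- additive_4taxon()
  tree <- build_tree(m)
  sup100 <- annotate_support(tree, list(m, m, m, m))
  internal <- attr(sup100, "support")[-1] # first node = root, trivial
  expect_true(all(internal == 100))
  # alternative matrix supporting the (A,C) split instead
  alt <- m
  alt["A", "C"] <- alt["C", "A"] <- 0.1
  alt["A", "B"] <- alt["B", "A"] <- 0.6
  expect_equal(tree_bipartitions(build_tree(alt))[[1]], c("B", "D"))
  sup50 <- annotate_support(tree, list(m, alt, m, alt))
  expect_equal(min(attr(sup50, "support")), 50)
  bad <- m; rownames(bad)[1] <- colnames(bad)[1] <- "X"
  expect_error(annotate_support(tree, list(bad)), "labels")
})

test_that("newick round-trip preserves topology, lengths, and supports", {
  withr::local_seed(64)
  m <- rnd_dist(6)
  tree <- annotate_support(build_tree(m),
                           lapply(1:4, function(i) {
                             n <- rnd_dist(6)
                             dimnames(n) <- dimnames(m)
                             n
                           }))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, tmp)
  back <- read_tree_newick(tmp)
  expect_true(setequal(tree_bipartitions(tree), tree_bipartitions(back)))
  o <- match(back$tip.label, tree$tip.label)
  expect_lt(max(abs(sort(back$edge.length) - sort(tree$edge.length))), 1e-9)
  # node numbering may rotate on round-trip; the label multiset and the
  # bipartition set (checked above) are what must survive
  expect_identical(sort(back$node.label), sort(tree$node.label))
  # rendering rule: supports <= 50 hidden on request, data layer untouched
  tmp2 <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, tmp2, hide_support_below = 50)
  shown <- read_tree_newick(tmp2)$node.label
  kept <- suppressWarnings(as.numeric(shown))
  expect_true(all(is.na(kept) | kept > 50))
})
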