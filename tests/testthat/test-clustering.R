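test_that("block-structured matrices cluster into their blocks at any F", {
  withr::local_seed(40)
  pl <- planted_dist(c(4, 4), win = c(0.005, 0.01), btw = c(0.45, 0.55))
  for (F in c(0, 0.5, 1)) {
    p <- threshold_cluster(pl$m, T = 0.1, F = F)
    expect_equal(length(unique(p)), 2)
    expect_equal(partition_agreement(p, pl$truth), 1)
  }
  # all pairwise distances above T: all singletons
  p0 <- threshold_cluster(pl$m, T = 0.001, F = 0)
  expect_equal(length(unique(p0)), 8)
})

test_that("threshold clustering matches the brute-force agglomeration oracle", {
  withr::local_seed(41)
  for (trial in 1:5) {
    pl <- planted_dist(c(4, 4, 4), win = c(0.01, 0.12), btw = c(0.05, 0.6))
    for (F in c(0, 0.5, 1)) {
      got <- threshold_cluster(pl$m, T = 0.15, F = F)
      want <- oracle_threshold_cluster(pl$m, T = 0.15, F = F)
      expect_equal(partition_agreement(got, want), 1,
                   info = sprintf("trial %d F=%.1f", trial, F))
    }
  }
})

test_that("F = 0 clustering equals connected components of the d<=T graph", {
  skip_if_not_installed("igraph")
  withr::local_seed(42)
  for (trial in 1:30) {
    m <- rnd_dist(20)
    T <- runif(1, 0.1, 0.9)
    p <- threshold_cluster(m, T, 0)
    g <- igraph::graph_from_adjacency_matrix(m <= T & upper.tri(m) | t(m <= T & upper.tri(m)),
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    names(comp) <- rownames(m)
    expect_equal(partition_agreement(p, partition(comp)), 1)
  }
})

test_that("cluster counts are monotone in T and in F", {
  withr::local_seed(43)
  m <- rnd_dist(12)
  counts_T <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(T)
    length(unique(threshold_cluster(m, T, 0.5))), integer(1))
  expect_true(all(diff(counts_T) <= 0))
  counts_F <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(F)
    length(unique(threshold_cluster(m, 0.5, F))), integer(1))
  expect_true(all(diff(counts_F) >= 0))
})

test_that("cluster statistics match a direct pair-enumeration oracle", {
  # one pair cluster
  m <- dist_matrix(matrix(c(0, 0.2, 0.2, 0), 2), c("a", "b"))
  st <- cluster_stats(m, partition(c(a = 1, b = 1)))
  expect_equal(st$per_cluster$avg_within, 0.2)
  expect_equal(st$per_cluster$max_within, 0.2)
  # all singletons: explicit marker
  st0 <- cluster_stats(m, partition(c(a = 1, b = 2)))
  expect_true(st0$no_multi_member)
  expect_null(st0$summary)
  # random partition vs independent enumeration
  withr::local_seed(44)
  m2 <- rnd_dist(20)
  p <- partition(setNames(sample(1:5, 20, replace = TRUE), rownames(m2)))
  st2 <- cluster_stats(m2, p)
  for (k in st2$per_cluster$cluster) {
    members <- names(p)[p == k]
    if (length(members) < 2) next
    pairs <- t(combn(members, 2))
    vals <- m2[pairs]
    row <- st2$per_cluster[st2$per_cluster$cluster == k, ]
    expect_equal(row$avg_within, mean(vals))
    expect_equal(row$max_within, max(vals))
  }
  # lower-median convention
  expect_equal(gbdtax:::median_low(c(1, 2, 3, 4)), 2)
  expect_equal(gbdtax:::median_low(c(5, 1, 3)), 3)
})

test_that("adjusted Rand index matches pair-counting and library oracles", {
  p1 <- partition(c(a = 1, b = 1, c = 2, d = 2, e = 3))
  p2 <- partition(c(a = 1, b = 2, c = 2, d = 2, e = 3))
  expect_equal(partition_agreement(p1, p1), 1)
  # identical up to relabeling
  p1r <- partition(c(a = 9, b = 9, c = 4, d = 4, e = 7))
  expect_equal(partition_agreement(p1, p1r), 1)
  # all-singletons vs one-cluster: chance level
  n <- 6
  ps <- partition(setNames(1:n, letters[1:n]))
  pc <- partition(setNames(rep(1, n), letters[1:n]))
  expect_equal(partition_agreement(ps, pc), 0)
  # random partitions vs both oracles
  withr::local_seed(45)
  for (trial in 1:10) {
    q1 <- partition(setNames(sample(1:4, 12, TRUE), letters[1:12]))
    q2 <- partition(setNames(sample(1:4, 12, TRUE), letters[1:12]))
    got <- partition_agreement(q1, q2)
    expect_equal(got, oracle_ari(q1, q2))
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(got,
                   mclust::adjustedRandIndex(as.integer(q1),
                                             as.integer(q2[names(q1)])))
  }
  expect_error(partition_agreement(p1, ps), "label sets")
})

test_that("reference optimization recovers block structure and honors ties", {
  withr::local_seed(46)
  pl <- planted_dist(c(3, 3, 3), win = c(0.01, 0.05), btw = c(0.4, 0.6))
  res <- optimize_against_reference(pl$m, pl$truth)
  expect_equal(res$agreement, 1)
  expect_equal(partition_agreement(res$partition, pl$truth), 1)
  # any T separating the bands reaches agreement 1; tie -> smallest such T
  expect_lt(res$T, 0.4)
  # all-singleton reference: smallest grid T wins, everything stays apart
  ref0 <- partition(setNames(seq_len(9), rownames(pl$m)))
  res0 <- optimize_against_reference(pl$m, ref0)
  expect_equal(length(unique(res0$partition)), 9)
})

test_that("noisy reference: optimization recovers at least reference quality", {
  withr::local_seed(47)
  pl <- planted_dist(c(4, 4, 4, 4), win = c(0.005, 0.03), btw = c(0.3, 0.6))
  noisy <- as.integer(pl$truth)
  flip <- sample(length(noisy), 2) # ~10% relabeled
  noisy[flip] <- sample(1:4, 2, replace = TRUE)
  ref <- partition(setNames(noisy, names(pl$truth)))
  res <- optimize_against_reference(pl$m, ref)
  expect_gte(partition_agreement(res$partition, pl$truth),
             partition_agreement(ref, pl$truth))
})

test_that("clustering consistency: ultrametric data score 1, chains do not", {
  # ultrametric: cophenetic distances of a dendrogram
  withr::local_seed(48)
  x <- matrix(rnorm(14), 7)
  hc <- hclust(dist(x), method = "average")
  mu <- as.matrix(cophenetic(hc))
  mu <- mu / max(mu) / 2
  labs <- sprintf("t%d", 1:7)
  dimnames(mu) <- list(labs, labs)
  for (T in c(0.05, 0.15, 0.3, 0.45))
    expect_equal(clustering_consistency(list(mu), T), 1)
  # chain a-b 0.1, b-c 0.1, a-c 0.5: single and complete linkage disagree
  mc <- dist_matrix(matrix(c(0, .1, .5, .1, 0, .1, .5, .1, 0), 3),
                    c("a", "b", "c"))
  expect_lt(clustering_consistency(list(mc), 0.2), 1)
  expect_error(clustering_consistency(list(), 0.2), "non-empty")
})

test_that("consistency is maximal exactly between the planted bands", {
  withr::local_seed(49)
  pl <- planted_dist(c(4, 4), win = c(0.005, 0.015), btw = c(0.04, 0.06))
  # brute-force scan: consistency must be 1 on the whole band gap and < 1
  # somewhere inside each band
  for (T in seq(0.016, 0.039, by = 0.004))
    expect_equal(clustering_consistency(list(pl$m), T), 1)
  in_band <- vapply(seq(0.006, 0.014, by = 0.001), function(T)
    clustering_consistency(list(pl$m), T), numeric(1))
  expect_lt(min(in_band), 1)
})

test_that("subspecies threshold lands mid-gap with a full profile", {
  withr::local_seed(50)
  mats <- lapply(1:10, function(i)
    planted_dist(c(4, 4), win = c(0.008, 0.012), btw = c(0.048, 0.052))$m)
  res <- optimize_subspecies_threshold(mats)
  expect_equal(res$status, "ok")
  expect_lt(abs(res$T_star - 0.03), 0.004)
  expect_true(all(c("T", "ddh", "consistency") %in% names(res$profile)))
  expect_equal(max(res$profile$consistency), 1)
  # no substructure: plateau hits the end of the grid -> degenerate flag
  one_band <- planted_dist(c(8), win = c(0.01, 0.02))$m
  res1 <- optimize_subspecies_threshold(list(one_band))
  expect_equal(res1$status, "degenerate_plateau")
})
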