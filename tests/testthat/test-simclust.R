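test_that("Tanimoto similarity: identity, disjoint, overlap, undefined cases", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  # bits {1,2,3} vs {2,3,4}: 2 shared / 4 in union
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_error(tanimoto(c(0, 0), c(0, 0)), class = "herbiscreen_validation_error")
  expect_error(tanimoto(c(1, 0), c(1, 0, 0)), class = "herbiscreen_validation_error")
})

test_that("1 - Tanimoto is a metric: triangle inequality over all 6-bit vectors", {
  vecs <- as.matrix(expand.grid(rep(list(0:1), 6)))
  vecs <- vecs[rowSums(vecs) > 0, ]  # distance undefined for the zero vector
  d <- jaccard_distance_matrix(fingerprint_matrix(vecs))
  n <- nrow(d)
  worst <- 0
  for (b in seq_len(n)) {  # d(a,c) <= d(a,b) + d(b,c) for every triple
    slack <- outer(d[, b], d[b, ], "+") - d
    worst <- min(worst, min(slack))
  }
  expect_gte(worst, -1e-12)
})

test_that("pairwise Jaccard distances agree with the elementwise definition", {
  set.seed(3)
  bits <- matrix(rbinom(20 * 16, 1, 0.4), nrow = 20)
  bits[rowSums(bits) == 0, 1] <- 1L
  d <- jaccard_distance_matrix(fingerprint_matrix(bits))
  for (i in c(1, 7, 20)) for (j in c(2, 13)) {
    expect_equal(d[i, j], 1 - tanimoto(bits[i, ], bits[j, ]))
  }
  expect_equal(unname(diag(d)), rep(0, 20))
  expect_equal(max(abs(d - t(d))), 0)
})

test_that("minimum distances to a training set behave as gates expect", {
  tr <- fingerprint_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  # identical to a training compound -> 0
  expect_equal(min_jaccard_distance(rbind(c(1, 1, 0, 0)), tr), 0)
  # disjoint from every training compound -> 1
  expect_equal(min_jaccard_distance(rbind(c(0, 0, 1, 1)),
                                    fingerprint_matrix(rbind(c(1, 1, 0, 0)))), 1)
  # TC 1/2 to both training rows -> minimum distance 1/2
  q <- rbind(c(1, 1, 1, 1))
  expect_equal(min_jaccard_distance(q, tr), 0.5)
  # TC 1/2 and 3/4 to the rows of a wider set -> min distance 1/4
  tr2 <- fingerprint_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 1, 0)))
  expect_equal(min_jaccard_distance(q, tr2), 0.25)
  expect_error(min_jaccard_distance(q, tr[0, , drop = FALSE]),
               class = "herbiscreen_validation_error")

  # Euclidean: query on a training row -> 0; 1-D toy
  expect_equal(min_euclidean_distance(matrix(3), matrix(c(0, 5))), 2)
  expect_equal(min_euclidean_distance(rbind(c(1, 2)), rbind(c(1, 2), c(9, 9))), 0)
  # adding a training point can only decrease the minimum
  tr2 <- matrix(c(0, 5, 3.5), ncol = 1)
  expect_lte(min_euclidean_distance(matrix(3), tr2),
             min_euclidean_distance(matrix(3), matrix(c(0, 5))))
})

test_that("Ward clustering recovers well-separated groups; degenerate k works", {
  # two tight groups: brute-force best 2-partition by within-cluster distance
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.05
  d[3, 4] <- d[4, 3] <- 0.05
  diag(d) <- 0
  best <- NULL; best_cost <- Inf
  for (mask in 1:7) {  # non-trivial bipartitions of 4 points
    grp <- as.integer(intToBits(mask))[1:4]
    if (length(unique(grp)) < 2) next
    cost <- sum(d[grp == 1, grp == 1]) / 2 + sum(d[grp == 0, grp == 0]) / 2
    if (cost < best_cost) { best_cost <- cost; best <- grp }
  }
  oracle_same <- outer(best, best, "==")
  lab <- hierarchical_clusters(d, 2)
  expect_equal(outer(lab, lab, "=="), oracle_same, ignore_attr = TRUE)

  expect_equal(length(unique(hierarchical_clusters(d, 4))), 4)  # singletons
  expect_equal(length(unique(hierarchical_clusters(d, 1))), 1)
  expect_error(hierarchical_clusters(d, 5), class = "herbiscreen_validation_error")
})

test_that("Dunn, Dunn2 and silhouette match hand-evaluated toy values", {
  d <- as.matrix(dist(c(0, 1, 10, 11)))
  lab <- c(1, 1, 2, 2)
  v <- cluster_validation(d, lab)
  expect_equal(v$dunn, 9)        # min separation 9 / max diameter 1
  expect_equal(v$dunn2, 10)      # min avg between 10 / max avg within 1
  # hand evaluation: s(0)=9.5/10.5, s(1)=8.5/9.5, symmetric for 10, 11
  expect_equal(v$avg_silhouette, (9.5 / 10.5 + 8.5 / 9.5) / 2,
               tolerance = 1e-9)
  expect_error(cluster_validation(d, rep(1, 4)),
               class = "herbiscreen_validation_error")
})

test_that("near-duplicate clusters push silhouette toward its upper limit", {
  d <- as.matrix(dist(c(0, 1e-6, 50, 50 + 1e-6)))
  v <- cluster_validation(d, c(1, 1, 2, 2))
  expect_gt(v$avg_silhouette, 0.999)
})

test_that("Dunn indices strictly increase as clusters move apart", {
  prev <- c(dunn = 0, dunn2 = 0)
  for (gap in c(5, 10, 20, 40)) {
    d <- as.matrix(dist(c(0, 1, gap, gap + 1)))
    v <- cluster_validation(d, c(1, 1, 2, 2))
    expect_gt(v$dunn, prev["dunn"])
    expect_gt(v$dunn2, prev["dunn2"])
    prev <- c(dunn = v$dunn, dunn2 = v$dunn2)
  }
})

test_that("adjusted Rand index: toys, label invariance, symmetry, null mean", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  # index equals its expectation here -> exactly 0
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4),
               class = "herbiscreen_validation_error")

  set.seed(11)
  base <- rep(1:4, each = 10)
  aris <- replicate(1000, adjusted_rand_index(base, sample(base)))
  expect_lt(abs(mean(aris)), 0.02)
  # symmetry
  a <- sample(1:3, 30, TRUE); b <- sample(1:3, 30, TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
})

test_that("pair-counting ARI agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:4, 40, TRUE); b <- sample(1:3, 40, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})
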