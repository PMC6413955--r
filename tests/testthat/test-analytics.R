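# deterministic blob generator for clustering tests
make_blobs <- function(centers, n_per, noise = 0.05, seed = 1) {
  set.seed(seed)
  cells <- do.call(cbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rep(centers[i, ], n_per), ncol = n_per) +
      stats::rnorm(length(centers[i, ]) * n_per, sd = noise)
  }))
  rownames(cells) <- paste0("f", seq_len(ncol(centers)))
  colnames(cells) <- paste0("cell", seq_len(ncol(cells)))
  list(m = cells,
       labels = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("min-max normalization maps rows to [0,1] and is idempotent", {
  m <- rbind(a = c(2, 4, 6), b = c(3, 3, 3), c = c(-1, 1, 0))
  colnames(m) <- paste0("c", 1:3)
  nm <- minmax_normalize(m)
  expect_equal(unname(nm["a", ]), c(0, 0.5, 1))
  expect_equal(unname(nm["b", ]), c(0, 0, 0))    # constant row policy
  expect_equal(unname(nm["c", ]), c(0, 1, 0.5))
  expect_equal(unclass(minmax_normalize(unclass(nm))), unclass(nm),
               ignore_attr = TRUE)
  nonconst <- nm[c("a", "c"), ]
  expect_true(all(apply(nonconst, 1, min) == 0) &&
                all(apply(nonconst, 1, max) == 1))
})

test_that("hierarchical clustering merges duplicates first, needs >= 2 cells", {
  m <- cbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  rownames(m) <- c("f1", "f2")
  hc <- hierarchical_cluster(minmax_normalize(m))
  expect_equal(hc$height[1], 0)                    # duplicated cells first
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  blo <- make_blobs(rbind(c(0, 0, 0), c(5, 5, 5)), 6)
  hc2 <- hierarchical_cluster(minmax_normalize(blo$m))
  expect_equal(adjusted_rand(stats::cutree(hc2, 2), blo$labels), 1)
  one <- matrix(1:2, 2, 1, dimnames = list(c("f1", "f2"), "c1"))
  expect_error(hierarchical_cluster(minmax_normalize(one)), "at least 2")
})

test_that("k-means restarts: recovery, determinism, edge cases", {
  blo <- make_blobs(rbind(c(0, 0, 0, 0), c(4, 4, 0, 0)), 8, seed = 3)
  nf <- minmax_normalize(blo$m)
  km <- kmeans_bootstrap(nf, 2, seed = 11)
  expect_equal(adjusted_rand(km, blo$labels), 1)
  expect_identical(km, kmeans_bootstrap(nf, 2, seed = 11))  # same seed
  # k = N_cells: singleton clusters with zero error
  kn <- kmeans_bootstrap(nf, ncol(nf), seed = 1)
  expect_equal(sort(unname(kn)), seq_len(ncol(nf)))
  expect_equal(attr(kn, "sse"), 0)
  expect_error(kmeans_bootstrap(nf, ncol(nf) + 1, seed = 1), "exceeds")
})

test_that("elbow and silhouette diagnostics behave on a 3-blob fixture", {
  blo <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), 6, noise = 0.08,
                    seed = 5)
  nf <- minmax_normalize(blo$m)
  rep <- elbow_and_silhouette(nf, k_range = 1:6, n_restarts = 30, seed = 2)
  # SSE at k=1 is the total sum of squares, and the curve never increases
  expect_equal(rep$sse[1], sum(scale(t(unclass(nf)), scale = FALSE)^2))
  expect_true(all(diff(rep$sse) < 1e-9))
  # elbow at the true k: the drop 2->3 dwarfs the drop 3->4
  drop23 <- rep$sse[2] - rep$sse[3]
  drop34 <- rep$sse[3] - rep$sse[4]
  expect_gt(drop23, 10 * max(drop34, 1e-12))
  expect_equal(which.max(rep$silhouette_avg), 3)
  # perfectly separated duplicate pairs give silhouette 1
  dup <- cbind(a = c(0, 0), b = c(0, 0), c = c(7, 7), d = c(7, 7))
  rownames(dup) <- c("f1", "f2")
  rep2 <- elbow_and_silhouette(minmax_normalize(dup), k_range = 2,
                               n_restarts = 10, seed = 1)
  expect_equal(rep2$silhouette_avg[1], 1)
})

test_that("z contrast flags separated features at the stated critical value", {
  set.seed(8)
  g1 <- matrix(stats::rnorm(20 * 2), nrow = 2)
  g2 <- matrix(stats::rnorm(20 * 2, mean = c(10, 0)), nrow = 2)
  m <- cbind(g1, g2)
  rownames(m) <- c("shifted", "null")
  colnames(m) <- paste0("c", 1:40)
  labels <- rep(1:2, each = 20)
  z <- zscore_between_clusters(m, labels, confidence = 0.99)
  expect_equal(attr(z, "critical_value"), stats::qnorm(0.995))  # 2.576
  expect_gt(abs(z$z[z$feature == "shifted"]), 2.58)
  expect_true(z$significant[z$feature == "shifted"])
  expect_false(z$significant[z$feature == "null"])
  # identical group means give z = 0
  mm <- rbind(flat = rep(c(1, 2), 10))
  colnames(mm) <- paste0("c", 1:20)
  zz <- zscore_between_clusters(mm, rep(1:2, each = 10))
  expect_equal(zz$z, 0)
  expect_error(zscore_between_clusters(m, c(1, rep(2, 39))), "at least 2")
  expect_error(zscore_between_clusters(m, rep(1, 40)), "exactly two")
})
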