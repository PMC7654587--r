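## separated Gaussian blobs in 23 dimensions
make_blobs <- function(k, per = 20, sep = 10, sd = 1, seed = 1, p = 23) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p), k, p) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(per * p, sd = sd), per, p) +
      matrix(centers[i, ], per, p, byrow = TRUE)))
  list(X = X, truth = rep(seq_len(k), each = per))
}

test_that("deterministic k-means recovers well-separated blobs exactly", {
  b <- make_blobs(2, per = 25, sep = 10)
  fit <- kmeans_deterministic(b$X, 2)
  ## exact recovery up to label permutation
  expect_equal(length(unique(paste(fit$labels, b$truth))), 2L)
  ## agrees with the independent stats::kmeans oracle on this easy case
  km <- stats::kmeans(b$X, centers = fit$centroids, algorithm = "Lloyd")
  expect_equal(fit$inertia, km$tot.withinss, tolerance = 1e-8)

  ## k = 1: inertia is the total scatter about the mean
  f1 <- kmeans_deterministic(b$X, 1)
  expect_equal(unique(f1$labels), 1L)
  expect_equal(f1$inertia, sum(scale(b$X, scale = FALSE)^2))

  ## duplicated rows share a label
  X <- rbind(b$X, b$X[1, ], b$X[1, ])
  fd <- kmeans_deterministic(X, 2)
  n <- nrow(X)
  expect_equal(fd$labels[n], fd$labels[n - 1])
  expect_equal(fd$labels[n], fd$labels[1])
})

test_that("clustering is deterministic and row-permutation equivariant", {
  b <- make_blobs(3, per = 15, sep = 8, seed = 4)
  f1 <- kmeans_deterministic(b$X, 3)
  f2 <- kmeans_deterministic(b$X, 3)
  expect_identical(f1, f2)
  ## permuting rows permutes labels consistently (same partition)
  set.seed(5)
  p <- sample(nrow(b$X))
  fp <- kmeans_deterministic(b$X[p, ], 3)
  expect_equal(length(unique(paste(fp$labels, f1$labels[p]))), 3L)
})

test_that("elbow plus silhouette finds the blob count", {
  b <- make_blobs(3, per = 20, sep = 10, seed = 7)
  ks <- choose_k(b$X, k_range = 2:8)
  expect_equal(ks$k, 3L)
  expect_true(all(diff(ks$inertia_curve$inertia) <= 0))

  ## elbow at the boundary: vicinity is clipped to k_range
  b2 <- make_blobs(2, per = 20, sep = 12, seed = 8)
  ks2 <- choose_k(b2$X, k_range = 2:8)
  expect_equal(ks2$k, 2L)

  ## featureless data exercises the fallback path
  set.seed(9)
  U <- matrix(runif(40 * 3), 40, 3)
  expect_warning(ksu <- choose_k(U, k_range = 2:10,
                                 sensitivity = 1e6),
                 "no knee")
  expect_true(ksu$k %in% 2:10)
})

test_that("cluster selection maximizes |correlation| with the property", {
  props <- hg19_chrom_properties()
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  prof_len <- mm(props$length_bp)
  set.seed(11)
  ## cluster 1: mean profile = scaled length (|r| = 1); cluster 2: noise
  D <- rbind(
    matrix(rep(prof_len, 10), 10, 23, byrow = TRUE) +
      matrix(rnorm(230, sd = 1e-4), 10),
    matrix(runif(230), 10, 23))
  colnames(D) <- props$chrom
  labels <- rep(1:2, each = 10)
  sel <- select_cluster(labels, D, props, "length")
  expect_equal(sel$selected_cluster, 1L)
  expect_gt(abs(sel$selection_corr), 0.999)
  expect_equal(nrow(sel$selected_models), 10L)
  ## reported |r| is the maximum over clusters
  expect_equal(abs(sel$selection_corr),
               max(abs(sel$cluster_corrs), na.rm = TRUE))

  ## small clusters are excluded with a warning
  labels2 <- c(rep(1, 17), rep(2, 3))
  expect_warning(sel2 <- select_cluster(labels2, D, props, "length"),
                 "smaller than")
  expect_equal(sel2$selected_cluster, 1L)
})

test_that("mirror-image clusters tie in |r| and break deterministically", {
  props <- hg19_chrom_properties()
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  prof <- mm(props$length_bp)
  D <- rbind(matrix(rep(prof, 12), 12, 23, byrow = TRUE),
             matrix(rep(1 - prof, 8), 8, 23, byrow = TRUE))
  colnames(D) <- props$chrom
  labels <- rep(1:2, c(12, 8))
  sel <- select_cluster(labels, D, props, "length")
  ## mirrored profiles d and 1-d have equal |r|, opposite sign
  expect_equal(abs(sel$cluster_corrs[["1"]]),
               abs(sel$cluster_corrs[["2"]]), tolerance = 1e-12)
  expect_lt(sel$cluster_corrs[["1"]] * sel$cluster_corrs[["2"]], 0)
  ## tie broken toward the larger cluster
  expect_equal(sel$selected_cluster, 1L)

  ## equal sizes: lower cluster id wins
  De <- rbind(D[1:8, ], D[13:20, ])
  sel2 <- select_cluster(rep(1:2, each = 8), De, props, "length")
  expect_equal(sel2$selected_cluster, 1L)
})
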