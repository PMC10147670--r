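spot_df <- function(xyz, channel, gene = channel, fov = "f") {
  data.frame(fov = fov, gene = gene, channel = channel,
             z_um = xyz[, 1], y_um = xyz[, 2], x_um = xyz[, 3],
             stringsAsFactors = FALSE)
}

random_spots <- function(n, seed, channels = c("Cy3", "Cy5"), box = 10) {
  set.seed(seed)
  ch <- sample(channels, n, TRUE)
  spot_df(matrix(runif(3 * n, 0, box), n, 3), channel = ch, gene = ch)
}

test_that("coincident spots of different channels are removed, both partners", {
  s <- spot_df(rbind(c(1, 2, 3), c(1, 2, 3)), channel = c("Cy3", "Cy5"))
  res <- filter_cross_channel(s, tolerance_um = 0)
  expect_equal(nrow(res$removed), 2L)
  expect_equal(nrow(res$kept), 0L)

  # same channel, same place: kept (only cross-channel counts)
  s2 <- spot_df(rbind(c(1, 2, 3), c(1, 2, 3)), channel = c("Cy3", "Cy3"),
                gene = c("g", "g"))
  res2 <- filter_cross_channel(s2, tolerance_um = 0)
  expect_equal(nrow(res2$removed), 0L)
})

test_that("single-channel input passes through unchanged", {
  s <- random_spots(50, seed = 1, channels = "Cy3")
  res <- filter_cross_channel(s, tolerance_um = 1)
  expect_equal(nrow(res$kept), 50L)
  expect_equal(nrow(res$removed), 0L)
})

test_that("filter matches the all-pairs brute-force oracle and is idempotent", {
  for (seed in 1:4) {
    tol <- c(0.3, 0.5, 1, 2)[seed]
    s <- random_spots(200, seed = seed)
    res <- filter_cross_channel(s, tolerance_um = tol)
    oracle <- oracle_crosschannel_removed(s, tol)
    expect_equal(sort(res$report$row), which(oracle))
    # kept + removed partition the input
    expect_equal(nrow(res$kept) + nrow(res$removed), nrow(s))
    # idempotent: a second pass removes nothing
    res2 <- filter_cross_channel(res$kept, tolerance_um = tol)
    expect_equal(nrow(res2$removed), 0L)
  }
})

test_that("too-few spots are all noise and empty input is not an error", {
  X <- matrix(runif(9), 3, 3)
  cl <- cluster_spots(X, eps = 1)
  expect_equal(cl$labels, rep(0L, 3))
  expect_length(cl$clusters, 0)
  cl0 <- cluster_spots(matrix(numeric(0), 0, 3), eps = 1)
  expect_length(cl0$labels, 0)
  expect_error(cluster_spots(X, eps = 0), "eps")
})

test_that("well-separated dense blobs give one cluster each", {
  set.seed(7)
  blob <- function(center) sweep(matrix(rnorm(18, 0, 0.1), 6, 3), 2, center, `+`)
  X <- rbind(blob(c(0, 0, 0)), blob(c(10, 10, 10)))
  cl <- cluster_spots(X, eps = 0.5)
  expect_length(cl$clusters, 2)
  expect_equal(sort(vapply(cl$clusters, length, 0L)), c(6L, 6L))
  expect_equal(cl$labels[1:6], rep(cl$labels[1], 6))
})

test_that("cluster memberships equal the brute-force DBSCAN oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(50:150, 1)
    # mixture of blobs and uniform noise
    k <- sample(2:4, 1)
    centers <- matrix(runif(3 * k, 0, 20), k, 3)
    X <- do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(rnorm(3 * 15, 0, 0.6), 15, 3), 2, centers[i, ], `+`)))
    X <- rbind(X, matrix(runif(3 * n, 0, 20), n, 3))
    eps <- runif(1, 0.5, 2)
    cl <- cluster_spots(X, eps = eps)
    oracle <- oracle_dbscan(X, eps = eps)
    expect_identical(partition_signature(cl$labels),
                     partition_signature(oracle))
    sizes <- vapply(cl$clusters, length, 0L)
    if (length(sizes)) expect_true(all(sizes >= 4L))
  }
})

test_that("cluster memberships are invariant to input permutation", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 20, 3),
             sweep(matrix(rnorm(60, 0, 0.5), 20, 3), 2, c(8, 8, 8), `+`),
             matrix(runif(30, 0, 16), 10, 3))
  cl <- cluster_spots(X, eps = 1.5)
  perm <- sample(nrow(X))
  clp <- cluster_spots(X[perm, ], eps = 1.5)
  # map permuted labels back to original order and compare partitions
  back <- integer(nrow(X))
  back[perm] <- clp$labels
  expect_identical(partition_signature(cl$labels), partition_signature(back))
})

test_that("eps suggestion falls between intra- and inter-blob spacing", {
  set.seed(3)
  b1 <- matrix(rnorm(90, 0, 0.15), 30, 3)
  b2 <- sweep(matrix(rnorm(90, 0, 0.15), 30, 3), 2, c(12, 0, 0), `+`)
  X <- rbind(b1, b2)
  s <- suggest_eps(X)
  max_intra <- max(max(dist(b1)), max(dist(b2)))
  D12 <- sqrt(outer(rowSums(b1^2), rowSums(b2^2), `+`) - 2 * tcrossprod(b1, b2))
  min_inter <- min(D12)
  expect_gt(s$eps, 0)
  expect_lt(s$eps, min_inter)
  # uniform cloud: positive, finite suggestion
  set.seed(4)
  u <- suggest_eps(matrix(runif(150, 0, 5), 50, 3))
  expect_true(is.finite(u$eps) && u$eps > 0)
  expect_error(suggest_eps(matrix(runif(9), 3, 3), min_samples = 4), "min_samples")
})
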