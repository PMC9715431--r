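test_that("window_pca matches a dense eigendecomposition oracle", {
  dos <- matrix(c(0, 1, 2, 1,
                  2, 1, 0, 1,
                  1, 0, 1, 2,
                  0, 2, 2, 0), nrow = 4, byrow = TRUE)
  gm <- toy_gm(dos)
  wp <- window_pca(gm, gi("chr1", 0, 1000), k = 2, min_snps = 2)
  expect_false(wp$excluded)
  # oracle: dense eigen of the centred covariance, independent arithmetic
  X <- dos
  Xc <- sweep(X, 2, colMeans(X))
  C <- Xc %*% t(Xc)
  eo <- eigen(C, symmetric = TRUE)
  expect_equal(wp$values, eo$values[1:2] / sum(diag(C)), tolerance = 1e-10)
  for (j in 1:2)
    expect_equal(abs(as.numeric(crossprod(wp$vectors[, j],
                                          eo$vectors[, j]))), 1,
                 tolerance = 1e-10)
  # eigenvalues descending, eigenvectors orthonormal
  expect_true(diff(wp$values) <= 0)
  expect_equal(crossprod(wp$vectors), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("window_pca flags degenerate windows and is deterministic", {
  gm_const <- toy_gm(matrix(1, nrow = 4, ncol = 20))
  wp <- window_pca(gm_const, gi("chr1", 0, 1e4), min_snps = 1)
  expect_true(wp$excluded)
  gm_few <- toy_gm(matrix(c(0, 1, 2, 1, 1, 0, 2, 0), nrow = 4))
  expect_true(window_pca(gm_few, gi("chr1", 0, 1e4), min_snps = 10)$excluded)
  # identical genotype content in two windows gives identical PCA
  dos <- matrix(sample(0:2, 80, replace = TRUE), nrow = 4)
  gm2 <- toy_gm(cbind(dos, dos), pos = c(1:20 * 10, 1000 + 1:20 * 10))
  a <- window_pca(gm2, gi("chr1", 0, 500), min_snps = 5)
  b <- window_pca(gm2, gi("chr1", 1000, 1500), min_snps = 5)
  expect_equal(a$values, b$values)
  expect_equal(a$vectors, b$vectors)
  expect_lt(pca_map_distance(a, b), 1e-7)
})

test_that("pca_map_distance matches the dense rank-2 Frobenius oracle", {
  set.seed(11)
  for (rep in 1:5) {
    g1 <- toy_gm(matrix(sample(0:2, 6 * 30, replace = TRUE), nrow = 6))
    g2 <- toy_gm(matrix(sample(0:2, 6 * 30, replace = TRUE), nrow = 6))
    a <- window_pca(g1, gi("chr1", 0, 1e4), min_snps = 5)
    b <- window_pca(g2, gi("chr1", 0, 1e4), min_snps = 5)
    recon <- function(p) {
      M <- matrix(0, 6, 6)
      for (j in 1:2) M <- M + p$values[j] * tcrossprod(p$vectors[, j])
      M
    }
    oracle <- sqrt(sum((recon(a) - recon(b))^2))
    expect_equal(pca_map_distance(a, b), oracle, tolerance = 1e-10)
    # metric sanity: symmetry, identity, non-negativity
    expect_equal(pca_map_distance(a, b), pca_map_distance(b, a))
    # identity up to sqrt(machine eps): the distance is a sqrt of a
    # cancellation-prone sum
    expect_lt(pca_map_distance(a, a), 1e-7)
    expect_gte(pca_map_distance(a, b), 0)
  }
})

test_that("orthogonal rank-1 maps with unit weight sit at squared distance 2", {
  fake <- function(vec) structure(list(values = c(1, 0),
                                       vectors = cbind(vec, rep(0, 4)),
                                       excluded = FALSE),
                                  class = "window_pca")
  a <- fake(c(1, 0, 0, 0)); b <- fake(c(0, 1, 0, 0))
  expect_equal(pca_map_distance(a, b)^2, 2, tolerance = 1e-12)
})

test_that("classical MDS reproduces known configurations", {
  # two windows at distance 4: coordinates +/- 2 on axis 1
  D <- matrix(c(0, 4, 4, 0), 2)
  fit <- classical_mds(D)
  expect_equal(sort(fit$points[, 1]), c(-2, 2), tolerance = 1e-8)
  expect_equal(fit$points[, 2], c(0, 0), tolerance = 1e-8, ignore_attr = TRUE)

  # a genuinely planar 5-point configuration embeds exactly
  set.seed(2)
  P <- matrix(rnorm(10), 5, 2)
  D5 <- as.matrix(dist(P))
  fit5 <- classical_mds(D5)
  expect_equal(as.matrix(dist(fit5$points)), D5, tolerance = 1e-8,
               ignore_attr = TRUE)

  # degenerate all-zero distances
  fit0 <- classical_mds(matrix(0, 4, 4))
  expect_true(all(fit0$points == 0))
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("silhouette matches the textbook formula on a hand example", {
  # 1-D points: {1, 2} in cluster 1, {8, 9, 10} in cluster 2
  x <- matrix(c(1, 2, 8, 9, 10))
  lab <- c(1, 1, 2, 2, 2)
  # hand computation per point: s = (b - a) / max(a, b)
  s1 <- (mean(c(7, 8, 9)) - 1) / mean(c(7, 8, 9))
  s2 <- (mean(c(6, 7, 8)) - 1) / mean(c(6, 7, 8))
  s3 <- (mean(c(7, 6)) - (1 + 2) / 2) / mean(c(7, 6))
  s4 <- (mean(c(8, 7)) - (1 + 1) / 2) / mean(c(8, 7))
  s5 <- (mean(c(9, 8)) - (2 + 1) / 2) / mean(c(9, 8))
  expect_equal(invscan:::silhouette_mean(x, lab),
               mean(c(s1, s2, s3, s4, s5)), tolerance = 1e-12)
})

test_that("cluster_windows separates Gaussian blobs and picks k = 2", {
  set.seed(5)
  pts <- rbind(cbind(rnorm(30, 0, 0.2), rnorm(30, 0, 0.2)),
               cbind(rnorm(30, 5, 0.2), rnorm(30, 5, 0.2)))
  cl <- cluster_windows(pts, k_range = 2:10, seed = 9)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$labels[1:30])), 1)
  expect_equal(length(unique(cl$labels[31:60])), 1)
  expect_true(cl$labels[1] != cl$labels[31])
})

test_that("find_outlier_regions applies the run-length and cluster rules", {
  win <- make_windows(c(chr1 = 3e6), 1e5)   # 30 windows
  z <- rep(0, 30); lab <- rep(1L, 30)
  # 12 consecutive high windows in one cluster -> exactly one region
  z[6:17] <- 2.0
  regs <- find_outlier_regions(win, z, lab)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$window_indices, 6:17)
  expect_equal(regs[[1]]$max_run_length, 12L)
  expect_equal(c(regs[[1]]$region$start, regs[[1]]$region$end),
               c(5e5, 17e5))

  # 9 consecutive windows is below the min-run boundary
  z9 <- rep(0, 30); z9[6:14] <- 2.0
  expect_length(find_outlier_regions(win, z9, lab), 0)

  # all-zero z-scores -> nothing
  expect_length(find_outlier_regions(win, rep(0, 30), lab), 0)

  # a cluster switch inside the run splits it below threshold
  lab2 <- lab; lab2[12] <- 2L
  expect_length(find_outlier_regions(win, z, lab2), 0)

  # excluded windows (NA) break runs
  zNA <- z; zNA[12] <- NA
  expect_length(find_outlier_regions(win, zNA, lab), 0)
})

test_that("scan output is invariant to sample ordering", {
  pop <- population_spec(n_samples = 24, chrom_length = 6e6, snp_density = 1)
  inv <- inversion_spec(gi("chr1", 2e6, 4e6), inv_freq = 0.4,
                        divergence = 0.4)
  sim <- simulate_population_vcf(pop, inv, seed = 31)
  res1 <- scan_inversions(sim$gm, min_run = 5, seed = 3)
  perm <- rev(seq_len(24))
  res2 <- scan_inversions(gm_subset(sim$gm, samples = perm),
                          min_run = 5, seed = 3)
  expect_equal(res1$window_table$z1, res2$window_table$z1, tolerance = 1e-8)
  expect_equal(length(res1$regions), length(res2$regions))
  if (length(res1$regions))
    expect_equal(res1$regions[[1]]$region, res2$regions[[1]]$region)
})
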