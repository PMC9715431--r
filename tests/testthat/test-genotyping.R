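test_that("region_pca matches a hand-computed Patterson-scaled SVD", {
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 2, 1,
                  0, 0, 1), nrow = 4, byrow = TRUE)
  gm <- toy_gm(dos)
  pca <- region_pca(gm, gi("chr1", 0, 1000), n_components = 2)
  # oracle: scale independently and take the dense SVD
  p <- colMeans(dos) / 2
  Xs <- sweep(sweep(dos, 2, 2 * p), 2, sqrt(p * (1 - p)), "/")
  sv <- svd(Xs)
  sc_oracle <- sv$u[, 1] * sv$d[1]
  expect_equal(abs(pca$scores[, 1]), abs(sc_oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(abs(as.numeric(crossprod(pca$loadings[, 1], sv$v[, 1]))), 1,
               tolerance = 1e-8)
  # components orthogonal
  expect_equal(crossprod(pca$scores)[1, 2], 0, tolerance = 1e-8)
})

test_that("region_pca rejects monomorphic regions and keeps PC1 under sample duplication", {
  gm_mono <- toy_gm(matrix(2, nrow = 4, ncol = 5))
  expect_error(region_pca(gm_mono, gi("chr1", 0, 1000)), "polymorphic")

  set.seed(21)
  dos <- matrix(sample(0:2, 6 * 40, replace = TRUE), nrow = 6)
  gm <- toy_gm(dos)
  gm2 <- toy_gm(rbind(dos, dos))
  p1 <- region_pca(gm, gi("chr1", 0, 1e4))
  p2 <- region_pca(gm2, gi("chr1", 0, 1e4))
  # doubling every sample leaves the PC1 axis (loadings) unchanged
  cosang <- abs(sum(p1$loadings[, 1] * p2$loadings[, 1]))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("cluster_genotypes finds the three PC1 groups, with k=2 fallback", {
  fake_pca <- function(pc1) structure(list(scores = cbind(pc1, 0)),
                                      class = "region_pca")
  cl <- cluster_genotypes(fake_pca(c(-5, -5, 0, 0, 5, 5)))
  expect_equal(cl$k, 3)
  expect_equal(cl$assignment, c(1, 1, 2, 2, 3, 3))
  # only two modes -> k = 2 fallback
  cl2 <- cluster_genotypes(fake_pca(c(-5, -5, -5, 5, 5, 5)))
  expect_equal(cl2$k, 2)
  expect_equal(cl2$assignment, c(1, 1, 1, 2, 2, 2))
  # constant PC1 -> single cluster
  cl1 <- cluster_genotypes(fake_pca(rep(1, 5)))
  expect_equal(cl1$k, 1)
})

test_that("sample_heterozygosity is the percentage of heterozygous sites", {
  gm <- toy_gm(rbind(rep(1, 5), c(0, 1, 1, 2, NA)))
  het <- sample_heterozygosity(gm)
  expect_equal(unname(het[1]), 100)
  expect_equal(unname(het[2]), 50)  # 2 of 4 non-missing
  gm_allmiss <- toy_gm(rbind(c(1, 1), c(NA, NA)))
  expect_true(is.na(sample_heterozygosity(gm_allmiss)[2]))
})

test_that("inversion calls match simulator truth and flag heterozygotes by heterozygosity", {
  pop <- population_spec(n_samples = 60, chrom_length = 8e6, snp_density = 1)
  region <- gi("chr1", 2e6, 6e6)
  inv <- inversion_spec(region, inv_freq = 0.3, divergence = 0.3)
  sim <- simulate_population_vcf(pop, inv, seed = 17)
  call <- inversion_call(sim$gm, region)
  expect_equal(call$k, 3)
  expect_false(call$ambiguous)
  acc <- mean(call$genotype == sim$truth$inv_genotype |
                call$genotype == 2 - sim$truth$inv_genotype)
  expect_gte(acc, 0.95)
  # middle cluster (heterozygotes) has the maximal mean heterozygosity
  expect_equal(unname(which.max(call$het_by_cluster)), 2)
  # calls are invariant to a PC1 orientation flip up to genotype polarity
  flipped <- call$genotype
  expect_true(all(sort(unique(flipped)) %in% 0:2))
})

test_that("projection reproduces training scores and genotypes held-out samples", {
  pop <- population_spec(n_samples = 90, chrom_length = 6e6, snp_density = 1)
  region <- gi("chr1", 1e6, 5e6)
  inv <- inversion_spec(region, inv_freq = 0.3, divergence = 0.3)
  sim <- simulate_population_vcf(pop, inv, seed = 23)
  train <- gm_subset(sim$gm, samples = 1:60)
  hold <- gm_subset(sim$gm, samples = 61:90)
  call <- inversion_call(train, region)

  # self-projection: PC1 reproduced
  selfp <- project_samples(call, train)
  expect_equal(selfp$PC1, unname(call$pca$scores[, 1]), tolerance = 1e-8)

  # held-out samples with 20% missingness genotyped >= 90% correctly
  holdm <- add_missingness(hold, 0.2, seed = 5)
  proj <- project_samples(call, holdm)
  truth <- sim$truth$inv_genotype[61:90]
  acc <- mean(proj$genotype == truth | proj$genotype == 2 - truth,
              na.rm = TRUE)
  expect_gte(acc, 0.90)

  # an all-missing sample gets a missing call
  allmiss <- hold
  allmiss$dosage[1, ] <- NA
  proj2 <- project_samples(call, allmiss)
  expect_true(is.na(proj2$genotype[1]))
})

test_that("diagnostic-SNP ML genotyping handles pure, balanced and noisy input", {
  # all observed alleles inversion-type -> homozygous inverted
  expect_equal(diagnostic_snp_genotype(rep(2, 10), rep(2, 10))$genotype, 2)
  # balanced counts -> heterozygote
  expect_equal(diagnostic_snp_genotype(rep(1, 50), rep(2, 50))$genotype, 1)
  # nothing observed -> missing
  expect_true(is.na(diagnostic_snp_genotype(integer(0), integer(0))$genotype))

  # low-coverage simulation: 2 reads x 50 SNPs, eps = 0.01 -> >= 95% correct
  set.seed(33)
  n_rep <- 200
  correct <- 0
  for (r in seq_len(n_rep)) {
    g <- sample(0:2, 1)
    q <- (g / 2) * 0.99 + (1 - g / 2) * 0.01
    reads <- rbinom(50, 2, q)
    if (diagnostic_snp_genotype(reads, rep(2, 50), eps = 0.01)$genotype == g)
      correct <- correct + 1
  }
  expect_gte(correct / n_rep, 0.95)
})

test_that("HWE chi-square matches hand computations and flags monomorphic input", {
  h <- hwe_test(c(25, 50, 25))
  expect_equal(h$chisq, 0)
  expect_equal(h$p, 1)
  # (40,20,40): expected 25/50/25 -> chi2 = 9 + 18 + 9 = 36
  h2 <- hwe_test(c(40, 20, 40))
  expect_equal(h2$chisq, 36)
  expect_equal(h2$df, 1L)
  h3 <- hwe_test(c(0, 0, 50))
  expect_true(h3$undefined)
})

test_that("genotype calls on HWE populations pass the HWE test most of the time", {
  pop <- population_spec(n_samples = 80, chrom_length = 3e6, snp_density = 1)
  region <- gi("chr1", 5e5, 2.5e6)
  pass <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    inv <- inversion_spec(region, inv_freq = 0.4, divergence = 0.4)
    sim <- simulate_population_vcf(pop, inv, seed = 100 + r)
    call <- inversion_call(sim$gm, region)
    if (!call$hwe$undefined && call$hwe$p > 0.05) pass <- pass + 1
  }
  expect_gte(pass / n_rep, 0.9)
})
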