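# independent translation oracle: classify a CDS-space substitution with
# Biostrings::translate (a different code path than the implementation's
# codon-table lookup)
oracle_class <- function(cds_seq, cds_off, alt_base) {
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
  alt_seq <- cds_seq
  substr(alt_seq, cds_off, cds_off) <- alt_base
  alt_aa <- as.character(Biostrings::translate(Biostrings::DNAString(alt_seq)))
  ci <- (cds_off - 1) %/% 3 + 1
  if (substr(ref_aa, ci, ci) == substr(alt_aa, ci, ci)) "syn" else "nonsyn"
}

test_that("synonymous/nonsynonymous classification matches code degeneracy", {
  # one plus-strand gene GGA CAT TGG: GGA->GGC syn (Gly), GGA->AGA nonsyn
  ref <- c(chr1 = paste0(strrep("T", 10), "GGACATTGG", strrep("T", 10)))
  gene <- structure(list(gene_id = "g1", chrom = "chr1", strand = "+",
                         tss = 11, span = gi("chr1", 10, 19),
                         cds = gi("chr1", 10, 19), phase = 0L),
                    class = "gene_model")
  gm <- toy_gm(matrix(c(1, 1), 1), pos = c(11, 16))
  gm$ref <- c("G", "T"); gm$alt <- c("A", "C")   # GGA->AGA; CAT->CAC
  cls <- classify_sites_syn_nonsyn(gm, list(gene), ref)
  expect_equal(cls, c("nonsyn", "syn"))

  # noncoding SNP
  gm2 <- toy_gm(matrix(1), pos = 3)
  gm2$ref <- "T"; gm2$alt <- "A"
  expect_equal(classify_sites_syn_nonsyn(gm2, list(gene), ref), "noncoding")

  # two variants in one codon -> both excluded
  gm3 <- toy_gm(matrix(c(1, 1), 1), pos = c(11, 12))
  gm3$ref <- c("G", "G"); gm3$alt <- c("A", "C")
  expect_equal(classify_sites_syn_nonsyn(gm3, list(gene), ref),
               c("excluded", "excluded"))
})

test_that("classification agrees with a brute-force translation oracle on both strands", {
  set.seed(61)
  sim <- simulate_coding_region(n_genes = 8, codons_per_gene = 40,
                                syn_rate = 0.15,
                                nonsyn_rate_by_class = c(inv = 0.15,
                                                         std = 0.15),
                                seed = 61)
  cls <- classify_sites_syn_nonsyn(sim$gm, sim$genes, sim$ref)
  # generator truth is an exact cross-module oracle
  expect_equal(cls, sim$truth$site_class)
  expect_gt(sum(cls == "syn"), 10)
  expect_gt(sum(cls == "nonsyn"), 10)

  # and per-variant Biostrings::translate agrees, strand-aware
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (j in seq_len(n_variants(sim$gm))) {
    pos0 <- sim$gm$pos[j] - 1
    g <- Filter(function(x) pos0 >= x$span$start & pos0 < x$span$end,
                sim$genes)[[1]]
    cds_len <- sum(gi_width(g$cds))
    gseq <- substr(sim$ref[["chr1"]], g$cds$start + 1, g$cds$end)
    if (g$strand == "-")
      gseq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(gseq)))
    off <- if (g$strand == "+") pos0 - g$cds$start + 1
           else g$cds$end - pos0
    alt <- if (g$strand == "+") sim$gm$alt[j] else comp[[sim$gm$alt[j]]]
    expect_equal(cls[j], oracle_class(gseq, off, alt))
  }
})

test_that("per-site diversity equals the pairwise-difference enumeration", {
  expect_equal(site_diversity(c(0, 0, 0)), 0)          # fixed site
  expect_equal(site_diversity(c(1, 1)), 2 * 0.25 * 4 / 3)  # p=0.5, n=4
  expect_true(is.na(site_diversity(c(NA, NA))))

  # O(n^2) oracle: mean pairwise difference over all allele pairs
  set.seed(62)
  for (r in 1:10) {
    dos <- sample(c(0, 1, 2, NA), 8, replace = TRUE)
    alleles <- unlist(lapply(dos[!is.na(dos)],
                             function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) next
    pairs <- combn(n, 2)
    oracle <- mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
    expect_equal(site_diversity(dos), oracle, tolerance = 1e-12)
  }
})

test_that("windowed load statistics respect the segregating-within-set rule", {
  sim <- simulate_coding_region(n_genes = 10, codons_per_gene = 50,
                                syn_rate = 0.10,
                                nonsyn_rate_by_class = c(inv = 0.10,
                                                         std = 0.10),
                                n_per_class = 15, seed = 63)
  cls <- classify_sites_syn_nonsyn(sim$gm, sim$genes, sim$ref)
  inv_samples <- names(sim$classes)[sim$classes == "inv"]
  gm_inv <- gm_subset(sim$gm, samples = inv_samples)
  lw <- window_load(gm_inv, cls, window_size = 1e6)
  # counts sum to the truth for the inv class only: std-class variants are
  # monomorphic within the inv sample set and contribute nothing
  expect_equal(sum(lw$pN) + sum(lw$pS),
               sum(sim$truth$hap_class == "inv"))
  expect_equal(sum(lw$pN), sum(sim$truth$hap_class == "inv" &
                                 sim$truth$site_class == "nonsyn"))

  # zero nonsynonymous rate -> pN/pS = 0 wherever defined
  sim0 <- simulate_coding_region(n_genes = 6, codons_per_gene = 40,
                                 syn_rate = 0.15,
                                 nonsyn_rate_by_class = c(inv = 0, std = 0),
                                 seed = 64)
  cls0 <- classify_sites_syn_nonsyn(sim0$gm, sim0$genes, sim0$ref)
  lw0 <- window_load(sim0$gm, cls0, window_size = 1e6)
  expect_true(all(lw0$pn_ps[!is.na(lw0$pn_ps)] == 0))
})

test_that("load t-tests match the Welch formula and calibrate under the null", {
  # identical groups -> t = 0, p = 1 for the two-sided contrast
  x <- c(0.4, 0.5, 0.6, 0.7)
  res <- load_tests(x, x, x + 0.1)
  expect_equal(res$p[res$comparison == "inv_vs_std"], 1)

  # hand-computed Welch statistic on a 6-window toy
  a <- c(0.2, 0.3, 0.5); b <- c(0.6, 0.8, 0.9)
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df_hand <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  res2 <- load_tests(a, b, c(a, b))
  expect_equal(res2$t[1], t_hand, tolerance = 1e-10)
  expect_equal(res2$df[1], df_hand, tolerance = 1e-10)

  # type-I error of the two-sided contrast near nominal 0.05
  set.seed(65)
  rej <- mean(replicate(500, {
    load_tests(rnorm(20, 1, 0.2), rnorm(20, 1, 0.2), rnorm(20, 1, 0.2))$p[1] < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("equal-rate classes show no significant load difference", {
  set.seed(66)
  sig <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    sim <- simulate_coding_region(n_genes = 12, codons_per_gene = 40,
                                  syn_rate = 0.12,
                                  nonsyn_rate_by_class = c(inv = 0.12,
                                                           std = 0.12),
                                  n_per_class = 12, seed = 600 + r)
    cls <- classify_sites_syn_nonsyn(sim$gm, sim$genes, sim$ref)
    inv_s <- names(sim$classes)[sim$classes == "inv"]
    std_s <- names(sim$classes)[sim$classes == "std"]
    lw_i <- window_load(gm_subset(sim$gm, samples = inv_s), cls,
                        window_size = 2e3)
    lw_s <- window_load(gm_subset(sim$gm, samples = std_s), cls,
                        window_size = 2e3)
    p <- load_tests(lw_i$pn_ps, lw_s$pn_ps, lw_i$pn_ps)$p[1]
    if (!is.na(p) && p < 0.05) sig <- sig + 1
  }
  expect_gte((n_rep - sig) / n_rep, 0.9)
})

test_that("TSS distances and gene-disruption flags match a linear scan", {
  genes <- read_gff3(toy_gff3())       # TSS at 101 (gA), 700 (gB), 901 (gC)
  bp <- data.frame(chrom = "chr1", pos = c(101, 450, 800, 60))
  d <- tss_distance(bp, genes)
  expect_equal(d$tss_distance, c(0, 250, 100, 41))
  expect_equal(d$in_gene, c(TRUE, TRUE, FALSE, FALSE))
  # brute-force scan over all genes
  tsss <- vapply(genes, `[[`, numeric(1), "tss")
  for (i in seq_len(nrow(bp)))
    expect_equal(d$tss_distance[i], min(abs(tsss - bp$pos[i])))
  expect_error(tss_distance(bp, list()), "empty annotation")
})

test_that("the breakpoint binomial test equals the enumeration oracle", {
  # minimum-likelihood two-sided rule, enumerated directly
  enum_p <- function(k, n, p) {
    probs <- dbinom(0:n, n, p)
    sum(probs[probs <= dbinom(k, n, p) * (1 + 1e-7)])
  }
  expect_equal(breakpoint_gene_binomial(3, 20, 0.39), enum_p(3, 20, 0.39),
               tolerance = 1e-9)
  expect_equal(breakpoint_gene_binomial(0, 1, 0.39), enum_p(0, 1, 0.39),
               tolerance = 1e-9)
  # at the mode the two-sided p is ~1
  expect_gt(breakpoint_gene_binomial(8, 20, 0.39), 0.9)
  expect_equal(breakpoint_gene_binomial(2, 13, 0.39), enum_p(2, 13, 0.39),
               tolerance = 1e-9)
})

test_that("SD-density enrichment uses truncated flanks and the KS oracle", {
  sds <- gi(c("chr1", "chr1"), c(0, 2e6), c(1e6, 2.1e6))
  lens <- c(chr1 = 1e7)
  # interior site: +/-500 kb fully inside, covered 500 kb of 1 Mb
  d1 <- flank_sd_density(data.frame(chrom = "chr1", pos = 1e6 + 1), sds, lens)
  expect_equal(d1, 0.5)
  # site near the chromosome start: flank truncated, density on realized flank
  d2 <- flank_sd_density(data.frame(chrom = "chr1", pos = 2e5 + 1), sds, lens)
  expect_equal(d2, 7e5 / 7e5)
  # breakpoint exactly at the end is dropped
  expect_length(flank_sd_density(data.frame(chrom = "chr1", pos = 1), sds,
                                 lens), 0)

  # KS: identical -> D = 0, p = 1; disjoint supports -> D = 1
  expect_equal(sd_enrichment(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$D, 0)
  expect_equal(sd_enrichment(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$p, 1)
  expect_equal(sd_enrichment(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))$D, 1)
  # ECDF max-gap oracle on mixed samples
  x <- c(0.05, 0.3, 0.31, 0.6); y <- c(0.1, 0.2, 0.5, 0.9, 0.95)
  grid <- sort(c(x, y))
  oracle_D <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(sd_enrichment(x, y)$D, oracle_D, tolerance = 1e-12)
  expect_true(sd_enrichment(numeric(0), c(0.1))$undefined)
  expect_true(sd_enrichment(c(0, 0), c(0, 0))$undefined)

  # declarative SD filter with the published thresholds
  tab <- data.frame(chrom = "chr1", start = c(0, 0, 0, 0),
                    end = c(2000, 500, 2000, 2000),
                    identity = c(0.9, 0.9, 0.5, 0.9),
                    repeat_frac = c(0.1, 0.1, 0.1, 0.9))
  expect_equal(nrow(sd_filter(tab)), 1)
})
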