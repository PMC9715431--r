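#' Region PCA with Patterson scaling
#'
#' PCA over all SNPs in a candidate inversion region (no MAF filter or
#' thinning). Dosages are centred by twice the alternate allele frequency
#' p-hat and divided by sqrt(p-hat (1 - p-hat)) (Patterson scaling);
#' missing dosages are imputed to the SNP mean before scaling. Scores and
#' loadings come from the SVD of the scaled matrix.
#'
#' @param gm a \code{genotype_matrix}.
#' @param region single-row \code{genomic_interval}.
#' @param n_components components to keep (default 10, capped at the
#'   matrix rank).
#' @return a \code{region_pca} list: \code{scores} (samples x k),
#'   \code{loadings} (SNPs x k), \code{p_hat}, \code{chrom}, \code{pos},
#'   \code{sample_ids}.
#' @export
region_pca <- function(gm, region, n_components = 10) {
  sub <- gm_subset(gm, region = region)
  f <- alt_freq(sub)
  poly <- !is.na(f) & f > 0 & f < 1
  if (sum(poly) < 2) stop("fewer than 2 polymorphic SNPs in region")
  sub <- gm_subset(sub, variants = poly)
  p <- alt_freq(sub)
  X <- sub$dosage
  mu <- 2 * p
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  Xs <- sweep(X, 2, mu) ; Xs <- sweep(Xs, 2, sqrt(p * (1 - p)), "/")
  k <- min(n_components, nrow(Xs) - 1, ncol(Xs))
  sv <- svd(Xs, nu = k, nv = k)
  # deterministic sign: largest-|loading| sample score positive
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) { scores[, j] <- -scores[, j]
                            sv$v[, j] <- -sv$v[, j] }
  }
  rownames(scores) <- sub$sample_ids
  structure(list(scores = scores, loadings = sv$v, p_hat = p,
                 chrom = sub$chrom, pos = sub$pos,
                 sample_ids = sub$sample_ids, n_components = k),
            class = "region_pca")
}

#' Cluster samples into inversion genotype groups on PC1
#'
#' 1-D k-means with k = 3, starting centres at the minimum, midpoint and
#' maximum of the PC1 scores (so unequal cluster sizes do not pull the
#' starts). If a cluster comes back empty or the clustering degenerates,
#' k = 2 is retried; if PC1 is constant a single cluster is returned.
#' Clusters are labelled 1..k in ascending PC1 centre order, so clusters 1
#' and 3 are the putative homozygotes and cluster 2 the heterozygotes.
#'
#' @param pca a \code{region_pca}.
#' @return list: \code{assignment} (1..k per sample), \code{k},
#'   \code{centres} (ascending PC1 means).
#' @export
cluster_genotypes <- function(pca) {
  pc1 <- pca$scores[, 1]
  stopifnot(length(pc1) >= 3)
  lo <- min(pc1); hi <- max(pc1)
  if (hi - lo < .Machine$double.eps^0.5)
    return(list(assignment = rep(1L, length(pc1)), k = 1L, centres = lo))
  km3 <- tryCatch(stats::kmeans(matrix(pc1), centers =
                                  matrix(c(lo, (lo + hi) / 2, hi))),
                  error = function(e) NULL)
  fit <- km3
  if (is.null(fit) || length(unique(fit$cluster)) < 3)
    fit <- tryCatch(stats::kmeans(matrix(pc1), centers = matrix(c(lo, hi))),
                    error = function(e) NULL)
  if (is.null(fit)) stop("k-means failed on PC1 scores")
  ord <- order(fit$centers[, 1])
  relabel <- match(fit$cluster, ord)
  list(assignment = relabel, k = length(ord),
       centres = sort(fit$centers[, 1]))
}

#' Per-sample heterozygosity in a region
#'
#' Percentage of non-missing sites at which the sample is heterozygous
#' (dosage 1). Samples with no non-missing sites get NA.
#'
#' @param gm a \code{genotype_matrix}.
#' @param region optional single-row \code{genomic_interval}.
#' @param samples optional sample subset.
#' @return named numeric vector of percentages.
#' @export
sample_heterozygosity <- function(gm, region = NULL, samples = NULL) {
  sub <- gm_subset(gm, region = region, samples = samples)
  if (n_variants(sub) == 0) stop("no sites in region")
  het <- rowSums(sub$dosage == 1, na.rm = TRUE)
  nn <- rowSums(!is.na(sub$dosage))
  out <- ifelse(nn > 0, 100 * het / nn, NA_real_)
  names(out) <- sub$sample_ids
  out
}

#' Call inversion genotypes for a candidate region
#'
#' Region PCA, PC1 clustering and per-cluster heterozygosity in one step.
#' The middle cluster is taken as heterozygote (genotype 1) and the PC1
#' extremes as the homozygotes; which extreme is the derived (inverted)
#' arrangement is an input label (\code{derived_extreme}), since the
#' orientation comes from outgroup alignment, not from the genotype data.
#' A post-hoc check requires the middle cluster to have the highest mean
#' heterozygosity; otherwise calls are flagged ambiguous rather than
#' reassigned. An HWE chi-square on the genotype counts is included.
#'
#' @param gm a \code{genotype_matrix}.
#' @param region single-row \code{genomic_interval}.
#' @param derived_extreme "high" (default) or "low": which PC1 extreme is
#'   the inverted arrangement.
#' @return an \code{inversion_call} list: \code{region}, \code{genotype}
#'   (0/1/2 per sample), \code{cluster}, \code{k}, \code{cluster_means}
#'   (PC1), \code{het_by_cluster}, \code{ambiguous}, \code{hwe},
#'   \code{pca}.
#' @export
inversion_call <- function(gm, region, derived_extreme = c("high", "low")) {
  derived_extreme <- match.arg(derived_extreme)
  pca <- region_pca(gm, region)
  cl <- cluster_genotypes(pca)
  het <- sample_heterozygosity(gm, region)
  het_by <- tapply(het, cl$assignment, mean, na.rm = TRUE)
  if (cl$k == 3) {
    geno_map <- if (derived_extreme == "high") c(0L, 1L, 2L) else c(2L, 1L, 0L)
    ambiguous <- !(which.max(het_by) == 2)
  } else if (cl$k == 2) {
    het_cl <- which.max(het_by)
    hom_cl <- setdiff(1:2, het_cl)
    geno_map <- integer(2)
    geno_map[het_cl] <- 1L
    # the single homozygote cluster: orientation label decides 0 vs 2
    hom_is_high <- hom_cl == 2
    geno_map[hom_cl] <- if (xor(hom_is_high, derived_extreme == "low")) 2L else 0L
    ambiguous <- FALSE
  } else {
    geno_map <- 0L
    ambiguous <- TRUE
  }
  genotype <- geno_map[cl$assignment]
  names(genotype) <- pca$sample_ids
  counts <- c(sum(genotype == 0), sum(genotype == 1), sum(genotype == 2))
  structure(list(region = region, genotype = genotype,
                 cluster = cl$assignment, k = cl$k,
                 cluster_means = cl$centres, het_by_cluster = het_by,
                 ambiguous = ambiguous, hwe = hwe_test(counts), pca = pca),
            class = "inversion_call")
}

#' Project new samples onto a trained region PCA and call genotypes
#'
#' New dosages are Patterson-scaled with the training allele frequencies
#' (missing values imputed to the training mean) and projected onto the
#' stored loadings. A genotype is called by the nearest cluster mean on
#' PC1; the call is set to missing when the distance to the nearest centre
#' is not less than \code{margin} times the gap to the adjacent centre.
#'
#' @param call an \code{inversion_call} (holds the trained PCA and the PC1
#'   genotype centres).
#' @param new_gm a \code{genotype_matrix} sharing the region's SNPs
#'   (missing allowed; zero overlap is an error).
#' @param margin ambiguity margin (default 0.5 = midpoint rule).
#' @return data.frame: sample, PC1, PC2, genotype (NA when ambiguous or
#'   all-missing).
#' @export
project_samples <- function(call, new_gm, margin = 0.5) {
  pca <- call$pca
  key <- paste(pca$chrom, pca$pos)
  new_key <- paste(new_gm$chrom, new_gm$pos)
  idx <- match(key, new_key)
  if (all(is.na(idx))) stop("no overlapping SNPs between region and new samples")
  n <- n_samples(new_gm)
  m <- length(key)
  X <- matrix(NA_real_, nrow = n, ncol = m)
  X[, !is.na(idx)] <- new_gm$dosage[, idx[!is.na(idx)], drop = FALSE]
  all_missing <- rowSums(!is.na(X)) == 0
  mu <- 2 * pca$p_hat
  miss <- which(is.na(X), arr.ind = TRUE)
  if (nrow(miss)) X[miss] <- mu[miss[, 2]]
  Xs <- sweep(X, 2, mu); Xs <- sweep(Xs, 2, sqrt(pca$p_hat * (1 - pca$p_hat)), "/")
  proj <- Xs %*% pca$loadings
  # genotype centres on PC1, in ascending-genotype order
  centres <- tapply(pca$scores[, 1], call$genotype, mean)
  genos <- as.integer(names(centres))
  geno <- rep(NA_integer_, n)
  if (length(centres) >= 2) {
    for (i in seq_len(n)) {
      dists <- abs(proj[i, 1] - centres)
      j <- which.min(dists)
      gap <- min(abs(centres[j] - centres[-j]))
      if (dists[j] < margin * gap) geno[i] <- genos[j]
    }
  }
  geno[all_missing] <- NA_integer_
  proj1 <- proj[, 1]
  proj2 <- if (ncol(proj) >= 2) proj[, 2] else NA_real_
  proj1[all_missing] <- NA_real_
  data.frame(sample = new_gm$sample_ids, PC1 = proj1, PC2 = proj2,
             genotype = geno, stringsAsFactors = FALSE)
}

#' Diagnostic-SNP maximum-likelihood genotyping
#'
#' Genotype call from allele counts at SNPs fixed between the inverted and
#' standard arrangements (the low-coverage replacement for HMM ancestry
#' calling). Under per-SNP binomial sampling with error rate \code{eps},
#' the probability that a read shows the inversion-type allele is
#' g/2 (1 - eps) + (1 - g/2) eps for genotype g; the call maximizes the
#' summed binomial log-likelihood.
#'
#' @param inv_reads,total_reads per-SNP counts of inversion-type reads and
#'   total reads.
#' @param eps per-read error probability (default 0.01).
#' @return list: \code{genotype} (0/1/2 or NA when nothing observed),
#'   \code{loglik} (length-3 vector).
#' @export
diagnostic_snp_genotype <- function(inv_reads, total_reads, eps = 0.01) {
  stopifnot(length(inv_reads) == length(total_reads),
            all(inv_reads <= total_reads))
  keep <- total_reads > 0
  if (!any(keep)) return(list(genotype = NA_integer_,
                              loglik = rep(NA_real_, 3)))
  k <- inv_reads[keep]; m <- total_reads[keep]
  ll <- vapply(0:2, function(g) {
    q <- (g / 2) * (1 - eps) + (1 - g / 2) * eps
    sum(k * log(q) + (m - k) * log(1 - q))
  }, numeric(1))
  list(genotype = (0:2)[which.max(ll)], loglik = ll)
}

#' Hardy-Weinberg chi-square test
#'
#' Pearson chi-square (no continuity correction) of observed genotype
#' counts against Hardy-Weinberg expectations from the sample allele
#' frequency, on 1 degree of freedom. Monomorphic samples (allele
#' frequency 0 or 1) are flagged undefined.
#'
#' @param counts integer vector (n0, n1, n2) of genotype counts.
#' @return list: \code{chisq}, \code{df}, \code{p}, \code{undefined}.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, sum(counts) >= 1)
  n <- sum(counts)
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1)
    return(list(chisq = NA_real_, df = 1L, p = NA_real_, undefined = TRUE))
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((counts - expd)^2 / expd)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       undefined = FALSE)
}
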