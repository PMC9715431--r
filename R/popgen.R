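#' Minor-allele-frequency filter
#'
#' Keeps SNPs with MAF strictly greater than the threshold (so a SNP at
#' exactly 5\% is removed under the default), computed over non-missing
#' genotypes.
#'
#' @param gm a \code{genotype_matrix}.
#' @param maf threshold (default 0.05, the LD pipeline's setting).
#' @return a filtered \code{genotype_matrix}.
#' @export
maf_filter <- function(gm, maf = 0.05) {
  if (n_variants(gm) == 0) return(gm)
  f <- alt_freq(gm)
  keep <- !is.na(f) & pmin(f, 1 - f) > maf
  gm_subset(gm, variants = keep)
}

#' Thin SNPs to one per bin
#'
#' Keeps the first SNP in each non-overlapping \code{bp} window per
#' chromosome (at most one SNP per kb under the default), mirroring
#' vcftools --thin semantics on a sorted file. Composable with
#' \code{\link{maf_filter}} in either order.
#'
#' @param gm a \code{genotype_matrix}.
#' @param bp bin width (default 1000).
#' @return a thinned \code{genotype_matrix}.
#' @export
thin_snps <- function(gm, bp = 1000) {
  if (n_variants(gm) == 0) return(gm)
  bin <- (gm$pos - 1) %/% bp
  key <- paste(gm$chrom, bin)
  keep <- !duplicated(key)
  gm_subset(gm, variants = keep)
}

#' Squared genotype correlation between two SNPs
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples
#' (the geno-r2 statistic). NA when fewer than \code{min_complete}
#' complete pairs remain or either SNP has zero variance among them.
#'
#' @param g1,g2 dosage vectors.
#' @param min_complete minimum pairwise-complete samples (default 4).
#' @return r-squared in [0,1], or NA.
#' @export
geno_r2 <- function(g1, g2, min_complete = 4) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < max(2, min_complete)) return(NA_real_)
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0) return(NA_real_)
  stats::cor(g1[ok], g2[ok])^2
}

#' Mean r-squared between genomic windows
#'
#' For every pair of windows, the mean of \code{\link{geno_r2}} over all
#' SNP pairs with one SNP in each window; the diagonal uses within-window
#' pairs. Apply \code{maf_filter} and \code{thin_snps} first, as the LD
#' pipeline does.
#'
#' @param gm a filtered, thinned \code{genotype_matrix} (one chromosome).
#' @param window_size window size in bp (default 500 kb).
#' @param min_complete minimum pairwise-complete samples per SNP pair.
#' @return list: \code{windows} (genomic_interval), \code{mean_r2}
#'   (symmetric matrix, NA where a window pair has no usable SNP pairs),
#'   \code{n_snps} per window.
#' @export
window_pair_mean_r2 <- function(gm, window_size = 5e5, min_complete = 4) {
  stopifnot(length(unique(gm$chrom)) == 1)
  chrom_len <- max(gm$pos)
  windows <- make_windows(setNames(chrom_len, gm$chrom[1]), window_size,
                          window_size)
  widx <- findInterval(gm$pos - 1, windows$start)
  m <- n_variants(gm)
  r2 <- suppressWarnings(stats::cor(gm$dosage,
                                    use = "pairwise.complete.obs")^2)
  cc <- crossprod(!is.na(gm$dosage))
  r2[cc < min_complete] <- NA
  W <- nrow(windows)
  out <- matrix(NA_real_, W, W)
  for (a in seq_len(W)) for (b in a:W) {
    ia <- which(widx == a); ib <- which(widx == b)
    if (!length(ia) || !length(ib)) next
    block <- r2[ia, ib, drop = FALSE]
    if (a == b) {
      if (length(ia) < 2) next
      vals <- block[upper.tri(block)]
    } else vals <- as.vector(block)
    if (all(is.na(vals))) next
    out[a, b] <- out[b, a] <- mean(vals, na.rm = TRUE)
  }
  list(windows = windows, mean_r2 = out,
       n_snps = tabulate(widx, nbins = W))
}

# per-SNP Hudson FST components over two sample groups
hudson_components <- function(gm, groupA, groupB) {
  dA <- gm_subset(gm, samples = groupA)$dosage
  dB <- gm_subset(gm, samples = groupB)$dosage
  nA <- 2 * colSums(!is.na(dA))
  nB <- 2 * colSums(!is.na(dB))
  p1 <- colSums(dA, na.rm = TRUE) / nA
  p2 <- colSums(dB, na.rm = TRUE) / nB
  ok <- nA >= 2 & nB >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (nA - 1) - p2 * (1 - p2) / (nB - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA; den[!ok] <- NA
  list(num = num, den = den, ok = ok)
}

#' Windowed Hudson F_ST
#'
#' The Hudson estimator with sample-size correction, windowed as a ratio
#' of sums: per SNP,
#' num = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1) and
#' den = p1 (1 - p2) + p2 (1 - p1), with n counted in alleles; the window
#' value is sum(num) / sum(den). Negative window values are reported as
#' computed, not clipped.
#'
#' @param gm a \code{genotype_matrix}.
#' @param groupA,groupB sample names or indices (>= 2 samples each).
#' @param window_size,step window size and step in bp (deer-mouse analyses use
#'   10 kb/10 kb within inversions and 100 kb/100 kb genome-wide).
#' @return data.frame: chrom, start, end, fst, n_snps (fst NA for windows
#'   with no usable SNPs).
#' @export
hudson_fst_windowed <- function(gm, groupA, groupB, window_size = 1e5,
                                step = window_size) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need >= 2 samples")
  comp <- hudson_components(gm, groupA, groupB)
  chrom_lengths <- vapply(unique(gm$chrom),
                          function(ch) max(gm$pos[gm$chrom == ch]),
                          numeric(1))
  windows <- make_windows(chrom_lengths, window_size, step)
  fst <- rep(NA_real_, nrow(windows))
  n_snps <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    sel <- gi_contains_pos(windows[i, ], gm$chrom, gm$pos) & comp$ok
    n_snps[i] <- sum(sel)
    if (n_snps[i] > 0) {
      den <- sum(comp$den[sel])
      if (den > 0) fst[i] <- sum(comp$num[sel]) / den
    }
  }
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, fst = fst, n_snps = n_snps)
}

#' Local-regression smoothing of a windowed statistic
#'
#' Presentation-only loess smoothing of per-window values (e.g. an F_ST
#' track), with span expressed as a fraction of the chromosome.
#'
#' @param pos window midpoints (bp).
#' @param value per-window values (NA dropped).
#' @param span loess span (default 0.05).
#' @return numeric vector of smoothed values aligned to \code{pos}.
#' @export
smooth_track <- function(pos, value, span = 0.05) {
  ok <- !is.na(value)
  out <- rep(NA_real_, length(pos))
  if (sum(ok) < 10) return(out)
  fit <- stats::loess(value[ok] ~ pos[ok], span = span, degree = 1)
  out[ok] <- stats::predict(fit)
  out
}
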