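#' Classify SNPs as synonymous or nonsynonymous
#'
#' For each biallelic SNP inside a CDS, the alternate allele is swapped
#' into its codon (reference context, strand-aware) and the site is
#' synonymous iff the amino acid is unchanged (standard genetic code).
#' SNPs outside CDS are "noncoding". Codons containing more than one
#' variant site are "excluded" (conservative), as are SNPs in genes with
#' inconsistent phase or a reference-allele mismatch (with a warning).
#'
#' @param gm a \code{genotype_matrix}.
#' @param genes list of \code{gene_model} (e.g. \code{\link{read_gff3}}).
#' @param ref named character vector of chromosome sequences.
#' @return character vector per variant: "syn", "nonsyn", "noncoding" or
#'   "excluded".
#' @export
classify_sites_syn_nonsyn <- function(gm, genes, ref) {
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- n_variants(gm)
  out <- rep("noncoding", m)
  pos0 <- gm$pos - 1
  for (g in genes) {
    if (is.null(g$cds)) next
    if (length(g$phase) && g$phase[1] != 0) {
      hits <- which(gm$chrom == g$chrom &
                      vapply(pos0, function(p) any(p >= g$cds$start &
                                                     p < g$cds$end), logical(1)))
      if (length(hits)) {
        warning("gene ", g$gene_id, " has inconsistent phase; SNPs excluded")
        out[hits] <- "excluded"
      }
      next
    }
    widths <- gi_width(g$cds)
    cum <- c(0, cumsum(widths))
    seq_chr <- ref[[g$chrom]]
    # CDS offset (1-based, translation order) of a 0-based genomic position
    cds_offset <- function(p0) {
      for (s in seq_len(nrow(g$cds))) {
        if (p0 >= g$cds$start[s] && p0 < g$cds$end[s]) {
          within <- if (g$strand == "+") p0 - g$cds$start[s] + 1
                    else g$cds$end[s] - p0
          return(cum[s] + within)
        }
      }
      NA_integer_
    }
    # genomic 0-based position of a CDS offset
    genomic_pos <- function(off) {
      s <- findInterval(off - 1, cum, rightmost.closed = FALSE)
      within <- off - cum[s]
      if (g$strand == "+") g$cds$start[s] + within - 1
      else g$cds$end[s] - within
    }
    hits <- which(gm$chrom == g$chrom)
    offs <- vapply(pos0[hits], cds_offset, numeric(1))
    in_cds <- !is.na(offs)
    hits <- hits[in_cds]; offs <- offs[in_cds]
    if (!length(hits)) next
    codon_idx <- (offs - 1) %/% 3 + 1
    multi <- codon_idx %in% codon_idx[duplicated(codon_idx)]
    out[hits[multi]] <- "excluded"
    for (j in which(!multi)) {
      i <- hits[j]
      ci <- codon_idx[j]
      cod_offs <- (ci - 1) * 3 + 1:3
      gpos <- vapply(cod_offs, genomic_pos, numeric(1))
      bases <- substring(seq_chr, gpos + 1, gpos + 1)
      if (g$strand == "-") bases <- comp[bases]
      ref_allele <- gm$ref[i]; alt_allele <- gm$alt[i]
      if (g$strand == "-") { ref_allele <- comp[[ref_allele]]
                             alt_allele <- comp[[alt_allele]] }
      cp <- offs[j] - (ci - 1) * 3
      if (bases[cp] != ref_allele) {
        warning("reference allele mismatch at ", gm$chrom[i], ":", gm$pos[i],
                "; SNP excluded")
        out[i] <- "excluded"
        next
      }
      aa_ref <- code[[paste(bases, collapse = "")]]
      bases[cp] <- alt_allele
      aa_alt <- code[[paste(bases, collapse = "")]]
      out[i] <- if (aa_ref == aa_alt) "syn" else "nonsyn"
    }
  }
  out
}

#' Per-site nucleotide diversity
#'
#' Unbiased pairwise heterozygosity at one site:
#' pi = 2 p (1 - p) n / (n - 1), with n the number of non-missing alleles
#' and p the alternate-allele frequency. Equals the mean pairwise
#' difference over all allele pairs. NA with fewer than 2 alleles.
#'
#' @param dosages dosage vector at one site.
#' @return pi (numeric scalar).
#' @export
site_diversity <- function(dosages) {
  ok <- !is.na(dosages)
  n <- 2 * sum(ok)
  if (n < 2) return(NA_real_)
  p <- sum(dosages[ok]) / n
  2 * p * (1 - p) * n / (n - 1)
}

#' Windowed mutational-load statistics (pN/pS, piN/piS)
#'
#' For windows across a region, counts segregating nonsynonymous (pN) and
#' synonymous (pS) sites and their mean per-site diversities (piN, piS),
#' restricted to sites segregating within the provided sample set (pass a
#' matrix subset to one homozygote class to measure that haplotype's
#' load). Ratios are NA (flagged) when the denominator is 0.
#'
#' @param gm a \code{genotype_matrix} already subset to the samples of
#'   interest.
#' @param site_class per-variant classes from
#'   \code{\link{classify_sites_syn_nonsyn}}.
#' @param region single-row \code{genomic_interval} to window (defaults to
#'   the span of the data).
#' @param window_size window size in bp (default 500 kb).
#' @return data.frame: chrom, start, end, pN, pS, piN, piS, pn_ps, pin_pis.
#' @export
window_load <- function(gm, site_class, region = NULL, window_size = 5e5) {
  stopifnot(length(site_class) == n_variants(gm))
  if (is.null(region))
    region <- gi(gm$chrom[1], 0, max(gm$pos))
  windows <- make_windows(setNames(gi_width(region), region$chrom),
                          window_size, window_size)
  windows$start <- windows$start + region$start
  windows$end <- windows$end + region$start
  f <- alt_freq(gm)
  seg <- !is.na(f) & f > 0 & f < 1
  pi_site <- apply(gm$dosage, 2, site_diversity)
  out <- windows
  out$pN <- out$pS <- 0L
  out$piN <- out$piS <- NA_real_
  for (i in seq_len(nrow(windows))) {
    inw <- gi_contains_pos(windows[i, ], gm$chrom, gm$pos) & seg
    nsyn <- inw & site_class == "nonsyn"
    syn <- inw & site_class == "syn"
    out$pN[i] <- sum(nsyn); out$pS[i] <- sum(syn)
    if (any(nsyn)) out$piN[i] <- mean(pi_site[nsyn], na.rm = TRUE)
    if (any(syn)) out$piS[i] <- mean(pi_site[syn], na.rm = TRUE)
  }
  out$pn_ps <- ifelse(out$pS > 0, out$pN / out$pS, NA_real_)
  out$pin_pis <- ifelse(!is.na(out$piS) & out$piS > 0, out$piN / out$piS,
                        NA_real_)
  out
}

#' Mutational-load hypothesis tests
#'
#' Welch t-tests on per-window load ratios: inversion vs standard
#' haplotypes (two-sided) and each haplotype class vs genome-wide windows
#' (one-sided, testing enrichment). Degenerate inputs (fewer than 2
#' windows or zero variance in both groups) are flagged with NA.
#'
#' @param inv_windows,std_windows,genome_windows numeric vectors of a load
#'   ratio (e.g. the pn_ps column of \code{\link{window_load}} output; NAs
#'   dropped).
#' @return data.frame: comparison, alternative, t, df, p.
#' @export
load_tests <- function(inv_windows, std_windows, genome_windows) {
  one <- function(x, y, alternative) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    fit <- tryCatch(stats::t.test(x, y, alternative = alternative),
                    error = function(e) NULL)
    if (is.null(fit)) return(c(t = NA_real_, df = NA_real_, p = NA_real_))
    c(t = unname(fit$statistic), df = unname(fit$parameter),
      p = fit$p.value)
  }
  rows <- rbind(
    c(comparison = "inv_vs_std", alternative = "two.sided"),
    c(comparison = "inv_vs_genome", alternative = "greater"),
    c(comparison = "std_vs_genome", alternative = "greater"))
  stats_mat <- rbind(one(inv_windows, std_windows, "two.sided"),
                     one(inv_windows, genome_windows, "greater"),
                     one(std_windows, genome_windows, "greater"))
  data.frame(comparison = rows[, 1], alternative = rows[, 2],
             t = stats_mat[, "t"], df = stats_mat[, "df"],
             p = stats_mat[, "p"], stringsAsFactors = FALSE)
}
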