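#' Distance from breakpoints to the nearest TSS
#'
#' Unsigned distance (bp) from each breakpoint to the nearest annotated
#' transcription start site, plus whether the breakpoint lies inside any
#' gene span (exon, intron or UTR).
#'
#' @param breakpoints data.frame with columns \code{chrom}, \code{pos}
#'   (1-based bp).
#' @param genes list of \code{gene_model}.
#' @return data.frame: chrom, pos, tss_distance, nearest_gene, in_gene.
#' @export
tss_distance <- function(breakpoints, genes) {
  if (!length(genes)) stop("empty annotation")
  gchrom <- vapply(genes, function(g) g$chrom, character(1))
  gtss <- vapply(genes, function(g) g$tss, numeric(1))
  gid <- vapply(genes, function(g) g$gene_id, character(1))
  out <- breakpoints
  out$tss_distance <- NA_real_
  out$nearest_gene <- NA_character_
  out$in_gene <- FALSE
  for (i in seq_len(nrow(breakpoints))) {
    sel <- gchrom == breakpoints$chrom[i]
    if (!any(sel)) next
    d <- abs(gtss[sel] - breakpoints$pos[i])
    j <- which.min(d)
    out$tss_distance[i] <- d[j]
    out$nearest_gene[i] <- gid[sel][j]
    out$in_gene[i] <- any(vapply(genes[sel], function(g)
      gi_contains_pos(g$span, breakpoints$chrom[i], breakpoints$pos[i]),
      logical(1)))
  }
  out
}

#' Binomial test for breakpoints falling in genes
#'
#' Two-sided exact binomial test of the number of breakpoints inside gene
#' bodies against the genome-wide gene density (the minimum-likelihood
#' two-sided rule, i.e. \code{binom.test}). The deer-mouse annotation
#' gives density 0.39; recompute it with \code{\link{gene_density}} for
#' other annotations.
#'
#' @param k_in_gene breakpoints inside genes.
#' @param n_breakpoints total breakpoints.
#' @param gene_density success probability in (0,1).
#' @return two-sided p-value.
#' @export
breakpoint_gene_binomial <- function(k_in_gene, n_breakpoints, gene_density) {
  stopifnot(k_in_gene >= 0, k_in_gene <= n_breakpoints,
            gene_density > 0, gene_density < 1)
  stats::binom.test(k_in_gene, n_breakpoints, gene_density)$p.value
}

#' Filter a segmental-duplication table
#'
#' Declarative filter with the SD definition used near breakpoints:
#' length >= 1 kb, identity >= 70\%, and < 70\% of the sequence masked as
#' common repeats.
#'
#' @param sd data.frame with columns chrom, start, end (0-based half-open)
#'   and optionally \code{identity} (fraction) and \code{repeat_frac}.
#' @param min_len,min_identity,max_repeat_frac thresholds.
#' @return filtered data.frame.
#' @export
sd_filter <- function(sd, min_len = 1000, min_identity = 0.70,
                      max_repeat_frac = 0.70) {
  keep <- (sd$end - sd$start) >= min_len
  if (!is.null(sd$identity)) keep <- keep & sd$identity >= min_identity
  if (!is.null(sd$repeat_frac)) keep <- keep & sd$repeat_frac < max_repeat_frac
  sd[keep, , drop = FALSE]
}

#' SD density in breakpoint flanks
#'
#' Fraction of the +/- \code{flank} bp around each site covered by
#' segmental-duplication intervals; the flank is truncated at chromosome
#' edges and the realized flank length is the denominator. Breakpoints at
#' chromosome ends (within \code{end_buffer} of either end) are dropped,
#' since telomeres are not assembled.
#'
#' @param sites data.frame with \code{chrom}, \code{pos} (1-based).
#' @param sd \code{genomic_interval}-like data.frame of SD intervals.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param flank half-window (default 500 kb).
#' @param end_buffer drop sites closer than this to a chromosome end.
#' @return numeric vector of densities in [0,1] (dropped sites omitted).
#' @export
flank_sd_density <- function(sites, sd, chrom_lengths, flank = 5e5,
                             end_buffer = 0) {
  dens <- numeric(0)
  for (i in seq_len(nrow(sites))) {
    L <- chrom_lengths[[sites$chrom[i]]]
    p0 <- sites$pos[i] - 1
    if (p0 <= end_buffer || p0 >= L - end_buffer) next
    win <- gi(sites$chrom[i], max(0, p0 - flank), min(L, p0 + flank))
    dens <- c(dens, gi_cover_width(win, sd) / gi_width(win))
  }
  dens
}

#' SD enrichment at breakpoints (two-sample KS)
#'
#' Two-sample Kolmogorov-Smirnov test comparing flank SD densities at
#' inversion breakpoints against densities at random genome-wide sites
#' (10,000 is the conventional draw). Undefined (flagged) when either sample is
#' empty or all densities are zero.
#'
#' @param breakpoint_densities,genome_densities numeric density vectors
#'   (e.g. from \code{\link{flank_sd_density}}).
#' @return list: \code{D}, \code{p}, \code{undefined}.
#' @export
sd_enrichment <- function(breakpoint_densities, genome_densities) {
  if (!length(breakpoint_densities) || !length(genome_densities) ||
      (all(breakpoint_densities == 0) && all(genome_densities == 0)))
    return(list(D = NA_real_, p = NA_real_, undefined = TRUE))
  fit <- suppressWarnings(stats::ks.test(breakpoint_densities,
                                         genome_densities))
  list(D = unname(fit$statistic), p = fit$p.value, undefined = FALSE)
}
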