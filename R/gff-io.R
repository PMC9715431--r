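#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon/CDS features with rtracklayer and assembles one
#' gene model per gene (the first mRNA is used where a gene has several).
#' The transcription start site (TSS) respects strand: it is the transcript
#' start for + genes and the transcript end for - genes. Genes whose summed
#' CDS length is not divisible by 3 are dropped with a warning.
#'
#' @param path path to a GFF3 file.
#' @return a list of \code{gene_model} objects, each a list with
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{tss} (1-based),
#'   \code{span} (genomic_interval covering the gene: exons, introns, UTRs),
#'   \code{cds} (genomic_interval of CDS segments in translation order) and
#'   \code{phase} (frame offsets per CDS segment).
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  genes <- g[type == "gene"]
  mrnas <- g[type == "mRNA"]
  cds <- g[type == "CDS"]
  out <- list()
  for (i in seq_along(genes)) {
    gene <- genes[i]
    gid <- gene$ID
    tx <- mrnas[vapply(mrnas$Parent, function(p) gid %in% p, logical(1))]
    if (length(tx) >= 1) tx <- tx[1] else tx <- gene
    txid <- if (!is.null(tx$ID)) tx$ID else gid
    seg <- cds[vapply(cds$Parent, function(p) txid %in% p, logical(1))]
    strand <- as.character(GenomicRanges::strand(gene))
    chrom <- as.character(GenomicRanges::seqnames(gene))
    tss <- if (strand == "-") GenomicRanges::end(tx) else GenomicRanges::start(tx)
    cds_gi <- NULL
    phase <- integer(0)
    if (length(seg) > 0) {
      o <- order(GenomicRanges::start(seg), decreasing = (strand == "-"))
      seg <- seg[o]
      total <- sum(GenomicRanges::width(seg))
      if (total %% 3 != 0) {
        warning("gene ", gid, " has CDS length ", total,
                " not divisible by 3; excluded")
        next
      }
      cds_gi <- gi(rep(chrom, length(seg)),
                   GenomicRanges::start(seg) - 1, GenomicRanges::end(seg))
      ph <- seg$phase
      phase <- if (is.null(ph)) rep(0L, length(seg)) else as.integer(ph)
    }
    out[[length(out) + 1L]] <- structure(
      list(gene_id = gid, chrom = chrom, strand = strand, tss = tss,
           span = gi(chrom, GenomicRanges::start(gene) - 1,
                     GenomicRanges::end(gene)),
           cds = cds_gi, phase = phase),
      class = "gene_model")
  }
  out
}

#' Genome-wide gene density
#'
#' Fraction of the genome covered by gene bodies (exons, introns and UTRs,
#' i.e. the union of gene spans) -- the success probability used by the
#' breakpoint binomial test. The deer-mouse annotation gives 0.39; the value
#' is always recomputed from the supplied annotation.
#'
#' @param genes list of \code{gene_model} (from \code{\link{read_gff3}}).
#' @param genome_length total genome length in bp.
#' @return fraction in (0,1).
#' @export
gene_density <- function(genes, genome_length) {
  spans <- do.call(rbind, lapply(genes, function(g) g$span))
  class(spans) <- c("genomic_interval", "data.frame")
  gi_union_width(spans) / genome_length
}
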