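#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (plain or gzipped) with VariantAnnotation and
#' returns biallelic SNPs as alternate-allele dosages. Multiallelic records
#' and indels are dropped; missing genotypes are kept as \code{NA};
#' coordinates remain 1-based in the returned object.
#'
#' @param path path to a VCF file.
#' @param region optional single-row \code{genomic_interval} (0-based
#'   half-open); only variants inside it are returned.
#' @return a \code{genotype_matrix}.
#' @export
read_vcf <- function(path, region = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  ref <- VariantAnnotation::ref(vcf)
  biallelic <- S4Vectors::elementNROWS(alt) == 1L
  altc <- rep(NA_character_, length(biallelic))
  altc[biallelic] <- as.character(unlist(alt[biallelic]))
  refc <- as.character(ref)
  snp <- biallelic & nchar(refc) == 1L & !is.na(altc) & nchar(altc) == 1L &
    altc %in% c("A", "C", "G", "T") & refc %in% c("A", "C", "G", "T")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  keep <- snp
  if (!is.null(region)) keep <- keep & gi_contains_pos(region, chrom, pos)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- t(gt[keep, , drop = FALSE])  # samples x variants
  dos <- gt_to_dosage(gt)
  genotype_matrix(sample_ids = rownames(gt), chrom = chrom[keep],
                  pos = pos[keep], ref = refc[keep], alt = altc[keep],
                  dosage = dos)
}

# "0/1"-style GT strings -> dosage; any missing allele -> NA
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".") || length(a) != 2L) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
  matrix(map[match(gt, u)], nrow = nrow(gt), ncol = ncol(gt))
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 file with GT genotypes. Missing dosages are
#' written as \code{./.}; dosage 1 is written \code{0/1} (phase is not
#' represented). \code{read_vcf(write_vcf(gm))} reproduces \code{dosage},
#' \code{pos} and \code{sample_ids} exactly.
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output path (".gz" suffix gives gzip output).
#' @param chrom_lengths optional named vector for contig header lines;
#'   defaults to max position per chromosome.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gm, path, chrom_lengths = NULL) {
  chroms <- unique(gm$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(gm$pos[gm$chrom == ch]),
                            numeric(1))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=invscan",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  m <- n_variants(gm)
  if (m > 0) {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = nrow(gm$dosage), ncol = m)
    idx <- !is.na(gm$dosage)
    gt[idx] <- gt_code[as.character(gm$dosage[idx])]
    lines <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                   "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
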