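#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes as alternate-allele dosages (0, 1, 2 or
#' \code{NA} for missing) for a set of samples, plus per-variant coordinates.
#' Variants are stored in columns, samples in rows. Positions are 1-based
#' (the VCF convention) and must be strictly increasing within a chromosome.
#'
#' @param sample_ids character vector of sample names (length n).
#' @param chrom character vector of per-variant chromosome names (length m).
#' @param pos integer vector of 1-based positions (length m).
#' @param ref,alt character vectors of alleles (length m).
#' @param dosage n x m numeric matrix with entries in \{0,1,2,NA\}.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(sample_ids, chrom, pos, ref, alt, dosage) {
  dosage <- as.matrix(dosage)
  m <- length(pos)
  stopifnot(length(chrom) == m, length(ref) == m, length(alt) == m,
            ncol(dosage) == m, nrow(dosage) == length(sample_ids))
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  rownames(dosage) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids),
                 chrom = as.character(chrom),
                 pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %d chromosome(s)\n",
              length(x$sample_ids), length(x$pos), length(unique(x$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of variants / samples
#' @param x a \code{genotype_matrix}.
#' @export
n_variants <- function(x) length(x$pos)

#' @rdname n_variants
#' @export
n_samples <- function(x) length(x$sample_ids)

#' Subset a genotype matrix
#'
#' @param gm a \code{genotype_matrix}.
#' @param region optional single-row \code{genomic_interval}; variants kept
#'   iff their (1-based) position falls inside the half-open interval.
#' @param samples optional character vector or index of samples to keep.
#' @param variants optional logical/integer index over variants.
#' @return a \code{genotype_matrix}.
#' @export
gm_subset <- function(gm, region = NULL, samples = NULL, variants = NULL) {
  keep <- rep(TRUE, n_variants(gm))
  if (!is.null(region))
    keep <- keep & gi_contains_pos(region, gm$chrom, gm$pos)
  if (!is.null(variants)) {
    kv <- rep(FALSE, n_variants(gm))
    kv[variants] <- TRUE
    keep <- keep & kv
  }
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else samples
  if (is.character(si)) si <- match(si, gm$sample_ids)
  genotype_matrix(gm$sample_ids[si], gm$chrom[keep], gm$pos[keep],
                  gm$ref[keep], gm$alt[keep],
                  gm$dosage[si, keep, drop = FALSE])
}

#' Per-variant alternate allele frequency
#'
#' Computed over non-missing dosages; \code{NaN} for all-missing variants.
#' @param gm a \code{genotype_matrix}.
#' @return numeric vector of length \code{n_variants(gm)}.
#' @export
alt_freq <- function(gm) colMeans(gm$dosage, na.rm = TRUE) / 2
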