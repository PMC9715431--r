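#' Simulate coding regions with planted synonymous/nonsynonymous variants
#'
#' Builds a synthetic chromosome carrying single-exon genes of random sense
#' codons (both strands), then plants at most one variant per codon:
#' synonymous variants at sites where a base change preserves the amino
#' acid, nonsynonymous variants where it does not. Variants are assigned to
#' one of two haplotype classes ("inv" or "std") at class-specific rates,
#' segregate only within that class's samples, and are recorded in a truth
#' table, so mutational-load contrasts can be created or withheld.
#'
#' @param n_genes number of genes.
#' @param codons_per_gene codons per gene.
#' @param syn_rate per-codon probability of a synonymous variant (per class).
#' @param nonsyn_rate_by_class named numeric, per-codon nonsynonymous
#'   variant probability for classes \code{inv} and \code{std}.
#' @param n_per_class diploid samples per class.
#' @param seed integer seed.
#' @return list with \code{gm} (genotype_matrix over both classes),
#'   \code{genes} (list of \code{gene_model}), \code{ref} (named character:
#'   chromosome sequence), \code{truth} (data.frame: pos, ref, alt,
#'   site_class, hap_class) and \code{classes} (per-sample class labels).
#' @export
simulate_coding_region <- function(n_genes = 10, codons_per_gene = 50,
                                   syn_rate = 0.05,
                                   nonsyn_rate_by_class =
                                     c(inv = 0.05, std = 0.05),
                                   n_per_class = 20, seed = 1) {
  stopifnot(syn_rate >= 0, all(nonsyn_rate_by_class >= 0),
            all(c("inv", "std") %in% names(nonsyn_rate_by_class)))
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  with_seed(seed, {
    gap <- 300L
    glen <- 3L * codons_per_gene
    chrom_len <- n_genes * (glen + gap) + gap
    refseq <- sample(bases, chrom_len, replace = TRUE)
    genes <- vector("list", n_genes)
    truth <- list()
    events <- c(syn_rate, nonsyn_rate_by_class[["inv"]],
                syn_rate, nonsyn_rate_by_class[["std"]])
    if (sum(events) > 1) stop("per-codon variant rates sum to > 1")
    ev_class <- c("syn", "nonsyn", "syn", "nonsyn")
    ev_hap <- c("inv", "inv", "std", "std")
    for (gidx in seq_len(n_genes)) {
      strand <- if (gidx %% 2 == 0) "-" else "+"
      start1 <- gap + (gidx - 1L) * (glen + gap) + 1L  # 1-based CDS start
      codons <- sample(sense, codons_per_gene, replace = TRUE)
      cds <- unlist(strsplit(paste(codons, collapse = ""), ""))
      # plant variants codon by codon (at most one per codon)
      for (ci in seq_len(codons_per_gene)) {
        u <- runif(1)
        ev <- findInterval(u, cumsum(events)) + 1L
        if (ev > length(events)) next
        cod <- substring(codons[ci], 1:3, 1:3)
        opts <- list()
        for (cp in 1:3) for (b in setdiff(bases, cod[cp])) {
          alt_cod <- cod; alt_cod[cp] <- b
          aa_alt <- code[[paste(alt_cod, collapse = "")]]
          kind <- if (aa_alt == "*") NA_character_
                  else if (aa_alt == code[[codons[ci]]]) "syn" else "nonsyn"
          if (!is.na(kind) && kind == ev_class[ev])
            opts[[length(opts) + 1L]] <- c(cp, b)
        }
        if (!length(opts)) next
        pick <- opts[[sample.int(length(opts), 1)]]
        cp <- as.integer(pick[1]); alt_cds <- pick[2]
        cds_off <- (ci - 1L) * 3L + cp            # 1-based offset in CDS
        if (strand == "+") {
          pos1 <- start1 + cds_off - 1L
          ref_b <- cds[cds_off]; alt_b <- alt_cds
        } else {
          pos1 <- start1 + glen - cds_off
          ref_b <- comp[[cds[cds_off]]]; alt_b <- comp[[alt_cds]]
        }
        truth[[length(truth) + 1L]] <- data.frame(
          pos = pos1, ref = ref_b, alt = alt_b,
          site_class = ev_class[ev], hap_class = ev_hap[ev],
          stringsAsFactors = FALSE)
      }
      # write gene sequence into the chromosome
      gseq <- if (strand == "+") cds else rev(unname(comp[cds]))
      refseq[start1:(start1 + glen - 1L)] <- gseq
      genes[[gidx]] <- structure(
        list(gene_id = sprintf("gene%03d", gidx), chrom = "chr1",
             strand = strand,
             tss = if (strand == "+") start1 else start1 + glen - 1L,
             span = gi("chr1", start1 - 1L, start1 + glen - 1L),
             cds = gi("chr1", start1 - 1L, start1 + glen - 1L),
             phase = 0L),
        class = "gene_model")
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(pos = integer(0), ref = character(0), alt = character(0),
                 site_class = character(0), hap_class = character(0))
    truth <- truth[order(truth$pos), , drop = FALSE]
    # genotypes: each variant segregates within its own class only
    n <- 2L * n_per_class
    classes <- rep(c("inv", "std"), each = n_per_class)
    ids <- sprintf("%s_%02d", classes, c(seq_len(n_per_class),
                                         seq_len(n_per_class)))
    m <- nrow(truth)
    dos <- matrix(0, nrow = n, ncol = m)
    for (j in seq_len(m)) {
      members <- which(classes == truth$hap_class[j])
      repeat {
        d <- rbinom(length(members), 2, runif(1, 0.1, 0.5))
        if (any(d > 0)) break
      }
      dos[members, j] <- d
    }
    gm <- genotype_matrix(ids, rep("chr1", m), truth$pos, truth$ref,
                          truth$alt, dos)
    list(gm = gm, genes = genes,
         ref = c(chr1 = paste(refseq, collapse = "")),
         truth = truth, classes = setNames(classes, ids))
  })
}

#' Write gene models as GFF3
#'
#' Minimal GFF3 emitter (gene/mRNA/CDS features) for synthetic annotations;
#' round-trips through \code{\link{read_gff3}}.
#'
#' @param genes list of \code{gene_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    s <- g$span
    lines <- c(lines,
      sprintf("%s\tinvscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, s$start + 1, s$end, g$strand, g$gene_id),
      sprintf("%s\tinvscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, s$start + 1, s$end, g$strand, g$gene_id, g$gene_id))
    if (!is.null(g$cds)) {
      for (k in seq_len(nrow(g$cds))) {
        lines <- c(lines,
          sprintf("%s\tinvscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
                  g$chrom, g$cds$start[k] + 1, g$cds$end[k], g$strand,
                  g$phase[min(k, length(g$phase))], g$gene_id, g$gene_id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
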