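# shared fixture builders (everything generated in code; no binary files)

toy_gm <- function(dosage, pos = NULL, chrom = "chr1", ref = "A", alt = "T") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100
  genotype_matrix(sample_ids = sprintf("s%02d", seq_len(nrow(dosage))),
                  chrom = rep(chrom, m), pos = pos,
                  ref = rep(ref, length.out = m),
                  alt = rep(alt, length.out = m), dosage = dosage)
}

random_gm <- function(n = 10, m = 100, miss = 0.05, seed = 1) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  dos[matrix(runif(n * m) < miss, n, m)] <- NA
  toy_gm(dos, pos = sort(sample.int(m * 50, m)))
}

write_text_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# minimal 3-sample VCF used by the reader tests
vcf3_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=3000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", "ind2", "ind3", sep = "\t"),
    paste("chr1", "1000001", ".", "G", "A", ".", "PASS", ".", "GT",
          "0/1", "1/1", "0/0", sep = "\t"),
    paste("chr1", "1500000", ".", "C", "A,T", ".", "PASS", ".", "GT",
          "0/1", "1/2", "0/0", sep = "\t"),
    paste("chr1", "2000000", ".", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0/1", "1/1", sep = "\t"))
}

# toy three-gene annotation with known union coverage, for density tests
toy_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\ttoy\tmRNA\t101\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttoy\texon\t101\t220\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\texon\t301\t400\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\tCDS\t101\t220\t.\t+\t0\tID=gA.c;Parent=gA.t1",
    "chr1\ttoy\tCDS\t301\t360\t.\t+\t0\tID=gA.c;Parent=gA.t1",
    "chr1\ttoy\tgene\t301\t700\t.\t-\t.\tID=gB",
    "chr1\ttoy\tmRNA\t301\t700\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\ttoy\tCDS\t401\t700\t.\t-\t0\tID=gB.c;Parent=gB.t1",
    "chr1\ttoy\tgene\t901\t1000\t.\t+\t.\tID=gC",
    "chr1\ttoy\tmRNA\t901\t1000\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr1\ttoy\tCDS\t901\t999\t.\t+\t0\tID=gC.c;Parent=gC.t1")
  writeLines(lines, path)
  path
}
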