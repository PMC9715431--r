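#' Genomic intervals (0-based, half-open)
#'
#' All interval arithmetic in invscan uses a single convention: coordinates
#' are 0-based and half-open, i.e. an interval covers base pairs
#' \code{start, start+1, ..., end-1}. VCF positions (1-based) are converted
#' at the I/O boundary only.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, 0-based exclusive end.
#' @return A data.frame of class \code{genomic_interval} with columns
#'   \code{chrom}, \code{start}, \code{end}.
#' @examples
#' gi("chr1", 0, 100000)
#' @export
gi <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(start >= end))
    stop("invalid interval: require 0 <= start < end")
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

#' Width of an interval in bp
#' @param x a \code{genomic_interval}.
#' @return numeric vector of widths.
#' @export
gi_width <- function(x) x$end - x$start

#' Membership of 1-based positions in an interval
#'
#' The shared coordinate primitive: a 1-based position \code{pos} on
#' \code{chrom} lies in the 0-based half-open interval iff
#' \code{start <= pos - 1 < end}.
#'
#' @param x a single-row \code{genomic_interval}.
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @return logical vector.
#' @export
gi_contains_pos <- function(x, chrom, pos) {
  stopifnot(nrow(x) == 1L)
  chrom == x$chrom & (pos - 1) >= x$start & (pos - 1) < x$end
}

#' Overlap test between one interval and a set of intervals
#' @param x single-row \code{genomic_interval}.
#' @param y \code{genomic_interval} (any number of rows).
#' @return logical vector, one per row of \code{y}.
#' @export
gi_overlaps <- function(x, y) {
  stopifnot(nrow(x) == 1L)
  y$chrom == x$chrom & y$start < x$end & y$end > x$start
}

#' Tile chromosomes into windows
#'
#' Windows of \code{size} bp are laid every \code{step} bp from the start of
#' each chromosome; the final partial window is retained. With
#' \code{step == size} the tiling covers every bp exactly once. A variant
#' whose 0-based coordinate equals a window end belongs to the next window.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 100 kb, the scan's window).
#' @param step step size in bp (default equal to \code{size}).
#' @return a \code{genomic_interval} with one row per window, ordered by
#'   chromosome then start.
#' @export
make_windows <- function(chrom_lengths, size = 1e5, step = size) {
  stopifnot(size > 0, step > 0, length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(chr) {
    L <- chrom_lengths[[chr]]
    n <- if (L <= size) 1L else ceiling((L - size) / step) + 1L
    starts <- (seq_len(n) - 1) * step
    gi(rep(chr, n), starts, pmin(starts + size, L))
  })
  out <- do.call(rbind, out)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Union length of a set of intervals
#'
#' Total bp covered by the union of the intervals (overlaps merged),
#' per the half-open convention.
#'
#' @param x a \code{genomic_interval}.
#' @return total covered bp (numeric scalar).
#' @export
gi_union_width <- function(x) {
  if (nrow(x) == 0) return(0)
  tot <- 0
  for (chr in unique(x$chrom)) {
    xi <- x[x$chrom == chr, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = xi$start + 1, end = xi$end))
    tot <- tot + sum(IRanges::width(ir))
  }
  tot
}

#' Intersection length of one interval with a set of intervals
#' @param x single-row \code{genomic_interval}.
#' @param y \code{genomic_interval} set (e.g. segmental-duplication annotations).
#' @return bp of \code{x} covered by the union of \code{y}.
#' @export
gi_cover_width <- function(x, y) {
  stopifnot(nrow(x) == 1L)
  y <- y[y$chrom == x$chrom & y$start < x$end & y$end > x$start, , drop = FALSE]
  if (nrow(y) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = pmax(y$start, x$start) + 1,
                                         end = pmin(y$end, x$end)))
  sum(IRanges::width(ir))
}

#' Read intervals from BED
#'
#' BED is already 0-based half-open, matching the internal convention.
#'
#' @param path path to a BED file (3+ columns).
#' @return a \code{genomic_interval}.
#' @export
read_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  gi(as.character(GenomicRanges::seqnames(g)),
     GenomicRanges::start(g) - 1, GenomicRanges::end(g))
}

#' @rdname read_bed
#' @param x a \code{genomic_interval} to write.
#' @export
write_bed <- function(x, path) {
  writeLines(sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                     as.integer(x$end)), path)
  invisible(path)
}
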