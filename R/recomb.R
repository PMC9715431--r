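#' Infer crossovers from F2 ancestry states
#'
#' Counts ancestry state changes along ordered markers for each F2.
#' With \code{singleton_clean} (default), single-marker state runs are
#' treated as genotyping errors and removed (iteratively, merging the
#' flanking runs) before counting; runs of up to \code{max_blip} markers
#' flanked by the same state on both sides are removed as well, since
#' paired miscalls otherwise masquerade as double crossovers (a real
#' double crossover inside one or two marker intervals is vanishingly
#' rare at the default 100 kb spacing and sub-cM/Mb rates). A direct
#' AA <-> BB transition counts as two crossovers. Each crossover is
#' placed at the midpoint of the two flanking (retained) markers.
#'
#' @param panel a \code{cross_panel} (fields \code{marker_pos},
#'   \code{ancestry}: individuals x markers, values AA/AB/BB or NA).
#' @param singleton_clean remove single-marker runs (and flanked blips up
#'   to \code{max_blip}) first (default TRUE).
#' @param max_blip longest same-state run removed when flanked by equal
#'   states on both sides (default 2; 1 restricts cleaning to singletons).
#' @return list: \code{crossovers} (data.frame individual, pos; an AA<->BB
#'   transition contributes two rows at the same midpoint),
#'   \code{n_informative} markers per individual, \code{flagged}
#'   (individuals with no informative markers).
#' @export
infer_crossovers <- function(panel, singleton_clean = TRUE, max_blip = 2) {
  anc <- panel$ancestry
  pos <- panel$marker_pos
  stopifnot(length(pos) >= 2, ncol(anc) == length(pos))
  steps <- c(AA = 0L, AB = 1L, BB = 2L)
  res <- vector("list", nrow(anc))
  n_inf <- integer(nrow(anc))
  for (i in seq_len(nrow(anc))) {
    obs <- which(!is.na(anc[i, ]))
    n_inf[i] <- length(obs)
    if (length(obs) < 2) next
    v <- anc[i, obs]; p <- pos[obs]
    if (singleton_clean) {
      repeat {
        r <- rle(v)
        nr <- length(r$lengths)
        if (nr <= 1) break
        if (any(r$lengths == 1)) {
          drop <- inverse.rle(list(lengths = r$lengths,
                                   values = r$lengths == 1))
          v <- v[!drop]; p <- p[!drop]
          if (length(v) == 0) break
          next
        }
        # flanked blip: a short run whose neighbours share a state
        blip <- which(r$lengths <= max_blip &
                        seq_len(nr) > 1 & seq_len(nr) < nr &
                        r$values[pmax(seq_len(nr) - 1, 1)] ==
                          r$values[pmin(seq_len(nr) + 1, nr)])
        if (!length(blip)) break
        sel <- rep(FALSE, nr); sel[blip[1]] <- TRUE
        drop <- inverse.rle(list(lengths = r$lengths, values = sel))
        v <- v[!drop]; p <- p[!drop]
      }
    }
    if (length(v) < 2) next
    r <- rle(v)
    if (length(r$lengths) <= 1) next
    last_idx <- cumsum(r$lengths)
    first_idx <- c(1, last_idx[-length(last_idx)] + 1)
    mids <- numeric(0)
    for (tr in seq_len(length(r$values) - 1)) {
      nx <- abs(steps[[r$values[tr + 1]]] - steps[[r$values[tr]]])
      mid <- (p[last_idx[tr]] + p[first_idx[tr + 1]]) / 2
      mids <- c(mids, rep(mid, nx))
    }
    if (length(mids))
      res[[i]] <- data.frame(individual = i, pos = mids)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  co <- if (length(res)) do.call(rbind, res) else
    data.frame(individual = integer(0), pos = numeric(0))
  list(crossovers = co, n_informative = n_inf, flagged = which(n_inf == 0))
}

#' Recombination rate of a region from crossover counts
#'
#' Map length in cM = 100 x (crossovers in region) / (2 n_f2), two meioses
#' per F2; rate = cM / (region length in Mb). A crossover belongs to the
#' region iff its midpoint position falls inside (half-open). When
#' computing within-inversion rates, pass only crossovers and n_f2 from
#' F2s whose F1 parents are heterozygous for the focal inversion.
#'
#' @param crossovers data.frame with column \code{pos} (bp), e.g. from
#'   \code{\link{infer_crossovers}}.
#' @param n_f2 number of F2 individuals the crossovers came from.
#' @param region single-row \code{genomic_interval}.
#' @return rate in cM/Mb.
#' @export
recombination_rate_region <- function(crossovers, n_f2, region) {
  stopifnot(n_f2 >= 1, gi_width(region) > 0)
  x <- sum(crossovers$pos - 1 >= region$start & crossovers$pos - 1 < region$end)
  cm <- 100 * x / (2 * n_f2)
  cm / (gi_width(region) / 1e6)
}
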