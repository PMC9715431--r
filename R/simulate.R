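#' @importFrom stats rbinom rpois runif rnorm rchisq setNames
NULL

# Run code under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Population simulation specs
#'
#' \code{population_spec} describes the sampled population:
#' \code{n_samples} diploids genotyped at SNPs laid down at
#' \code{snp_density} per kb along one chromosome of \code{chrom_length} bp,
#' with background alternate-allele frequencies drawn from
#' \code{maf_sampler} (a function of n returning minor allele frequencies in
#' (0, 0.5]; alternate/reference orientation is randomized).
#' \code{hwe_deviation} is an inbreeding-style coefficient F applied to the
#' inversion genotype frequencies (negative = heterozygote excess).
#'
#' @param n_samples number of diploid samples (>= 2).
#' @param chrom_length chromosome length in bp.
#' @param snp_density SNPs per kb.
#' @param maf_sampler function(n) -> minor allele frequencies.
#' @param hwe_deviation F coefficient at the inversion locus.
#' @return a \code{population_spec} list.
#' @export
population_spec <- function(n_samples = 30, chrom_length = 3e7,
                            snp_density = 1,
                            maf_sampler = function(n) runif(n, 0.05, 0.5),
                            hwe_deviation = 0) {
  stopifnot(n_samples >= 2, snp_density > 0, chrom_length > 0)
  structure(list(n_samples = n_samples, chrom_length = chrom_length,
                 snp_density = snp_density, maf_sampler = maf_sampler,
                 hwe_deviation = hwe_deviation), class = "population_spec")
}

#' @rdname population_spec
#'
#' @details \code{inversion_spec} describes one segregating inversion: the
#' inverted-class haplotype frequency \code{inv_freq}; \code{divergence},
#' the fraction of inversion-region SNPs at which the two arrangement
#' classes differ in allele frequency; and \code{delta_p}, the absolute
#' frequency difference at those divergent SNPs. Non-divergent SNPs keep
#' the background frequency in both classes (within-class diversity).
#'
#' @param region single-row \code{genomic_interval} for the inversion.
#' @param inv_freq inverted-arrangement frequency in [0,1].
#' @param divergence fraction of region SNPs that are class-divergent.
#' @param delta_p mean |allele frequency difference| at divergent SNPs.
#' @export
inversion_spec <- function(region, inv_freq = 0.3, divergence = 0.3,
                           delta_p = 0.9) {
  stopifnot(inv_freq >= 0, inv_freq <= 1, divergence >= 0, divergence <= 1,
            delta_p >= 0, delta_p <= 1)
  structure(list(region = region, inv_freq = inv_freq,
                 divergence = divergence, delta_p = delta_p),
            class = "inversion_spec")
}

#' Simulate a population genotype matrix carrying an inversion
#'
#' Haplotypes outside the inversion are independent draws per SNP from the
#' background frequency law (no background LD, so the inversion's block
#' signal is unambiguous). Inside the inversion each haplotype belongs to
#' the inverted (I) or standard (S) arrangement class; divergent SNPs carry
#' class-specific frequencies differing by \code{delta_p}. Diploid
#' inversion genotypes follow Hardy-Weinberg proportions unless
#' \code{hwe_deviation} is set.
#'
#' @param pop a \code{population_spec}.
#' @param inv an \code{inversion_spec} (or NULL for a null genome).
#' @param seed integer seed; generators are deterministic given it.
#' @return list with \code{gm} (a \code{genotype_matrix}) and \code{truth}
#'   (data.frame: sample, inv_genotype = copies of the inverted class).
#' @export
simulate_population_vcf <- function(pop, inv = NULL, seed = 1) {
  with_seed(seed, {
    n <- pop$n_samples
    L <- pop$chrom_length
    m <- round(L / 1000 * pop$snp_density)
    pos <- sort(sample.int(L, m))
    chrom <- rep("chr1", m)
    maf <- pop$maf_sampler(m)
    flip <- runif(m) < 0.5
    p_bg <- ifelse(flip, 1 - maf, maf)

    inv_genotype <- rep(0L, n)
    in_reg <- rep(FALSE, m)
    if (!is.null(inv)) {
      if (inv$region$end > L) stop("inversion region outside chromosome")
      in_reg <- gi_contains_pos(inv$region, chrom, pos)
      q <- inv$inv_freq
      f <- pop$hwe_deviation
      probs <- c((1 - q)^2 + f * q * (1 - q),
                 2 * q * (1 - q) * (1 - f),
                 q^2 + f * q * (1 - q))
      probs <- pmax(probs, 0); probs <- probs / sum(probs)
      inv_genotype <- sample(0:2, n, replace = TRUE, prob = probs)
    }

    # per-class allele frequencies (identical outside region / non-divergent)
    p_I <- p_S <- p_bg
    if (!is.null(inv) && inv$divergence > 0) {
      idx <- which(in_reg)
      div <- idx[runif(length(idx)) < inv$divergence]
      base <- runif(length(div), 0, 1 - inv$delta_p)
      hi_in_I <- runif(length(div)) < 0.5
      p_S[div] <- ifelse(hi_in_I, base, base + inv$delta_p)
      p_I[div] <- ifelse(hi_in_I, base + inv$delta_p, base)
    }

    # two haplotypes per sample; class membership from the inversion genotype
    n_inv_hap <- matrix(0L, nrow = n, ncol = 2)
    n_inv_hap[inv_genotype >= 1, 1] <- 1L
    n_inv_hap[inv_genotype == 2, 2] <- 1L
    dos <- matrix(0, nrow = n, ncol = m)
    for (h in 1:2) {
      cls_I <- n_inv_hap[, h] == 1L
      pmat <- matrix(rep(p_bg, each = n), nrow = n)
      if (any(in_reg)) {
        pmat[cls_I, in_reg] <- rep(p_I[in_reg], each = sum(cls_I))
        pmat[!cls_I, in_reg] <- rep(p_S[in_reg], each = sum(!cls_I))
      }
      dos <- dos + (matrix(runif(n * m), n, m) < pmat)
    }
    ids <- sprintf("S%03d", seq_len(n))
    gm <- genotype_matrix(ids, chrom, pos, rep("A", m), rep("T", m), dos)
    list(gm = gm,
         truth = data.frame(sample = ids, inv_genotype = inv_genotype,
                            stringsAsFactors = FALSE))
  })
}

#' Knock out genotypes at random
#'
#' Sets a fraction of dosage entries to missing, to exercise
#' missing-data handling downstream.
#'
#' @param gm a \code{genotype_matrix}.
#' @param rate per-entry missingness probability.
#' @param seed integer seed.
#' @return a \code{genotype_matrix} with NAs inserted.
#' @export
add_missingness <- function(gm, rate, seed = 1) {
  with_seed(seed, {
    drop <- matrix(runif(length(gm$dosage)) < rate, nrow = nrow(gm$dosage))
    gm$dosage[drop] <- NA
    gm
  })
}

#' F2 intercross simulation spec
#'
#' Emulates an F2 intercross scored at evenly spaced markers. Each F2
#' receives two gametes; a gamete's crossover count over L Mb is
#' Poisson(background_rate * L / 100) with uniform positions (no
#' interference). Gametes from F1 parents heterozygous for an inversion
#' place zero crossovers inside that inversion's interval.
#'
#' @param n_f2 number of F2 individuals.
#' @param chrom_length chromosome length (bp).
#' @param marker_spacing marker spacing (bp), default 100 kb.
#' @param background_rate background recombination rate (cM/Mb).
#' @param inversion_regions \code{genomic_interval} of inversions whose F1
#'   parents are heterozygous (crossovers suppressed), or NULL.
#' @param genotyping_error per-marker probability of miscalling the state.
#' @return a \code{cross_spec} list.
#' @export
cross_spec <- function(n_f2 = 300, chrom_length = 3e7, marker_spacing = 1e5,
                       background_rate = 0.8, inversion_regions = NULL,
                       genotyping_error = 0) {
  stopifnot(n_f2 >= 1, background_rate >= 0,
            genotyping_error >= 0, genotyping_error < 0.5)
  structure(list(n_f2 = n_f2, chrom_length = chrom_length,
                 marker_spacing = marker_spacing,
                 background_rate = background_rate,
                 inversion_regions = inversion_regions,
                 genotyping_error = genotyping_error), class = "cross_spec")
}

#' Simulate an F2 intercross panel
#'
#' @param cross a \code{cross_spec}.
#' @param seed integer seed.
#' @return list with \code{panel} (a \code{cross_panel}: \code{marker_pos},
#'   \code{ancestry} matrix of "AA"/"AB"/"BB") and \code{crossovers}
#'   (data.frame of true crossover positions: individual, gamete, pos).
#' @export
simulate_f2_cross <- function(cross, seed = 1) {
  with_seed(seed, {
    L <- cross$chrom_length
    markers <- seq(cross$marker_spacing, L, by = cross$marker_spacing)
    regs <- cross$inversion_regions
    if (!is.null(regs) && nrow(regs) == 0) regs <- NULL
    # map "free" (recombining) coordinate -> genome coordinate
    if (is.null(regs)) {
      free_len <- L
      to_genome <- function(x) x
    } else {
      regs <- regs[order(regs$start), , drop = FALSE]
      supp <- gi_width(regs)
      free_len <- L - sum(supp)
      starts <- regs$start
      to_genome <- function(x) {
        for (i in seq_along(starts)) x <- ifelse(x >= starts[i], x + supp[i], x)
        x
      }
    }
    rate_morgan <- cross$background_rate * (free_len / 1e6) / 100
    n_gam <- 2 * cross$n_f2
    nco <- rpois(n_gam, rate_morgan)
    co_list <- vector("list", n_gam)
    gam_allele <- matrix(0L, nrow = n_gam, ncol = length(markers))
    start_allele <- rbinom(n_gam, 1, 0.5)
    for (g in seq_len(n_gam)) {
      a <- start_allele[g]
      if (nco[g] > 0) {
        xpos <- sort(to_genome(runif(nco[g], 0, free_len)))
        co_list[[g]] <- data.frame(individual = ((g - 1) %/% 2) + 1,
                                   gamete = ((g - 1) %% 2) + 1, pos = xpos)
        nflip <- findInterval(markers, xpos)
        gam_allele[g, ] <- (a + nflip) %% 2
      } else {
        gam_allele[g, ] <- a
      }
    }
    co_list <- co_list[!vapply(co_list, is.null, logical(1))]
    co <- if (length(co_list)) do.call(rbind, co_list) else
      data.frame(individual = integer(0), gamete = integer(0),
                 pos = numeric(0))
    state <- gam_allele[seq(1, n_gam, 2), , drop = FALSE] +
      gam_allele[seq(2, n_gam, 2), , drop = FALSE]
    codes <- c("AA", "AB", "BB")
    anc <- matrix(codes[state + 1], nrow = cross$n_f2)
    if (cross$genotyping_error > 0) {
      err <- matrix(runif(length(anc)) < cross$genotyping_error, nrow(anc))
      wrong <- vapply(anc[err], function(s) sample(setdiff(codes, s), 1),
                      character(1))
      anc[err] <- wrong
    }
    rownames(anc) <- sprintf("F2_%04d", seq_len(cross$n_f2))
    panel <- structure(list(chrom = "chr1", marker_pos = markers,
                            ancestry = anc), class = "cross_panel")
    list(panel = panel, crossovers = co)
  })
}

#' Geographic cline model
#'
#' Sigmoid allele-frequency cline along a one-dimensional gradient:
#' p(x) = pMin + (pMax - pMin) * (1 + tanh(2 (x - c) / w)) / 2, optionally
#' with exponential tails starting delta km from the centre, with slope
#' ratio tau at the junction (value- and slope-continuous).
#'
#' @param pMin,pMax asymptotic frequencies (0 <= pMin <= pMax <= 1).
#' @param centre cline centre c (km).
#' @param width cline width w (km), > 0.
#' @param tails one of "none", "left", "right", "mirror", "both".
#' @param deltaL,tauL,deltaR,tauR tail distance (km) and slope ratio for
#'   the left/right tails ("mirror" shares deltaL/tauL on both sides).
#' @return a \code{cline_model} list.
#' @export
cline_model <- function(pMin = 0, pMax = 1, centre, width,
                        tails = c("none", "left", "right", "mirror", "both"),
                        deltaL = NA, tauL = NA, deltaR = NA, tauR = NA) {
  tails <- match.arg(tails)
  stopifnot(pMin >= 0, pMax <= 1, pMin <= pMax, width > 0)
  structure(list(pMin = pMin, pMax = pMax, centre = centre, width = width,
                 tails = tails, deltaL = deltaL, tauL = tauL,
                 deltaR = deltaR, tauR = tauR), class = "cline_model")
}

#' Transect sampling spec
#'
#' @param site_positions strictly increasing distances along the gradient (km).
#' @param n_per_site diploids sampled per site (scalar or per-site vector).
#' @param true_cline the generating \code{cline_model}.
#' @return a \code{transect_spec} list.
#' @export
transect_spec <- function(site_positions, n_per_site, true_cline) {
  stopifnot(!is.unsorted(site_positions, strictly = TRUE),
            all(n_per_site >= 1))
  structure(list(site_positions = site_positions,
                 n_per_site = rep(n_per_site, length.out =
                                    length(site_positions)),
                 true_cline = true_cline), class = "transect_spec")
}

#' Simulate allele counts along a transect
#'
#' At site x the alternate-allele count is Binomial(2 n, p(x)) with p(x)
#' from the generating cline.
#'
#' @param t a \code{transect_spec}.
#' @param seed integer seed.
#' @return data.frame: dist_km, n_alleles, alt_count.
#' @export
simulate_transect_counts <- function(t, seed = 1) {
  with_seed(seed, {
    p <- cline_predict(t$true_cline, t$site_positions)
    n_alleles <- 2 * t$n_per_site
    data.frame(dist_km = t$site_positions, n_alleles = n_alleles,
               alt_count = rbinom(length(p), n_alleles, p))
  })
}

#' Simulate phenotypes with an additive inversion effect
#'
#' y = a g + b body_length + e, with e ~ N(0, noise_sd^2). Body length is
#' drawn N(92, 6) mm (typical adult deer-mouse body length). Defaults give
#' a field-scale scenario: a = 2.7 mm (the largest reported additive
#' tail-length effect) with noise_sd = 4.8 mm, which at an F2 genotype
#' variance of 0.5 yields ~12.5% variance explained, the top of the
#' reported per-inversion range.
#'
#' @param genotypes integer vector of inversion dosages (0/1/2).
#' @param additive_effect a, trait units per inverted-arrangement copy.
#' @param covariate_effect b, trait units per mm body length.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return data.frame: sample, genotype, body_length, trait.
#' @export
simulate_phenotypes <- function(genotypes, additive_effect = 2.7,
                                covariate_effect = 0.25, noise_sd = 4.8,
                                seed = 1) {
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    n <- length(genotypes)
    body <- rnorm(n, 92, 6)
    y <- additive_effect * genotypes + covariate_effect * body +
      rnorm(n, 0, noise_sd)
    data.frame(sample = sprintf("F2_%04d", seq_len(n)),
               genotype = genotypes, body_length = body, trait = y)
  })
}
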