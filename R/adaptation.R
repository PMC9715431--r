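#' Two-deme Wright-Fisher parameters
#'
#' Parameters for the forest/prairie divergent-selection simulation. The
#' demographic defaults are config placeholders (they are not fitted
#' forest-prairie estimates); the split-time default of 2.2e6 generations
#' is the reported forest-prairie divergence time. Times and sizes are in
#' unscaled units; apply \code{\link{scale_params}} for rescaled runs.
#'
#' @param N_forest,N_prairie diploid population sizes.
#' @param m symmetric per-generation migration fraction.
#' @param s_forest,s_prairie selection coefficients on the inverted
#'   arrangement in each deme (deer-mouse analyses scan -0.01..0.01).
#' @param h dominance (default 0.5, genic selection).
#' @param t_intro generations before present at which the allele appears.
#' @param intro_pop "forest" or "prairie".
#' @param intro_freq introduction frequency; NULL = single copy, 1/(2N)
#'   of the introduction deme at the current (unscaled) size.
#' @param lambda scaling factor applied so far (1 = unscaled).
#' @param t_split forest-prairie split time (generations).
#' @return a \code{wf_params} list.
#' @export
wf_params <- function(N_forest = 1e4, N_prairie = 1e4, m = 1e-3,
                      s_forest = 0, s_prairie = 0, h = 0.5,
                      t_intro = 1.5e4, intro_pop = c("forest", "prairie"),
                      intro_freq = NULL, lambda = 1, t_split = 2.2e6) {
  intro_pop <- match.arg(intro_pop)
  stopifnot(m >= 0, m <= 1, h >= 0, h <= 1, lambda >= 1,
            t_intro <= t_split, N_forest >= 1, N_prairie >= 1)
  structure(list(N_forest = N_forest, N_prairie = N_prairie, m = m,
                 s_forest = s_forest, s_prairie = s_prairie, h = h,
                 t_intro = t_intro, intro_pop = intro_pop,
                 intro_freq = intro_freq, lambda = lambda,
                 t_split = t_split), class = "wf_params")
}

#' Rescale Wright-Fisher parameters
#'
#' The standard rescaling scheme (factor 100): population sizes and times divided
#' by lambda, migration and selection coefficients multiplied by lambda,
#' keeping N m and N s invariant. The introduction frequency is a
#' frequency and is left unchanged (materialized as 1/(2N) of the
#' pre-scaling introduction deme if unset). Errors if the scaled m exceeds
#' 1 or |scaled s| exceeds \code{max_scaled_s}.
#'
#' @param p a \code{wf_params} (unscaled).
#' @param lambda scaling factor (100 is the conventional factor).
#' @param max_scaled_s bound on |s * lambda| (default 1, the post-scaling
#'   extreme of the -0.01..0.01 grid at factor 100).
#' @return a scaled \code{wf_params}.
#' @export
scale_params <- function(p, lambda, max_scaled_s = 1) {
  stopifnot(inherits(p, "wf_params"), lambda >= 1)
  if (p$m * lambda > 1) stop("scaled migration rate exceeds 1")
  if (max(abs(c(p$s_forest, p$s_prairie))) * lambda > max_scaled_s)
    stop("scaled selection coefficient exceeds bound")
  intro_N <- if (p$intro_pop == "forest") p$N_forest else p$N_prairie
  intro_freq <- if (is.null(p$intro_freq)) 1 / (2 * intro_N) else p$intro_freq
  wf_params(N_forest = p$N_forest / lambda, N_prairie = p$N_prairie / lambda,
            m = p$m * lambda, s_forest = p$s_forest * lambda,
            s_prairie = p$s_prairie * lambda, h = p$h,
            t_intro = p$t_intro / lambda, intro_pop = p$intro_pop,
            intro_freq = intro_freq, lambda = p$lambda * lambda,
            t_split = p$t_split / lambda)
}

#' Two-deme Wright-Fisher forward simulation
#'
#' Discrete generations with the life cycle selection -> migration ->
#' binomial drift (the order matters at large scaled s and is fixed).
#' Selection: p* = (p^2 w_AA + p(1-p) w_Aa) / w_bar with w_AA = 1 + s,
#' w_Aa = 1 + h s, w_aa = 1. Migration is symmetric and simultaneous.
#' Drift samples 2N alleles per deme; an infinite N switches drift off
#' (deterministic recursion). The allele starts at \code{intro_freq}
#' (default a single copy) in the introduction deme, 0 in the other, and
#' the simulation runs \code{t_intro} generations; lost replicates end at
#' frequency 0. All replicates run vectorized.
#'
#' @param p a \code{wf_params} (already scaled if desired).
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return list: \code{p_forest}, \code{p_prairie} (final frequencies per
#'   replicate).
#' @export
wf_two_pop_sim <- function(p, n_reps, seed = 1) {
  stopifnot(inherits(p, "wf_params"), n_reps >= 1)
  with_seed(seed, {
    Nf <- p$N_forest; Np <- p$N_prairie
    f0 <- if (is.null(p$intro_freq)) {
      1 / (2 * (if (p$intro_pop == "forest") Nf else Np))
    } else p$intro_freq
    pf <- rep(if (p$intro_pop == "forest") f0 else 0, n_reps)
    pp <- rep(if (p$intro_pop == "prairie") f0 else 0, n_reps)
    sel <- function(q, s, h) {
      if (s == 0) return(q)
      waa <- 1 + s; wah <- 1 + h * s
      wbar <- q^2 * waa + 2 * q * (1 - q) * wah + (1 - q)^2
      (q^2 * waa + q * (1 - q) * wah) / wbar
    }
    t_gen <- round(p$t_intro)
    for (gen in seq_len(t_gen)) {
      pf <- sel(pf, p$s_forest, p$h)
      pp <- sel(pp, p$s_prairie, p$h)
      pf_new <- (1 - p$m) * pf + p$m * pp
      pp_new <- (1 - p$m) * pp + p$m * pf
      pf <- pf_new; pp <- pp_new
      if (is.finite(Nf)) pf <- rbinom(n_reps, round(2 * Nf), pf) / round(2 * Nf)
      if (is.finite(Np)) pp <- rbinom(n_reps, round(2 * Np), pp) / round(2 * Np)
    }
    list(p_forest = pf, p_prairie = pp)
  })
}

#' Probability of a large between-deme frequency difference
#'
#' Fraction of replicates whose final absolute forest-prairie frequency
#' difference exceeds the threshold (50\% is the conventional criterion for
#' ecotype-differentiating loci).
#'
#' @param final result of \code{\link{wf_two_pop_sim}}.
#' @param threshold difference threshold (default 0.5).
#' @return probability in [0,1].
#' @export
prob_freq_diff <- function(final, threshold = 0.5) {
  stopifnot(length(final$p_forest) >= 1)
  mean(abs(final$p_forest - final$p_prairie) > threshold)
}
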