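#' Additive genotype-phenotype association
#'
#' Least-squares fit of trait ~ (covariate +) genotype with genotype coded
#' numerically 0/1/2 (additive model). The genotype p-value comes from the
#' analysis-of-variance decomposition (covariate entered first, so the
#' genotype sum of squares is covariate-adjusted); PVE is the genotype sum
#' of squares as a percentage of the total. Bonferroni correction
#' multiplies the raw p by \code{n_tests} (13 inversions in the deer-mouse
#' ecotype screen), capped at 1.
#'
#' @param genotypes integer dosages (0/1/2; NA dropped with the row).
#' @param trait numeric trait values.
#' @param covariate optional numeric covariate (e.g. body length for tail
#'   and foot length).
#' @param n_tests Bonferroni family size (default 13).
#' @return an \code{assoc_result} list: \code{beta} (trait units per
#'   copy), \code{se}, \code{p_raw}, \code{p_bonferroni}, \code{pve}
#'   (percent), \code{n}, \code{degenerate}.
#' @export
assoc_additive <- function(genotypes, trait, covariate = NULL, n_tests = 13) {
  df <- data.frame(g = as.numeric(genotypes), y = trait)
  if (!is.null(covariate)) df$cov <- covariate
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3) stop("need >= 3 non-missing samples")
  if (stats::var(df$g) == 0)
    return(structure(list(beta = NA_real_, se = NA_real_, p_raw = NA_real_,
                          p_bonferroni = NA_real_, pve = NA_real_,
                          n = nrow(df), degenerate = TRUE),
                     class = "assoc_result"))
  fit <- if (is.null(covariate)) stats::lm(y ~ g, data = df)
         else stats::lm(y ~ cov + g, data = df)
  an <- stats::anova(fit)
  grow <- which(rownames(an) == "g")
  ss_total <- sum(an[["Sum Sq"]])
  pve <- 100 * an[["Sum Sq"]][grow] / ss_total
  coefs <- summary(fit)$coefficients
  p_raw <- an[["Pr(>F)"]][grow]
  structure(list(beta = coefs["g", "Estimate"], se = coefs["g", "Std. Error"],
                 p_raw = p_raw, p_bonferroni = min(1, n_tests * p_raw),
                 pve = pve, n = nrow(df), degenerate = FALSE),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (x$degenerate) { cat("assoc_result: degenerate (constant genotype)\n")
    return(invisible(x)) }
  cat(sprintf(
    "assoc_result: beta = %.3f (se %.3f), PVE = %.1f%%, p = %.3g (Bonferroni %.3g), n = %d\n",
    x$beta, x$se, x$pve, x$p_raw, x$p_bonferroni, x$n))
  invisible(x)
}
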