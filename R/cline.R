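#' Predict allele frequency along a cline
#'
#' Centre sigmoid p(x) = pMin + (pMax - pMin) (1 + tanh(2 (x - c)/w)) / 2.
#' With tails, beyond delta km from the centre the sigmoid hands over to
#' an exponential that matches the sigmoid's value at the junction and
#' decays with tau times its slope there (slope-ratio form), so the curve
#' is continuous (and tau = 1 keeps the slope continuous too). "mirror"
#' applies the left tail's delta/tau on both sides.
#'
#' @param model a \code{cline_model}.
#' @param x positions along the gradient (km).
#' @return predicted frequencies in [pMin, pMax].
#' @export
cline_predict <- function(model, x) {
  cc <- model$centre; w <- model$width
  S <- function(z) (1 + tanh(2 * (z - cc) / w)) / 2
  Sp <- function(z) (1 / w) / cosh(2 * (z - cc) / w)^2
  f <- S(x)
  tails <- model$tails
  if (tails %in% c("left", "mirror", "both") && is.finite(model$deltaL)) {
    xL <- cc - model$deltaL
    vL <- S(xL)
    if (vL > 0) {
      rate <- model$tauL * Sp(xL) / vL
      sel <- x < xL
      f[sel] <- vL * exp(rate * (x[sel] - xL))
    }
  }
  if (tails %in% c("right", "mirror", "both")) {
    dR <- if (tails == "mirror") model$deltaL else model$deltaR
    tR <- if (tails == "mirror") model$tauL else model$tauR
    if (is.finite(dR)) {
      xR <- cc + dR
      gR <- 1 - S(xR)
      if (gR > 0) {
        rate <- tR * Sp(xR) / gR
        sel <- x > xR
        f[sel] <- 1 - gR * exp(-rate * (x[sel] - xR))
      }
    }
  }
  model$pMin + (model$pMax - model$pMin) * f
}

#' AICc (small-sample Akaike information criterion)
#'
#' AICc = -2 lnL + 2 k + 2 k (k + 1) / (n - k - 1); undefined (NA) when
#' n <= k + 1.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations (sites).
#' @return AICc value, or NA when undefined.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

cline_families <- function() {
  expand.grid(scaling = c("fixed", "free"),
              tails = c("none", "left", "right", "mirror", "both"),
              stringsAsFactors = FALSE)
}

# binomial log-likelihood of counts under a cline model
cline_loglik <- function(model, counts) {
  p <- cline_predict(model, counts$dist_km)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(counts$alt_count * log(p) +
        (counts$n_alleles - counts$alt_count) * log(1 - p))
}

#' Fit geographic cline models by maximum likelihood and rank by AICc
#'
#' Fits the ten standard cline families (scaling fixed/free x tails
#' none/left/right/mirror/both) to per-site allele counts by maximizing
#' the binomial log-likelihood with bounded multi-start L-BFGS-B (20
#' random restarts per family, plus warm starts from the same-scaling
#' untailed fit for tailed families). "fixed" scaling pins pMin/pMax at
#' the terminal-site frequencies; "free" estimates them. Families
#' whose parameter count k satisfies n_sites <= k + 1 are skipped (AICc
#' undefined). The best family minimizes AICc.
#'
#' @param counts data.frame: dist_km, n_alleles, alt_count (>= 3 sites).
#' @param families optional subset of rows of the family grid (default
#'   all ten).
#' @param n_restarts random restarts per family (default 20).
#' @param seed integer seed for the restarts.
#' @return list: \code{best} (family label), \code{table} (data.frame
#'   family, scaling, tails, k, logLik, AICc) and \code{fits} (named list
#'   of fitted \code{cline_model}s).
#' @export
fit_cline <- function(counts, families = cline_families(), n_restarts = 20,
                      seed = 1) {
  stopifnot(nrow(counts) >= 3,
            all(c("dist_km", "n_alleles", "alt_count") %in% names(counts)))
  x <- counts$dist_km
  R <- diff(range(x)); if (R <= 0) stop("sites must span a gradient")
  p_obs <- counts$alt_count / counts$n_alleles
  n_sites <- nrow(counts)
  build <- function(theta, scaling, tails) {
    i <- 0
    nxt <- function() { i <<- i + 1; theta[i] }
    cc <- nxt(); w <- nxt()
    if (scaling == "free") { a <- nxt(); b <- nxt()
      pMin <- min(a, b); pMax <- max(a, b)
    } else {
      # "fixed" pins the asymptotes at the terminal-site frequencies
      # (min/max over all sites would chase single-site sampling noise)
      ends <- p_obs[c(which.min(x), which.max(x))]
      pMin <- min(ends); pMax <- max(ends)
    }
    dL <- tL <- dR <- tR <- NA
    if (tails %in% c("left", "mirror", "both")) { dL <- nxt(); tL <- nxt() }
    if (tails %in% c("right", "both")) { dR <- nxt(); tR <- nxt() }
    cline_model(pMin = pMin, pMax = pMax, centre = cc, width = w,
                tails = tails, deltaL = dL, tauL = tL,
                deltaR = dR, tauR = tR)
  }
  bounds <- function(scaling, tails) {
    lo <- c(min(x) - R, R / 100); hi <- c(max(x) + R, 10 * R)
    if (scaling == "free") { lo <- c(lo, 0, 0); hi <- c(hi, 1, 1) }
    if (tails %in% c("left", "mirror", "both")) {
      lo <- c(lo, 0, 1e-3); hi <- c(hi, 2 * R, 1) }
    if (tails %in% c("right", "both")) {
      lo <- c(lo, 0, 1e-3); hi <- c(hi, 2 * R, 1) }
    list(lo = lo, hi = hi)
  }
  tab <- cline_families()[0, ]
  tab$k <- tab$logLik <- tab$AICc <- numeric(0)
  fits <- list()
  rows <- list()
  with_seed(seed, {
    for (fi in seq_len(nrow(families))) {
      scaling <- families$scaling[fi]; tails <- families$tails[fi]
      b <- bounds(scaling, tails)
      k <- length(b$lo)
      fam <- paste(scaling, tails, sep = "/")
      if (n_sites - k - 1 <= 0) {
        rows[[fam]] <- data.frame(family = fam, scaling = scaling,
                                  tails = tails, k = k, logLik = NA_real_,
                                  AICc = NA_real_)
        next
      }
      negll <- function(theta)
        -cline_loglik(build(theta, scaling, tails), counts)
      # random restarts plus a warm start from the same-scaling no-tail fit
      # (tail likelihood surfaces have narrow basins; starting at the plain
      # sigmoid with small tails reliably reaches them)
      starts <- lapply(seq_len(n_restarts), function(r)
        b$lo + runif(k) * (b$hi - b$lo))
      plain <- fits[[paste(scaling, "none", sep = "/")]]
      if (!is.null(plain) && tails != "none") {
        th <- c(plain$centre, plain$width)
        if (scaling == "free") th <- c(th, plain$pMin, plain$pMax)
        n_tail_pairs <- (k - length(th)) / 2
        for (dd in c(R / 20, R / 5)) for (tt in c(0.05, 0.5))
          starts[[length(starts) + 1L]] <-
            pmin(pmax(c(th, rep(c(dd, tt), n_tail_pairs)), b$lo), b$hi)
      }
      best <- NULL
      for (th0 in starts) {
        fit <- tryCatch(stats::optim(th0, negll, method = "L-BFGS-B",
                                     lower = b$lo, upper = b$hi),
                        error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
          best <- fit
      }
      if (is.null(best)) next
      ll <- -best$value
      rows[[fam]] <- data.frame(family = fam, scaling = scaling,
                                tails = tails, k = k, logLik = ll,
                                AICc = aicc(ll, k, n_sites))
      fits[[fam]] <- build(best$par, scaling, tails)
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (all(is.na(tab$AICc))) stop("no cline family could be fit")
  best_fam <- tab$family[which.min(tab$AICc)]
  list(best = best_fam, table = tab, fits = fits)
}
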