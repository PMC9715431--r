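#' Local PCA for one genomic window
#'
#' Computes the top-k eigenpairs of the sample-by-sample covariance of the
#' window's genotypes. Missing dosages are mean-imputed per SNP, dosages
#' are mean-centred per SNP, and monomorphic sites are dropped. Eigenvalues
#' are returned divided by the covariance trace (total variance), which
#' makes windows with different SNP counts comparable in the map-distance
#' step.
#'
#' @param gm a \code{genotype_matrix}.
#' @param window single-row \code{genomic_interval}.
#' @param k number of components to keep (default 2, the scan's setting).
#' @param min_snps minimum polymorphic SNPs; below it the window is flagged
#'   excluded rather than raising an error.
#' @return a \code{window_pca} list: \code{window}, \code{values}
#'   (normalized eigenvalues, length k), \code{vectors} (samples x k,
#'   unit-norm), \code{total_variance}, \code{n_snps}, \code{excluded}.
#' @export
window_pca <- function(gm, window, k = 2, min_snps = 10) {
  sub <- gm_subset(gm, region = window)
  X <- sub$dosage
  # mean-impute missing, then drop monomorphic sites
  if (ncol(X) > 0) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- mu[idx[, 2]]
    X <- X[, apply(X, 2, function(v) stats::var(v) > 0), drop = FALSE]
  }
  if (ncol(X) < min_snps)
    return(structure(list(window = window, excluded = TRUE,
                          n_snps = ncol(X)), class = "window_pca"))
  Xc <- sweep(X, 2, colMeans(X))
  C <- tcrossprod(Xc)
  tot <- sum(diag(C))
  if (tot <= 0)
    return(structure(list(window = window, excluded = TRUE,
                          n_snps = ncol(X)), class = "window_pca"))
  e <- eigen(C, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(window = window,
                 values = pmax(e$values[seq_len(k)], 0) / tot,
                 vectors = vec, total_variance = tot,
                 n_snps = ncol(X), excluded = FALSE),
            class = "window_pca")
}

#' Distance between two local-PCA maps
#'
#' The squared distance between the rank-k covariance approximations of two
#' windows, using trace-normalized eigenvalues:
#' d^2 = sum(lambda_a^2) + sum(lambda_b^2)
#'       - 2 sum_{a,b} lambda_a lambda_b (u_a . u_b)^2,
#' which equals the squared Frobenius distance between the two normalized
#' rank-k covariance reconstructions. The returned value is d (>= 0).
#'
#' @param a,b \code{window_pca} objects over the same samples and k.
#' @return non-negative distance.
#' @export
pca_map_distance <- function(a, b) {
  if (a$excluded || b$excluded) stop("cannot compare excluded windows")
  if (nrow(a$vectors) != nrow(b$vectors) ||
      ncol(a$vectors) != ncol(b$vectors))
    stop("windows have mismatched sample sets or k")
  cross <- crossprod(a$vectors, b$vectors)  # k x k of u_a . u_b
  d2 <- sum(a$values^2) + sum(b$values^2) -
    2 * as.numeric(t(a$values) %*% (cross^2) %*% b$values)
  sqrt(max(d2, 0))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric zero-diagonal distance matrix via
#' \code{stats::cmdscale} (double-centring of -D^2/2 and eigendecomposition);
#' axes associated with negative eigenvalues are truncated to zero. Axis
#' sign indeterminacy is resolved by making the largest-magnitude
#' coordinate on each axis positive.
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @param dims number of axes (default 2).
#' @return list with \code{points} (n x dims) and \code{eig} (all
#'   eigenvalues of the doubly centred matrix, descending).
#' @export
classical_mds <- function(D, dims = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  # cmdscale warns when fewer than k eigenvalues are positive; that case is
  # legitimate here (degenerate distance matrices) and handled below
  fit <- suppressWarnings(stats::cmdscale(D, k = min(dims, nrow(D) - 1),
                                          eig = TRUE))
  pts <- matrix(0, nrow = nrow(D), ncol = dims)
  got <- min(ncol(fit$points), dims)
  if (got > 0) pts[, seq_len(got)] <- fit$points
  for (j in seq_len(dims)) {
    if (j <= length(fit$eig) && fit$eig[j] <= 0) pts[, j] <- 0
    if (any(pts[, j] != 0)) {
      i <- which.max(abs(pts[, j]))
      if (pts[i, j] < 0) pts[, j] <- -pts[, j]
    }
  }
  list(points = pts, eig = fit$eig)
}

# mean silhouette over all points (Euclidean); s(i) = 0 for singleton
# clusters, following the textbook definition
silhouette_mean <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' k-means clustering of windows in MDS space with silhouette model choice
#'
#' Runs k-means on the (MDS1, MDS2) coordinates for each k in
#' \code{k_range} (default 2..10) with multi-restart, picks the k with the
#' maximum mean silhouette score (ties broken toward smaller k), and
#' returns the labels for that k. k values exceeding n-1 windows are
#' skipped.
#'
#' @param points matrix of window coordinates (n x 2).
#' @param k_range candidate cluster counts.
#' @param seed integer seed (k-means restarts are seeded from it).
#' @param nstart restarts per k.
#' @return list: \code{labels}, \code{k}, \code{silhouette} (named vector).
#' @export
cluster_windows <- function(points, k_range = 2:10, seed = 1, nstart = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  k_range <- k_range[k_range <= n - 1 & k_range >= 2]
  if (!length(k_range)) stop("too few windows to cluster")
  with_seed(seed, {
    fits <- list(); sil <- setNames(rep(NA_real_, length(k_range)),
                                    as.character(k_range))
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      fit <- tryCatch(stats::kmeans(points, centers = k, nstart = nstart,
                                    iter.max = 50),
                      error = function(e) NULL)
      if (is.null(fit)) next
      fits[[as.character(k)]] <- fit
      sil[i] <- silhouette_mean(points, fit$cluster)
    }
    if (all(is.na(sil))) stop("k-means failed for all k")
    best <- k_range[which.max(sil)]  # which.max takes the first (smallest k) tie
    list(labels = fits[[as.character(best)]]$cluster, k = best,
         silhouette = sil)
  })
}

#' Find outlier regions from the MDS scan
#'
#' A candidate region is a maximal run of consecutive same-chromosome
#' windows sharing a cluster label that contains at least \code{min_run}
#' consecutive windows with MDS1 z-score above \code{z_thresh}. The
#' reported region spans from the first to the last window of the run that
#' exceeds the threshold, so isolated interior windows whose z-score dips
#' below it do not fragment a region, while sub-threshold windows at the
#' run's edges are trimmed. Excluded (low-SNP) windows break runs. The
#' z-score is computed genome-wide over all included windows.
#'
#' @param windows \code{genomic_interval} of all scan windows (in order).
#' @param z1 per-window z-scores (NA for excluded windows).
#' @param labels per-window cluster labels (NA for excluded windows).
#' @param z_thresh z-score threshold (default 1.5, one-sided).
#' @param min_run minimum consecutive high-z windows (default 10).
#' @return list of \code{outlier_region} objects: \code{region},
#'   \code{window_indices} (first to last high-z window of the run),
#'   \code{cluster_id}, \code{max_run_length} (longest consecutive high-z
#'   stretch).
#' @export
find_outlier_regions <- function(windows, z1, labels, z_thresh = 1.5,
                                 min_run = 10) {
  n <- nrow(windows)
  stopifnot(length(z1) == n, length(labels) == n)
  qual <- !is.na(z1) & !is.na(labels) & z1 > z_thresh
  out <- list()
  i <- 1
  while (i <= n) {
    if (is.na(labels[i])) { i <- i + 1; next }
    j <- i
    while (j + 1 <= n && !is.na(labels[j + 1]) &&
           labels[j + 1] == labels[i] &&
           windows$chrom[j + 1] == windows$chrom[i]) j <- j + 1
    hi <- which(qual[i:j]) + i - 1L
    if (length(hi)) {
      # longest consecutive high-z stretch within the cluster run
      r <- rle(qual[i:j])
      longest <- max(r$lengths[r$values])
      if (longest >= min_run) {
        a <- min(hi); b <- max(hi)
        out[[length(out) + 1L]] <- structure(
          list(region = gi(windows$chrom[a], windows$start[a],
                           windows$end[b]),
               window_indices = a:b, cluster_id = labels[i],
               max_run_length = as.integer(longest)),
          class = "outlier_region")
      }
    }
    i <- j + 1
  }
  out
}

#' Genome scan for inversion-like outlier regions
#'
#' The full local-PCA pipeline: window the genome, compute per-window PCA
#' (top two components), measure distances between PCA maps, embed with
#' classical MDS, cluster windows by k-means with silhouette-selected k,
#' z-score MDS1 and report runs of at least \code{min_run} consecutive
#' same-cluster windows with z > \code{z_thresh}.
#'
#' @param gm a \code{genotype_matrix}.
#' @param window_size,step window size and step in bp (default 100 kb each).
#' @param min_snps windows with fewer polymorphic SNPs are excluded.
#' @param k_range candidate k for k-means.
#' @param z_thresh,min_run outlier-run thresholds.
#' @param seed integer seed (clustering restarts).
#' @param chrom_lengths optional named vector; defaults to max position
#'   per chromosome.
#' @return list: \code{regions} (outlier_region list) and \code{window_table}
#'   (data.frame: chrom, start, end, n_snps, included, mds1, mds2, z1,
#'   cluster).
#' @export
scan_inversions <- function(gm, window_size = 1e5, step = window_size,
                            min_snps = 10, k_range = 2:10, z_thresh = 1.5,
                            min_run = 10, seed = 1, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(unique(gm$chrom),
                            function(ch) max(gm$pos[gm$chrom == ch]),
                            numeric(1))
  }
  windows <- make_windows(chrom_lengths, window_size, step)
  pcas <- lapply(seq_len(nrow(windows)),
                 function(i) window_pca(gm, windows[i, ], k = 2,
                                        min_snps = min_snps))
  included <- !vapply(pcas, function(p) p$excluded, logical(1))
  M <- sum(included)
  if (M < max(3, min(k_range) + 1)) stop("too few usable windows for the scan")
  D <- pca_pairwise_distances(pcas[included])
  mds <- classical_mds(D, dims = 2)
  cl <- cluster_windows(mds$points, k_range = k_range, seed = seed)
  z1_inc <- as.numeric(scale(mds$points[, 1]))
  tab <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end,
                    n_snps = vapply(pcas, function(p) as.numeric(p$n_snps),
                                    numeric(1)),
                    included = included,
                    mds1 = NA_real_, mds2 = NA_real_, z1 = NA_real_,
                    cluster = NA_integer_)
  tab$mds1[included] <- mds$points[, 1]
  tab$mds2[included] <- mds$points[, 2]
  tab$z1[included] <- z1_inc
  tab$cluster[included] <- cl$labels
  regions <- find_outlier_regions(windows, tab$z1, tab$cluster,
                                  z_thresh = z_thresh, min_run = min_run)
  list(regions = regions, window_table = tab, k = cl$k,
       silhouette = cl$silhouette)
}

# all-pairs pca_map_distance, vectorized over the stacked weighted
# eigenvector matrices: d^2(a,b) = s_a + s_b - 2 ||W_a' W_b||_F^2 with
# W_i = U_i diag(sqrt(lambda_i)), s_i = sum(lambda_i^2)
pca_pairwise_distances <- function(pcas) {
  M <- length(pcas)
  k <- ncol(pcas[[1]]$vectors)
  W <- do.call(cbind, lapply(pcas, function(p)
    p$vectors %*% diag(sqrt(p$values), nrow = k)))
  G2 <- crossprod(W)^2                        # (kM x kM)
  E <- matrix(0, nrow = k * M, ncol = M)
  E[cbind(seq_len(k * M), rep(seq_len(M), each = k))] <- 1
  R <- t(E) %*% G2 %*% E                      # M x M block Frobenius^2
  s <- vapply(pcas, function(p) sum(p$values^2), numeric(1))
  D2 <- outer(s, s, "+") - 2 * R
  D <- sqrt(pmax(D2, 0))
  diag(D) <- 0
  D
}
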