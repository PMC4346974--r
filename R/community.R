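#' Pairwise Bray-Curtis dissimilarity
#'
#' Computes `d[i,j] = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` between all
#' sample pairs of a relative-abundance matrix. Bray-Curtis is bounded in
#' \[0, 1\] for non-negative data, with 0 for identical compositions and 1
#' for disjoint ones; it is not a metric (no triangle inequality).
#'
#' @param rel_abund non-negative numeric matrix, samples as rows. Intended
#'   input is the output of [standardize()]; a warning is issued if rows do
#'   not sum to 1.
#' @return a [stats::dist] object with sample labels.
#' @export
bray_curtis <- function(rel_abund) {
  if (!is.matrix(rel_abund) || !is.numeric(rel_abund)) {
    stop("rel_abund must be a numeric matrix (samples x OTUs)", call. = FALSE)
  }
  if (any(rel_abund < 0)) stop("negative abundances", call. = FALSE)
  totals <- rowSums(rel_abund)
  if (any(totals == 0)) {
    stop("sample(s) with all-zero abundance: ",
         paste(rownames(rel_abund)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(abs(totals - 1) > 1e-6)) {
    warning("rows do not sum to 1; did you call standardize() first?")
  }
  vegan::vegdist(rel_abund, method = "bray")
}

# Kruskal stress-1 of a configuration against target dissimilarities,
# using least-squares monotone (isotonic) regression of configuration
# distances on the dissimilarities.
.kruskal_stress <- function(d, coords) {
  dd <- as.vector(stats::as.dist(d))
  e <- as.vector(stats::dist(coords))
  ord <- order(dd, e)
  fit <- stats::isoreg(seq_along(ord), e[ord])
  sqrt(sum((e[ord] - fit$yf)^2) / sum(e^2))
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal
#' stress-1 with monotone regression (via [vegan::monoMDS()], global model,
#' primary tie treatment). Because the stress surface is multimodal, the
#' optimizer is run from one metric (principal-coordinate) start plus
#' `n_restarts` random starts, and the lowest-stress solution is returned.
#' Fully deterministic given `seed`.
#'
#' @param d a [stats::dist] object or symmetric dissimilarity matrix.
#' @param k number of ordination axes (must be < number of samples).
#' @param n_restarts number of random restarts in addition to the metric
#'   start.
#' @param max_iter maximum optimizer iterations per start.
#' @param tol relative stress-improvement convergence tolerance.
#' @param seed integer seed controlling the random starts.
#' @return an object of class `nmds_result`: list with `coordinates`
#'   (centered, samples x k), `stress` (Kruskal stress-1), `converged`,
#'   `n_restarts_used`, `seed`, and `restart_stress` (a data.frame with the
#'   initial and final stress of every start).
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 500, tol = 1e-6,
                 seed = 1) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("d must be symmetric", call. = FALSE)
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) stop("d must be a dist or symmetric matrix",
                                 call. = FALSE)
  n <- attr(d, "Size")
  .assert_scalar(k, "k", lower = 1, integer = TRUE)
  if (k >= n) stop("k must be smaller than the number of samples",
                   call. = FALSE)
  .assert_scalar(n_restarts, "n_restarts", lower = 0, integer = TRUE)

  fits <- withr::with_seed(seed, {
    inits <- vector("list", n_restarts + 1L)
    pcoa <- suppressWarnings(stats::cmdscale(d, k = k))
    if (ncol(pcoa) < k) {
      pcoa <- cbind(pcoa, matrix(stats::runif(n * (k - ncol(pcoa)), -1e-3,
                                              1e-3), nrow = n))
    }
    inits[[1L]] <- pcoa
    scale0 <- max(as.vector(d))
    for (r in seq_len(n_restarts)) {
      inits[[r + 1L]] <- matrix(stats::runif(n * k, -scale0, scale0),
                                nrow = n)
    }
    lapply(inits, function(y) {
      fit <- vegan::monoMDS(d, y = y, k = k, model = "global",
                            maxit = max_iter, smin = 1e-8, sfgrmin = 1e-9,
                            sratmax = 1 - tol)
      list(fit = fit, initial_stress = .kruskal_stress(d, y))
    })
  })
  stresses <- vapply(fits, function(f) f$fit$stress, numeric(1))
  best <- fits[[which.min(stresses)]]$fit
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  rownames(coords) <- attr(d, "Labels")
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(
    coordinates = coords,
    stress = best$stress,
    converged = best$icause != 1L,  # 1 = stopped at max iterations
    n_restarts_used = n_restarts,
    seed = seed,
    restart_stress = data.frame(
      restart = seq_along(fits) - 1L,
      initial_stress = vapply(fits, `[[`, numeric(1), "initial_stress"),
      final_stress = stresses
    )
  ), class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("Non-metric multidimensional scaling\n")
  cat(sprintf("  %d samples, %d axes\n", nrow(x$coordinates),
              ncol(x$coordinates)))
  cat(sprintf("  Kruskal stress-1: %.6f (best of %d starts, seed %d)\n",
              x$stress, x$n_restarts_used + 1L, x$seed))
  invisible(x)
}

# within-group and total sums of squares from a squared-distance matrix
.perm_ss <- function(d2, idx_by_group) {
  ssw <- 0
  for (idx in idx_by_group) {
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssw
}

#' Permutation test for community differences among groups
#'
#' PERMANOVA-style one-way test on a dissimilarity matrix: the pseudo-F
#' statistic contrasts between- and within-group sums of squared
#' dissimilarities, and its null distribution is obtained by permuting
#' group labels across samples. The p-value uses the standard permutation
#' estimator `(1 + #\{F* >= F\}) / (1 + n_permutations)`, so it can never be
#' smaller than `1 / (n_permutations + 1)`.
#'
#' @param d a [stats::dist] object or symmetric dissimilarity matrix.
#' @param groups group labels, one per sample (at least 2 groups, each with
#'   at least 2 samples).
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @return an object of class `perm_test`: list with `statistic` (pseudo-F),
#'   `p_value`, `n_permutations`, `seed`, `df` (between/within degrees of
#'   freedom).
#' @export
permutation_community_test <- function(d, groups, n_permutations = 9999,
                                       seed = 1) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (!inherits(d, "dist")) stop("d must be a dist or symmetric matrix",
                                 call. = FALSE)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) {
    stop("length(groups) must equal the number of samples", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 samples; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  .assert_scalar(n_permutations, "n_permutations", lower = 1, integer = TRUE)

  d2 <- as.matrix(d)^2
  k <- length(sizes)
  sst <- sum(d2) / (2 * n)
  idx <- split(seq_len(n), groups)
  ssw <- .perm_ss(d2, idx)
  if (sst < 1e-12) {
    # all samples identical: F is degenerate and ties with every permutation
    return(structure(list(statistic = 0, p_value = 1,
                          n_permutations = n_permutations, seed = seed,
                          df = c(between = k - 1L, within = n - k)),
                     class = "perm_test"))
  }
  f_stat <- function(ssw) ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  f_obs <- f_stat(ssw)
  labs <- as.integer(groups)
  f_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      pl <- labs[sample.int(n)]
      f_stat(.perm_ss(d2, split(seq_len(n), pl)))
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(list(statistic = f_obs, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 df = c(between = k - 1L, within = n - k)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test for community differences (pseudo-F)\n")
  cat(sprintf("  F = %.4f (df %d/%d), p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$df[["between"]], x$df[["within"]],
              x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Confidence ellipses of group centroids in ordination space
#'
#' For each group with at least 3 samples, summarizes the spread of the
#' group mean in a 2-D ordination: centroid, covariance of the mean
#' (`cov(points)/n`), and the half-axis lengths of the confidence ellipse at
#' the chi-square(2) quantile for `level`. Groups with fewer than 3 samples
#' are skipped with a warning.
#'
#' @param coordinates numeric matrix with exactly 2 columns (e.g.
#'   `nmds(...)$coordinates`).
#' @param groups group labels, one per row of `coordinates`.
#' @param level confidence level in (0, 1).
#' @return a `data.frame` with one row per summarized group: centroid,
#'   half-axis lengths (`radius_major`, `radius_minor`), orientation of the
#'   major axis in radians, and `n`.
#' @export
group_ellipse <- function(coordinates, groups, level = 0.95) {
  if (!is.matrix(coordinates) || ncol(coordinates) != 2L) {
    stop("coordinates must be a matrix with 2 columns", call. = FALSE)
  }
  .assert_scalar(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  groups <- as.factor(groups)
  if (length(groups) != nrow(coordinates)) {
    stop("length(groups) must equal nrow(coordinates)", call. = FALSE)
  }
  q <- stats::qchisq(level, df = 2)
  out <- lapply(levels(groups), function(g) {
    pts <- coordinates[groups == g, , drop = FALSE]
    if (nrow(pts) < 3L) {
      warning("group '", g, "' has fewer than 3 samples; skipped")
      return(NULL)
    }
    ctr <- colMeans(pts)
    S <- stats::cov(pts) / nrow(pts)
    ev <- eigen(S, symmetric = TRUE)
    radii <- sqrt(pmax(ev$values, 0) * q)
    data.frame(group = g, n = nrow(pts),
               center_1 = ctr[1], center_2 = ctr[2],
               radius_major = radii[1], radius_minor = radii[2],
               angle_rad = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}
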