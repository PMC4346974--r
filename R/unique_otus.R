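#' Detect signature ("unique") OTUs of a focal group
#'
#' An OTU is a signature of a focal group when it is consistently abundant
#' there and nearly absent elsewhere. Two criteria are applied to raw read
#' counts: (1) the mean count of the OTU in the focal group is at least
#' `fold` times the maximum of its mean counts in every other group, and
#' (2) its coefficient of variation within the focal group (sample standard
#' deviation, n-1 denominator, divided by the mean, as a percentage) is
#' below `cv_max_percent`. The fold rule demands specificity; the CV rule
#' demands that the signal is carried by the group, not by one extreme
#' sample.
#'
#' Conventions for degenerate cases: an OTU with focal mean 0 never passes
#' (its CV is undefined); an OTU absent from all other groups but present
#' in the focal group has infinite fold ratio and passes the fold rule.
#'
#' @param table raw integer count matrix (samples x OTUs); do not pass
#'   standardized abundances.
#' @param groups group labels, one per sample.
#' @param focal_group the group whose signatures are sought (at least 2
#'   samples).
#' @param fold fold-change threshold (default 5).
#' @param cv_max_percent CV threshold in percent (default 300).
#' @return an object of class `unique_otu_report`: a `data.frame` with one
#'   row per OTU (`otu_id`, `focal_mean`, `max_other_mean`, `fold_ratio`,
#'   `cv_percent`, `passed`), with the focal group and thresholds stored as
#'   attributes.
#' @export
#' @examples
#' counts <- rbind(a1 = c(10L, 5L), a2 = c(12L, 0L),
#'                 b1 = c(1L, 0L), b2 = c(0L, 0L))
#' colnames(counts) <- c("otu1", "otu2")
#' select_unique_otus(counts, c("A", "A", "B", "B"), "A")
select_unique_otus <- function(table, groups, focal_group, fold = 5,
                               cv_max_percent = 300) {
  .assert_count_matrix(table, "OTU table")
  groups <- as.character(groups)
  if (length(groups) != nrow(table)) {
    stop("length(groups) must equal nrow(table)", call. = FALSE)
  }
  .assert_scalar(fold, "fold", lower = 0, strict_lower = TRUE)
  .assert_scalar(cv_max_percent, "cv_max_percent", lower = 0,
                 strict_lower = TRUE)
  focal_idx <- which(groups == focal_group)
  if (length(focal_idx) == 0L) {
    stop("focal group '", focal_group, "' not found", call. = FALSE)
  }
  if (length(focal_idx) < 2L) {
    stop("focal group '", focal_group,
         "' needs at least 2 samples to compute a CV", call. = FALSE)
  }
  other_groups <- setdiff(unique(groups), focal_group)
  if (length(other_groups) == 0L) {
    stop("need at least one non-focal group", call. = FALSE)
  }

  focal <- table[focal_idx, , drop = FALSE]
  focal_mean <- colMeans(focal)
  other_means <- vapply(other_groups, function(g) {
    colMeans(table[groups == g, , drop = FALSE])
  }, numeric(ncol(table)))
  if (is.null(dim(other_means))) other_means <- matrix(other_means, nrow = 1)
  max_other_mean <- apply(other_means, 1, max)

  fold_ratio <- ifelse(max_other_mean == 0,
                       ifelse(focal_mean > 0, Inf, 0),
                       focal_mean / max_other_mean)
  focal_sd <- apply(focal, 2, stats::sd)
  cv_percent <- ifelse(focal_mean == 0, NA_real_, 100 * focal_sd / focal_mean)
  passed <- (fold_ratio >= fold) & !is.na(cv_percent) &
    (cv_percent < cv_max_percent)

  out <- data.frame(otu_id = colnames(table), focal_mean = focal_mean,
                    max_other_mean = max_other_mean, fold_ratio = fold_ratio,
                    cv_percent = cv_percent, passed = passed,
                    row.names = NULL)
  attr(out, "focal_group") <- focal_group
  attr(out, "fold") <- fold
  attr(out, "cv_max_percent") <- cv_max_percent
  class(out) <- c("unique_otu_report", "data.frame")
  out
}

#' @export
print.unique_otu_report <- function(x, ...) {
  cat(sprintf(
    "Unique-OTU report for group '%s' (fold >= %g, CV < %g%%): %d of %d OTUs pass\n",
    attr(x, "focal_group"), attr(x, "fold"), attr(x, "cv_max_percent"),
    sum(x$passed), nrow(x)))
  if (sum(x$passed) > 0) {
    print.data.frame(x[x$passed, , drop = FALSE], digits = 4)
  }
  invisible(x)
}

# compact letter display from a logical "not significantly different"
# relation: letters are the maximal cliques of the relation graph, ordered
# by decreasing group mean so that 'a' marks the highest group.
.compact_letters <- function(not_diff, group_means) {
  k <- nrow(not_diff)
  ord <- order(-group_means)
  g <- igraph::graph_from_adjacency_matrix(not_diff[ord, ord, drop = FALSE],
                                           mode = "undirected", diag = FALSE)
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  lab <- rep("", k)
  for (i in seq_along(cliques)) {
    members <- as.integer(cliques[[i]])
    lab[members] <- paste0(lab[members], letters[i])
  }
  out <- character(k)
  out[ord] <- lab
  stats::setNames(out, rownames(not_diff))
}

#' Per-OTU group comparison with a compact letter display
#'
#' Tests whether the read counts of one OTU differ among groups:
#' Kruskal-Wallis omnibus test, followed (when significant at `alpha`) by
#' pairwise two-sided Wilcoxon rank-sum tests with Holm correction. The
#' result is returned as a compact letter display: groups sharing a letter
#' are not significantly different. All-tied data yield a single shared
#' letter.
#'
#' @param table raw integer count matrix (samples x OTUs).
#' @param groups group labels, one per sample (at least 2 groups).
#' @param otu_id the OTU column to test.
#' @param alpha significance level for both the omnibus and pairwise tests.
#' @return an object of class `otu_group_test`: list with `letters` (named
#'   character vector per group), `kruskal_p`, `pairwise_p` (Holm-adjusted
#'   matrix or NULL), `group_means`, `alpha`.
#' @export
per_otu_group_test <- function(table, groups, otu_id, alpha = 0.05) {
  .assert_count_matrix(table, "OTU table")
  if (!otu_id %in% colnames(table)) {
    stop("OTU '", otu_id, "' not found in table", call. = FALSE)
  }
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  .assert_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  x <- table[, otu_id]
  gm <- tapply(x, groups, mean)
  k <- nlevels(groups)

  all_tied <- length(unique(x)) == 1L
  kw_p <- if (all_tied) 1 else
    suppressWarnings(stats::kruskal.test(x, groups)$p.value)
  if (is.na(kw_p)) kw_p <- 1

  if (kw_p >= alpha) {
    lets <- stats::setNames(rep("a", k), levels(groups))
    return(structure(list(letters = lets, kruskal_p = kw_p,
                          pairwise_p = NULL, group_means = gm,
                          alpha = alpha), class = "otu_group_test"))
  }
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(x, groups, p.adjust.method = "holm"))$p.value
  # symmetric full matrix of adjusted p-values; NA (untestable) -> 1
  pmat <- matrix(1, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in rownames(pw)) for (j in colnames(pw)) {
    if (!is.na(pw[i, j])) pmat[i, j] <- pmat[j, i] <- pw[i, j]
  }
  not_diff <- pmat >= alpha
  lets <- .compact_letters(not_diff, gm)
  structure(list(letters = lets, kruskal_p = kw_p, pairwise_p = pmat,
                 group_means = gm, alpha = alpha),
            class = "otu_group_test")
}

#' @export
print.otu_group_test <- function(x, ...) {
  cat(sprintf("Per-OTU group test (Kruskal-Wallis p = %.4g, alpha = %g)\n",
              x$kruskal_p, x$alpha))
  df <- data.frame(group = names(x$letters),
                   mean_count = as.numeric(x$group_means[names(x$letters)]),
                   letter = unname(x$letters))
  print.data.frame(df, digits = 4, row.names = FALSE)
  invisible(x)
}
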