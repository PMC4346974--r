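#' Rank candidate pollinator taxa by similarity to flower communities
#'
#' The core inference: insect taxa whose surface microbial communities are
#' most similar to the communities found on a plant's flowers are the most
#' plausible visitors, because visiting insects deposit their surface
#' microbes on the flower. For each insect taxon, the mean and standard
#' deviation of Bray-Curtis dissimilarity over all (insect sample, flower
#' sample) pairs are computed, and taxa are ranked by ascending mean
#' (rank 1 = most similar). Ties are broken lexicographically by taxon
#' name.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix over all
#'   samples (e.g. from [bray_curtis()]).
#' @param metadata sample metadata `data.frame` with columns `sample_id`,
#'   `sample_class`, `group`; insect taxa are the `group` values of samples
#'   with `sample_class == "insect"`.
#' @param flower_group the `group` label of the flower samples to compare
#'   against.
#' @return an object of class `fingerprint_ranking`: a `data.frame` with
#'   columns `insect_taxon`, `mean_dissimilarity`, `sd_dissimilarity`,
#'   `n_pairs`, `rank`, ordered by rank.
#' @export
rank_by_fingerprint <- function(d, metadata, flower_group) {
  dm <- as.matrix(d)
  validate_sample_metadata(metadata)
  metadata <- metadata[metadata$sample_id %in% rownames(dm), , drop = FALSE]
  flower_ids <- metadata$sample_id[metadata$group == flower_group]
  if (length(flower_ids) == 0L) {
    stop("no flower samples in group '", flower_group, "'", call. = FALSE)
  }
  insects <- metadata[metadata$sample_class == "insect", , drop = FALSE]
  if (nrow(insects) == 0L) stop("no insect samples in metadata",
                                call. = FALSE)
  taxa <- sort(unique(insects$group))
  recs <- lapply(taxa, function(tx) {
    ids <- insects$sample_id[insects$group == tx]
    pairs <- dm[ids, flower_ids, drop = FALSE]
    data.frame(insect_taxon = tx,
               mean_dissimilarity = mean(pairs),
               sd_dissimilarity = stats::sd(as.vector(pairs)),
               n_pairs = length(pairs))
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$mean_dissimilarity, out$insect_taxon), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("fingerprint_ranking", "data.frame")
  out
}

#' @export
print.fingerprint_ranking <- function(x, ...) {
  cat("Pollinator candidates ranked by mean Bray-Curtis dissimilarity",
      "to flowers\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Apply the standard exclusions to visitation records
#'
#' Direct visual censuses record every arthropod on the flowers, but very
#' small insects, ants, and spiders are excluded before comparison with the
#' microbial fingerprint: small insects cannot be sampled for surface
#' microbes, and ants/spiders are residents rather than flying visitors.
#' Records are marked excluded with a reason from `{too_small, ant,
#' spider}`; nothing is dropped, so exclusions stay auditable.
#'
#' @param records a `data.frame` of visitation records with columns `taxon`
#'   and `count`, optionally `body_length_mm` (NA allowed) and `taxon_type`
#'   (values `"ant"` or `"spider"` flag residents; anything else is an
#'   ordinary visitor).
#' @param min_length_mm body-length threshold in mm; records strictly below
#'   it are excluded as `too_small`.
#' @return the records with logical column `excluded` and character column
#'   `exclusion_reason` (`NA` for retained records).
#' @export
filter_visitors <- function(records, min_length_mm = 4) {
  if (!all(c("taxon", "count") %in% names(records))) {
    stop("records must have columns 'taxon' and 'count'", call. = FALSE)
  }
  if (any(records$count < 0)) stop("negative visit count", call. = FALSE)
  .assert_scalar(min_length_mm, "min_length_mm", lower = 0)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if ("taxon_type" %in% names(records)) {
    reason[!is.na(records$taxon_type) &
             records$taxon_type == "ant"] <- "ant"
    reason[!is.na(records$taxon_type) &
             records$taxon_type == "spider"] <- "spider"
  }
  if ("body_length_mm" %in% names(records)) {
    small <- !is.na(records$body_length_mm) &
      records$body_length_mm < min_length_mm & is.na(reason)
    reason[small] <- "too_small"
  }
  records$excluded <- !is.na(reason)
  records$exclusion_reason <- reason
  records
}

#' Compare the fingerprint ranking with direct visual observation
#'
#' Quantifies the agreement between the two ways of identifying
#' pollinators: a taxon observed often on the flowers should also have a
#' microbial community similar to the flowers'. The summary is the
#' Spearman rank correlation between visitation counts and negated mean
#' dissimilarity over the taxa shared by both inputs, so rho = 1 means the
#' most frequent visitor is also the most similar taxon. Taxa present in
#' only one input are listed separately; a fingerprint-only taxon is the
#' classic discordance of a similar-community insect that was never seen
#' visiting.
#'
#' @param ranking a `fingerprint_ranking` from [rank_by_fingerprint()].
#' @param visitation a `data.frame` of visitation records (`taxon`,
#'   `count`); if it carries an `excluded` column (from
#'   [filter_visitors()]), excluded records are ignored. Counts are summed
#'   per taxon.
#' @return an object of class `fingerprint_comparison`: list with
#'   `spearman_rho`, `n_common_taxa`, `table` (per-taxon counts,
#'   dissimilarities, and both ranks), `only_in_fingerprint`,
#'   `only_in_observation`, and `degenerate_ranks` (TRUE when either
#'   ranking is constant, in which case rho is reported as 0).
#' @export
compare_with_observation <- function(ranking, visitation) {
  if (!all(c("insect_taxon", "mean_dissimilarity") %in% names(ranking))) {
    stop("ranking must come from rank_by_fingerprint()", call. = FALSE)
  }
  if (!all(c("taxon", "count") %in% names(visitation))) {
    stop("visitation must have columns 'taxon' and 'count'", call. = FALSE)
  }
  if ("excluded" %in% names(visitation)) {
    visitation <- visitation[!visitation$excluded, , drop = FALSE]
  }
  obs <- stats::aggregate(count ~ taxon, data = visitation, FUN = sum)
  shared <- intersect(ranking$insect_taxon, obs$taxon)
  if (length(shared) < 3L) {
    stop("need at least 3 taxa shared between ranking and observations; ",
         "found ", length(shared), call. = FALSE)
  }
  tab <- merge(ranking[, c("insect_taxon", "mean_dissimilarity")],
               obs, by.x = "insect_taxon", by.y = "taxon")
  tab <- tab[order(tab$mean_dissimilarity, tab$insect_taxon), , drop = FALSE]
  tab$fingerprint_rank <- rank(tab$mean_dissimilarity,
                               ties.method = "average")
  tab$visit_rank <- rank(-tab$count, ties.method = "average")
  degenerate <- stats::sd(tab$count) == 0 ||
    stats::sd(tab$mean_dissimilarity) == 0
  rho <- if (degenerate) 0 else
    stats::cor(tab$count, -tab$mean_dissimilarity, method = "spearman")
  rownames(tab) <- NULL
  structure(list(
    spearman_rho = rho,
    n_common_taxa = length(shared),
    table = tab,
    only_in_fingerprint = setdiff(ranking$insect_taxon, obs$taxon),
    only_in_observation = setdiff(obs$taxon, ranking$insect_taxon),
    degenerate_ranks = degenerate
  ), class = "fingerprint_comparison")
}

#' @export
print.fingerprint_comparison <- function(x, ...) {
  cat("Fingerprint vs direct observation\n")
  cat(sprintf("  Spearman rho = %.3f over %d shared taxa%s\n",
              x$spearman_rho, x$n_common_taxa,
              if (x$degenerate_ranks) " (degenerate ranks)" else ""))
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  if (length(x$only_in_fingerprint) > 0) {
    cat("  In fingerprint only (never observed visiting):",
        paste(x$only_in_fingerprint, collapse = ", "), "\n")
  }
  if (length(x$only_in_observation) > 0) {
    cat("  Observed only (no microbial samples):",
        paste(x$only_in_observation, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Observation-effort bookkeeping for visual censuses
#'
#' Total census effort for a design with `n_plots` plots, each observed
#' `sessions_per_plot` times for `minutes_per_session` minutes, with
#' `sessions_per_day` sessions on any observation day.
#'
#' @param n_plots number of census plots.
#' @param sessions_per_plot number of sessions each plot receives in total.
#' @param minutes_per_session session length in minutes.
#' @param sessions_per_day sessions per plot per observation day.
#' @return list with `total_minutes` and `minutes_per_plot_per_day`.
#' @export
#' @examples
#' observation_effort(24, 8, 10, 2)  # 1920 min total, 20 min/plot/day
observation_effort <- function(n_plots, sessions_per_plot,
                               minutes_per_session, sessions_per_day) {
  for (nm in c("n_plots", "sessions_per_plot", "minutes_per_session",
               "sessions_per_day")) {
    .assert_scalar(get(nm), nm, lower = 0, strict_lower = TRUE,
                   integer = TRUE)
  }
  list(total_minutes = n_plots * sessions_per_plot * minutes_per_session,
       minutes_per_plot_per_day = sessions_per_day * minutes_per_session)
}
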