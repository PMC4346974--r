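# Orchestration of the two analysis workflows. Both write a plain-text
# report bundle plus a manifest that echoes every threshold and seed
# actually used, so a run can be audited and replayed.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.manifest <- function(outdir, settings, attrition) {
  jsonlite::write_json(list(settings = settings, attrition = attrition),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full contact-experiment analysis
#'
#' Reproduces the laboratory contact-experiment chain on an OTU table with
#' insect, touched-flower, and control-flower samples: optional chloroplast
#' exclusion, read-depth filter, total-sum standardization, Bray-Curtis
#' dissimilarity, NMDS ordination, a permutation test of each species'
#' touched flowers against the control flowers, and unique-OTU reports per
#' insect species (among insect samples) and per touched-flower treatment
#' (among flower samples). Writes `nmds_coordinates.tsv`,
#' `permutation_tests.tsv`, `unique_otus_<group>.tsv`, and
#' `manifest.json` into `outdir`; reruns with identical inputs produce
#' byte-identical bundles.
#'
#' @param table raw integer count matrix (samples x OTUs).
#' @param metadata sample metadata with insect groups, `touched_by_<species>`
#'   flower groups, and a control flower group.
#' @param outdir output directory (created if missing).
#' @param taxonomy optional taxonomy table for chloroplast exclusion.
#' @param control_group name of the control flower group.
#' @param touched_prefix prefix linking a species to its touched flowers.
#' @param min_reads read-depth threshold (samples must exceed it).
#' @param fold,cv_max_percent unique-OTU thresholds.
#' @param alpha significance level.
#' @param n_permutations permutations per community test.
#' @param nmds_k,nmds_restarts NMDS dimensions and random restarts.
#' @param seed integer seed for NMDS and permutations.
#' @return invisibly, a list with `nmds`, `permutation_tests` (data.frame),
#'   `unique_otus` (named list of reports), and `manifest`.
#' @export
run_contact_analysis <- function(table, metadata, outdir,
                                 taxonomy = NULL,
                                 control_group = "control",
                                 touched_prefix = "touched_by_",
                                 min_reads = 200, fold = 5,
                                 cv_max_percent = 300, alpha = 0.05,
                                 n_permutations = 999, nmds_k = 2,
                                 nmds_restarts = 20, seed = 1) {
  validate_sample_metadata(metadata)
  if (!control_group %in% metadata$group) {
    stop("no control flower group '", control_group, "' in metadata",
         call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  attrition <- list(input = dim(table))
  if (!is.null(taxonomy)) {
    table <- exclude_chloroplast(table, taxonomy)
    attrition$after_chloroplast <- dim(table)
  }
  table <- filter_min_reads(table, min_reads)
  attrition$after_min_reads <- dim(table)
  md <- metadata[match(rownames(table), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) {
    stop("metadata is missing sample(s) present in the table", call. = FALSE)
  }
  rel <- standardize(table)
  d <- bray_curtis(rel)
  ord <- nmds(d, k = nmds_k, n_restarts = nmds_restarts, seed = seed)

  species <- sort(unique(md$group[md$sample_class == "insect"]))
  dm <- as.matrix(d)
  perm_rows <- lapply(species, function(sp) {
    touched <- md$sample_id[md$group == paste0(touched_prefix, sp)]
    control <- md$sample_id[md$group == control_group]
    if (length(touched) < 2L || length(control) < 2L) {
      return(data.frame(species = sp, n_touched = length(touched),
                        n_control = length(control), statistic = NA_real_,
                        p_value = NA_real_, significant = NA))
    }
    ids <- c(touched, control)
    pt <- permutation_community_test(
      stats::as.dist(dm[ids, ids]),
      c(rep("touched", length(touched)), rep("control", length(control))),
      n_permutations = n_permutations, seed = seed)
    data.frame(species = sp, n_touched = length(touched),
               n_control = length(control), statistic = pt$statistic,
               p_value = pt$p_value, significant = pt$p_value < alpha)
  })
  perm_df <- do.call(rbind, perm_rows)

  insect_idx <- md$sample_class == "insect"
  flower_idx <- md$sample_class == "flower"
  reports <- list()
  for (sp in species) {
    if (sum(md$group == sp) >= 2L && sum(insect_idx) > sum(md$group == sp)) {
      reports[[sp]] <- select_unique_otus(
        table[insect_idx, , drop = FALSE], md$group[insect_idx], sp,
        fold = fold, cv_max_percent = cv_max_percent)
    }
    tg <- paste0(touched_prefix, sp)
    if (sum(md$group == tg) >= 2L && sum(flower_idx) > sum(md$group == tg)) {
      reports[[tg]] <- select_unique_otus(
        table[flower_idx, , drop = FALSE], md$group[flower_idx], tg,
        fold = fold, cv_max_percent = cv_max_percent)
    }
  }

  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates,
                       group = md$group[match(rownames(ord$coordinates),
                                              md$sample_id)])
  .write_tsv(coords, file.path(outdir, "nmds_coordinates.tsv"))
  .write_tsv(perm_df, file.path(outdir, "permutation_tests.tsv"))
  for (g in names(reports)) {
    .write_tsv(as.data.frame(reports[[g]]),
               file.path(outdir, paste0("unique_otus_", g, ".tsv")))
  }
  settings <- list(min_reads = min_reads, fold = fold,
                   cv_max_percent = cv_max_percent, alpha = alpha,
                   n_permutations = n_permutations, nmds_k = nmds_k,
                   nmds_restarts = nmds_restarts, seed = seed,
                   control_group = control_group,
                   touched_prefix = touched_prefix,
                   chloroplast_excluded = !is.null(taxonomy),
                   nmds_stress = ord$stress)
  .manifest(outdir, settings, attrition)
  invisible(list(nmds = ord, permutation_tests = perm_df,
                 unique_otus = reports,
                 manifest = list(settings = settings,
                                 attrition = attrition)))
}

#' Run the field fingerprint-vs-observation comparison
#'
#' Reproduces the field chain: read-depth filter, standardization,
#' Bray-Curtis, ranking of insect taxa by mean dissimilarity to the flower
#' samples, exclusion filtering of the visitation records, and the
#' rank-correlation comparison of the two. Writes `ranking.tsv`,
#' `comparison.tsv`, `visitors.tsv`, and `manifest.json` into `outdir`.
#'
#' @param table raw integer count matrix (samples x OTUs).
#' @param metadata sample metadata with insect taxa and a flower group.
#' @param observations visitation records (`taxon`, `count`, optional
#'   `body_length_mm`, `taxon_type`); must be non-empty.
#' @param outdir output directory (created if missing).
#' @param flower_group metadata group of the flower samples.
#' @param taxonomy optional taxonomy table for chloroplast exclusion.
#' @param min_reads read-depth threshold.
#' @param min_length_mm visitor body-length exclusion threshold (mm).
#' @param seed integer seed (recorded in the manifest).
#' @return invisibly, a list with `ranking`, `comparison`, `visitors`, and
#'   `manifest`.
#' @export
run_field_comparison <- function(table, metadata, observations, outdir,
                                 flower_group = "flower", taxonomy = NULL,
                                 min_reads = 200, min_length_mm = 4,
                                 seed = 1) {
  validate_sample_metadata(metadata)
  if (is.null(observations) || nrow(observations) == 0L) {
    stop("observations input is empty", call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  attrition <- list(input = dim(table))
  if (!is.null(taxonomy)) {
    table <- exclude_chloroplast(table, taxonomy)
    attrition$after_chloroplast <- dim(table)
  }
  table <- filter_min_reads(table, min_reads)
  attrition$after_min_reads <- dim(table)
  rel <- standardize(table)
  d <- bray_curtis(rel)
  ranking <- rank_by_fingerprint(d, metadata, flower_group)
  visitors <- filter_visitors(observations, min_length_mm = min_length_mm)
  comparison <- compare_with_observation(ranking, visitors)

  .write_tsv(as.data.frame(ranking), file.path(outdir, "ranking.tsv"))
  .write_tsv(comparison$table, file.path(outdir, "comparison.tsv"))
  .write_tsv(visitors, file.path(outdir, "visitors.tsv"))
  settings <- list(min_reads = min_reads, min_length_mm = min_length_mm,
                   flower_group = flower_group, seed = seed,
                   chloroplast_excluded = !is.null(taxonomy),
                   spearman_rho = comparison$spearman_rho,
                   n_common_taxa = comparison$n_common_taxa,
                   only_in_fingerprint = comparison$only_in_fingerprint,
                   only_in_observation = comparison$only_in_observation)
  .manifest(outdir, settings, attrition)
  invisible(list(ranking = ranking, comparison = comparison,
                 visitors = visitors,
                 manifest = list(settings = settings,
                                 attrition = attrition)))
}
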