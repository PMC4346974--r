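#' Read an OTU count table from a tab-separated file
#'
#' The expected layout is the one exported by most amplicon pipelines:
#' a header row of OTU ids, a first column of sample ids, and non-negative
#' integer read counts in the body (samples as rows). Parsing is strict:
#' ragged rows, duplicated ids, and negative or non-integer counts are
#' errors that name the offending row, id, or cell.
#'
#' @param path path to a tab-separated file.
#' @return an integer matrix with sample ids as rownames and OTU ids as
#'   colnames.
#' @seealso [write_otu_table()], [filter_min_reads()], [standardize()]
#' @export
#' @examples
#' tab <- matrix(c(1L, 2L, 0L, 5L), nrow = 2,
#'               dimnames = list(c("s1", "s2"), c("otuA", "otuB")))
#' f <- tempfile(fileext = ".tsv")
#' write_otu_table(tab, f)
#' identical(read_otu_table(f), tab)
read_otu_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty OTU table file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  otu_ids <- header[-1L]
  if (anyDuplicated(otu_ids)) {
    stop("duplicated OTU id in header: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- fields[-1L]
  sample_ids <- character(length(body))
  counts <- matrix(0L, nrow = length(body), ncol = length(otu_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col) {
      stop("ragged row ", i + 1L, " (sample '", row[1L], "'): expected ",
           n_col, " fields, found ", length(row), call. = FALSE)
    }
    sample_ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad) > 0L) {
      stop("invalid count at sample '", row[1L], "', OTU '",
           otu_ids[bad[1L]], "': '", row[-1L][bad[1L]],
           "' (counts must be non-negative integers)", call. = FALSE)
    }
    counts[i, ] <- as.integer(vals)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  counts
}

#' Write an OTU count table to a tab-separated file
#'
#' Inverse of [read_otu_table()]; `read_otu_table(write_otu_table(x, f))`
#' reproduces `x` exactly.
#'
#' @param table integer count matrix, samples as rows, with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  .assert_count_matrix(table, "OTU table")
  header <- paste(c("sample_id", colnames(table)), collapse = "\t")
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(table[i, ], scientific = FALSE,
                                       trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read or write a sample metadata table
#'
#' Metadata is a tab-separated table with columns `sample_id`,
#' `sample_class` (one of insect, flower, leaf, soil, water, fingertip),
#' `group` (insect species or flower treatment), and optionally
#' `body_weight_mg`.
#'
#' @param path path to a tab-separated metadata file.
#' @return a `data.frame` with validated columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata a metadata `data.frame`.
#' @export
write_sample_metadata <- function(metadata, path) {
  validate_sample_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_metadata
#' @export
validate_sample_metadata <- function(metadata) {
  need <- c("sample_id", "sample_class", "group")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0L) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicated sample id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(metadata$sample_class), SAMPLE_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown sample_class value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(SAMPLE_CLASSES, collapse = ", "), call. = FALSE)
  }
  if ("body_weight_mg" %in% names(metadata)) {
    w <- metadata$body_weight_mg
    if (any(!is.na(w) & w <= 0)) {
      stop("body_weight_mg must be positive where present", call. = FALSE)
    }
  }
  metadata
}

#' Read or write a taxonomy table
#'
#' Two tab-separated columns: `otu_id` and `lineage`, where lineage is a
#' rank-delimited string such as `"k__Bacteria;p__Cyanobacteria;c__Chloroplast"`.
#' Unknown ranks are left empty, never guessed.
#'
#' @param path path to a tab-separated taxonomy file.
#' @return a `data.frame` with columns `otu_id` and `lineage`.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(tx))) {
    stop("taxonomy table must have columns 'otu_id' and 'lineage'",
         call. = FALSE)
  }
  if (anyDuplicated(tx$otu_id)) {
    stop("duplicated otu_id in taxonomy: ",
         paste(unique(tx$otu_id[duplicated(tx$otu_id)]), collapse = ", "),
         call. = FALSE)
  }
  tx
}

#' @rdname read_taxonomy
#' @param taxonomy a taxonomy `data.frame`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove chloroplast OTUs from a count table
#'
#' Plant-derived 16S reads (chloroplast sequences) are not part of the
#' surface microbial community and are dropped before any downstream
#' analysis. An OTU is removed when the string "chloroplast" occurs,
#' case-insensitively, at any rank of its lineage. OTUs absent from the
#' taxonomy table are retained and reported via a message.
#'
#' @param table integer count matrix (samples x OTUs).
#' @param taxonomy taxonomy `data.frame` (columns `otu_id`, `lineage`).
#' @return the count table without chloroplast OTUs.
#' @export
exclude_chloroplast <- function(table, taxonomy) {
  .assert_count_matrix(table, "OTU table")
  lineage <- stats::setNames(taxonomy$lineage, taxonomy$otu_id)
  known <- colnames(table) %in% names(lineage)
  if (any(!known)) {
    message(sum(!known), " OTU(s) absent from taxonomy were retained: ",
            paste(utils::head(colnames(table)[!known], 5), collapse = ", "))
  }
  is_chloro <- rep(FALSE, ncol(table))
  is_chloro[known] <- grepl("chloroplast",
                            lineage[colnames(table)[known]],
                            ignore.case = TRUE)
  out <- table[, !is_chloro, drop = FALSE]
  if (ncol(out) == 0L) {
    warning("all OTUs were identified as chloroplast; empty table returned")
  }
  out
}

#' Drop samples with insufficient sequencing depth
#'
#' Keeps samples whose total read count is strictly greater than
#' `min_reads`; a sample totalling exactly `min_reads` is excluded.
#' The default of 200 reads reflects the usual minimum depth at which
#' Bray-Curtis comparisons of these communities are considered reliable.
#'
#' @param table integer count matrix (samples x OTUs).
#' @param min_reads depth threshold; samples must have more than this many
#'   reads in total.
#' @return the table restricted to sufficiently deep samples.
#' @export
filter_min_reads <- function(table, min_reads = 200) {
  .assert_count_matrix(table, "OTU table")
  .assert_scalar(min_reads, "min_reads", lower = 0)
  if (nrow(table) == 0L) return(table)
  table[rowSums(table) > min_reads, , drop = FALSE]
}

#' Convert counts to relative abundances
#'
#' Total-sum scaling: each sample row is divided by its read total, so
#' rows sum to 1. `method = "sqrt"` applies a square-root transform to the
#' proportions (and renormalizes) for sensitivity analyses that damp the
#' influence of dominant OTUs. Samples with zero totals are an error;
#' filter them out first with [filter_min_reads()].
#'
#' @param table integer count matrix (samples x OTUs).
#' @param method `"total"` (default; total-sum scaling) or `"sqrt"`.
#' @return a numeric matrix of relative abundances; rows sum to 1.
#' @export
standardize <- function(table, method = c("total", "sqrt")) {
  method <- match.arg(method)
  .assert_count_matrix(table, "OTU table")
  totals <- rowSums(table)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(rownames(table)[totals == 0], collapse = ", "),
         "; apply filter_min_reads() first", call. = FALSE)
  }
  rel <- table / totals
  if (method == "sqrt") {
    rel <- sqrt(rel)
    rel <- rel / rowSums(rel)
  }
  rel
}
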