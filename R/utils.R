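# shared internal helpers

# closed vocabulary of sample classes used throughout metadata handling
SAMPLE_CLASSES <- c("insect", "flower", "leaf", "soil", "water", "fingertip")

#' Draw from a Dirichlet distribution
#'
#' Standard gamma-normalization sampler. Entries of `alpha` equal to zero
#' yield structural zeros in the draw.
#'
#' @param n number of draws.
#' @param alpha concentration vector (non-negative, at least one positive).
#' @return an `n` x `length(alpha)` matrix whose rows sum to 1.
#' @keywords internal
#' @noRd
rdirichlet <- function(n, alpha) {
  stopifnot(n >= 1, all(alpha >= 0), any(alpha > 0))
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  rs <- rowSums(x)
  # guard against numerically all-zero rows at very small concentrations
  bad <- rs == 0
  if (any(bad)) {
    x[bad, which.max(alpha)] <- 1
    rs <- rowSums(x)
  }
  x / rs
}

.assert_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(what, " must be a numeric matrix (samples x OTUs)", call. = FALSE)
  }
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop(what, " must have sample ids as rownames and OTU ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated OTU id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop(what, " contains negative entries", call. = FALSE)
  invisible(counts)
}

.assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                           integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("'", name, "' must be a single number", call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) stop("'", name, "' must be > ", lower, call. = FALSE)
  } else if (x < lower) {
    stop("'", name, "' must be >= ", lower, call. = FALSE)
  }
  if (x > upper) stop("'", name, "' must be <= ", upper, call. = FALSE)
  if (integer && x != round(x)) {
    stop("'", name, "' must be an integer", call. = FALSE)
  }
  invisible(x)
}
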