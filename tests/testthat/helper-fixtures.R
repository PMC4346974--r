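# small in-code fixtures shared across test files

# a tiny labelled count matrix
tiny_table <- function() {
  m <- matrix(c(1L, 2L, 0L, 5L, 3L, 4L), nrow = 2,
              dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC")))
  m
}

# labelled random Dirichlet relative-abundance matrix
random_rel_abund <- function(n_samples, n_otus, conc = 0.8, seed = 1) {
  withr::with_seed(seed, {
    x <- pollenprint:::rdirichlet(n_samples, rep(conc, n_otus))
  })
  dimnames(x) <- list(paste0("s", seq_len(n_samples)),
                      paste0("o", seq_len(n_otus)))
  x
}

# brute-force Bray-Curtis oracle: per-pair formula loop
bc_oracle <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  d
}

# count strict local maxima above background in an image (independent
# spot-count oracle for well-separated spots)
count_local_maxima <- function(px, background) {
  n <- 0L
  for (i in 2:(nrow(px) - 1)) for (j in 2:(ncol(px) - 1)) {
    v <- px[i, j]
    if (v <= background + 1e-9) next
    nb <- px[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v > max(nb[-5])) n <- n + 1L
  }
  n
}
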