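test_that("Bray-Curtis matches the formula on hand-computed cases", {
  # identical rows -> 0; disjoint supports -> 1
  x <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5), c = c(1, 0), d = c(0, 1))
  colnames(x) <- c("o1", "o2")
  dm <- as.matrix(bray_curtis(x))
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm["c", "d"], 1)

  # hand evaluation: (2,2,0)/4 vs (1,3,4)/8 -> 1.0 / 2 = 0.5
  y <- rbind(p = c(2, 2, 0) / 4, q = c(1, 3, 4) / 8)
  colnames(y) <- paste0("o", 1:3)
  expect_equal(as.matrix(bray_curtis(y))["p", "q"], 0.5, tolerance = 1e-15)

  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 0))), "all-zero")
  expect_warning(bray_curtis(rbind(a = c(2, 2), b = c(1, 3))), "sum to 1")
})

test_that("Bray-Curtis agrees with a brute-force pair loop", {
  for (seed in 1:5) {
    x <- random_rel_abund(10, 20, seed = seed)
    expect_lt(max(abs(as.matrix(bray_curtis(x)) - bc_oracle(x))), 1e-12)
  }
})

test_that("NMDS recovers an exactly embeddable configuration", {
  withr::with_seed(11, {
    planted <- matrix(rnorm(20), 10, 2)
  })
  rownames(planted) <- paste0("s", 1:10)
  d <- dist(planted)
  res <- nmds(d, k = 2, n_restarts = 10, seed = 4)
  expect_lt(res$stress, 0.01)
  pr <- vegan::procrustes(planted, res$coordinates, symmetric = TRUE)
  expect_lt(sqrt(pr$ss), 1e-3)
  # coordinates centered
  expect_lt(max(abs(colMeans(res$coordinates))), 1e-9)
  # optimizer contract: every start ends at most at its initial stress
  expect_true(all(res$restart_stress$final_stress <=
                    res$restart_stress$initial_stress + 1e-8))
  # reported stress agrees with an independent isotonic-regression stress
  own <- pollenprint:::.kruskal_stress(d, res$coordinates)
  expect_equal(own, res$stress, tolerance = 0.05)
})

test_that("NMDS places identical samples together and is deterministic", {
  m <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0.5, 0),
             s3 = c(0, 0.2, 0.8), s4 = c(0.1, 0.1, 0.8),
             s5 = c(0.3, 0.3, 0.4))
  colnames(m) <- paste0("o", 1:3)
  d <- bray_curtis(m)
  r1 <- nmds(d, k = 2, n_restarts = 8, seed = 3)
  r2 <- nmds(d, k = 2, n_restarts = 8, seed = 3)
  expect_identical(r1$coordinates, r2$coordinates)
  gap <- sqrt(sum((r1$coordinates["s1", ] - r1$coordinates["s2", ])^2))
  expect_lt(gap, 1e-3 * max(dist(r1$coordinates)))

  expect_error(nmds(d, k = 5), "smaller than")
  expect_error(nmds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("permutation test p-values behave like permutation p-values", {
  x <- random_rel_abund(12, 30, seed = 21)
  d <- bray_curtis(x)
  g <- rep(c("a", "b"), each = 6)
  pt <- permutation_community_test(d, g, n_permutations = 199, seed = 5)
  expect_gte(pt$p_value, 1 / 200)
  expect_lte(pt$p_value, 1)
  # invariant to renaming the groups
  pt2 <- permutation_community_test(d, rep(c("zzz", "qqq"), each = 6),
                                    n_permutations = 199, seed = 5)
  expect_equal(pt$p_value, pt2$p_value)
  expect_equal(pt$statistic, pt2$statistic)
  # deterministic given seed
  pt3 <- permutation_community_test(d, g, n_permutations = 199, seed = 5)
  expect_identical(pt$p_value, pt3$p_value)

  # observed pseudo-F matches the standard PERMANOVA implementation
  av <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(pt$statistic, av$F[1], tolerance = 1e-10)

  # all-identical samples: F ties with every permutation, p = 1
  z <- matrix(0.25, 8, 4, dimnames = list(paste0("s", 1:8), paste0("o", 1:4)))
  ptz <- permutation_community_test(bray_curtis(z), rep(c("a", "b"), 4),
                                    n_permutations = 99, seed = 1)
  expect_equal(ptz$p_value, 1)

  expect_error(permutation_community_test(d, rep("a", 12)), "2 groups")
  expect_error(permutation_community_test(d, c("a", rep("b", 11))),
               "at least 2 samples")
})

test_that("separated communities are detected with small p", {
  withr::with_seed(9, {
    x1 <- cbind(pollenprint:::rdirichlet(6, rep(1, 10)), matrix(0, 6, 10))
    x2 <- cbind(matrix(0, 6, 10), pollenprint:::rdirichlet(6, rep(1, 10)))
  })
  x <- rbind(x1, x2)
  dimnames(x) <- list(paste0("s", 1:12), paste0("o", 1:20))
  pt <- permutation_community_test(bray_curtis(x), rep(c("a", "b"), each = 6),
                                   n_permutations = 999, seed = 2)
  expect_lte(pt$p_value, 0.01)
})

test_that("group ellipses summarize ordination spread", {
  # identical points: degenerate zero-area ellipse
  pts <- rbind(matrix(1, 4, 2), matrix(rnorm(8, 5), 4, 2))
  g <- rep(c("same", "cloud"), each = 4)
  ell <- group_ellipse(pts, g)
  expect_equal(ell$radius_major[ell$group == "same"], 0, tolerance = 1e-12)

  # isotropic cloud: near-equal axes
  withr::with_seed(2, big <- matrix(rnorm(2000), 1000, 2))
  e2 <- group_ellipse(big, rep("g", 1000))
  expect_lt(abs(e2$radius_major / e2$radius_minor - 1), 0.1)

  # wider level contains the narrower one
  e95 <- group_ellipse(big, rep("g", 1000), level = 0.95)
  e50 <- group_ellipse(big, rep("g", 1000), level = 0.5)
  expect_gt(e95$radius_major, e50$radius_major)
  expect_gt(e95$radius_minor, e50$radius_minor)

  # too-small groups are skipped with a warning
  expect_warning(e3 <- group_ellipse(pts, c(rep("a", 2), rep("b", 6))),
                 "fewer than 3")
  expect_equal(e3$group, "b")
})
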