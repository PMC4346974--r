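test_that("fingerprint ranking equals a brute-force pair average", {
  x <- random_rel_abund(12, 15, seed = 8)
  md <- data.frame(
    sample_id = rownames(x),
    sample_class = c(rep("insect", 8), rep("flower", 4)),
    group = c(rep(c("bee", "fly"), each = 4), rep("flw", 4)))
  d <- bray_curtis(x)
  rk <- rank_by_fingerprint(d, md, "flw")
  dm <- as.matrix(d)
  for (tx in c("bee", "fly")) {
    ids <- md$sample_id[md$group == tx]
    fids <- md$sample_id[md$group == "flw"]
    vals <- c()
    for (i in ids) for (j in fids) vals <- c(vals, dm[i, j])
    row <- rk[rk$insect_taxon == tx, ]
    expect_equal(row$mean_dissimilarity, mean(vals), tolerance = 1e-12)
    expect_equal(row$sd_dissimilarity, sd(vals), tolerance = 1e-12)
    expect_equal(row$n_pairs, 16)
  }
  expect_equal(sort(rk$rank), seq_len(nrow(rk)))
  expect_true(all(diff(rk$mean_dissimilarity) >= 0))
})

test_that("identical-to-flowers taxa rank first, disjoint taxa last", {
  x <- rbind(
    ident1 = c(0.5, 0.5, 0, 0), ident2 = c(0.5, 0.5, 0, 0),
    disj1 = c(0, 0, 0.5, 0.5), disj2 = c(0, 0, 0.5, 0.5),
    flw1 = c(0.5, 0.5, 0, 0), flw2 = c(0.5, 0.5, 0, 0))
  colnames(x) <- paste0("o", 1:4)
  md <- data.frame(sample_id = rownames(x),
                   sample_class = c(rep("insect", 4), "flower", "flower"),
                   group = c("same", "same", "far", "far", "flw", "flw"))
  rk <- rank_by_fingerprint(bray_curtis(x), md, "flw")
  expect_equal(rk$mean_dissimilarity[rk$insect_taxon == "same"], 0)
  expect_equal(rk$rank[rk$insect_taxon == "same"], 1)
  expect_equal(rk$mean_dissimilarity[rk$insect_taxon == "far"], 1)
  expect_equal(rk$rank[rk$insect_taxon == "far"], 2)

  expect_error(rank_by_fingerprint(bray_curtis(x), md, "nope"),
               "no flower samples")
})

test_that("visitor exclusion rules mark small insects, ants, and spiders", {
  recs <- data.frame(
    taxon = c("smallfly", "hoverfly", "ant_sp", "spider_sp", "bigbee"),
    count = c(10, 5, 50, 2, 7),
    body_length_mm = c(3.5, 5, 8, NA, 12),
    taxon_type = c("fly", "fly", "ant", "spider", "bee"))
  out <- filter_visitors(recs, min_length_mm = 4)
  expect_equal(out$excluded,
               c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$exclusion_reason,
               c("too_small", NA, "ant", "spider", NA))
  # an ant of any size is excluded as an ant, not as too small
  expect_equal(out$exclusion_reason[3], "ant")
  # records without length or type columns are retained
  plain <- filter_visitors(data.frame(taxon = "x", count = 1))
  expect_false(plain$excluded)
})

test_that("comparison with observation computes Spearman rho on shared taxa", {
  # fingerprint ranks (B,A,D,C) vs visit ranks (A,B,C,D): rho = 0.6
  ranking <- data.frame(insect_taxon = c("A", "B", "C", "D"),
                        mean_dissimilarity = c(0.2, 0.1, 0.4, 0.3))
  visitation <- data.frame(taxon = c("A", "B", "C", "D"),
                           count = c(40, 30, 20, 10))
  cmp <- compare_with_observation(ranking, visitation)
  expect_equal(cmp$spearman_rho, 0.6, tolerance = 1e-12)
  expect_equal(cmp$n_common_taxa, 4)
  expect_false(cmp$degenerate_ranks)

  # perfect concordance: counts inversely ordered to dissimilarity
  vis2 <- data.frame(taxon = c("B", "A", "D", "C"),
                     count = c(100, 80, 20, 10))
  expect_equal(compare_with_observation(ranking, vis2)$spearman_rho, 1)

  # identical counts: degenerate ranks reported as rho = 0 with a flag
  vis3 <- data.frame(taxon = c("A", "B", "C", "D"), count = rep(5, 4))
  cmp3 <- compare_with_observation(ranking, vis3)
  expect_equal(cmp3$spearman_rho, 0)
  expect_true(cmp3$degenerate_ranks)

  # taxa present on one side only are listed, not dropped silently
  vis4 <- data.frame(taxon = c("A", "B", "C", "Stomorhina"),
                     count = c(4, 3, 2, 90))
  cmp4 <- compare_with_observation(ranking, vis4)
  expect_equal(cmp4$only_in_fingerprint, "D")
  expect_equal(cmp4$only_in_observation, "Stomorhina")

  expect_error(
    compare_with_observation(ranking,
                             data.frame(taxon = c("A", "B"), count = 1:2)),
    "at least 3")
})

test_that("observation effort arithmetic is exact", {
  eff <- observation_effort(24, 8, 10, 2)
  expect_identical(eff$total_minutes, 1920)
  expect_identical(eff$minutes_per_plot_per_day, 20)
  expect_equal(observation_effort(1, 1, 10, 1),
               list(total_minutes = 10, minutes_per_plot_per_day = 10))
  expect_equal(observation_effort(10, 4, 15, 2),
               list(total_minutes = 600, minutes_per_plot_per_day = 30))
  expect_error(observation_effort(0, 8, 10, 2), "n_plots")
})

test_that("a heavier species with the same visitation rate looks more similar to flowers", {
  base_w <- c(300, 300, 300)
  cfg_light <- simulation_config(seed = 17, n_insect_species = 3,
                                 replicates_per_group = 3,
                                 transfer_fraction = 0.3,
                                 visitation_rates = c(3, 3, 3),
                                 species_weights_mg = base_w)
  cfg_heavy <- simulation_config(seed = 17, n_insect_species = 3,
                                 replicates_per_group = 3,
                                 transfer_fraction = 0.3,
                                 visitation_rates = c(3, 3, 3),
                                 species_weights_mg = c(3000, 300, 300))
  mean_diss <- function(cfg) {
    sim <- simulate_field_study(cfg, n_flowers = 6)
    rel <- standardize(filter_min_reads(sim$table))
    rk <- rank_by_fingerprint(bray_curtis(rel), sim$metadata, "flower")
    rk$mean_dissimilarity[rk$insect_taxon == "species_1"]
  }
  expect_lt(mean_diss(cfg_heavy), mean_diss(cfg_light))
})
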