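test_that("configuration validation enforces the model's constraints", {
  expect_error(simulation_config(transfer_fraction = 1.5),
               "transfer_fraction")
  expect_error(simulation_config(transfer_fraction = -0.1),
               "transfer_fraction")
  expect_error(simulation_config(n_otus = 10, n_insect_species = 3,
                                 n_signature_otus_per_species = 4),
               "disjoint")
  expect_error(simulation_config(sequencing_depth_mean = 0),
               "sequencing_depth_mean")
  expect_error(simulation_config(insect_concentration = 0),
               "insect_concentration")
  expect_error(simulation_config(replicates_per_group = 0),
               "replicates_per_group")
  # default visitation rates span a 10-fold range
  cfg <- simulation_config(n_insect_species = 4)
  expect_equal(max(cfg$visitation_rates) / min(cfg$visitation_rates), 10,
               tolerance = 1e-12)
})

test_that("ground truth bookkeeping: profiles, signatures, loads", {
  cfg <- simulation_config(seed = 2, n_insect_species = 3,
                           n_signature_otus_per_species = 2)
  sim <- simulate_insect_communities(cfg)
  # profiles are distributions
  expect_equal(unname(rowSums(sim$truth$species_profiles)), rep(1, 3),
               tolerance = 1e-9)
  # 3 disjoint signature sets of size 2
  sig <- sim$truth$signature_otus
  expect_length(sig, 3)
  expect_true(all(lengths(sig) == 2))
  expect_equal(length(unique(unlist(sig))), 6)
  # load model arithmetic: slope 1000 cells/mg, zero intercept, 650 mg
  cfg2 <- simulation_config(load_intercept = 0, load_slope = 1000)
  expect_equal(true_load(cfg2, 650), 6.5e5)
  expect_equal(true_load(cfg2, c(65, 650)), c(6.5e4, 6.5e5))
  # negative predicted loads are floored at zero
  cfg3 <- simulation_config(load_intercept = -1e5, load_slope = 100)
  expect_equal(true_load(cfg3, 10), 0)
})

test_that("every simulator is deterministic given its seed", {
  cfg <- simulation_config(seed = 99, n_otus = 40,
                           replicates_per_group = 3)
  expect_identical(simulate_insect_communities(cfg),
                   simulate_insect_communities(cfg))
  expect_identical(simulate_contact_experiment(cfg),
                   simulate_contact_experiment(cfg))
  expect_identical(simulate_visitation(cfg, 3, 2),
                   simulate_visitation(cfg, 3, 2))
  expect_identical(simulate_field_study(cfg, n_flowers = 4),
                   simulate_field_study(cfg, n_flowers = 4))
  expect_identical(simulate_dapi_image(10, seed = 5)$pixels,
                   simulate_dapi_image(10, seed = 5)$pixels)
})

test_that("realized sequencing depth tracks the configured mean", {
  cfg <- simulation_config(seed = 12, n_otus = 50, n_insect_species = 5,
                           n_signature_otus_per_species = 0,
                           replicates_per_group = 12,
                           sequencing_depth_mean = 1000)
  sim <- simulate_insect_communities(cfg)
  expect_gte(nrow(sim$table), 50)
  expect_lt(abs(mean(rowSums(sim$table)) / 1000 - 1), 0.05)
})

test_that("contact transfer follows the cell-mixing model", {
  # transfer_fraction = 0: touched flowers are statistically controls
  cfg0 <- simulation_config(seed = 4, transfer_fraction = 0,
                            individual_jitter_concentration = 0)
  sim0 <- simulate_contact_experiment(cfg0)
  expect_true(all(sim0$truth$transfer_events$deposited_cells == 0))

  # deposits never exceed the source insect's load
  cfg1 <- simulation_config(seed = 5, transfer_fraction = 0.7)
  sim1 <- simulate_contact_experiment(cfg1)
  ev <- sim1$truth$transfer_events
  expect_true(all(ev$deposited_cells <=
                    sim1$truth$cell_loads[ev$insect_sample] + 1e-9))

  # weights 650 vs 65 mg, zero intercept: deposits differ by factor 10
  cfg2 <- simulation_config(seed = 6, n_insect_species = 2,
                            replicates_per_group = 2,
                            load_intercept = 0, load_slope = 1000,
                            transfer_fraction = 0.5,
                            species_weights_mg = c(650, 65))
  ev2 <- simulate_contact_experiment(cfg2)$truth$transfer_events
  dep_by_sp <- tapply(ev2$deposited_cells,
                      sub("_[0-9]+$", "", ev2$insect_sample), unique)
  expect_equal(unname(dep_by_sp[["species_1"]] / dep_by_sp[["species_2"]]),
               10, tolerance = 1e-12)

  # pure-transfer limit: zero flower baseline, tf = 1, no jitter ->
  # touched flower expected composition equals the insect profile
  cfg3 <- simulation_config(seed = 7, n_insect_species = 1,
                            replicates_per_group = 2, transfer_fraction = 1,
                            flower_baseline_cells = 0,
                            individual_jitter_concentration = 0,
                            sequencing_depth_mean = 200000)
  sim3 <- simulate_contact_experiment(cfg3)
  touched <- sim3$table[sim3$metadata$group == "touched_by_species_1", ,
                        drop = FALSE]
  rel <- touched[1, ] / sum(touched[1, ])
  expect_lt(max(abs(rel - sim3$truth$species_profiles[1, ])), 0.005)
})

test_that("expected touched-control divergence is monotone in transferred load", {
  # noise-free check on expected compositions
  withr::with_seed(10, {
    base <- pollenprint:::rdirichlet(1, rep(0.5, 60))[1, ]
    prof <- pollenprint:::rdirichlet(1, rep(0.5, 60))[1, ]
  })
  baseline_cells <- 1e5
  bc_to_base <- vapply(c(0, 1e3, 1e4, 1e5, 1e6, 1e7), function(dep) {
    mix <- baseline_cells * base + dep * prof
    mix <- mix / sum(mix)
    sum(abs(mix - base)) / sum(mix + base)
  }, numeric(1))
  expect_true(all(diff(bc_to_base) >= -1e-12))
})

test_that("planted signatures are enriched in their own species", {
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, signature_enrichment = 10)
    tr <- simulate_insect_communities(cfg)$truth
    for (sp in rownames(tr$species_profiles)) {
      sig <- tr$signature_otus[[sp]]
      own <- tr$species_profiles[sp, sig]
      others <- tr$species_profiles[setdiff(rownames(tr$species_profiles),
                                            sp), sig, drop = FALSE]
      expect_true(all(own > apply(others, 2, max)))
    }
  }
})

test_that("visitation counts are Poisson with the species rates", {
  cfg <- simulation_config(seed = 1, n_insect_species = 2,
                           visitation_rates = c(10, 1))
  # all-zero rates give all-zero counts
  cfg0 <- simulation_config(seed = 1, n_insect_species = 2,
                            visitation_rates = c(0, 0))
  expect_true(all(simulate_visitation(cfg0, 3, 3)$count == 0))

  # grand total expectation r * plots * sessions, within 3 SE over 400 seeds
  totals <- vapply(1:400, function(s) {
    v <- simulate_visitation(cfg, n_plots = 3, n_sessions = 2, seed = s)
    sum(v$count[v$taxon == "species_1"])
  }, numeric(1))
  expected <- 10 * 3 * 2
  se <- sqrt(expected / 400)
  expect_lt(abs(mean(totals) - expected), 3 * se)

  # a 10x rate gives a ~10x grand total
  v_all <- do.call(rbind, lapply(1:200, function(s) {
    simulate_visitation(cfg, 2, 2, seed = 1000 + s)
  }))
  ratio <- sum(v_all$count[v_all$taxon == "species_1"]) /
    sum(v_all$count[v_all$taxon == "species_2"])
  expect_lt(abs(ratio - 10), 1.5)
})

test_that("DAPI images honour planting, separation, and error contracts", {
  # blank image is uniform background
  img0 <- simulate_dapi_image(0, noise_sd = 0, seed = 1)
  expect_equal(length(unique(as.vector(img0$pixels))), 1L)

  # planted spots appear as exactly n local maxima above background
  img25 <- simulate_dapi_image(25, noise_sd = 0, seed = 2,
                               background_level = 0.1)
  expect_equal(count_local_maxima(img25$pixels, 0.1), 25L)
  expect_equal(nrow(img25$planted_centers), 25L)
  # minimum separation honoured
  cd <- as.matrix(dist(img25$planted_centers))
  diag(cd) <- Inf
  expect_gte(min(cd), 4 * 2)

  # impossible packing is an error
  expect_error(simulate_dapi_image(5000, image_shape = c(64, 64),
                                   spot_sigma_px = 2),
               "separation")

  # 16-bit TIFF round trip preserves the picture to quantization error
  f <- withr::local_tempfile(fileext = ".tif")
  write_cell_image(img25, f)
  back <- read_cell_image(f)
  expect_lt(max(abs(back$pixels - img25$pixels)), 1 / 65535 + 1e-6)
})
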