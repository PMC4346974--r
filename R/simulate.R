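#' Configuration for the insect-to-flower microbial transfer simulator
#'
#' Collects every free parameter of the simulator in one validated object.
#' The defaults describe the study system the package targets: a shared
#' pool of ~200 OTUs, three insect species (a large carpenter-bee-like,
#' a medium bumblebee-like, and a small honeybee-like visitor when
#' `species_weights_mg` is supplied), fresh weights between 65 and 650 mg,
#' a linear cell-load model whose mean load is about 1.2 million cells per
#' individual, and multinomial sequencing at a mean depth of ~1000 reads
#' per sample.
#'
#' Species profiles are drawn once per species from a Dirichlet over the
#' OTU pool; each species' disjoint set of signature OTUs has its Dirichlet
#' concentration multiplied by `signature_enrichment`, so signatures are
#' enriched in expectation and `signature_enrichment = 1` is the
#' exchangeable null. Individuals share their species profile up to a
#' small Dirichlet jitter.
#'
#' @param seed integer seed; every `simulate_*` output is reproducible from
#'   it.
#' @param n_otus size of the shared OTU pool.
#' @param n_insect_species number of insect species.
#' @param n_signature_otus_per_species signature OTUs planted per species
#'   (disjoint across species; the total cannot exceed `n_otus`).
#' @param signature_enrichment concentration multiplier for signature OTUs
#'   within their own species (dimensionless, >= 0; 1 = no signature).
#' @param flower_baseline_concentration Dirichlet concentration of the
#'   flower baseline community.
#' @param insect_concentration Dirichlet concentration of insect species
#'   profiles.
#' @param body_weight_mg_range range insect fresh weights are drawn from
#'   (uniform), in mg.
#' @param load_intercept,load_slope linear cell-load model: true load =
#'   `max(0, load_intercept + load_slope * weight_mg)` cells. With
#'   `load_model = "loglog"` the model is `log10(load) = load_intercept +
#'   load_slope * log10(weight)`.
#' @param load_model `"linear"` (default) or `"loglog"`.
#' @param transfer_fraction fraction of an insect's surface cells deposited
#'   on a flower per contact, in \[0, 1\].
#' @param flower_baseline_cells microbial cells resident on an untouched
#'   flower.
#' @param individual_jitter_concentration concentration of the
#'   per-individual Dirichlet jitter around the species profile (larger =
#'   tighter; 0 disables jitter).
#' @param sequencing_depth_mean mean per-sample read depth (Poisson-jittered,
#'   floored at 1).
#' @param replicates_per_group samples per insect species / flower
#'   treatment.
#' @param visitation_rates expected visits per species per flower; default
#'   is a geometric ladder spanning a 10-fold range across species.
#' @param species_weights_mg optional fixed per-species weights (length
#'   `n_insect_species`); when given, every individual of a species has
#'   that weight instead of a uniform draw.
#' @param species_names optional species labels; default `species_1`, ...
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_otus = 200,
                              n_insect_species = 3,
                              n_signature_otus_per_species = 5,
                              signature_enrichment = 10,
                              flower_baseline_concentration = 0.5,
                              insect_concentration = 0.5,
                              body_weight_mg_range = c(65, 650),
                              load_intercept = 0,
                              load_slope = 3400,
                              load_model = c("linear", "loglog"),
                              transfer_fraction = 0.1,
                              flower_baseline_cells = 2e5,
                              individual_jitter_concentration = 200,
                              sequencing_depth_mean = 1000,
                              replicates_per_group = 5,
                              visitation_rates = NULL,
                              species_weights_mg = NULL,
                              species_names = NULL) {
  load_model <- match.arg(load_model)
  .assert_scalar(seed, "seed", integer = TRUE)
  .assert_scalar(n_otus, "n_otus", lower = 1, integer = TRUE)
  .assert_scalar(n_insect_species, "n_insect_species", lower = 1,
                 integer = TRUE)
  .assert_scalar(n_signature_otus_per_species,
                 "n_signature_otus_per_species", lower = 0, integer = TRUE)
  if (n_signature_otus_per_species * n_insect_species > n_otus) {
    stop("signature OTU sets cannot be disjoint: ",
         "n_signature_otus_per_species * n_insect_species > n_otus",
         call. = FALSE)
  }
  .assert_scalar(signature_enrichment, "signature_enrichment", lower = 0,
                 strict_lower = TRUE)
  .assert_scalar(flower_baseline_concentration,
                 "flower_baseline_concentration", lower = 0,
                 strict_lower = TRUE)
  .assert_scalar(insect_concentration, "insect_concentration", lower = 0,
                 strict_lower = TRUE)
  if (length(body_weight_mg_range) != 2L || any(body_weight_mg_range <= 0) ||
      body_weight_mg_range[1] > body_weight_mg_range[2]) {
    stop("body_weight_mg_range must be an increasing pair of positive reals",
         call. = FALSE)
  }
  .assert_scalar(transfer_fraction, "transfer_fraction", lower = 0,
                 upper = 1)
  .assert_scalar(flower_baseline_cells, "flower_baseline_cells", lower = 0)
  .assert_scalar(individual_jitter_concentration,
                 "individual_jitter_concentration", lower = 0)
  .assert_scalar(sequencing_depth_mean, "sequencing_depth_mean", lower = 1,
                 integer = TRUE)
  .assert_scalar(replicates_per_group, "replicates_per_group", lower = 1,
                 integer = TRUE)
  if (is.null(visitation_rates)) {
    visitation_rates <- if (n_insect_species == 1L) 10 else
      10 * 10^(-seq(0, 1, length.out = n_insect_species))
  }
  if (any(visitation_rates < 0)) {
    stop("visitation_rates must be non-negative", call. = FALSE)
  }
  if (length(visitation_rates) != n_insect_species) {
    stop("visitation_rates must have one rate per insect species",
         call. = FALSE)
  }
  if (!is.null(species_weights_mg)) {
    if (length(species_weights_mg) != n_insect_species ||
        any(species_weights_mg <= 0)) {
      stop("species_weights_mg must be positive, one per species",
           call. = FALSE)
    }
  }
  if (is.null(species_names)) {
    species_names <- paste0("species_", seq_len(n_insect_species))
  }
  if (length(species_names) != n_insect_species ||
      anyDuplicated(species_names)) {
    stop("species_names must be unique, one per species", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_otus = as.integer(n_otus),
    n_insect_species = as.integer(n_insect_species),
    n_signature_otus_per_species = as.integer(n_signature_otus_per_species),
    signature_enrichment = signature_enrichment,
    flower_baseline_concentration = flower_baseline_concentration,
    insect_concentration = insect_concentration,
    body_weight_mg_range = body_weight_mg_range,
    load_intercept = load_intercept, load_slope = load_slope,
    load_model = load_model, transfer_fraction = transfer_fraction,
    flower_baseline_cells = flower_baseline_cells,
    individual_jitter_concentration = individual_jitter_concentration,
    sequencing_depth_mean = as.integer(sequencing_depth_mean),
    replicates_per_group = as.integer(replicates_per_group),
    visitation_rates = visitation_rates,
    species_weights_mg = species_weights_mg,
    species_names = species_names
  ), class = "simulation_config")
}

#' True microbial load of an insect from its body weight
#'
#' @param config a [simulation_config()].
#' @param weight_mg body weight(s) in mg.
#' @return expected cell load(s), floored at 0.
#' @export
true_load <- function(config, weight_mg) {
  if (config$load_model == "linear") {
    pmax(0, config$load_intercept + config$load_slope * weight_mg)
  } else {
    10^(config$load_intercept + config$load_slope * log10(weight_mg))
  }
}

# Draw the per-species relative-abundance profiles and signature sets.
# signature_enrichment e acts on the host/non-host concentration ratio:
# a signature OTU's Dirichlet concentration is multiplied by e in its host
# species and divided by e everywhere else (other species and the flower
# baseline), modelling host-specific symbionts that are frequent on their
# host and almost absent elsewhere. e = 1 leaves all profiles exchangeable.
.draw_species <- function(cfg) {
  n_sig_total <- cfg$n_signature_otus_per_species * cfg$n_insect_species
  sig_pool <- if (n_sig_total > 0) sample.int(cfg$n_otus, n_sig_total)
              else integer(0)
  sig_sets <- if (n_sig_total > 0) {
    split(sig_pool, rep(seq_len(cfg$n_insect_species),
                        each = cfg$n_signature_otus_per_species))
  } else {
    rep(list(integer(0)), cfg$n_insect_species)
  }
  profiles <- matrix(0, cfg$n_insect_species, cfg$n_otus,
                     dimnames = list(cfg$species_names, .otu_ids(cfg)))
  for (s in seq_len(cfg$n_insect_species)) {
    alpha <- rep(cfg$insect_concentration, cfg$n_otus)
    foreign <- setdiff(sig_pool, sig_sets[[s]])
    alpha[foreign] <- alpha[foreign] / cfg$signature_enrichment
    alpha[sig_sets[[s]]] <- alpha[sig_sets[[s]]] * cfg$signature_enrichment
    profiles[s, ] <- rdirichlet(1, alpha)
  }
  names(sig_sets) <- cfg$species_names
  list(profiles = profiles, signature_idx = sig_pool,
       signature_otus = lapply(sig_sets, function(i) .otu_ids(cfg)[i]))
}

# flower baseline: insect signature OTUs are down-weighted the same way
.draw_flower_baseline <- function(cfg, signature_idx) {
  alpha <- rep(cfg$flower_baseline_concentration, cfg$n_otus)
  alpha[signature_idx] <- alpha[signature_idx] / cfg$signature_enrichment
  drop(rdirichlet(1, alpha))
}

.otu_ids <- function(cfg) sprintf("otu_%03d", seq_len(cfg$n_otus))

.individual_profile <- function(cfg, species_profile) {
  if (cfg$individual_jitter_concentration <= 0) return(species_profile)
  drop(rdirichlet(1, cfg$individual_jitter_concentration * species_profile))
}

.sequence_counts <- function(cfg, profile) {
  depth <- max(1L, stats::rpois(1, cfg$sequencing_depth_mean))
  drop(stats::rmultinom(1, depth, profile))
}

.insect_weight <- function(cfg, species_idx) {
  if (!is.null(cfg$species_weights_mg)) cfg$species_weights_mg[species_idx]
  else stats::runif(1, cfg$body_weight_mg_range[1],
                    cfg$body_weight_mg_range[2])
}

#' Simulate surface microbial communities of field-collected insects
#'
#' Draws one community profile per insect species, then for each individual
#' a body weight, a true cell load from the weight-load model, a jittered
#' individual profile, and multinomial read counts at Poisson-jittered
#' depth. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `table` (integer count matrix, one row per insect
#'   sample), `metadata` (sample metadata data.frame), and `truth` (list
#'   with `species_profiles`, `signature_otus`, `cell_loads`,
#'   `body_weights_mg`, `transfer_events` (NULL here),
#'   `true_visitation_rates`).
#' @export
simulate_insect_communities <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .sim_insects(config))
}

.sim_insects <- function(cfg) {
  sp <- .draw_species(cfg)
  n_samples <- cfg$n_insect_species * cfg$replicates_per_group
  counts <- matrix(0L, n_samples, cfg$n_otus,
                   dimnames = list(NULL, .otu_ids(cfg)))
  ids <- character(n_samples)
  species <- character(n_samples)
  weights <- numeric(n_samples)
  loads <- numeric(n_samples)
  row <- 0L
  for (s in seq_len(cfg$n_insect_species)) {
    for (r in seq_len(cfg$replicates_per_group)) {
      row <- row + 1L
      ids[row] <- paste0(cfg$species_names[s], "_", r)
      species[row] <- cfg$species_names[s]
      weights[row] <- .insect_weight(cfg, s)
      loads[row] <- true_load(cfg, weights[row])
      prof <- .individual_profile(cfg, sp$profiles[s, ])
      counts[row, ] <- .sequence_counts(cfg, prof)
    }
  }
  rownames(counts) <- ids
  metadata <- data.frame(sample_id = ids, sample_class = "insect",
                         group = species, body_weight_mg = weights)
  truth <- list(species_profiles = sp$profiles,
                signature_otus = sp$signature_otus,
                signature_idx = sp$signature_idx,
                cell_loads = stats::setNames(loads, ids),
                body_weights_mg = stats::setNames(weights, ids),
                transfer_events = NULL,
                true_visitation_rates = stats::setNames(
                  cfg$visitation_rates, cfg$species_names))
  list(table = counts, metadata = metadata, truth = truth)
}

#' Simulate a laboratory insect-flower contact experiment
#'
#' Each simulated insect is paired with one flower: the flower's cell
#' community after contact is the sum of its own baseline cells and the
#' cells deposited by the insect (`transfer_fraction` times the insect's
#' load, in the insect's community proportions), renormalized and
#' sequenced. Control flowers receive no deposit. Groups emitted in the
#' metadata are the insect species, `touched_by_<species>`, and
#' `"control"`.
#'
#' @param config a [simulation_config()].
#' @return list with `table`, `metadata`, and `truth`; `truth$transfer_events`
#'   records, per contact, the insect sample, flower sample, and deposited
#'   cell count (always <= the insect's load).
#' @export
simulate_contact_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .sim_contact(config))
}

.sim_contact <- function(cfg) {
  sp <- .draw_species(cfg)
  flower_base <- .draw_flower_baseline(cfg, sp$signature_idx)
  n_insects <- cfg$n_insect_species * cfg$replicates_per_group
  n_samples <- 2L * n_insects + cfg$replicates_per_group
  counts <- matrix(0L, n_samples, cfg$n_otus,
                   dimnames = list(NULL, .otu_ids(cfg)))
  md <- data.frame(sample_id = character(n_samples),
                   sample_class = character(n_samples),
                   group = character(n_samples),
                   body_weight_mg = NA_real_)
  events <- data.frame(insect_sample = character(n_insects),
                       flower_sample = character(n_insects),
                       deposited_cells = numeric(n_insects))
  loads <- numeric(0)
  row <- 0L; ev <- 0L
  for (s in seq_len(cfg$n_insect_species)) {
    for (r in seq_len(cfg$replicates_per_group)) {
      w <- .insect_weight(cfg, s)
      load <- true_load(cfg, w)
      iprof <- .individual_profile(cfg, sp$profiles[s, ])
      # insect sample
      row <- row + 1L
      iid <- paste0(cfg$species_names[s], "_", r)
      md[row, ] <- list(iid, "insect", cfg$species_names[s], w)
      counts[row, ] <- .sequence_counts(cfg, iprof)
      loads[iid] <- load
      # its touched flower
      deposited <- cfg$transfer_fraction * load
      fprof <- .individual_profile(cfg, flower_base)
      cells <- cfg$flower_baseline_cells * fprof + deposited * iprof
      row <- row + 1L
      fid <- paste0("flower_", cfg$species_names[s], "_", r)
      md[row, ] <- list(fid, "flower",
                        paste0("touched_by_", cfg$species_names[s]),
                        NA_real_)
      counts[row, ] <- .sequence_counts(cfg, cells / sum(cells))
      ev <- ev + 1L
      events[ev, ] <- list(iid, fid, deposited)
    }
  }
  for (r in seq_len(cfg$replicates_per_group)) {
    fprof <- .individual_profile(cfg, flower_base)
    row <- row + 1L
    md[row, ] <- list(paste0("flower_control_", r), "flower", "control",
                      NA_real_)
    counts[row, ] <- .sequence_counts(cfg, fprof)
  }
  rownames(counts) <- md$sample_id
  truth <- list(species_profiles = sp$profiles,
                flower_baseline_profile = flower_base,
                signature_otus = sp$signature_otus,
                cell_loads = loads,
                transfer_events = events,
                true_visitation_rates = stats::setNames(
                  cfg$visitation_rates, cfg$species_names))
  list(table = counts, metadata = md, truth = truth)
}

#' Simulate a visual visitation census
#'
#' Per plot, session, and insect species, the number of observed visits is
#' Poisson with the species' visitation rate.
#'
#' @param config a [simulation_config()] (supplies the species and rates).
#' @param n_plots number of census plots.
#' @param n_sessions number of sessions per plot.
#' @param seed seed (defaults to `config$seed`).
#' @return a `data.frame` with columns `plot`, `session`, `taxon`, `count`.
#' @export
simulate_visitation <- function(config, n_plots, n_sessions,
                                seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  .assert_scalar(n_plots, "n_plots", lower = 1, integer = TRUE)
  .assert_scalar(n_sessions, "n_sessions", lower = 1, integer = TRUE)
  rates <- config$visitation_rates
  if (any(rates < 0)) stop("negative visitation rate", call. = FALSE)
  grid <- expand.grid(plot = seq_len(n_plots), session = seq_len(n_sessions),
                      taxon = config$species_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- withr::with_seed(seed, {
    stats::rpois(nrow(grid),
                 rates[match(grid$taxon, config$species_names)])
  })
  grid
}

#' Simulate a field study: insects, visited flowers, and ground truth
#'
#' The field scenario behind the fingerprint inference: each flower
#' receives a Poisson number of visits from every insect species (at the
#' species' visitation rate), each visit depositing
#' `transfer_fraction x load` cells in the visiting species' community
#' proportions on top of the flower's baseline community. Insect samples
#' are drawn as in [simulate_insect_communities()] from the same species
#' profiles.
#'
#' @param config a [simulation_config()].
#' @param n_flowers number of flower samples.
#' @param flower_group metadata group label for the flowers.
#' @return list with `table` (insect + flower samples), `metadata`, and
#'   `truth` (adds `visits`: flowers x species matrix of realized visit
#'   counts, and `deposited_cells`: same shape).
#' @export
simulate_field_study <- function(config, n_flowers = 5,
                                 flower_group = "flower") {
  stopifnot(inherits(config, "simulation_config"))
  .assert_scalar(n_flowers, "n_flowers", lower = 1, integer = TRUE)
  withr::with_seed(config$seed, {
    ins <- .sim_insects(config)
    cfg <- config
    flower_base <- .draw_flower_baseline(cfg, ins$truth$signature_idx)
    # one representative weight/load per species for deposition
    sp_weights <- vapply(seq_len(cfg$n_insect_species),
                         function(s) .insect_weight(cfg, s), numeric(1))
    sp_loads <- true_load(cfg, sp_weights)
    visits <- matrix(0L, n_flowers, cfg$n_insect_species,
                     dimnames = list(paste0("flower_", seq_len(n_flowers)),
                                     cfg$species_names))
    deposited <- matrix(0, n_flowers, cfg$n_insect_species,
                        dimnames = dimnames(visits))
    fcounts <- matrix(0L, n_flowers, cfg$n_otus,
                      dimnames = list(rownames(visits), .otu_ids(cfg)))
    for (f in seq_len(n_flowers)) {
      v <- stats::rpois(cfg$n_insect_species, cfg$visitation_rates)
      visits[f, ] <- v
      dep <- v * cfg$transfer_fraction * sp_loads
      deposited[f, ] <- dep
      fprof <- .individual_profile(cfg, flower_base)
      cells <- cfg$flower_baseline_cells * fprof +
        drop(dep %*% ins$truth$species_profiles)
      fcounts[f, ] <- .sequence_counts(cfg, cells / sum(cells))
    }
    metadata <- rbind(
      ins$metadata,
      data.frame(sample_id = rownames(visits), sample_class = "flower",
                 group = flower_group, body_weight_mg = NA_real_))
    truth <- ins$truth
    truth$flower_baseline_profile <- flower_base
    truth$visits <- visits
    truth$deposited_cells <- deposited
    truth$species_loads <- stats::setNames(sp_loads, cfg$species_names)
    list(table = rbind(ins$table, fcounts), metadata = metadata,
         truth = truth)
  })
}

#' Simulate a DAPI-stained micrograph with a known number of cells
#'
#' Renders `n_cells` Gaussian spots on a uniform background, with centers
#' placed by rejection sampling under a minimum separation of
#' `4 * spot_sigma_px`, so every planted cell is unambiguously countable.
#' Optional Gaussian pixel noise. Bit-identical given `seed`.
#'
#' @param n_cells number of cells to plant (>= 0).
#' @param image_shape image dimensions (rows, cols), each >= 16.
#' @param spot_sigma_px Gaussian spot width in pixels.
#' @param background_level uniform background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise (0 =
#'   noise-free).
#' @param seed integer seed.
#' @param peak_intensity spot amplitude above background.
#' @return a `cell_count_image` with `pixels`, `pixel_size_um`, and
#'   `planted_centers` (n x 2 matrix of row/col centers).
#' @export
simulate_dapi_image <- function(n_cells, image_shape = c(256, 256),
                                spot_sigma_px = 2, background_level = 0.1,
                                noise_sd = 0, seed = 1,
                                peak_intensity = 0.6) {
  .assert_scalar(n_cells, "n_cells", lower = 0, integer = TRUE)
  if (length(image_shape) != 2L || any(image_shape < 16)) {
    stop("image_shape must be two integers >= 16", call. = FALSE)
  }
  .assert_scalar(spot_sigma_px, "spot_sigma_px", lower = 0,
                 strict_lower = TRUE)
  .assert_scalar(noise_sd, "noise_sd", lower = 0)
  min_sep <- 4 * spot_sigma_px
  margin <- ceiling(3 * spot_sigma_px)
  usable <- (image_shape - 2 * margin)
  if (any(usable < 1)) stop("image too small for spot size", call. = FALSE)
  # quick packing bound before attempting placement
  if (n_cells * min_sep^2 > 2 * prod(usable)) {
    stop("n_cells too large for the minimum-separation constraint",
         call. = FALSE)
  }
  img <- matrix(background_level, image_shape[1], image_shape[2])
  centers <- matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("row", "col")))
  withr::with_seed(seed, {
    if (n_cells > 0) {
      placed <- matrix(NA_real_, n_cells, 2)
      k <- 0L
      attempts <- 0L
      max_attempts <- 2000L * n_cells
      while (k < n_cells) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("n_cells too large for the minimum-separation constraint",
               call. = FALSE)
        }
        cand <- c(stats::runif(1, margin + 1, image_shape[1] - margin),
                  stats::runif(1, margin + 1, image_shape[2] - margin))
        if (k > 0L) {
          dd <- sqrt((placed[seq_len(k), 1] - cand[1])^2 +
                       (placed[seq_len(k), 2] - cand[2])^2)
          if (min(dd) < min_sep) next
        }
        k <- k + 1L
        placed[k, ] <- cand
      }
      centers <- placed
      colnames(centers) <- c("row", "col")
      win <- ceiling(5 * spot_sigma_px)
      for (i in seq_len(n_cells)) {
        r0 <- max(1L, floor(centers[i, 1]) - win)
        r1 <- min(image_shape[1], floor(centers[i, 1]) + win)
        c0 <- max(1L, floor(centers[i, 2]) - win)
        c1 <- min(image_shape[2], floor(centers[i, 2]) + win)
        rr <- r0:r1; cc <- c0:c1
        g <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
        img[rr, cc] <- img[rr, cc] +
          peak_intensity * exp(-g / (2 * spot_sigma_px^2))
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow(img), ncol(img))
    }
  })
  img <- pmax(img, 0)
  structure(list(pixels = img, pixel_size_um = 0.25,
                 planted_centers = centers),
            class = "cell_count_image")
}

#' Write a simulated dataset to a directory
#'
#' Writes `otu_table.tsv`, `metadata.tsv`, and `truth.json` (ground truth,
#' JSON-serialized) into `dir`.
#'
#' @param sim output of one of the table-producing `simulate_*` functions.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_otu_table(sim$table, file.path(dir, "otu_table.tsv"))
  write_sample_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
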