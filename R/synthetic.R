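# Run code with a private RNG state, seeded; restores the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Region fusion-order presets
#'
#' The two infraclass-specific region fusion orders, as permutations of
#' Krogman region ordinals from first-fusing to last: the placental
#' order coincides with the classical Krogman order (vault, cranial
#' base, circum-meatal, palate, facial, cranio-facial); the marsupial
#' order is vault, cranio-facial, facial, circum-meatal, palate,
#' cranial base.
#'
#' @param preset `"placental"` or `"marsupial"`.
#' @return Integer vector of length 6, region ordinals in fusion order.
#' @export
region_order_preset <- function(preset = c("placental", "marsupial")) {
  preset <- match.arg(preset)
  switch(preset,
         placental = c(1L, 2L, 3L, 4L, 5L, 6L),
         marsupial = c(1L, 6L, 5L, 3L, 4L, 2L))
}

#' Simulation configuration
#'
#' Parameters of the synthetic ontogenetic fusion dataset. Defaults
#' mirror the study conditions the generator emulates: 22 species with
#' 4-13 specimens each spanning foetal to adult, 31 sutures over the six
#' Krogman regions, an infraclass-specific region fusion order, species-
#' level fusion offsets evolving under Brownian motion on a pure-birth
#' tree, and realistic missingness.
#'
#' @param n_species Number of species (tips).
#' @param specimens_per_species Length-2 integer range, specimens sampled
#'   uniformly per species.
#' @param suture_map A `suture_map`; default the bundled 31-suture map.
#' @param preset `"placental"` or `"marsupial"`; sets `region_order` and
#'   the metadata infraclass.
#' @param region_order Optional explicit permutation of region ordinals
#'   1-6 (first-fusing first); overrides `preset`.
#' @param onset_base Age (on the (0,1] ontogeny axis) at which the
#'   first-fusing region's sutures reach half fusion.
#' @param onset_spread Onset gap between successive regions.
#' @param slope Steepness of the logistic latent fusion trajectory.
#' @param jitter_sd SD of per-suture onset jitter around its region onset.
#' @param noise_sd SD of specimen-level noise on the latent fusion
#'   fraction (0-1 scale).
#' @param missing_rate Probability a cell is recorded as `?`.
#' @param absent_bone_rate Probability a species lacks one of the
#'   variably present bones (its suture then scores 1 throughout).
#' @param bm_sigma2,bm_root Brownian rate and root value of the species-
#'   level onset offsets (age units squared per unit tree depth).
#' @param seed Integer master seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 22L,
                       specimens_per_species = c(4L, 13L),
                       suture_map = NULL,
                       preset = c("placental", "marsupial"),
                       region_order = NULL,
                       onset_base = 0.35, onset_spread = 0.12,
                       slope = 6, jitter_sd = 0.03, noise_sd = 0.05,
                       missing_rate = 0.03, absent_bone_rate = 0.15,
                       bm_sigma2 = 0.005, bm_root = 0,
                       seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(suture_map)) suture_map <- krogman_sutures()
  if (is.null(region_order)) region_order <- region_order_preset(preset)
  region_order <- as.integer(region_order)
  if (!identical(sort(region_order), 1:6)) {
    stop("region_order must be a permutation of 1..6")
  }
  stopifnot(n_species >= 2, length(specimens_per_species) == 2,
            specimens_per_species[1] >= 1,
            diff(specimens_per_species) >= 0,
            noise_sd >= 0, jitter_sd >= 0, bm_sigma2 >= 0,
            missing_rate >= 0, missing_rate <= 1,
            absent_bone_rate >= 0, absent_bone_rate <= 1,
            onset_spread > 0, slope > 0)
  cfg <- list(n_species = as.integer(n_species),
              specimens_per_species = as.integer(specimens_per_species),
              suture_map = suture_map, preset = preset,
              region_order = region_order,
              onset_base = onset_base, onset_spread = onset_spread,
              slope = slope, jitter_sd = jitter_sd, noise_sd = noise_sd,
              missing_rate = missing_rate,
              absent_bone_rate = absent_bone_rate,
              bm_sigma2 = bm_sigma2, bm_root = bm_root,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule tree with the stated number of tips, rescaled to total depth 1.
#' Deterministic for a given seed; the caller's RNG state is untouched.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric `ape::phylo` tree of depth 1, tips labelled
#'   `species_01`, `species_02`, ...
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (n_species < 2L) stop("need at least two species")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("species_%02d", seq_len(n_species))
  tree
}

#' Simulate tip values under Brownian motion
#'
#' Recursive simulation from the root: each node's value is its parent's
#' plus a Normal(0, sigma2 * edge length) increment.
#'
#' @param tree An `ape::phylo` tree.
#' @param sigma2 Brownian rate (>= 0).
#' @param root_value State at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values; internal-node values are
#'   kept in attribute `node_states`.
#' @export
simulate_bm_tips <- function(tree, sigma2, root_value = 0, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  n <- length(tree$tip.label)
  states <- numeric(n + tree$Nnode)
  states[n + 1L] <- root_value
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  incr <- with_seed(seed,
                    stats::rnorm(nrow(tree$edge), 0,
                                 sqrt(sigma2 * tree$edge.length)))
  for (e in seq_len(nrow(tree$edge))) {
    states[tree$edge[e, 2]] <- states[tree$edge[e, 1]] + incr[e]
  }
  tips <- stats::setNames(states[seq_len(n)], tree$tip.label)
  attr(tips, "node_states") <- states[(n + 1L):(n + tree$Nnode)]
  tips
}

#' Simulate a complete ontogenetic fusion dataset
#'
#' Generates a score matrix, specimen metadata, and the generating
#' ground truth. Each species receives specimens at ages spread over
#' (0, 1] with a guaranteed adult at age 1 and centroid sizes
#' proportional to age. Each suture's latent fusion fraction follows a
#' logistic trajectory \eqn{f(age) = logistic(slope (age - onset))},
#' with onset determined by its region's position in the configured
#' fusion order, per-suture jitter, and a species-level Brownian offset
#' evolved on the tree. Scores quantize the noisy latent fraction onto
#' the 5-level scale; missing cells (`?`) and species-level absent bones
#' (scored 1) are injected afterwards from an independent substream, so
#' toggling missingness never perturbs the scores.
#'
#' @param config A `sim_config`.
#' @return A `fusion_simulation` list: `matrix` (a `fusion_matrix`),
#'   `meta` (specimen metadata data frame), `tree`, and `truth` (region
#'   order, per-suture onsets, species offsets, ages).
#' @export
simulate_fusion_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phase_seeds <- with_seed(config$seed, sample.int(2^20, 4L))
  smap <- config$suture_map
  n_sut <- nrow(smap)

  tree <- simulate_tree(config$n_species, phase_seeds[1])
  species <- tree$tip.label
  offsets <- simulate_bm_tips(tree, config$bm_sigma2, config$bm_root,
                              phase_seeds[2])

  # region position in the fusion order: 1 = first region to fuse
  region_pos <- match(smap$region, config$region_order)

  sim <- with_seed(phase_seeds[3], {
    onsets <- config$onset_base +
      (region_pos - 1) * config$onset_spread +
      stats::rnorm(n_sut, 0, config$jitter_sd)
    names(onsets) <- smap$suture

    meta <- list(); rows <- list(); ages_all <- list()
    for (sp in species) {
      rng <- config$specimens_per_species
      n_i <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1L)
      ages <- sort(c(stats::runif(n_i - 1L, 0.02, 0.95), 1))
      a_sp <- exp(stats::rnorm(1, log(100), 0.3))
      cs <- a_sp * ages
      ids <- sprintf("%s_s%02d", sp, seq_len(n_i))
      stage <- ifelse(ages == 1, "A", ifelse(ages < 0.25, "F", "I"))
      infracls <- config$preset
      known_age <- ifelse(infracls == "marsupial" & ages < 0.2,
                          round(ages * 100), NA_real_)
      meta[[sp]] <- data.frame(
        specimen_id = ids, species = sp, infraclass = infracls,
        stage = stage, known_age_days = known_age, centroid_size = cs,
        stringsAsFactors = FALSE)
      ages_all[[sp]] <- data.frame(specimen_id = ids, age = ages,
                                   stringsAsFactors = FALSE)

      f <- stats::plogis(config$slope *
                           outer(ages, onsets + offsets[sp], "-"))
      latent <- f + stats::rnorm(length(f), 0, config$noise_sd)
      latent <- pmin(pmax(latent, 0), 1)
      sc <- matrix(1L + as.integer(round(4 * latent)), nrow = n_i,
                   dimnames = list(ids, smap$suture))
      rows[[sp]] <- sc
    }
    list(onsets = onsets, meta = do.call(rbind, meta),
         scores = do.call(rbind, rows),
         ages = do.call(rbind, ages_all))
  })
  scores <- sim$scores

  variably_present <- intersect(
    c("maxillo-jugal", "jugo-squamosal", "premaxillo-maxillary-ventral"),
    smap$suture)
  absent <- with_seed(phase_seeds[4], {
    miss <- matrix(stats::runif(length(scores)) < config$missing_rate,
                   nrow = nrow(scores))
    ab <- expand.grid(species = species, suture = variably_present,
                      stringsAsFactors = FALSE)
    ab <- ab[stats::runif(nrow(ab)) < config$absent_bone_rate, ,
             drop = FALSE]
    list(miss = miss, ab = ab)
  })
  scores[absent$miss] <- NA_integer_
  if (nrow(absent$ab)) {
    for (k in seq_len(nrow(absent$ab))) {
      ids <- sim$meta$specimen_id[sim$meta$species == absent$ab$species[k]]
      scores[ids, absent$ab$suture[k]] <- 1L
    }
  }
  rownames(sim$meta) <- NULL

  structure(list(matrix = fusion_matrix(scores),
                 meta = sim$meta,
                 tree = tree,
                 truth = list(region_order = config$region_order,
                              onsets = sim$onsets,
                              species_offsets = offsets,
                              ages = sim$ages,
                              absent_bones = absent$ab,
                              config = config)),
            class = "fusion_simulation")
}

#' Write a simulated dataset to disk
#'
#' Emits the same plain-text formats the ingestion functions read:
#' `scores.csv`, `metadata.csv`, `sutures.csv`, `tree.nwk`, and
#' `config.yaml`.
#'
#' @param sim A `fusion_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_score_matrix(sim$matrix, file.path(dir, "scores.csv"))
  utils::write.csv(sim$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  smap <- sim$truth$config$suture_map
  utils::write.csv(data.frame(suture = smap$suture,
                              region = smap$region_name,
                              origin = smap$origin),
                   file.path(dir, "sutures.csv"), row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  cfg <- sim$truth$config
  cfg$suture_map <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
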