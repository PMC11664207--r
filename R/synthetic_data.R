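#' Configuration for the synthetic canopy-fogging study generator
#'
#' Builds a validated configuration for [generate_study()]. Defaults emulate
#' the study design the package targets: 4 land-use systems (rainforest `F`,
#' jungle rubber `J`, rubber `R`, oil palm `O`) x 2 landscape clusters x
#' 4 plots = 32 plots, each sampled by 3 subplots x 8 one-square-metre traps,
#' a 14-species pool with nested occupancy across the disturbance gradient
#' (13/10/4/4 species in F/J/R/O), log-normal species abundance with strong
#' dominance, land-use-specific density thinning, and leaf-calibrated isotope
#' offsets with a monoculture d13C shift and niche-range compression.
#'
#' @param n_clusters number of landscape clusters.
#' @param plots_per_landuse_per_cluster plots per land use within each cluster.
#' @param n_subplots subplots per plot.
#' @param traps_per_subplot collection traps per subplot.
#' @param trap_area_m2 area of one trap (m^2).
#' @param effective_area_m2 per-plot area used for density normalisation
#'   (m^2). See [community_density()] for why this defaults to 12.
#' @param species_pool_size size of the regional species pool.
#' @param occupancy_nestedness fraction in `[0, 1]`: 1 forces the species set
#'   of each more-disturbed land use to be a subset of every less-disturbed
#'   one (order F > J > R > O); 0 makes occupancy independent across land uses.
#' @param landuse_occupancy named fractions of the pool present per land use.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma log-scale
#'   parameters of per-trap species mean abundance.
#' @param colonization_scale controls plot-level patchiness: a species of
#'   mean per-trap abundance `lambda` holds a colony in (and can be caught
#'   at) a given plot with probability `1 - exp(-colonization_scale *
#'   lambda)`, so abundant species are omnipresent while sparse species
#'   occupy few plots. Larger values make all species more prevalent.
#' @param landuse_density_factor named multiplicative expected-count factor
#'   per land use.
#' @param plot_dispersion shape of the mean-1 gamma multiplier shared by all
#'   species within a plot; plot total counts are then negative binomial with
#'   this size parameter. Smaller = more between-plot overdispersion.
#' @param species_d13C_offset_mean,species_d13C_offset_sd permil; distribution
#'   of species-level trophic d13C offsets from the leaf baseline.
#' @param species_d15N_offset_mean,species_d15N_offset_sd permil; as above for
#'   d15N (about one trophic level of enrichment).
#' @param landuse_d13C_shift named permil shift added to specimen d13C per
#'   land use (d15N receives no land-use shift).
#' @param landuse_range_compression named factor in `(0, 1]` scaling species
#'   offsets per land use (compresses the between-species isotopic spread).
#' @param within_species_sd permil; individual + measurement noise.
#' @param leaf_d13C_mean,leaf_d13C_sd,leaf_d15N_mean,leaf_d15N_sd permil;
#'   distribution of per-plot pooled-leaf baselines.
#' @param specimens_per_species maximum isotope specimens measured per
#'   functional-community species per plot.
#' @param functional_threshold cumulative relative-abundance threshold
#'   defining the per-plot functional community that receives isotope
#'   measurements (see [select_functional_community()]).
#' @param seed integer RNG seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 2,
                       plots_per_landuse_per_cluster = 4,
                       n_subplots = 3,
                       traps_per_subplot = 8,
                       trap_area_m2 = 1,
                       effective_area_m2 = 12,
                       species_pool_size = 14,
                       occupancy_nestedness = 1,
                       landuse_occupancy = c(F = 13 / 14, J = 10 / 14,
                                             R = 4 / 14, O = 4 / 14),
                       abundance_lognormal_mu = 0.1,
                       abundance_lognormal_sigma = 1.5,
                       colonization_scale = 0.3,
                       landuse_density_factor = c(F = 1, J = 0.87,
                                                  R = 0.145, O = 0.21),
                       plot_dispersion = 1.2,
                       species_d13C_offset_mean = 4,
                       species_d13C_offset_sd = 1.5,
                       species_d15N_offset_mean = 2.5,
                       species_d15N_offset_sd = 1,
                       landuse_d13C_shift = c(F = 0, J = 0, R = -2, O = -1.5),
                       landuse_range_compression = c(F = 1, J = 1,
                                                     R = 0.5, O = 0.5),
                       within_species_sd = 0.5,
                       leaf_d13C_mean = -33, leaf_d13C_sd = 1,
                       leaf_d15N_mean = 2, leaf_d15N_sd = 1,
                       specimens_per_species = 5,
                       functional_threshold = 0.9,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) value_error(paste("sim_config:", msg))
  counts <- c("n_clusters", "plots_per_landuse_per_cluster", "n_subplots",
              "traps_per_subplot", "species_pool_size", "specimens_per_species")
  for (nm in counts) {
    chk(is.numeric(cfg[[nm]]) && length(cfg[[nm]]) == 1 && cfg[[nm]] >= 1 &&
          cfg[[nm]] == round(cfg[[nm]]),
        sprintf("'%s' must be an integer >= 1", nm))
  }
  chk(cfg$trap_area_m2 > 0 && cfg$effective_area_m2 > 0,
      "areas must be > 0")
  chk(cfg$occupancy_nestedness >= 0 && cfg$occupancy_nestedness <= 1,
      "occupancy_nestedness must be in [0, 1]")
  for (nm in c("landuse_occupancy", "landuse_density_factor",
               "landuse_d13C_shift", "landuse_range_compression")) {
    chk(all(LAND_USES %in% names(cfg[[nm]])),
        sprintf("'%s' must be named with all of %s", nm,
                paste(LAND_USES, collapse = ", ")))
  }
  chk(all(cfg$landuse_occupancy > 0 & cfg$landuse_occupancy <= 1),
      "landuse_occupancy fractions must be in (0, 1]")
  chk(all(cfg$landuse_density_factor > 0), "density factors must be > 0")
  chk(all(cfg$landuse_range_compression > 0 &
            cfg$landuse_range_compression <= 1),
      "range-compression factors must be in (0, 1]")
  sds <- c("abundance_lognormal_sigma", "species_d13C_offset_sd",
           "species_d15N_offset_sd", "within_species_sd",
           "leaf_d13C_sd", "leaf_d15N_sd")
  for (nm in sds) chk(cfg[[nm]] >= 0, sprintf("'%s' must be >= 0", nm))
  chk(cfg$plot_dispersion > 0, "'plot_dispersion' must be > 0")
  chk(cfg$colonization_scale > 0, "'colonization_scale' must be > 0")
  chk(cfg$functional_threshold > 0 && cfg$functional_threshold <= 1,
      "'functional_threshold' must be in (0, 1]")
  invisible(cfg)
}

# one master stream split into named per-stage substreams: adding a stage does
# not perturb the draws of earlier stages
stage_seeds <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("pool", "communities", "isotopes", "spare")
  s
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate the regional species pool and land-use occupancy
#'
#' Draws species-level parameters (per-trap log-normal mean abundance and
#' normal isotope offsets from the leaf baseline) and a species x land-use
#' occupancy matrix. At `occupancy_nestedness = 1` the matrix is perfectly
#' nested along the disturbance order F > J > R > O (each more-disturbed
#' land use hosting a subset of the less-disturbed ones); at 0 occupancy is
#' drawn independently per land use. Intermediate values blend a shared
#' species tolerance ranking with independent noise.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for this stage.
#' @return A list with `species` (data frame: `species_id`, `lambda`,
#'   `offset_d13C`, `offset_d15N`, `tolerance_rank`) and `occupancy`
#'   (logical species x land-use matrix).
#' @export
generate_species_pool <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  with_seed(seed, {
    n <- cfg$species_pool_size
    ids <- sprintf("sp%02d", seq_len(n))
    species <- data.frame(
      species_id  = ids,
      lambda      = exp(stats::rnorm(n, cfg$abundance_lognormal_mu,
                                     cfg$abundance_lognormal_sigma)),
      offset_d13C = stats::rnorm(n, cfg$species_d13C_offset_mean,
                                 cfg$species_d13C_offset_sd),
      offset_d15N = stats::rnorm(n, cfg$species_d15N_offset_mean,
                                 cfg$species_d15N_offset_sd),
      tolerance_rank = sample.int(n),
      stringsAsFactors = FALSE
    )
    occ <- matrix(FALSE, n, length(LAND_USES),
                  dimnames = list(ids, LAND_USES))
    w <- cfg$occupancy_nestedness
    for (lu in LAND_USES) {
      k <- max(1L, round(cfg$landuse_occupancy[[lu]] * n))
      # blended score: shared tolerance ranking vs independent noise
      score <- w * species$tolerance_rank + (1 - w) * stats::runif(n, 0, n)
      occ[order(score)[seq_len(k)], lu] <- TRUE
    }
    list(species = species, occupancy = occ)
  })
}

#' Generate plot metadata and a pooled abundance table
#'
#' For every plot, each species present in the plot's land use first has to
#' hold a colony at the plot (Bernoulli with probability
#' `1 - exp(-colonization_scale * lambda)`, making abundant species
#' omnipresent and sparse species patchy). Where present, its count is a
#' Poisson draw summed over all traps with expectation
#' `traps x lambda_species x land-use factor x plot multiplier`; the plot
#' multiplier is gamma distributed (mean 1, shape `plot_dispersion`) and
#' shared by all species of a plot (gamma-Poisson overdispersion of plot
#' totals). Zero draws are omitted from the table.
#'
#' @param cfg a [sim_config()].
#' @param pool result of [generate_species_pool()].
#' @param seed integer seed for this stage.
#' @return A list with `plots` (metadata data frame) and `abundances`.
#' @export
generate_communities <- function(cfg, pool, seed = cfg$seed) {
  validate_sim_config(cfg)
  with_seed(seed, {
    meta <- expand.grid(
      land_use = LAND_USES,
      cluster  = sprintf("C%d", seq_len(cfg$n_clusters)),
      rep      = seq_len(cfg$plots_per_landuse_per_cluster),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    meta$plot_id <- sprintf("%s%s_%d", meta$land_use,
                            sub("^C", "", meta$cluster), meta$rep)
    meta <- data.frame(
      plot_id = meta$plot_id, land_use = meta$land_use,
      cluster = meta$cluster,
      n_subplots = cfg$n_subplots,
      traps_per_subplot = cfg$traps_per_subplot,
      trap_area_m2 = cfg$trap_area_m2,
      effective_area_m2 = cfg$effective_area_m2,
      stringsAsFactors = FALSE
    )
    meta <- meta[order(meta$plot_id), , drop = FALSE]
    rownames(meta) <- NULL

    n_traps <- cfg$n_subplots * cfg$traps_per_subplot
    rows <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      lu <- meta$land_use[i]
      present <- pool$species$species_id[pool$occupancy[, lu]]
      if (length(present) == 0) next
      m <- stats::rgamma(1, shape = cfg$plot_dispersion,
                         rate = cfg$plot_dispersion)
      lam <- pool$species$lambda[match(present, pool$species$species_id)]
      colonised <- stats::runif(length(present)) <
        1 - exp(-cfg$colonization_scale * lam)
      mu <- n_traps * lam * cfg$landuse_density_factor[[lu]] * m * colonised
      cnt <- stats::rpois(length(present), mu)
      keep <- cnt > 0
      if (!any(keep)) next
      rows[[i]] <- data.frame(plot_id = meta$plot_id[i],
                              species_id = present[keep],
                              count = as.integer(cnt[keep]),
                              stringsAsFactors = FALSE)
    }
    ab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(ab)) {
      ab <- data.frame(plot_id = character(0), species_id = character(0),
                       count = integer(0))
    }
    rownames(ab) <- NULL
    list(plots = meta, abundances = ab)
  })
}

#' Generate leaf baselines and specimen-level isotope measurements
#'
#' Each plot receives one pooled-leaf baseline. Specimens are emitted only
#' for the plot's functional community (the most-abundant species cumulating
#' to the functional threshold, as in the measurement protocol), with
#' `min(specimens_per_species, count)` individuals per species and
#'
#' \deqn{\delta^{13}C = leaf + offset_{s} \cdot compression(LU) + shift(LU) + \epsilon}
#' \deqn{\delta^{15}N = leaf + offset_{s} \cdot compression(LU) + \epsilon}
#'
#' with independent Gaussian noise of sd `within_species_sd`.
#'
#' @param cfg a [sim_config()].
#' @param communities result of [generate_communities()].
#' @param pool result of [generate_species_pool()].
#' @param seed integer seed for this stage.
#' @return A list with `specimens` and `baselines` data frames.
#' @export
generate_isotopes <- function(cfg, communities, pool, seed = cfg$seed) {
  validate_sim_config(cfg)
  with_seed(seed, {
    meta <- communities$plots
    ab <- communities$abundances
    baselines <- data.frame(
      plot_id = meta$plot_id,
      d13C_leaf = stats::rnorm(nrow(meta), cfg$leaf_d13C_mean,
                               cfg$leaf_d13C_sd),
      d15N_leaf = stats::rnorm(nrow(meta), cfg$leaf_d15N_mean,
                               cfg$leaf_d15N_sd),
      stringsAsFactors = FALSE
    )
    rows <- list()
    for (i in seq_len(nrow(meta))) {
      pid <- meta$plot_id[i]
      lu <- meta$land_use[i]
      sub <- ab[ab$plot_id == pid, , drop = FALSE]
      if (nrow(sub) == 0) next
      counts <- stats::setNames(sub$count, sub$species_id)
      fc <- select_functional_community(counts, cfg$functional_threshold)
      comp <- cfg$landuse_range_compression[[lu]]
      shift <- cfg$landuse_d13C_shift[[lu]]
      for (s in fc) {
        n_spec <- min(cfg$specimens_per_species, counts[[s]])
        j <- match(s, pool$species$species_id)
        rows[[length(rows) + 1L]] <- data.frame(
          plot_id = pid, species_id = s,
          d13C = baselines$d13C_leaf[i] +
            pool$species$offset_d13C[j] * comp + shift +
            stats::rnorm(n_spec, 0, cfg$within_species_sd),
          d15N = baselines$d15N_leaf[i] +
            pool$species$offset_d15N[j] * comp +
            stats::rnorm(n_spec, 0, cfg$within_species_sd),
          stringsAsFactors = FALSE
        )
      }
    }
    specimens <- if (length(rows)) do.call(rbind, rows) else
      data.frame(plot_id = character(0), species_id = character(0),
                 d13C = numeric(0), d15N = numeric(0))
    rownames(specimens) <- NULL
    list(specimens = specimens, baselines = baselines)
  })
}

#' Generate a complete synthetic study
#'
#' Runs the three generator stages on named RNG substreams derived from
#' `cfg$seed` (so results are deterministic in the seed and stages do not
#' perturb each other), assembles a validated [iso_dataset()], and returns
#' the ground truth needed for parameter-recovery checks.
#'
#' @param cfg a [sim_config()].
#' @return A list with `dataset` (an `iso_dataset`) and `truth` (list:
#'   `species` offsets and abundances, `occupancy` matrix, `landuse` data
#'   frame of true shift/compression/density factor and expected density per
#'   square metre, and the `config`).
#' @export
#' @examples
#' study <- generate_study(sim_config(seed = 42))
#' study$dataset
generate_study <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  seeds <- stage_seeds(cfg$seed)
  pool <- generate_species_pool(cfg, seeds[["pool"]])
  comm <- generate_communities(cfg, pool, seeds[["communities"]])
  iso <- generate_isotopes(cfg, comm, pool, seeds[["isotopes"]])
  ds <- iso_dataset(comm$plots, comm$abundances, iso$specimens, iso$baselines)

  n_traps <- cfg$n_subplots * cfg$traps_per_subplot
  expected_density <- vapply(LAND_USES, function(lu) {
    lam <- pool$species$lambda[pool$occupancy[, lu]]
    p_col <- 1 - exp(-cfg$colonization_scale * lam)
    sum(p_col * n_traps * lam * cfg$landuse_density_factor[[lu]]) /
      cfg$effective_area_m2
  }, numeric(1))
  truth <- list(
    species = pool$species,
    occupancy = pool$occupancy,
    landuse = data.frame(
      land_use = LAND_USES,
      d13C_shift = as.numeric(cfg$landuse_d13C_shift[LAND_USES]),
      range_compression = as.numeric(cfg$landuse_range_compression[LAND_USES]),
      density_factor = as.numeric(cfg$landuse_density_factor[LAND_USES]),
      expected_density = as.numeric(expected_density),
      stringsAsFactors = FALSE
    ),
    config = cfg
  )
  list(dataset = ds, truth = truth)
}
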