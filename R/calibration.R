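#' Restrict a dataset to identified (Linnaean) species
#'
#' Drops abundance rows and specimens whose species is not in the registry of
#' identified species; counts of retained species are unchanged. Mirrors the
#' common practice of excluding unidentified morphospecies, which would
#' otherwise inflate the weight of very rare taxa in diversity analyses.
#'
#' @param ds an `iso_dataset`.
#' @param registry character vector of identified species.
#' @return The filtered `iso_dataset`. An empty result is a warning, not an
#'   error.
#' @export
filter_identified <- function(ds, registry) {
  if (length(registry) == 0) value_error("species registry must be non-empty")
  ds$abundances <- ds$abundances[ds$abundances$species_id %in% registry, ,
                                 drop = FALSE]
  ds$specimens <- ds$specimens[ds$specimens$species_id %in% registry, ,
                               drop = FALSE]
  rownames(ds$abundances) <- rownames(ds$specimens) <- NULL
  if (nrow(ds$abundances) == 0) {
    warning("no abundance records left after identified-species filter")
  }
  validate_dataset(ds)
}

#' Calibrate specimen isotope values to the plot leaf baseline
#'
#' Converts raw specimen values to basal-resource-calibrated values:
#' `D13C = d13C - d13C_leaf(plot)` and `D15N = d15N - d15N_leaf(plot)`.
#' The leaf baseline anchors every plot's food web at its local primary
#' producers, so calibrated values are comparable across plots and land uses.
#'
#' @param specimens data frame with `plot_id`, `species_id`, `d13C`, `d15N`.
#' @param baselines data frame with `plot_id`, `d13C_leaf`, `d15N_leaf`.
#' @return Data frame with `plot_id`, `species_id`, `D13C`, `D15N`, one row
#'   per specimen (order preserved).
#' @export
#' @examples
#' sp <- data.frame(plot_id = "p1", species_id = "a", d13C = -26, d15N = 4)
#' bl <- data.frame(plot_id = "p1", d13C_leaf = -30, d15N_leaf = 1)
#' calibrate_specimens(sp, bl)  # D13C = 4, D15N = 3
calibrate_specimens <- function(specimens, baselines) {
  missing <- setdiff(unique(specimens$plot_id), baselines$plot_id)
  if (length(missing) > 0) {
    integrity_error(sprintf("no leaf baseline for plot(s): %s",
                            paste(sort(missing), collapse = ", ")))
  }
  i <- match(specimens$plot_id, baselines$plot_id)
  data.frame(
    plot_id = specimens$plot_id,
    species_id = specimens$species_id,
    D13C = specimens$d13C - baselines$d13C_leaf[i],
    D15N = specimens$d15N - baselines$d15N_leaf[i],
    stringsAsFactors = FALSE
  )
}

#' Select the functional community of one plot
#'
#' Orders species by descending count (ties broken by species id, ascending)
#' and returns the shortest prefix whose cumulative relative abundance
#' reaches the threshold; the species crossing the threshold is included.
#' With the default threshold this is "every species that cumulatively
#' contributes at least 90% of the plot's abundance, starting with the most
#' abundant".
#'
#' @param counts named numeric vector, species -> worker count, for one plot.
#' @param threshold cumulative relative-abundance threshold in `(0, 1]`.
#' @return Character vector of species ids, most abundant first. Empty for an
#'   all-zero plot.
#' @export
#' @examples
#' select_functional_community(c(a = 50, b = 30, c = 15, d = 5))  # a, b, c
select_functional_community <- function(counts, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) {
    value_error("functional-community threshold must be in (0, 1]")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(character(0))
  ord <- order(-counts, names(counts))
  cum <- cumsum(counts[ord]) / sum(counts)
  k <- which(cum >= threshold)[1]
  if (is.na(k)) k <- length(counts)  # guard against rounding at threshold 1
  names(counts)[ord][seq_len(k)]
}

#' Per-species-per-plot calibrated means with abundance weights
#'
#' Averages calibrated specimen values per (plot, species), restricted to
#' each plot's functional community, and attaches relative-abundance weights.
#' Weights are renormalised over the functional species that actually have
#' isotope data, so they sum to one per plot: species without specimens
#' cannot contribute isotope values and are excluded rather than biasing the
#' community-weighted mean toward zero.
#'
#' @param calibrated output of [calibrate_specimens()].
#' @param functional named list, plot id -> functional species vector (from
#'   [select_functional_community()]).
#' @param abundances abundance table (`plot_id`, `species_id`, `count`).
#' @return Data frame with `plot_id`, `species_id`, `mean_D13C`, `mean_D15N`,
#'   `n_specimens`, `rel_abundance`.
#' @export
species_plot_means <- function(calibrated, functional, abundances) {
  out <- list()
  for (pid in names(functional)) {
    fc <- functional[[pid]]
    sub <- calibrated[calibrated$plot_id == pid &
                        calibrated$species_id %in% fc, , drop = FALSE]
    if (nrow(sub) == 0) next
    ag <- stats::aggregate(cbind(D13C, D15N) ~ species_id, data = sub,
                           FUN = mean)
    n <- stats::aggregate(D13C ~ species_id, data = sub, FUN = length)
    ag$n_specimens <- n$D13C[match(ag$species_id, n$species_id)]
    cnt <- abundances[abundances$plot_id == pid, , drop = FALSE]
    w <- cnt$count[match(ag$species_id, cnt$species_id)]
    if (any(is.na(w))) {
      integrity_error(sprintf(
        "plot %s: specimens for species absent from the abundance table", pid))
    }
    ag$rel_abundance <- w / sum(w)
    out[[pid]] <- data.frame(
      plot_id = pid, species_id = ag$species_id,
      mean_D13C = ag$D13C, mean_D15N = ag$D15N,
      n_specimens = as.integer(ag$n_specimens),
      rel_abundance = ag$rel_abundance,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(plot_id = character(0), species_id = character(0),
               mean_D13C = numeric(0), mean_D15N = numeric(0),
               n_specimens = integer(0), rel_abundance = numeric(0))
  rownames(res) <- NULL
  res
}

#' Functional communities for every plot of a dataset
#'
#' Convenience wrapper applying [select_functional_community()] plot by plot.
#'
#' @param abundances abundance table (`plot_id`, `species_id`, `count`).
#' @param threshold cumulative relative-abundance threshold.
#' @return Named list: plot id -> character vector of functional species.
#' @export
functional_communities <- function(abundances, threshold = 0.9) {
  plots <- unique(abundances$plot_id)
  stats::setNames(lapply(plots, function(pid) {
    sub <- abundances[abundances$plot_id == pid, , drop = FALSE]
    select_functional_community(stats::setNames(sub$count, sub$species_id),
                                threshold)
  }), plots)
}

#' Exclude plots with insufficient isotope data
#'
#' Plots with fewer than `min_species` species bearing isotope data are
#' excluded from isotope-metric calculation (they remain in community
#' metrics). A single measured species still defines Average/Maximum/Minimum,
#' but a meaningful Range needs at least two, so callers typically use
#' `min_species = 1` for location metrics and 2 for Range; every exclusion
#' is logged with its reason.
#'
#' @param means output of [species_plot_means()].
#' @param min_species minimum number of measured species per plot.
#' @param all_plots optional character vector of every plot that should have
#'   been measurable; plots absent from `means` are then logged with zero
#'   species.
#' @return A list with `means` (restricted to retained plots),
#'   `retained_plots`, and `exclusions` (data frame `plot_id`, `n_species`,
#'   `reason`).
#' @export
filter_insufficient_plots <- function(means, min_species = 1,
                                      all_plots = NULL) {
  if (min_species < 1) value_error("min_species must be >= 1")
  n_by_plot <- table(means$plot_id)
  counts <- stats::setNames(as.integer(n_by_plot), names(n_by_plot))
  if (!is.null(all_plots)) {
    zero <- setdiff(all_plots, names(counts))
    counts[zero] <- 0L
  }
  retained <- names(counts)[counts >= min_species]
  excluded <- names(counts)[counts < min_species]
  exclusions <- data.frame(
    plot_id = excluded,
    n_species = as.integer(counts[excluded]),
    reason = sprintf("only %d species with isotope data (need >= %d)",
                     as.integer(counts[excluded]), min_species),
    stringsAsFactors = FALSE
  )
  rownames(exclusions) <- NULL
  list(
    means = means[means$plot_id %in% retained, , drop = FALSE],
    retained_plots = sort(retained),
    exclusions = exclusions[order(exclusions$plot_id), , drop = FALSE]
  )
}
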