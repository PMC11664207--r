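#' Run the full analysis pipeline
#'
#' Executes the complete analysis on a dataset: identified-species filter,
#' leaf-baseline calibration, functional-community selection, species-per-plot
#' means, plot exclusions, abundance-weighted isotope metrics and biplot
#' points, land-use summaries, community metrics (density, richness, rarity),
#' species-pool estimation, rank-abundance and accumulation curves, land-use
#' overlap, and the land-use statistical contrasts. All stage outputs are
#' returned, and written as CSV/JSON to `output_dir` together with a manifest
#' recording every configurable decision. The run is deterministic given the
#' dataset and configuration.
#'
#' @param ds an `iso_dataset`, or `NULL` to read one from `input_dir`.
#' @param input_dir directory holding the four CSV tables (used when `ds` is
#'   `NULL`).
#' @param output_dir optional directory for the report bundle; created if
#'   needed. When `NULL` nothing is written.
#' @param registry identified-species registry; defaults to every species in
#'   the dataset (i.e. no filtering).
#' @param threshold functional-community cumulative-abundance threshold.
#' @param min_species minimum measured species for a plot to enter the
#'   location metrics (Average/Maximum/Minimum).
#' @param min_species_range minimum measured species for a plot's Range
#'   metrics (a single-species plot has no meaningful Range).
#' @param extremes `"unweighted"` or `"weighted"`, see
#'   [plot_isotope_metrics()].
#' @param accumulation_permutations permutations for the accumulation curves.
#' @param seed integer seed (used by the permutation accumulation curves).
#' @param families optional per-response family overrides, see
#'   [run_all_responses()].
#' @return A list of class `antniche_report` with elements `dataset`,
#'   `calibrated`, `functional`, `means`, `exclusions`, `plot_metrics`,
#'   `biplot`, `landuse_summary`, `community`, `species_pool`,
#'   `rank_abundance`, `accumulation`, `overlap`, `stats`, `manifest`.
#' @export
#' @examples
#' study <- generate_study(sim_config(seed = 7))
#' rep <- run_pipeline(study$dataset)
#' head(rep$plot_metrics)
run_pipeline <- function(ds = NULL, input_dir = NULL, output_dir = NULL,
                         registry = NULL, threshold = 0.9,
                         min_species = 1, min_species_range = 2,
                         extremes = "unweighted",
                         accumulation_permutations = 100,
                         seed = 1, families = NULL) {
  stage <- "read"
  result <- tryCatch({
    if (is.null(ds)) {
      if (is.null(input_dir)) value_error("need a dataset or an input_dir")
      ds <- read_dataset(input_dir)
    }
    validate_dataset(ds)

    stage <- "filter_identified"
    if (is.null(registry)) registry <- species_registry(ds)
    ds <- filter_identified(ds, registry)

    stage <- "calibrate"
    calibrated <- calibrate_specimens(ds$specimens, ds$baselines)

    stage <- "functional_community"
    functional <- functional_communities(ds$abundances, threshold)

    stage <- "species_plot_means"
    means <- species_plot_means(calibrated, functional, ds$abundances)

    stage <- "filter_insufficient_plots"
    filt <- filter_insufficient_plots(means, min_species,
                                      all_plots = ds$plots$plot_id)

    stage <- "isotope_metrics"
    pm <- plot_isotope_metrics(filt$means, extremes)
    # Range needs >= min_species_range measured species
    pm$range_D13C[pm$n_species < min_species_range] <- NA_real_
    pm$range_D15N[pm$n_species < min_species_range] <- NA_real_
    bp <- biplot_points(filt$means, ds$plots)
    ls <- landuse_summary(pm, ds$plots)

    stage <- "community_metrics"
    cm <- community_metrics(ds)
    pool <- chao_pool(ds$abundances, ds$plots)
    ra <- rank_abundance(ds$abundances, ds$plots)
    acc <- do.call(rbind, lapply(
      intersect(LAND_USES, unique(ds$plots$land_use)), function(lu) {
        accumulation_curve(ds$abundances, ds$plots, lu,
                           method = "permutation",
                           n_permutations = accumulation_permutations,
                           seed = seed)
      }))
    ov <- landuse_overlap(ds$abundances, ds$plots)

    stage <- "stats"
    iso_data <- merge(pm, ds$plots[c("plot_id", "land_use", "cluster")],
                      by = "plot_id")
    st <- run_all_responses(cm, iso_data, families)

    manifest <- list(
      package_version = as.character(utils::packageVersion("antniche")),
      r_version = as.character(getRversion()),
      config = list(threshold = threshold, min_species = min_species,
                    min_species_range = min_species_range,
                    extremes = extremes,
                    accumulation_permutations = accumulation_permutations,
                    seed = seed,
                    registry_size = length(registry)),
      n_plots = nrow(ds$plots),
      n_plots_isotope_retained = length(filt$retained_plots),
      exclusions = filt$exclusions
    )
    list(dataset = ds, calibrated = calibrated, functional = functional,
         means = filt$means, exclusions = filt$exclusions,
         plot_metrics = pm, biplot = bp, landuse_summary = ls,
         community = cm, species_pool = pool, rank_abundance = ra,
         accumulation = acc, overlap = ov, stats = st, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(result) <- "antniche_report"
  if (!is.null(output_dir)) write_report(result, output_dir)
  result
}

write_report <- function(report, output_dir) {
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  tables <- c("plot_metrics", "biplot", "landuse_summary", "community",
              "species_pool", "rank_abundance", "accumulation", "stats",
              "means", "calibrated", "exclusions")
  for (nm in tables) {
    utils::write.csv(report[[nm]], file.path(output_dir,
                                             paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$overlap,
                       file.path(output_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(output_dir)
}

#' @export
print.antniche_report <- function(x, ...) {
  cat("<antniche_report>\n")
  cat(sprintf("  %d plots (%d retained for isotope metrics)\n",
              x$manifest$n_plots, x$manifest$n_plots_isotope_retained))
  cat(sprintf("  %d species-plot means, %d statistical responses\n",
              nrow(x$means), nrow(x$stats)))
  invisible(x)
}

#' Plot-ready tidy tables for the standard figures
#'
#' Extracts tidy data series for the usual figure set: the D13C x D15N biplot
#' (per-plot weighted means with SDs), the metric dot plots with land-use
#' means and SDs, the community dot plots (density, richness, rarity), the
#' rank-abundance curves and the overlap partition. Land uses without data in
#' a panel are omitted with a note.
#'
#' @param report an `antniche_report` from [run_pipeline()].
#' @return A list of data frames: `biplot`, `isotope_panels`,
#'   `isotope_group_means`, `community_panels`, `community_group_means`,
#'   `rank_abundance`, `overlap_sets`, plus `notes`.
#' @export
make_figures_data <- function(report) {
  stopifnot(inherits(report, "antniche_report"))
  meta <- report$dataset$plots
  pm <- report$plot_metrics
  pm$land_use <- meta$land_use[match(pm$plot_id, meta$plot_id)]
  metric_cols <- grep("^(average|maximum|minimum|range)_", names(pm),
                      value = TRUE)
  iso_long <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(plot_id = pm$plot_id, land_use = pm$land_use,
               metric = mc, value = pm[[mc]], stringsAsFactors = FALSE)
  }))
  iso_long <- iso_long[!is.na(iso_long$value), , drop = FALSE]

  cm <- report$community
  comm_long <- do.call(rbind, lapply(c("density", "richness", "rarity"),
                                     function(mc) {
    data.frame(plot_id = cm$plot_id, land_use = cm$land_use, metric = mc,
               value = cm[[mc]], stringsAsFactors = FALSE)
  }))

  group_summary <- function(long) {
    ag <- stats::aggregate(value ~ land_use + metric, data = long,
                           FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                               n = length(x)))
    data.frame(land_use = ag$land_use, metric = ag$metric,
               mean = ag$value[, "mean"], sd = ag$value[, "sd"],
               n_plots = ag$value[, "n"], stringsAsFactors = FALSE)
  }
  notes <- character(0)
  empty <- setdiff(unique(meta$land_use), unique(iso_long$land_use))
  if (length(empty) > 0) {
    notes <- c(notes, sprintf("isotope panels omit land use(s) %s (no retained plots)",
                              paste(empty, collapse = ", ")))
  }
  overlap_sets <- data.frame(
    combination = names(report$overlap$partition),
    n_species = vapply(report$overlap$partition, length, integer(1)),
    species = vapply(report$overlap$partition, paste, character(1),
                     collapse = ","),
    stringsAsFactors = FALSE
  )
  rownames(overlap_sets) <- NULL
  list(biplot = report$biplot,
       isotope_panels = iso_long,
       isotope_group_means = group_summary(iso_long),
       community_panels = comm_long,
       community_group_means = group_summary(comm_long),
       rank_abundance = report$rank_abundance,
       overlap_sets = overlap_sets,
       notes = notes)
}
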