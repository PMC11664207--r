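weighted_mean_sd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  s <- if (length(x) > 1) sqrt(sum(w * (x - m)^2)) else NA_real_
  c(mean = m, sd = s)
}

#' Abundance-weighted univariate isotopic niche metrics per plot
#'
#' For each plot and each element (D13C, D15N), computes from the
#' species-per-plot calibrated means:
#' * `average_*`: abundance-weighted mean, `sum(w_i * x_i)` with `w_i` the
#'   renormalised relative abundances;
#' * `maximum_*` / `minimum_*`: extremes over the functional-community
#'   species means;
#' * `range_*`: maximum minus minimum.
#'
#' With `extremes = "unweighted"` (default) the extremes are taken over the
#' raw species means: abundance weights decide which species are in the
#' functional community and how much they contribute to the Average, but a
#' species' isotopic position is not rescaled by its abundance. The
#' alternative reading, `extremes = "weighted"`, takes extremes over the
#' products `w_i * x_i`; it is provided for comparability but is hard to
#' interpret for calibrated values that can be negative.
#'
#' @param means output of [species_plot_means()] (after plot filtering).
#' @param extremes `"unweighted"` or `"weighted"` (see Details).
#' @return Data frame with one row per plot: `plot_id`, `n_species`, and
#'   `average_`, `maximum_`, `minimum_`, `range_` for `D13C` and `D15N`.
#' @export
plot_isotope_metrics <- function(means, extremes = c("unweighted", "weighted")) {
  extremes <- match.arg(extremes)
  plots <- unique(means$plot_id)
  rows <- lapply(plots, function(pid) {
    sub <- means[means$plot_id == pid, , drop = FALSE]
    w <- sub$rel_abundance / sum(sub$rel_abundance)
    one <- list(plot_id = pid, n_species = nrow(sub))
    for (el in c("D13C", "D15N")) {
      x <- sub[[paste0("mean_", el)]]
      xe <- if (extremes == "weighted") w * x else x
      one[[paste0("average_", el)]] <- sum(w * x)
      one[[paste0("maximum_", el)]] <- max(xe)
      one[[paste0("minimum_", el)]] <- min(xe)
      one[[paste0("range_", el)]] <- max(xe) - min(xe)
    }
    as.data.frame(one, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(plot_id = character(0), n_species = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-plot biplot points (abundance-weighted mean and SD)
#'
#' Plot-level summaries for the D13C x D15N biplot: abundance-weighted mean
#' and abundance-weighted standard deviation
#' `sqrt(sum(w_i * (x_i - xbar)^2))` across species means. The SD is
#' undefined (NA) for single-species plots.
#'
#' @param means output of [species_plot_means()].
#' @param meta plot metadata (`plot_id`, `land_use`).
#' @return Data frame with `plot_id`, `land_use`, `n_species`, `mean_D13C`,
#'   `sd_D13C`, `mean_D15N`, `sd_D15N`.
#' @export
biplot_points <- function(means, meta) {
  plots <- unique(means$plot_id)
  rows <- lapply(plots, function(pid) {
    sub <- means[means$plot_id == pid, , drop = FALSE]
    c13 <- weighted_mean_sd(sub$mean_D13C, sub$rel_abundance)
    n15 <- weighted_mean_sd(sub$mean_D15N, sub$rel_abundance)
    data.frame(plot_id = pid,
               land_use = meta$land_use[match(pid, meta$plot_id)],
               n_species = nrow(sub),
               mean_D13C = c13[["mean"]], sd_D13C = c13[["sd"]],
               mean_D15N = n15[["mean"]], sd_D15N = n15[["sd"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Land-use summary of isotope metrics (mean and SD across plots)
#'
#' Unweighted mean and sample standard deviation (n-1 denominator) of every
#' plot-level metric within each land use, the usual "means +- SD" reporting.
#' Land uses with no retained plots are omitted with a warning.
#'
#' @param metrics output of [plot_isotope_metrics()].
#' @param meta plot metadata (`plot_id`, `land_use`).
#' @return Data frame with `land_use`, `metric`, `mean`, `sd`, `n_plots`.
#' @export
landuse_summary <- function(metrics, meta) {
  metrics$land_use <- meta$land_use[match(metrics$plot_id, meta$plot_id)]
  metric_cols <- grep("^(average|maximum|minimum|range)_", names(metrics),
                      value = TRUE)
  present <- intersect(LAND_USES, unique(metrics$land_use))
  absent <- setdiff(intersect(LAND_USES, unique(meta$land_use)), present)
  if (length(absent) > 0) {
    warning(sprintf("no retained plots in land use(s): %s",
                    paste(absent, collapse = ", ")))
  }
  rows <- list()
  for (lu in present) {
    sub <- metrics[metrics$land_use == lu, , drop = FALSE]
    for (mc in metric_cols) {
      x <- sub[[mc]][!is.na(sub[[mc]])]
      rows[[length(rows) + 1L]] <- data.frame(
        land_use = lu, metric = mc,
        mean = mean(x),
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        n_plots = length(x),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
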