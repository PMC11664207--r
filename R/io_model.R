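#' @keywords internal
"_PACKAGE"

#' Land-use systems of the study design
#'
#' Closed vocabulary of land-use codes, ordered from least to most disturbed:
#' `F` lowland rainforest, `J` jungle rubber (rubber agroforestry), `R` rubber
#' monoculture, `O` oil palm monoculture.
#'
#' @format Character vector of length 4.
#' @export
LAND_USES <- c("F", "J", "R", "O")

# classed conditions so callers/tests can distinguish the error taxonomy:
# schema (missing/wrong columns), integrity (dangling references), value
# (out-of-domain numbers)
abort_antniche <- function(message, class) {
  stop(structure(
    class = c(class, "antniche_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

schema_error    <- function(msg) abort_antniche(msg, "antniche_schema_error")
integrity_error <- function(msg) abort_antniche(msg, "antniche_integrity_error")
value_error     <- function(msg) abort_antniche(msg, "antniche_value_error")

DATASET_SCHEMAS <- list(
  plots = c("plot_id", "land_use", "cluster", "n_subplots",
            "traps_per_subplot", "trap_area_m2", "effective_area_m2"),
  abundances = c("plot_id", "species_id", "count"),
  specimens  = c("plot_id", "species_id", "d13C", "d15N"),
  baselines  = c("plot_id", "d13C_leaf", "d15N_leaf")
)

check_schema <- function(df, table) {
  required <- DATASET_SCHEMAS[[table]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    schema_error(sprintf("table '%s' is missing required column(s): %s",
                         table, paste(missing, collapse = ", ")))
  }
  df[required]
}

#' Construct a plot-based ant survey dataset
#'
#' Bundles the four tables of a canopy-fogging survey: plot metadata,
#' a plot x species abundance table (worker counts pooled over subplots),
#' specimen-level isotope measurements, and per-plot leaf baselines used to
#' calibrate consumer isotope values to the local basal resource.
#'
#' @param plots data frame with columns `plot_id`, `land_use` (one of
#'   [LAND_USES]), `cluster`, `n_subplots`, `traps_per_subplot`,
#'   `trap_area_m2`, `effective_area_m2`.
#' @param abundances data frame with columns `plot_id`, `species_id`,
#'   `count` (non-negative integer workers, pooled over subplots).
#' @param specimens data frame with columns `plot_id`, `species_id`, `d13C`
#'   (permil vs VPDB), `d15N` (permil vs atmospheric N2). A specimen row must
#'   have both elements measured; partial records are rejected.
#' @param baselines data frame with columns `plot_id`, `d13C_leaf`,
#'   `d15N_leaf` (pooled-leaf values, one row per plot).
#' @param validate logical; run [validate_dataset()] on the result.
#'
#' @return An object of class `iso_dataset`: a list with elements `plots`,
#'   `abundances`, `specimens`, `baselines`.
#' @seealso [read_dataset()], [write_dataset()], [generate_study()]
#' @export
#' @examples
#' plots <- data.frame(plot_id = "F1_1", land_use = "F", cluster = "C1",
#'                     n_subplots = 3, traps_per_subplot = 8,
#'                     trap_area_m2 = 1, effective_area_m2 = 12)
#' ab <- data.frame(plot_id = "F1_1", species_id = "sp01", count = 10L)
#' sp <- data.frame(plot_id = "F1_1", species_id = "sp01",
#'                  d13C = -26, d15N = 4)
#' bl <- data.frame(plot_id = "F1_1", d13C_leaf = -30, d15N_leaf = 1)
#' ds <- iso_dataset(plots, ab, sp, bl)
iso_dataset <- function(plots, abundances, specimens, baselines,
                        validate = TRUE) {
  ds <- structure(
    list(
      plots      = as.data.frame(plots),
      abundances = as.data.frame(abundances),
      specimens  = as.data.frame(specimens),
      baselines  = as.data.frame(baselines)
    ),
    class = "iso_dataset"
  )
  for (nm in names(DATASET_SCHEMAS)) {
    ds[[nm]] <- check_schema(ds[[nm]], nm)
    rownames(ds[[nm]]) <- NULL
  }
  if (validate) validate_dataset(ds)
  # normalise storage types so construction and file round trips agree
  for (col in c("n_subplots", "traps_per_subplot")) {
    ds$plots[[col]] <- as.integer(ds$plots[[col]])
  }
  for (col in c("trap_area_m2", "effective_area_m2")) {
    ds$plots[[col]] <- as.numeric(ds$plots[[col]])
  }
  cnt <- ds$abundances$count
  if (is.numeric(cnt) && (length(cnt) == 0 ||
                          all(is.finite(cnt) & cnt == round(cnt)))) {
    ds$abundances$count <- as.integer(cnt)
  }
  ds
}

#' Validate a dataset against the survey-design invariants
#'
#' Checks the schema and referential integrity of an [iso_dataset()]:
#' closed land-use vocabulary, positive sampling-design constants,
#' non-negative integer counts, finite isotope values, one baseline per plot,
#' no references to unknown plots, and a baseline for every plot that has
#' isotope specimens.
#'
#' @param ds an `iso_dataset`.
#' @return `ds`, invisibly, if valid. Otherwise signals a classed condition:
#'   `antniche_schema_error`, `antniche_integrity_error` or
#'   `antniche_value_error`.
#' @export
validate_dataset <- function(ds) {
  if (!inherits(ds, "iso_dataset")) {
    schema_error("expected an 'iso_dataset' object")
  }
  for (nm in names(DATASET_SCHEMAS)) check_schema(ds[[nm]], nm)
  p <- ds$plots

  if (anyDuplicated(p$plot_id)) {
    integrity_error("duplicated plot_id in plots table")
  }
  if (!all(p$land_use %in% LAND_USES)) {
    bad <- unique(p$land_use[!p$land_use %in% LAND_USES])
    value_error(sprintf("land_use outside {%s}: %s",
                        paste(LAND_USES, collapse = ", "),
                        paste(bad, collapse = ", ")))
  }
  num_pos <- function(x, nm, min = NULL, strict = FALSE) {
    if (!is.numeric(x) || any(!is.finite(x))) {
      value_error(sprintf("column '%s' must be finite numeric", nm))
    }
    if (!is.null(min) && any(if (strict) x <= min else x < min)) {
      value_error(sprintf("column '%s' must be %s %s", nm,
                          if (strict) ">" else ">=", min))
    }
  }
  num_pos(p$n_subplots, "n_subplots", 1)
  num_pos(p$traps_per_subplot, "traps_per_subplot", 1)
  num_pos(p$trap_area_m2, "trap_area_m2", 0, strict = TRUE)
  num_pos(p$effective_area_m2, "effective_area_m2", 0, strict = TRUE)

  ab <- ds$abundances
  if (nrow(ab) > 0) {
    if (!is.numeric(ab$count) || any(!is.finite(ab$count))) {
      value_error("abundance 'count' must be finite numeric")
    }
    if (any(ab$count < 0)) value_error("abundance 'count' must be >= 0")
    if (any(abs(ab$count - round(ab$count)) > 0)) {
      value_error("abundance 'count' must be integer-valued")
    }
    if (anyDuplicated(paste(ab$plot_id, ab$species_id))) {
      integrity_error(
        "duplicated (plot_id, species_id) in abundances; counts must be pooled over subplots")
    }
  }

  check_plots_known <- function(ids, table) {
    unknown <- setdiff(unique(ids), p$plot_id)
    if (length(unknown) > 0) {
      integrity_error(sprintf("table '%s' references unknown plot(s): %s",
                              table, paste(unknown, collapse = ", ")))
    }
  }
  check_plots_known(ab$plot_id, "abundances")
  check_plots_known(ds$specimens$plot_id, "specimens")
  check_plots_known(ds$baselines$plot_id, "baselines")

  sp <- ds$specimens
  if (nrow(sp) > 0) {
    if (!is.numeric(sp$d13C) || !is.numeric(sp$d15N) ||
        any(!is.finite(sp$d13C)) || any(!is.finite(sp$d15N))) {
      value_error(
        "specimen d13C/d15N must be finite (partial isotope records are not allowed)")
    }
  }

  bl <- ds$baselines
  if (nrow(bl) > 0) {
    if (anyDuplicated(bl$plot_id)) {
      integrity_error("more than one leaf baseline for some plot")
    }
    if (any(!is.finite(bl$d13C_leaf)) || any(!is.finite(bl$d15N_leaf))) {
      value_error("leaf baselines must be finite")
    }
  }
  no_base <- setdiff(unique(sp$plot_id), bl$plot_id)
  if (length(no_base) > 0) {
    integrity_error(sprintf("plot(s) with isotope specimens but no leaf baseline: %s",
                            paste(no_base, collapse = ", ")))
  }
  invisible(ds)
}

#' @export
print.iso_dataset <- function(x, ...) {
  cat("<iso_dataset>\n")
  cat(sprintf("  plots:      %d (%s)\n", nrow(x$plots),
              paste(sprintf("%s=%d", names(table(x$plots$land_use)),
                            as.integer(table(x$plots$land_use))),
                    collapse = ", ")))
  cat(sprintf("  abundances: %d plot-species records, %d species, %s workers\n",
              nrow(x$abundances),
              length(unique(x$abundances$species_id)),
              format(sum(x$abundances$count), big.mark = ",")))
  cat(sprintf("  specimens:  %d isotope measurements\n", nrow(x$specimens)))
  cat(sprintf("  baselines:  %d plots with leaf baseline\n", nrow(x$baselines)))
  invisible(x)
}

#' Species registry of a dataset
#'
#' Union of species identifiers over the abundance and specimen tables.
#'
#' @param ds an `iso_dataset`.
#' @return Sorted character vector of species identifiers.
#' @export
species_registry <- function(ds) {
  sort(unique(c(ds$abundances$species_id, ds$specimens$species_id)))
}

dataset_files <- c(plots = "plots.csv", abundances = "abundances.csv",
                   specimens = "specimens.csv", baselines = "baselines.csv")

#' Read a dataset from a directory of CSV tables
#'
#' Expects `plots.csv`, `abundances.csv`, `specimens.csv` and `baselines.csv`
#' (UTF-8, comma-separated, header row) with the column schema documented in
#' [iso_dataset()]. The result is validated.
#'
#' @param dir directory containing the four tables.
#' @param files optional named character vector overriding the default file
#'   names (names `plots`, `abundances`, `specimens`, `baselines`).
#' @return A validated `iso_dataset`.
#' @export
read_dataset <- function(dir, files = dataset_files) {
  stopifnot(length(files) == 4, all(names(DATASET_SCHEMAS) %in% names(files)))
  tabs <- lapply(names(DATASET_SCHEMAS), function(nm) {
    path <- file.path(dir, files[[nm]])
    if (!file.exists(path)) {
      schema_error(sprintf("missing table file: %s", path))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = NA, check.names = TRUE)
    # force identifier columns to character so empty tables round-trip
    for (col in intersect(c("plot_id", "species_id", "land_use", "cluster"),
                          names(df))) {
      df[[col]] <- as.character(df[[col]])
    }
    df
  })
  names(tabs) <- names(DATASET_SCHEMAS)
  iso_dataset(tabs$plots, tabs$abundances, tabs$specimens, tabs$baselines)
}

#' Write a dataset to a directory of CSV tables
#'
#' Inverse of [read_dataset()]: writes the four tables with reals formatted to
#' 17 significant digits so that a read/write round trip reproduces counts
#' bit-exactly and reals to full double precision.
#'
#' @param ds a validated `iso_dataset`.
#' @param dir output directory (created if absent).
#' @param files optional named file-name overrides as in [read_dataset()].
#' @return Named character vector of the four paths written, invisibly.
#' @export
write_dataset <- function(ds, dir, files = dataset_files) {
  validate_dataset(ds)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir))
  }
  paths <- character(0)
  for (nm in names(DATASET_SCHEMAS)) {
    df <- ds[[nm]]
    out <- df
    for (col in names(out)) {
      if (is.double(out[[col]])) {
        out[[col]] <- sprintf("%.17g", out[[col]])
      }
    }
    path <- file.path(dir, files[[nm]])
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    paths[nm] <- path
  }
  invisible(paths)
}
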