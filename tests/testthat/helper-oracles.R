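# Independent brute-force oracles and small fixtures, deliberately written
# with plain loops so they share no code path with the implementation.

# scaled-down study used by simulation-heavy tests
small_config <- function(seed, ...) {
  args <- list(
    plots_per_landuse_per_cluster = 2,
    species_pool_size = 8,
    landuse_occupancy = c(F = 7 / 8, J = 5 / 8, R = 3 / 8, O = 3 / 8),
    specimens_per_species = 3,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

toy_dataset <- function() {
  plots <- data.frame(
    plot_id = c("p1", "p2"),
    land_use = c("F", "O"),
    cluster = c("C1", "C1"),
    n_subplots = 3L, traps_per_subplot = 8L,
    trap_area_m2 = 1, effective_area_m2 = 12,
    stringsAsFactors = FALSE
  )
  ab <- data.frame(
    plot_id = c("p1", "p1", "p2"),
    species_id = c("a", "b", "a"),
    count = c(30L, 10L, 5L),
    stringsAsFactors = FALSE
  )
  sp <- data.frame(
    plot_id = c("p1", "p1", "p1", "p2"),
    species_id = c("a", "a", "b", "a"),
    d13C = c(-26, -25, -27.5, -28),
    d15N = c(4, 5, 3.5, 2),
    stringsAsFactors = FALSE
  )
  bl <- data.frame(
    plot_id = c("p1", "p2"),
    d13C_leaf = c(-30, -31),
    d15N_leaf = c(1, 0.5),
    stringsAsFactors = FALSE
  )
  iso_dataset(plots, ab, sp, bl)
}

# brute-force per-plot weighted metrics from a species_plot_means table
bf_plot_metrics <- function(means) {
  out <- list()
  for (pid in unique(means$plot_id)) {
    sub <- means[means$plot_id == pid, ]
    w <- sub$rel_abundance / sum(sub$rel_abundance)
    row <- list(plot_id = pid)
    for (el in c("D13C", "D15N")) {
      x <- sub[[paste0("mean_", el)]]
      avg <- 0
      for (i in seq_along(x)) avg <- avg + w[i] * x[i]
      row[[paste0("average_", el)]] <- avg
      row[[paste0("maximum_", el)]] <- max(x)
      row[[paste0("minimum_", el)]] <- min(x)
      row[[paste0("range_", el)]] <- max(x) - min(x)
    }
    out[[pid]] <- as.data.frame(row)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# brute-force species-per-plot means from calibrated specimens
bf_species_plot_means <- function(calibrated, functional, abundances) {
  rows <- list()
  for (pid in names(functional)) {
    for (s in functional[[pid]]) {
      sel <- calibrated$plot_id == pid & calibrated$species_id == s
      if (!any(sel)) next
      rows[[paste(pid, s)]] <- data.frame(
        plot_id = pid, species_id = s,
        mean_D13C = mean(calibrated$D13C[sel]),
        mean_D15N = mean(calibrated$D15N[sel]),
        n_specimens = sum(sel), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  # renormalised weights over measured functional species
  res$rel_abundance <- NA_real_
  for (pid in unique(res$plot_id)) {
    sel <- res$plot_id == pid
    cnt <- numeric(sum(sel))
    sp <- res$species_id[sel]
    for (i in seq_along(sp)) {
      cnt[i] <- abundances$count[abundances$plot_id == pid &
                                   abundances$species_id == sp[i]]
    }
    res$rel_abundance[sel] <- cnt / sum(cnt)
  }
  rownames(res) <- NULL
  res
}

# double loop over the incidence matrix
bf_rarity <- function(abundances) {
  ab <- abundances[abundances$count > 0, ]
  species <- unique(ab$species_id)
  plots <- unique(ab$plot_id)
  occ <- sapply(species, function(s) {
    length(unique(ab$plot_id[ab$species_id == s]))
  })
  rar <- numeric(length(plots))
  names(rar) <- plots
  for (p in plots) {
    here <- unique(ab$species_id[ab$plot_id == p])
    for (s in here) rar[p] <- rar[p] + 1 / occ[[s]]
  }
  rar
}

# independent rank-abundance recomputation
bf_rank_abundance <- function(abundances, meta, lu) {
  plots <- meta$plot_id[meta$land_use == lu]
  sub <- abundances[abundances$plot_id %in% plots & abundances$count > 0, ]
  if (nrow(sub) == 0) return(NULL)
  tot <- sort(tapply(sub$count, sub$species_id, sum), decreasing = TRUE)
  data.frame(species_id = names(tot), count = as.numeric(tot),
             cum_fraction = cumsum(as.numeric(tot)) / sum(tot),
             stringsAsFactors = FALSE)
}

# exact rarefaction by enumerating every subset of m plots
bf_rarefaction <- function(abundances, meta, lu) {
  plots <- meta$plot_id[meta$land_use == lu]
  sub <- abundances[abundances$plot_id %in% plots & abundances$count > 0, ]
  N <- length(plots)
  sapply(seq_len(N), function(m) {
    subsets <- utils::combn(plots, m, simplify = FALSE)
    mean(vapply(subsets, function(ss) {
      length(unique(sub$species_id[sub$plot_id %in% ss]))
    }, numeric(1)))
  })
}

# shortest most-abundant-first prefix by explicit prefix enumeration
bf_functional <- function(counts, threshold) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(character(0))
  ord <- names(counts)[order(-counts, names(counts))]
  for (k in seq_along(ord)) {
    if (sum(counts[ord[seq_len(k)]]) / sum(counts) >= threshold) {
      return(ord[seq_len(k)])
    }
  }
  ord
}
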