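test_that("leaf calibration is the plotwise difference", {
  sp <- data.frame(plot_id = c("p1", "p1", "p2"),
                   species_id = c("a", "a", "b"),
                   d13C = c(-26, -30, -27), d15N = c(4, 1, 2))
  bl <- data.frame(plot_id = c("p1", "p2"),
                   d13C_leaf = c(-30, -30), d15N_leaf = c(1, 1))
  cal <- calibrate_specimens(sp, bl)
  expect_equal(cal$D13C, c(4, 0, 3))
  expect_equal(cal$D15N, c(3, 0, 1))
})

test_that("a specimen plot without baseline raises an error naming it", {
  sp <- data.frame(plot_id = c("p1", "p9"), species_id = c("a", "a"),
                   d13C = c(-26, -26), d15N = c(4, 4))
  bl <- data.frame(plot_id = "p1", d13C_leaf = -30, d15N_leaf = 1)
  expect_error(calibrate_specimens(sp, bl), "p9",
               class = "antniche_integrity_error")
})

test_that("identified-species filtering keeps counts and warns when empty", {
  ds <- toy_dataset()
  expect_identical(filter_identified(ds, species_registry(ds))$abundances,
                   ds$abundances)
  expect_warning(out <- filter_identified(ds, "no_such_species"),
                 "no abundance records")
  expect_equal(nrow(out$abundances), 0)
  expect_error(filter_identified(ds, character(0)),
               class = "antniche_value_error")
})

test_that("the identified fraction of a realistic collection exceeds 99.5%", {
  # 12,185 workers of which 12,125 belong to 14 identifiable species and 60
  # to 12 unidentified morphospecies spread over two plots
  plots <- data.frame(plot_id = c("p1", "p2"), land_use = c("F", "J"),
                      cluster = "C1", n_subplots = 3L,
                      traps_per_subplot = 8L, trap_area_m2 = 1,
                      effective_area_m2 = 12)
  linnaean <- sprintf("C_%02d", 1:14)
  morpho <- sprintf("msp%02d", 1:12)
  ab <- rbind(
    data.frame(plot_id = "p1", species_id = linnaean,
               count = c(3905L, 3377L, rep(403L, 11), 410L)),
    data.frame(plot_id = "p2", species_id = morpho, count = 5L)
  )
  ds <- iso_dataset(plots, ab,
                    data.frame(plot_id = character(0),
                               species_id = character(0),
                               d13C = numeric(0), d15N = numeric(0)),
                    data.frame(plot_id = character(0),
                               d13C_leaf = numeric(0),
                               d15N_leaf = numeric(0)))
  expect_equal(sum(ds$abundances$count), 12185 - 60 + 60)
  kept <- filter_identified(ds, linnaean)
  frac <- sum(kept$abundances$count) / sum(ds$abundances$count)
  expect_gt(frac, 0.995)
})

test_that("functional community selection matches prefix enumeration", {
  expect_equal(select_functional_community(c(a = 50, b = 30, c = 15, d = 5)),
               c("a", "b", "c"))
  expect_equal(select_functional_community(c(a = 90, b = 10)), "a")
  expect_equal(select_functional_community(c(a = 7)), "a")
  expect_equal(select_functional_community(c(a = 0, b = 0)), character(0))

  set.seed(42)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    counts <- setNames(sample(0:60, n, replace = TRUE),
                       sample(letters, n))
    thr <- sample(c(0.5, 0.75, 0.9, 1), 1)
    got <- select_functional_community(counts, thr)
    expect_identical(got, bf_functional(counts, thr))
    if (length(got) > 0) {
      pos <- counts[counts > 0]
      expect_gte(sum(pos[got]) / sum(pos), thr)
      if (length(got) > 1) {
        expect_lt(sum(pos[got[-length(got)]]) / sum(pos), thr)
      }
      # deterministic: repeated selection is identical
      expect_identical(select_functional_community(counts, thr), got)
    }
  }
})

test_that("ties in abundance are broken by species id", {
  expect_equal(select_functional_community(c(b = 10, a = 10), 0.75),
               c("a", "b"))
})

test_that("species-plot means average specimens and renormalise weights", {
  cal <- data.frame(plot_id = "p1", species_id = c("a", "a", "b"),
                    D13C = c(3, 5, 6), D15N = c(1, 2, 3))
  ab <- data.frame(plot_id = "p1", species_id = c("a", "b", "c"),
                   count = c(60L, 20L, 20L))
  # c is functional but unmeasured: weights renormalise over a and b
  means <- species_plot_means(cal, list(p1 = c("a", "b", "c")), ab)
  expect_equal(means$mean_D13C[means$species_id == "a"], 4)
  expect_equal(means$rel_abundance, c(0.75, 0.25))
  expect_equal(sum(means$rel_abundance), 1, tolerance = 1e-12)
})

test_that("species-plot means equal brute-force recomputation on a study", {
  study <- generate_study(small_config(seed = 13))
  ds <- study$dataset
  cal <- calibrate_specimens(ds$specimens, ds$baselines)
  fc <- functional_communities(ds$abundances, 0.9)
  got <- species_plot_means(cal, fc, ds$abundances)
  want <- bf_species_plot_means(cal, fc, ds$abundances)
  key <- function(d) d[order(d$plot_id, d$species_id), ]
  got <- key(got); want <- key(want)
  expect_equal(got$mean_D13C, want$mean_D13C, tolerance = 1e-12)
  expect_equal(got$mean_D15N, want$mean_D15N, tolerance = 1e-12)
  expect_equal(got$rel_abundance, want$rel_abundance, tolerance = 1e-12)
  expect_identical(got$n_specimens, want$n_specimens)
  # weights sum to one within every plot
  sums <- tapply(got$rel_abundance, got$plot_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("plots below the minimum measured-species count are excluded and logged", {
  means <- data.frame(plot_id = c("p1", "p1", "p2"),
                      species_id = c("a", "b", "a"),
                      mean_D13C = 1, mean_D15N = 1,
                      n_specimens = 1L, rel_abundance = c(0.5, 0.5, 1))
  out <- filter_insufficient_plots(means, min_species = 2,
                                   all_plots = c("p1", "p2", "p3"))
  expect_equal(out$retained_plots, "p1")
  expect_setequal(out$exclusions$plot_id, c("p2", "p3"))
  expect_equal(out$exclusions$n_species[out$exclusions$plot_id == "p3"], 0L)
  # boundary: exactly min_species is retained
  out1 <- filter_insufficient_plots(means, min_species = 1,
                                    all_plots = c("p1", "p2", "p3"))
  expect_setequal(out1$retained_plots, c("p1", "p2"))
  expect_equal(out1$exclusions$plot_id, "p3")
})

test_that("ranges are invariant to the leaf baseline; averages shift with it", {
  study <- generate_study(small_config(seed = 17))
  ds <- study$dataset
  shift <- 2.5
  ds2 <- ds
  # shifting both specimens and leaves of a plot leaves all Deltas unchanged;
  # shifting only specimens moves locations one-to-one and ranges not at all
  ds2$specimens$d13C <- ds2$specimens$d13C + shift
  pm1 <- suppressWarnings(run_pipeline(ds))$plot_metrics
  pm2 <- suppressWarnings(run_pipeline(ds2))$plot_metrics
  expect_equal(pm2$average_D13C, pm1$average_D13C + shift, tolerance = 1e-10)
  expect_equal(pm2$maximum_D13C, pm1$maximum_D13C + shift, tolerance = 1e-10)
  expect_equal(pm2$range_D13C, pm1$range_D13C, tolerance = 1e-10)
  ds3 <- ds
  ds3$specimens$d13C <- ds3$specimens$d13C + shift
  ds3$baselines$d13C_leaf <- ds3$baselines$d13C_leaf + shift
  pm3 <- suppressWarnings(run_pipeline(ds3))$plot_metrics
  expect_equal(pm3$average_D13C, pm1$average_D13C, tolerance = 1e-10)
})
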