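test_that("density is counts over effective area", {
  meta <- data.frame(plot_id = c("p1", "p2"),
                     effective_area_m2 = c(24, 12))
  ab <- data.frame(plot_id = "p1", species_id = c("a", "b"),
                   count = c(40L, 8L))
  d <- community_density(ab, meta)
  expect_equal(d$density, c(2, 0))
  expect_equal(d$total_count, c(48, 0))
})

test_that("rarity weights are inverse plot occupancy", {
  ab <- data.frame(plot_id = rep(sprintf("p%02d", 1:8), each = 2),
                   species_id = rep(c("common", "patchy"), 8),
                   count = rep(c(5L, 0L), 8))
  ab$count[ab$species_id == "patchy" & ab$plot_id %in%
             c("p01", "p02", "p03", "p04")] <- 2L
  w <- rarity_weights(ab, n_plots_total = 8)
  expect_equal(w[["common"]], 1 / 8)
  expect_equal(w[["patchy"]], 1 / 4)
  expect_error(rarity_weights(ab, n_plots_total = 2),
               class = "antniche_integrity_error")
})

test_that("plot rarity sums weights of the species present", {
  ab <- data.frame(plot_id = c("p1", "p2", "p2"),
                   species_id = c("endemic", "a", "b"),
                   count = c(3L, 1L, 1L))
  meta <- data.frame(plot_id = c("p1", "p2", "p3"))
  r <- plot_rarity(ab, meta = meta)
  expect_equal(r$rarity[r$plot_id == "p1"], 1)   # one plot-endemic species
  expect_equal(r$rarity[r$plot_id == "p3"], 0)   # empty plot
  # a plot containing all species attains the total weight
  w <- rarity_weights(ab)
  expect_equal(max(r$rarity) <= sum(w), TRUE)
})

test_that("rarity matches the brute-force double loop on synthetic data", {
  for (seed in c(2, 8, 31)) {
    ds <- generate_study(small_config(seed = seed))$dataset
    got <- plot_rarity(ds$abundances, meta = ds$plots)
    want <- bf_rarity(ds$abundances)
    for (pid in names(want)) {
      expect_equal(got$rarity[got$plot_id == pid], want[[pid]],
                   tolerance = 1e-12)
    }
  }
})

test_that("Chao2 hand arithmetic, limits, and vegan agreement", {
  # helper building a dataset with prescribed incidence frequencies
  make_inc <- function(freqs, N = 8) {
    rows <- list()
    for (i in seq_along(freqs)) {
      rows[[i]] <- data.frame(plot_id = sprintf("p%d", seq_len(freqs[i])),
                              species_id = sprintf("s%02d", i), count = 1L)
    }
    list(ab = do.call(rbind, rows),
         meta = data.frame(plot_id = sprintf("p%d", 1:N), land_use = "F"))
  }
  # s_obs = 5, q1 = 2, q2 = 1, N = 8
  x <- make_inc(c(1, 1, 2, 5, 6))
  got <- chao_pool(x$ab, x$meta, bias_corrected = TRUE)
  A <- 7 / 8
  expect_equal(got$chao_est, 5 + A * 2 * 1 / (2 * 2))
  v_bc <- A * 2 * 1 / (2 * 2) + A^2 * 2 * (2 * 2 - 1)^2 / (4 * 2^2) +
    A^2 * 4 * 1 * 1 / (4 * 2^4)
  expect_equal(got$chao_se, sqrt(v_bc))

  # classic form matches vegan::specpool exactly
  skip_if_not_installed("vegan")
  classic <- chao_pool(x$ab, x$meta, bias_corrected = FALSE)
  inc <- with(x$ab, table(plot_id, species_id))
  inc <- rbind(inc, matrix(0, 8 - nrow(inc), ncol(inc)))
  vp <- vegan::specpool(inc)
  expect_equal(classic$chao_est, vp$chao, tolerance = 1e-12)
  expect_equal(classic$chao_se, vp$chao.se, tolerance = 1e-12)

  # no uniques: estimate collapses to s_obs
  x0 <- make_inc(c(3, 4, 8))
  got0 <- chao_pool(x0$ab, x0$meta)
  expect_equal(got0$chao_est, got0$s_obs)

  # every species everywhere: SE vanishes
  xall <- make_inc(c(8, 8, 8))
  gall <- chao_pool(xall$ab, xall$meta)
  expect_equal(gall$chao_est, 3)
  expect_equal(gall$chao_se, 0)
})

test_that("Chao2 never falls below observed richness (random incidence)", {
  set.seed(7)
  for (i in 1:100) {
    N <- sample(3:10, 1)
    S <- sample(2:15, 1)
    inc <- matrix(runif(N * S) < 0.3, N, S)
    ab <- data.frame(
      plot_id = sprintf("p%d", row(inc)[inc]),
      species_id = sprintf("s%02d", col(inc)[inc]),
      count = 1L
    )
    if (nrow(ab) == 0) next
    meta <- data.frame(plot_id = sprintf("p%d", 1:N), land_use = "F")
    for (bc in c(TRUE, FALSE)) {
      got <- chao_pool(ab, meta, bias_corrected = bc)
      expect_gte(got$chao_est, got$s_obs)
      expect_gte(got$chao_se, 0)
    }
  }
})

test_that("single-site groups are flagged as undefined", {
  ab <- data.frame(plot_id = "p1", species_id = "a", count = 1L)
  meta <- data.frame(plot_id = "p1", land_use = "F")
  got <- chao_pool(ab, meta)
  expect_true(is.na(got$chao_est))
})

test_that("rank-abundance curves are descending with closed-form cumulatives", {
  meta <- data.frame(plot_id = c("p1", "p2"), land_use = c("F", "F"))
  ab <- data.frame(plot_id = c("p1", "p1", "p2", "p2"),
                   species_id = c("a", "b", "a", "c"),
                   count = c(10L, 5L, 10L, 5L))
  ra <- rank_abundance(ab, meta)
  expect_equal(ra$species_id, c("a", "b", "c"))
  expect_equal(ra$cum_count, c(20, 25, 30))
  expect_equal(ra$cum_fraction[3], 1)
  # uniform counts: cumulative fraction i/k at rank i
  abu <- data.frame(plot_id = "p1", species_id = letters[1:5], count = 4L)
  rau <- rank_abundance(abu, meta)
  expect_equal(rau$cum_fraction, (1:5) / 5)
  # single species
  ra1 <- rank_abundance(abu[1, ], meta)
  expect_equal(ra1$cum_fraction, 1)
})

test_that("rank-abundance matches independent recomputation on a study", {
  ds <- generate_study(small_config(seed = 23))$dataset
  ra <- rank_abundance(ds$abundances, ds$plots)
  for (lu in unique(ra$land_use)) {
    want <- bf_rank_abundance(ds$abundances, ds$plots, lu)
    got <- ra[ra$land_use == lu, ]
    expect_equal(got$count, want$count)
    expect_equal(got$cum_fraction, want$cum_fraction, tolerance = 1e-12)
  }
})

test_that("exact rarefaction equals subset enumeration and is monotone", {
  ds <- generate_study(small_config(seed = 4))$dataset
  for (lu in c("F", "O")) {
    got <- accumulation_curve(ds$abundances, ds$plots, lu, method = "exact")
    want <- bf_rarefaction(ds$abundances, ds$plots, lu)
    expect_equal(got$expected_richness, want, tolerance = 1e-12)
    expect_true(all(diff(got$expected_richness) >= -1e-12))
    # endpoint is pooled observed richness
    plots <- ds$plots$plot_id[ds$plots$land_use == lu]
    pooled <- length(unique(ds$abundances$species_id[
      ds$abundances$plot_id %in% plots & ds$abundances$count > 0]))
    expect_equal(got$expected_richness[nrow(got)], pooled)
  }
})

test_that("permutation rarefaction converges to the exact curve", {
  ds <- generate_study(small_config(seed = 4))$dataset
  ex <- accumulation_curve(ds$abundances, ds$plots, "F", method = "exact")
  pm <- accumulation_curve(ds$abundances, ds$plots, "F",
                           method = "permutation", n_permutations = 2000,
                           seed = 99)
  expect_equal(pm$expected_richness, ex$expected_richness, tolerance = 0.05)
})

test_that("identical plots give a flat accumulation curve", {
  meta <- data.frame(plot_id = c("p1", "p2", "p3"), land_use = "F")
  ab <- data.frame(plot_id = rep(c("p1", "p2", "p3"), each = 2),
                   species_id = rep(c("a", "b"), 3), count = 1L)
  got <- accumulation_curve(ab, meta, "F", method = "exact")
  expect_equal(got$expected_richness, rep(2, 3))
})

test_that("overlap partition and nestedness report the Venn structure", {
  meta <- data.frame(plot_id = c("f", "j", "r", "o"),
                     land_use = c("F", "J", "R", "O"))
  ab <- data.frame(
    plot_id = c("f", "f", "f", "j", "j", "r", "o", "o"),
    species_id = c("s1", "s2", "s3", "s1", "s2", "s1", "s1", "x_oilpalm"),
    count = 1L
  )
  ov <- landuse_overlap(ab, meta)
  expect_setequal(ov$partition[["F+J+R+O"]], "s1")
  expect_setequal(ov$partition[["O"]], "x_oilpalm")
  nest <- ov$nestedness
  fo <- nest[nest$container == "F" & nest$contained == "O", ]
  expect_false(fo$is_subset)
  expect_equal(fo$n_violations, 1)
  expect_equal(fo$violating_species, "x_oilpalm")
  ro <- nest[nest$container == "R" & nest$contained == "O", ]
  expect_equal(ro$n_violations, 1)
  fj <- nest[nest$container == "F" & nest$contained == "J", ]
  expect_true(fj$is_subset)
})

test_that("disjoint communities fall into singleton subsets", {
  meta <- data.frame(plot_id = c("f", "j"), land_use = c("F", "J"))
  ab <- data.frame(plot_id = c("f", "j"), species_id = c("a", "b"),
                   count = 1L)
  ov <- landuse_overlap(ab, meta)
  expect_setequal(names(ov$partition), c("F", "J"))
})

test_that("community_metrics assembles density, richness and rarity", {
  ds <- toy_dataset()
  cm <- community_metrics(ds)
  expect_equal(cm$density, c(40, 5) / 12)
  expect_equal(cm$richness, c(2L, 1L))
  # a occurs in both plots (w = 1/2), b only in p1 (w = 1)
  expect_equal(cm$rarity, c(1.5, 0.5))
})
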