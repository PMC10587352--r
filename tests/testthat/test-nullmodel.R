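null_fixture <- function(seed = 87) {
  study <- small_study(seed)
  cen <- filter_stems(study$censuses[[1]])
  tr <- suppressMessages(assign_mycorrhizal_type(
    unique(cen$stems$species), study$traits))
  list(census = cen, traits = tr,
       assignments = assign_size_classes(cen))
}

test_that("null censuses keep adults fixed and conserve sapling counts", {
  fx <- null_fixture()
  cfg <- null_config(iterations = 1, seed = 1234)
  null <- suppressMessages(
    simulate_null_census(fx$census, fx$assignments, fx$traits, cfg))
  co <- fx$assignments$sapling_cutoff[match(fx$census$stems$species,
                                            fx$assignments$species)]
  is_adult <- fx$census$stems$dbh >= co
  # adults bit-identical, including coordinates
  expect_identical(null$stems[is_adult, ], fx$census$stems[is_adult, ])
  # per-species sapling counts and DBH values conserved
  for (sp in unique(fx$census$stems$species)) {
    obs <- fx$census$stems[fx$census$stems$species == sp & !is_adult, ]
    nul <- null$stems[null$stems$species == sp & !is_adult, ]
    expect_equal(nrow(nul), nrow(obs))
    expect_identical(sort(nul$dbh), sort(obs$dbh))
  }
  # saplings stay inside the plot
  expect_true(all(null$stems$x >= 0 & null$stems$x < null$x_extent))
  expect_true(all(null$stems$y >= 0 & null$stems$y < null$y_extent))
})

test_that("the same null seed reproduces bit-identical censuses", {
  fx <- null_fixture()
  cfg <- null_config(seed = 99)
  a <- suppressMessages(
    simulate_null_census(fx$census, fx$assignments, fx$traits, cfg))
  b <- suppressMessages(
    simulate_null_census(fx$census, fx$assignments, fx$traits, cfg))
  expect_identical(a$stems, b$stems)
  cfg2 <- null_config(seed = 100)
  c2 <- suppressMessages(
    simulate_null_census(fx$census, fx$assignments, fx$traits, cfg2))
  expect_false(identical(a$stems$x, c2$stems$x))
})

test_that("species without parents fall back to uniform placement", {
  stems <- data.frame(stem_id = sprintf("s%d", 1:6),
                      tree_id = sprintf("t%d", 1:6),
                      species = "aa", x = runif(6, 0, 40),
                      y = runif(6, 0, 40), dbh = 1.5,
                      status = "alive", main_stem = TRUE)
  cen <- plot_census(stems, "np", 40, 40)
  asg <- data.frame(species = "aa", sapling_cutoff = 10)
  tr <- data.frame(species = "aa", mycorrhizal_type = "AM",
                   max_height = 20)
  cfg <- null_config(adult_mortality = 0.1, seed = 5)
  expect_message(
    out <- simulate_null_census(cen, asg, tr, cfg), "no parents")
  expect_equal(nrow(out$stems), 6L)
})

test_that("very long dispersal erases conspecific spatial association", {
  fx <- null_fixture(91)
  # dispersal far beyond the plot scale (10^3 m on a 200 m plot):
  # re-dispersed saplings are near-uniform, so per-quadrat sapling
  # counts decouple from conspecific adult density
  cfg <- null_config(allometry = c(intercept = 3, slope = 0),
                     seed = 11, iterations = 1)
  cors <- numeric(0)
  xs <- numeric(0)
  for (i in 1:5) {
    cfg$seed <- 11 + i
    null <- suppressMessages(
      simulate_null_census(fx$census, fx$assignments, fx$traits, cfg))
    tab <- suppressMessages(build_quadrat_table(
      null, fx$assignments, fx$traits, clark2dt(u = 90, p = 1), "CDD"))
    for (g in unique(tab$group)) {
      rec <- tab[tab$group == g, ]
      if (sd(rec$S) > 0) cors <- c(cors, cor(rec$S, rec$A))
    }
    co <- fx$assignments$sapling_cutoff[match(null$stems$species,
                                              fx$assignments$species)]
    xs <- c(xs, null$stems$x[null$stems$dbh < co])
  }
  expect_gt(length(cors), 20)
  # mean sapling-adult correlation within Monte-Carlo error of zero
  expect_lt(abs(mean(cors)), 4 * sd(cors) / sqrt(length(cors)))
  # and sapling coordinates are compatible with spatial uniformity
  ks <- suppressWarnings(ks.test(xs, "punif", 0, fx$census$x_extent))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-sided exceedance has its documented edge behaviour", {
  draws <- c(-2, -1, 0, 1, 2)
  expect_equal(mycodd:::two_sided_exceedance(0, draws), 1)       # at median
  expect_equal(mycodd:::two_sided_exceedance(10, draws), 0)      # outside
  expect_equal(mycodd:::two_sided_exceedance(2, draws), 2 / 5)
})

test_that("a scaled null experiment runs end to end with reduced refits", {
  fx <- null_fixture(93)
  cfg <- null_config(iterations = 4, seed = 21)
  res <- suppressMessages(suppressWarnings(run_null_experiment(
    fx$census, fx$traits, clark2dt(u = 90, p = 1), cfg,
    dataset = "CDD", statistic = "cdd_am_em_difference",
    refit = "reduced")))
  expect_s3_class(res, "null_result")
  expect_lte(res$n_iterations, 4L)
  expect_gte(res$n_iterations, 1L)
  expect_true(is.finite(res$observed))
  expect_true(res$exceedance >= 0 && res$exceedance <= 1)
  # serialisation round-trip
  dp <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".json")
  write_null_result(res, dp, sp)
  expect_equal(nrow(read.csv(dp)), res$n_iterations)
  js <- jsonlite::read_json(sp)
  expect_equal(js$observed, res$observed, tolerance = 1e-12)
})
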