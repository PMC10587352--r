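test_that("the generator is fully deterministic under a seed", {
  cfg <- synthetic_config(x_extent = 120, y_extent = 120, n_species = 8,
                          n_adults = 300, seed = 404)
  a <- suppressMessages(generate_study(cfg, n_plots = 2))
  b <- suppressMessages(generate_study(cfg, n_plots = 2))
  expect_identical(a$censuses[[1]]$stems, b$censuses[[1]]$stems)
  expect_identical(a$censuses[[2]]$stems, b$censuses[[2]]$stems)
  expect_identical(a$traits, b$traits)
  cfg2 <- cfg
  cfg2$seed <- 405
  c2 <- suppressMessages(generate_study(cfg2, n_plots = 2))
  expect_false(identical(a$censuses[[1]]$stems, c2$censuses[[1]]$stems))
})

test_that("Thomas process adult counts match kappa * area * mu on average", {
  cfg <- synthetic_config(x_extent = 200, y_extent = 200, seed = NULL)
  species <- data.frame(species = "sp1", mycorrhizal_type = "AM",
                        max_height = 20, rel_abundance = 1,
                        kappa = 4e-4)
  set.seed(11)
  counts <- replicate(100, nrow(generate_adults(cfg, species)))
  lambda <- 4e-4 * 200 * 200 * cfg$thomas_mu
  # Poisson parents with Poisson offspring: var = kappa*A*mu*(1+mu)
  se_total <- sqrt(4e-4 * 200 * 200 * cfg$thomas_mu *
                     (1 + cfg$thomas_mu) / 100)
  expect_lt(abs(mean(counts) - lambda), 4 * se_total)
})

test_that("large parent intensity and spread approach spatial randomness", {
  cfg <- synthetic_config(x_extent = 200, y_extent = 200,
                          thomas_mu = 1, thomas_sigma = 200,
                          seed = NULL)
  species <- data.frame(species = "sp1", mycorrhizal_type = "AM",
                        max_height = 20, rel_abundance = 1,
                        kappa = 600 / (200 * 200))
  set.seed(13)
  ad <- generate_adults(cfg, species)
  n <- nrow(ad)
  expect_gt(n, 400)
  # Clark-Evans index: mean nearest-neighbour distance over the
  # Poisson expectation 0.5 / sqrt(density)
  d2 <- as.matrix(dist(cbind(ad$x, ad$y)))
  diag(d2) <- Inf
  ce <- mean(apply(d2, 1, min)) / (0.5 / sqrt(n / (200 * 200)))
  expect_gt(ce, 0.85)
  expect_lt(ce, 1.15)
})

test_that("count-model saplings match the generating mean when effects vanish", {
  cfg <- synthetic_config(x_extent = 480, y_extent = 400, n_species = 4,
                          n_adults = 700, r = 0.4, c_am = 0, c_em = 0,
                          d = 0, seed = NULL)
  set.seed(17)
  pool <- mycodd:::synthetic_species_pool(cfg)
  ad <- generate_adults(cfg, pool)
  sap <- generate_saplings(ad, cfg, pool)
  # expected total = sum over species x quadrat of A * e^r
  cen <- mycodd:::adults_as_census(ad, cfg)
  tab <- build_quadrat_table(cen,
                             data.frame(species = pool$species,
                                        sapling_cutoff = 10),
                             pool, cfg$kernel, "CDD", min_quadrats = 0)
  expected <- sum(tab$A * exp(cfg$r))
  # NB totals: var = sum mu (1 + mu/theta)
  se_tot <- sqrt(sum(tab$A * exp(cfg$r) *
                       (1 + tab$A * exp(cfg$r) / cfg$theta)))
  expect_lt(abs(nrow(sap) - expected), 5 * se_tot)
})

test_that("the generating conspecific slope is visible in binned per-capita means", {
  # independent check of the count model: weighted LS on log binned
  # means of S/A against binned A recovers c without any NB machinery
  set.seed(19)
  n <- 40000
  A <- rlnorm(n, 0.2, 0.5)
  r <- 2
  c_true <- -0.4
  S <- rnbinom(n, size = 2, mu = A * exp(r + c_true * A))
  bins <- cut(A, quantile(A, seq(0, 1, length.out = 26)),
              include.lowest = TRUE)
  mS <- tapply(S, bins, mean)
  mA <- tapply(A, bins, mean)
  wls <- lm(log(mS / mA) ~ mA, weights = as.numeric(table(bins)))
  expect_equal(unname(coef(wls)[2]), c_true, tolerance = 0.05)
  expect_equal(unname(coef(wls)[1]), r, tolerance = 0.1)
})

test_that("species with no adults produce no count-model saplings", {
  cfg <- synthetic_config(n_species = 3, seed = NULL)
  set.seed(23)
  pool <- mycodd:::synthetic_species_pool(cfg)
  ad <- generate_adults(cfg, pool)
  ad <- ad[ad$species != pool$species[1], ]
  sap <- generate_saplings(ad, cfg, pool)
  expect_false(pool$species[1] %in% sap$species)
})

test_that("mechanistic saplings cluster around adults at dispersal range", {
  cfg <- synthetic_config(x_extent = 200, y_extent = 200, n_species = 3,
                          n_adults = 250, c_am = -0.05, c_em = -0.05,
                          seed = NULL)
  set.seed(29)
  pool <- mycodd:::synthetic_species_pool(cfg)
  pool$max_height <- 10          # mean dispersal 10 m
  ad <- generate_adults(cfg, pool)
  sap <- generate_saplings(ad, cfg, pool, mode = "mechanistic",
                           fecundity = 3)
  expect_gt(nrow(sap), 50)
  # median distance to the nearest conspecific adult is on the
  # dispersal scale, far below the nearest-adult distance of random
  # points in the plot
  nearest <- function(px, py, ax, ay)
    vapply(seq_along(px), function(i)
      sqrt(min((px[i] - ax)^2 + (py[i] - ay)^2)), 0)
  dd <- unlist(lapply(unique(sap$species), function(sp) {
    a <- ad[ad$species == sp, ]
    s <- sap[sap$species == sp, ]
    if (nrow(a) == 0 || nrow(s) == 0) return(NULL)
    nearest(s$x, s$y, a$x, a$y)
  }))
  rand <- unlist(lapply(unique(sap$species), function(sp) {
    a <- ad[ad$species == sp, ]
    if (nrow(a) == 0) return(NULL)
    nearest(runif(50, 0, 200), runif(50, 0, 200), a$x, a$y)
  }))
  expect_lt(median(dd), median(rand))
})

test_that("study files and ground truth round-trip through the readers", {
  cfg <- synthetic_config(x_extent = 120, y_extent = 120, n_species = 6,
                          n_adults = 250, seed = 31)
  dir <- file.path(tempdir(), "mycodd_study")
  study <- suppressMessages(generate_study(cfg, n_plots = 2,
                                           out_dir = dir))
  cen <- read_census(file.path(dir, "census_plot01.csv"),
                     plot_id = "plot01", x_extent = 120, y_extent = 120)
  expect_equal(nrow(cen$stems), nrow(study$censuses[[1]]$stems))
  expect_equal(cen$stems$dbh, study$censuses[[1]]$stems$dbh)
  tt <- read_traits(file.path(dir, "traits.csv"))
  expect_setequal(tt$species, study$traits$species)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$params$c_am, cfg$c_am)
  expect_equal(truth$params$theta, cfg$theta)
  expect_equal(nrow(truth$species), nrow(study$traits))
})

test_that("the configured AM-EM latitudinal gradient appears in site summaries", {
  cfg <- synthetic_config(x_extent = 150, y_extent = 150,
                          n_species = 14, n_adults = 500, seed = 37)
  study <- suppressMessages(generate_study(cfg, n_plots = 6))
  tr <- suppressMessages(assign_mycorrhizal_type(
    unique(unlist(lapply(study$censuses,
                         function(cc) cc$stems$species))),
    study$traits))
  sites <- suppressMessages(build_site_table(study$censuses, tr))
  m <- site_level_model(sites, "proportion_EM_species", "latitude")
  expect_gt(m$estimate, 0)   # EM proportion increases with latitude
})
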