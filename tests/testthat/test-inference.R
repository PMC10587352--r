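make_effects <- function(deltas, types, sites = "s1") {
  data.frame(species = sprintf("sp%03d", seq_along(deltas)),
             plot_id = sites, delta = deltas, mycorrhizal_type = types)
}

test_that("type contrast is zero (p ~ 1) when both types share the same deltas", {
  d <- c(-0.1, 0, 0.1, -0.1, 0, 0.1)
  eff <- make_effects(d, rep(c("AM", "EM"), each = 3),
                      sites = rep(c("s1", "s2", "s3"), 2))
  ct <- suppressMessages(type_contrast(eff, "site_random"))
  expect_equal(ct$estimate, 0, tolerance = 1e-10)
  expect_gt(ct$p_value, 0.95)
  ci <- suppressMessages(type_contrast(eff, "site_interaction"))
  expect_equal(ci$estimate, 0, tolerance = 1e-10)
})

test_that("type contrast recovers a true AM-EM gap under site noise", {
  set.seed(61)
  gaps <- replicate(20, {
    n_sites <- 40
    site_eff <- rnorm(n_sites, 0, 0.1)
    rows <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
      make_effects(c(rnorm(4, -0.3 + site_eff[s], 0.05),
                     rnorm(4, 0 + site_eff[s], 0.05)),
                   rep(c("AM", "EM"), each = 4),
                   sites = sprintf("s%02d", s))
    }))
    suppressMessages(type_contrast(rows, "site_random"))$estimate
  })
  expect_lt(abs(mean(gaps) - (-0.3)), 0.05)
  expect_true(all(gaps < 0))
})

test_that("single-site data degrade gracefully to ordinary regression", {
  set.seed(67)
  eff <- make_effects(c(rnorm(10, -0.3, 0.1), rnorm(10, -0.1, 0.1)),
                      rep(c("AM", "EM"), each = 10))
  ct <- suppressMessages(type_contrast(eff, "site_random"))
  expect_equal(ct$n, 20L)
  expect_lt(ct$estimate, 0)
  expect_error(type_contrast(make_effects(rnorm(5), rep("AM", 5))),
               "both mycorrhizal types")
})

test_that("mean_vs_zero handles exact and degenerate inputs", {
  z <- mean_vs_zero(rep(0, 6))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  cst <- mean_vs_zero(rep(0.1, 4))
  expect_true(cst$degenerate)
  expect_lt(cst$p_value, 1e-6)
  expect_error(mean_vs_zero(0.3), "at least two")
})

test_that("mean_vs_zero rejects a true nonzero mean with high power", {
  set.seed(71)
  rejections <- replicate(100, {
    mean_vs_zero(rnorm(200, 0.08, 0.1))$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("weighted median follows the cumulative-weight rule", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 10)), 3)
  expect_equal(weighted_median(c(1, 2, 3)), 2)
  expect_equal(weighted_median(5), 5)
  set.seed(73)
  for (i in 1:20) {
    x <- rnorm(2 * sample(3:30, 1) + 1)   # odd length
    expect_equal(weighted_median(x), median(x))
  }
  expect_error(weighted_median(numeric(0)), "empty")
  expect_error(weighted_median(1:3, c(1, -1, 1)), "positive")
})

test_that("abundance weighting uses the natural log of species abundance", {
  eff <- data.frame(delta = c(-0.4, -0.2, 0.1),
                    abundance = c(100, 10, 1000))
  expect_equal(weighted_median_cdd(eff),
               weighted_median(eff$delta, log(c(100, 10, 1000))))
  single <- data.frame(delta = -0.25, abundance = 50)
  expect_equal(weighted_median_cdd(single), -0.25)
  expect_error(weighted_median_cdd(data.frame(delta = 1, abundance = 0.5)),
               ">= 1")
})

test_that("site-level models fit exactly one predictor and need three sites", {
  set.seed(79)
  sites <- data.frame(plot_id = sprintf("s%02d", 1:12),
                      latitude = seq(5, 60, length.out = 12))
  sites$species_richness <- round(120 - 1.5 * sites$latitude +
                                    rnorm(12, 0, 3))
  m <- site_level_model(sites, "species_richness", "latitude")
  expect_lt(m$estimate, 0)
  expect_lt(m$p_value, 0.01)
  expect_equal(m$estimate, -1.5, tolerance = 0.3)

  flat <- sites
  flat$species_richness <- 50
  expect_equal(site_level_model(flat, "species_richness",
                                "latitude")$estimate, 0,
               tolerance = 1e-10)
  expect_error(site_level_model(sites[1:2, ], "species_richness",
                                "latitude"), "three sites")
  cst <- sites
  cst$latitude <- 10
  expect_error(site_level_model(cst, "species_richness", "latitude"),
               "constant predictor")
})

test_that("tests are invariant to row order", {
  set.seed(83)
  eff <- make_effects(rnorm(30, -0.1, 0.2),
                      sample(c("AM", "EM"), 30, TRUE),
                      sites = sample(c("s1", "s2", "s3"), 30, TRUE))
  perm <- eff[sample(nrow(eff)), ]
  a <- suppressMessages(type_contrast(eff, "site_random"))
  b <- suppressMessages(type_contrast(perm, "site_random"))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
  expect_equal(mean_vs_zero(eff$delta)$p_value,
               mean_vs_zero(perm$delta)$p_value)
})
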