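write_toy_file <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

toy_rows <- function() {
  data.frame(stem_id = sprintf("s%d", 1:5), tree_id = sprintf("t%d", 1:5),
             species = c("aa", "aa", "bb", "bb", "cc"),
             x = c(1, 5, 10, 15, 19), y = c(2, 6, 11, 16, 18),
             dbh = c(12, 2, 30, 1.5, 8),
             status = c("alive", "alive", "alive", "dead", "alive"),
             main_stem = TRUE)
}

test_that("read_census parses canonical files and honours column mappings", {
  p1 <- write_toy_file(toy_rows())
  cen <- read_census(p1, plot_id = "t1", x_extent = 20, y_extent = 20)
  expect_s3_class(cen, "plot_census")
  expect_equal(nrow(cen$stems), 5L)
  expect_equal(cen$stems$dbh, toy_rows()$dbh)

  alt <- toy_rows()
  names(alt)[names(alt) == "x"] <- "gx"
  names(alt)[names(alt) == "y"] <- "gy"
  p2 <- write_toy_file(alt)
  cen2 <- read_census(p2, schema = c(gx = "x", gy = "y"),
                      plot_id = "t1", x_extent = 20, y_extent = 20)
  expect_identical(cen$stems, cen2$stems)
})

test_that("read_census reports schema and row-level validation errors", {
  bad <- toy_rows()
  bad$dbh <- as.character(bad$dbh)
  bad$dbh[3] <- "NA"
  expect_error(read_census(write_toy_file(bad), x_extent = 20,
                           y_extent = 20),
               "non-numeric dbh.*3")
  nox <- toy_rows()
  nox$x <- NULL
  expect_error(read_census(write_toy_file(nox), x_extent = 20,
                           y_extent = 20),
               "x")
  oob <- toy_rows()
  oob$x[1] <- 25
  expect_error(read_census(write_toy_file(oob), x_extent = 20,
                           y_extent = 20),
               "outside plot bounds")
})

test_that("write-then-read round-trips every retained field", {
  set.seed(42)
  n <- 40
  stems <- data.frame(
    stem_id = sprintf("s%03d", 1:n), tree_id = sprintf("t%03d", 1:n),
    species = sample(c("aa", "bb", "cc"), n, TRUE),
    x = round(runif(n, 0, 100), 6), y = round(runif(n, 0, 100), 6),
    dbh = round(runif(n, 1, 60), 3),
    status = sample(c("alive", "dead"), n, TRUE),
    main_stem = sample(c(TRUE, FALSE), n, TRUE))
  cen <- plot_census(stems, "rt", 100, 100)
  path <- tempfile(fileext = ".csv")
  write_census(cen, path)
  back <- read_census(path, plot_id = "rt", x_extent = 100, y_extent = 100)
  expect_identical(back$stems, cen$stems)
})

test_that("filter_stems drops dead stems and keeps one main stem per tree", {
  set.seed(7)
  n <- 10
  stems <- data.frame(
    stem_id = sprintf("s%02d", 1:n), tree_id = sprintf("t%02d", 1:n),
    species = "aa", x = runif(n, 0, 50), y = runif(n, 0, 50),
    dbh = runif(n, 1, 30),
    status = c(rep("alive", 7), rep("dead", 3)), main_stem = NA)
  cen <- plot_census(stems, "f", 50, 50)
  expect_equal(nrow(filter_stems(cen)$stems), 7L)

  multi <- data.frame(
    stem_id = c("s1", "s2", "s3"), tree_id = "t1", species = "aa",
    x = c(1, 2, 3), y = c(1, 2, 3), dbh = c(5, 20, 10),
    status = "alive", main_stem = c(FALSE, TRUE, FALSE))
  fm <- filter_stems(plot_census(multi, "m", 50, 50))
  expect_equal(fm$stems$stem_id, "s2")

  # no flags: largest DBH wins, DBH ties broken by smallest stem_id
  multi$main_stem <- NA
  multi$dbh <- c(20, 20, 10)
  fm2 <- filter_stems(plot_census(multi, "m", 50, 50))
  expect_equal(fm2$stems$stem_id, "s1")

  dead <- stems
  dead$status <- "dead"
  expect_warning(out <- filter_stems(plot_census(dead, "d", 50, 50)),
                 "no living stems")
  expect_equal(nrow(out$stems), 0L)
})

test_that("unrecognised status strings are conservatively treated as dead", {
  rows <- toy_rows()
  rows$status[5] <- "broken?"
  p <- write_toy_file(rows)
  cen <- suppressMessages(read_census(p, x_extent = 20, y_extent = 20))
  expect_equal(cen$stems$status[5], "dead")
})

test_that("size-class cascade depends only on the DBH multiset", {
  dbh <- c(runif(60, 1, 4), runif(25, 5, 9), runif(15, 10, 40))
  mk <- function(d) {
    n <- length(d)
    plot_census(data.frame(stem_id = sprintf("s%03d", 1:n),
                           tree_id = sprintf("t%03d", 1:n),
                           species = "aa", x = runif(n, 0, 100),
                           y = runif(n, 0, 100), dbh = d,
                           status = "alive", main_stem = TRUE),
                "p", 100, 100)
  }
  set.seed(1)
  a <- assign_size_classes(mk(dbh))
  for (i in 1:5) {
    b <- assign_size_classes(mk(sample(dbh)))
    expect_equal(b$sapling_cutoff, a$sapling_cutoff)
    expect_equal(b$adult_fraction_at_cutoff, a$adult_fraction_at_cutoff)
  }
})

test_that("site summaries compute EM proportions and abundances", {
  set.seed(3)
  sp <- c("a1", "a2", "e1", "e2")
  stems <- data.frame(
    stem_id = sprintf("s%02d", 1:8), tree_id = sprintf("t%02d", 1:8),
    species = rep(sp, each = 2), x = runif(8, 0, 40),
    y = runif(8, 0, 40), dbh = 10, status = "alive", main_stem = TRUE)
  traits <- data.frame(species = sp,
                       mycorrhizal_type = c("AM", "AM", "EM", "EM"))
  sm <- summarize_site(plot_census(stems, "s", 40, 40), traits)
  expect_equal(sm$proportion_EM_species, 0.5)
  expect_equal(sm$species_richness, 4L)
  expect_equal(sum(sm$abundance$relative_abundance), 1)

  # basal area: single EM stem dbh 20 vs single AM stem dbh 10 -> 0.8
  two <- data.frame(stem_id = c("s1", "s2"), tree_id = c("t1", "t2"),
                    species = c("em", "am"), x = c(1, 2), y = c(1, 2),
                    dbh = c(20, 10), status = "alive", main_stem = TRUE)
  tr2 <- data.frame(species = c("em", "am"),
                    mycorrhizal_type = c("EM", "AM"))
  sm2 <- summarize_site(plot_census(two, "s2", 40, 40), tr2)
  expect_equal(sm2$proportion_EM_basal_area, 0.8)

  # untyped species are excluded and counted
  tr3 <- traits[1:3, ]
  sm3 <- suppressMessages(
    summarize_site(plot_census(stems, "s", 40, 40), tr3))
  expect_equal(sm3$species_richness, 3L)
  expect_equal(sm3$n_excluded_species, 1L)

  empty <- plot_census(stems[0, ], "e", 40, 40)
  expect_error(summarize_site(empty, traits), "no stems")
})

test_that("adult and sapling counts partition the alive main-stem count", {
  study <- small_study(31)
  cen <- filter_stems(study$censuses[[1]])
  asg <- assign_size_classes(cen)
  for (sp in asg$species) {
    d <- cen$stems$dbh[cen$stems$species == sp]
    co <- asg$sapling_cutoff[asg$species == sp]
    expect_equal(sum(d >= co) + sum(d < co),
                 asg$n_stems[asg$species == sp])
  }
})
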