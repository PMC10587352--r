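# fixtures and independent oracles shared across test files; all data
# built in code under fixed seeds set by the calling tests

# quadrat-level records from the generating Ricker NB model (CDD form)
make_cdd_records <- function(n, r = 1, c = -0.3, d = -0.05, theta = 2,
                             meanlog_A = 0, sdlog_A = 0.5) {
  A <- rlnorm(n, meanlog_A, sdlog_A)
  H <- rlnorm(n, log(4), 0.4)
  S <- rnbinom(n, size = theta, mu = A * exp(r + c * A + d * H))
  data.frame(S = S, A = A, H = H)
}

make_cmdd_records <- function(n, r = 0.5, c = -0.2, d = 0.1, f = 0.02,
                              theta = 2) {
  A <- rlnorm(n, 0, 0.5)
  M <- rlnorm(n, log(2), 0.5)
  HMH <- rlnorm(n, log(2), 0.5)
  S <- rnbinom(n, size = theta,
               mu = A * exp(r + c * A + d * M + f * HMH))
  data.frame(S = S, A = A, H = M + HMH, M = M, HMH = HMH)
}

# brute-force joint NB maximum likelihood, independent of glm.nb:
# Nelder-Mead / BFGS polish on (coefs, log theta)
oracle_nb_fit <- function(records, dataset = "CDD") {
  k <- if (dataset == "CDD") 3L else 4L
  nll <- function(par) {
    eta <- par[1] + par[2] * records$A +
      if (dataset == "CDD") par[3] * records$H
      else par[3] * records$M + par[4] * records$HMH
    mu <- records$A * exp(eta)
    ll <- sum(dnbinom(records$S, size = exp(par[k + 1L]), mu = mu,
                      log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  o <- optim(rep(0, k + 1L), nll, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-14))
  o <- optim(o$par, nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-15))
  list(coefs = o$par[seq_len(k)], theta = exp(o$par[k + 1L]),
       loglik = -o$value)
}

# O(stems x quadrats) direct-summation oracle for the quadrat table
oracle_quadrat_table <- function(census, assignments, traits, kernel,
                                 floor = 1e-12) {
  grid <- quadrat_grid(census)
  q <- census$quadrat_size
  stems <- census$stems
  cutoff <- assignments$sapling_cutoff[match(stems$species,
                                             assignments$species)]
  type <- traits$mycorrhizal_type[match(stems$species, traits$species)]
  keep <- !is.na(cutoff) & type %in% c("AM", "EM")
  stems <- stems[keep, ]
  cutoff <- cutoff[keep]
  type <- type[keep]
  species <- sort(unique(stems$species))
  rows <- list()
  for (sp in species) {
    sp_type <- type[stems$species == sp][1]
    for (qi in seq_len(nrow(grid))) {
      g <- grid[qi, ]
      S <- 0L; A <- 0; M <- 0; HMH <- 0
      for (i in seq_len(nrow(stems))) {
        st_x <- stems$x[i]; st_y <- stems$y[i]
        if (stems$dbh[i] < cutoff[i]) {
          if (stems$species[i] == sp &&
              floor(st_x / q) == g$qcol && floor(st_y / q) == g$qrow)
            S <- S + 1L
          next
        }
        dx <- max(g$x0 - st_x, st_x - g$x1, 0)
        dy <- max(g$y0 - st_y, st_y - g$y1, 0)
        w <- if (dx == 0 && dy == 0) 1
             else kernel_weight(sqrt(dx^2 + dy^2), kernel)
        if (stems$species[i] == sp) A <- A + w
        else if (type[i] == sp_type) M <- M + w
        else HMH <- HMH + w
      }
      rows[[length(rows) + 1L]] <- data.frame(
        qrow = g$qrow, qcol = g$qcol, species = sp, S = S,
        A = max(A, floor), H = M + HMH, M = M, HMH = HMH)
    }
  }
  do.call(rbind, rows)
}

# small hand-specified plot: 2 species x 2x2 quadrats of 10 m
toy_census <- function() {
  stems <- data.frame(
    stem_id = sprintf("s%02d", 1:8),
    tree_id = sprintf("t%02d", 1:8),
    species = c("aa", "aa", "aa", "bb", "bb", "aa", "bb", "bb"),
    x = c(2, 5, 12, 3, 15, 8, 18, 6),
    y = c(3, 8, 4, 14, 16, 2, 3, 7),
    dbh = c(15, 1.5, 22, 30, 1.2, 1.8, 12, 25),
    status = "alive", main_stem = TRUE)
  plot_census(stems, plot_id = "toy", x_extent = 20, y_extent = 20,
              quadrat_size = 10)
}

toy_traits <- function() {
  data.frame(species = c("aa", "bb"), genus = c("aa", "bb"),
             mycorrhizal_type = c("AM", "EM"), max_height = c(20, 30),
             source = "species")
}

make_window <- function(start, increment = 1) {
  structure(list(start = start, end = start + increment,
                 increment = increment, n_retained = NA_integer_),
            class = "density_window")
}

# quick synthetic study small enough for repeated pipeline runs
small_study <- function(seed, n_plots = 1, c_am = -0.3, c_em = -0.1,
                        n_species = 12, n_adults = 700,
                        extent = 200, recruitment = "cdd",
                        mode = "count_model") {
  cfg <- synthetic_config(x_extent = extent, y_extent = extent,
                          n_species = n_species, n_adults = n_adults,
                          c_am = c_am, c_em = c_em,
                          recruitment = recruitment, seed = seed)
  # balanced AM/EM composition so both types are always represented
  suppressMessages(generate_study(cfg, n_plots = n_plots, mode = mode,
                                  prop_am_fun = function(lat) 0.55))
}
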