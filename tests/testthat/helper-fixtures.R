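# Small shared fixtures, built in code.

# 2x2 lattice with unit cells at the origin (geometry for point assignment)
tiny_grid <- function() lattice_grid(2, 2)

# hand-placed records on the 2x2 grid, two seasons
tiny_records <- function() {
  focal <- data.frame(
    species_tag = "focal",
    cell_id = c("1", "1", "4"),
    date = as.Date(c("2020-06-03", "2020-06-04", "2021-07-15"))
  )
  nonfocal <- data.frame(
    species_tag = "nonfocal",
    cell_id = c("1", "2", "2", "3", "1", "4", "4"),
    date = as.Date(c("2020-06-02", "2020-06-20", "2020-06-21", "2020-08-01",
                     "2021-06-10", "2021-07-16", "2021-09-29"))
  )
  list(focal = focal, nonfocal = nonfocal)
}

# a tiny already-fitted model reused across method tests (cached per session)
tiny_fit_cache <- new.env()
tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    sc <- sim_scenario(nrow = 6, ncol = 6, n_years = 3, n_weeks = 8,
                       params = default_true_params(3, 8),
                       pdsi = list(year_means = c(2.5, -1.5, 3.0), sd = 1.2, smooth = 2L),
                       seed = 404)
    sim <- simulate_dataset(sc)
    tiny_fit_cache$sim <- sim
    # short exploratory chains: convergence warnings are expected and not
    # the object of the interface tests that reuse this fixture
    tiny_fit_cache$fit <- suppressWarnings(autoccu(
      sim$history, sim$covariates, sim$grid,
      config = mcmc_config(n_chains = 2, n_iter = 1500, n_burnin = 500,
                           n_thin_total = 600, seed = 77)))
  }
  list(fit = tiny_fit_cache$fit, sim = tiny_fit_cache$sim)
}
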