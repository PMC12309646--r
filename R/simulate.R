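#' Default generating parameters for simulation scenarios
#'
#' Effect sizes follow the posterior means reported for the rusty-patched
#' bumble bee analysis this model family was developed for: strong positive
#' neighbor effect on colonization (0.94), negative neighbor (-0.34) and
#' drought (-0.94) effects on extirpation, lower extirpation in conservation
#' unit 1 (-0.80), small positive effort effect on detection (0.08), and a
#' weekly detection curve peaking midseason (roughly 0.05 early/late, 0.45
#' at the peak). Year intercepts put average extirpation near 0.4 and
#' colonization near 0.1 at one occupied neighbor, with the worst transition
#' year second.
#'
#' @param n_years number of seasons.
#' @param n_weeks weekly occasions per season.
#' @param week_peak,week_width,week_amp,week_base shape of the weekly
#'   detection intercept curve (logit scale).
#' @return an [occu_params()] object.
#' @export
default_true_params <- function(n_years = 6L, n_weeks = 18L,
                                week_peak = 9.5, week_width = 3.5,
                                week_amp = 2.7, week_base = -2.9) {
  Tm1 <- max(n_years - 1L, 0L)
  year_shift <- rep_len(c(0.15, 0, -0.3, 0.05, 0, 0.1), n_years)
  j <- seq_len(n_weeks)
  curve <- week_base + week_amp * exp(-((j - week_peak)^2) / (2 * week_width^2))
  a_p <- outer(curve, year_shift, "+")
  occu_params(
    n_years, n_weeks,
    a_psi = -0.85, b_psi = c(0.12, 0.24, 0.85, 0.30),
    a_eps = rep_len(c(0.4, 1.1, 0.5, 0.4, 0.6), Tm1),
    b_eps = c(-0.34, -0.94, -0.80),
    a_gam = rep_len(c(-3.4, -4.0, -3.6, -3.5, -3.4), Tm1),
    b_gam = c(0.94, 0.0, 0.0),
    a_p = a_p, b_p = 0.08, sigma_p = 0.3
  )
}

#' Define a simulation scenario
#'
#' A scenario bundles everything the generator needs: lattice dimensions,
#' seasons, true parameters, and the land-cover, drought and survey-effort
#' generation settings. Defaults emulate the structure of the community
#' science data the model is designed for: spatially smooth land cover, one
#' drought season (negative mean drought index) among mostly wet seasons,
#' survey effort concentrated in developed cells, overdispersed congener
#' counts averaging roughly 9.5 congener and 1.3 focal records per surveyed
#' cell-year.
#'
#' @param nrow,ncol lattice dimensions.
#' @param n_years,n_weeks seasons and weekly occasions.
#' @param years season labels.
#' @param params true generating [occu_params()].
#' @param landcover list: `base` (mean herb/dev/hay proportions), `field_sd`
#'   (log-scale spatial field sd), `smooth` (smoothing sweeps).
#' @param pdsi list: `year_means` (per-season mean drought index; negative =
#'   drought), `sd`, `smooth`.
#' @param effort list: `active_int`/`active_dev` (logit of a cell-year being
#'   visited at all, intercept and standardized-developed-cover slope),
#'   `p_week` (weekly visit probability given active), `congener_mu`/
#'   `congener_size` (negative-binomial congener records per visited week),
#'   `focal_extra_mu`/`focal_extra_size` (extra focal records beyond the
#'   first in a detected week).
#' @param seed scenario seed.
#' @export
sim_scenario <- function(nrow = 20L, ncol = 20L, n_years = 6L, n_weeks = 18L,
                         years = seq(2017L, by = 1L, length.out = n_years),
                         params = default_true_params(n_years, n_weeks),
                         landcover = list(base = c(herb = 0.18, dev = 0.10, hay = 0.18),
                                          field_sd = 1.0, smooth = 2L),
                         pdsi = list(year_means = rep_len(c(2.5, 3.0, 1.5, 3.5, -1.5, 3.0),
                                                          n_years),
                                     sd = 1.2, smooth = 3L),
                         effort = list(active_int = -0.2, active_dev = 0.9,
                                       p_week = 0.25, congener_mu = 2.4,
                                       congener_size = 0.35, focal_extra_mu = 2.5,
                                       focal_extra_size = 0.6),
                         seed = 1L) {
  stopifnot(nrow >= 2, ncol >= 2, n_years >= 1, length(years) == n_years,
            length(pdsi$year_means) == n_years)
  structure(list(nrow = nrow, ncol = ncol, n_years = n_years, n_weeks = n_weeks,
                 years = years, params = params, landcover = landcover,
                 pdsi = pdsi, effort = effort, seed = seed),
            class = "occu_scenario")
}

# Moore-neighborhood smoothing: each sweep replaces a cell's value by the
# average of itself and its neighbors. Many sweeps converge to a constant.
smooth_field <- function(v, grid, sweeps) {
  for (s in seq_len(sweeps)) {
    v <- vapply(seq_along(v), function(i) {
      nb <- grid$adj[[i]]
      mean(c(v[i], v[nb]))
    }, 1)
  }
  v
}

#' Simulate land-cover and drought covariates
#'
#' Land-cover proportions come from a spatially smoothed compositional
#' (softmax) draw, so herb + dev + hay sum to less than 1 per cell; the
#' drought index is a smoothed Gaussian field around the configured yearly
#' means. The conservation unit is the grid's column split.
#'
#' @param scenario an [sim_scenario()].
#' @param grid an `occu_grid` (defaults to the scenario's lattice).
#' @return an `occu_covariates` object.
#' @export
simulate_covariates <- function(scenario, grid = lattice_grid(scenario$nrow, scenario$ncol)) {
  lc <- scenario$landcover
  base <- c(lc$base, other = max(1 - sum(lc$base), 0.01))
  fields <- vapply(seq_along(base), function(k)
    smooth_field(stats::rnorm(grid$n, 0, lc$field_sd), grid, lc$smooth),
    numeric(grid$n))
  eta <- sweep(fields, 2, log(base), "+")
  props <- exp(eta) / rowSums(exp(eta))
  pd <- scenario$pdsi
  pdsi <- vapply(seq_len(scenario$n_years), function(t)
    pd$year_means[t] + smooth_field(stats::rnorm(grid$n, 0, pd$sd), grid, pd$smooth),
    numeric(grid$n))
  covariate_set(grid, herb = props[, 1], dev = props[, 2], hay = props[, 3],
                pdsi = pdsi, years = scenario$years)
}

#' Simulate the latent occupancy process
#'
#' First-season states are Bernoulli draws from the initial-occupancy model;
#' later seasons evolve by the extirpation/colonization dynamics with the
#' occupied-neighbor counts of the realized states at the previous season.
#'
#' @param scenario an [sim_scenario()].
#' @param covs an `occu_covariates`.
#' @param grid an `occu_grid`.
#' @return binary matrix `cells x years`.
#' @export
simulate_occupancy <- function(scenario, covs, grid) {
  p <- scenario$params
  n <- grid$n; T <- scenario$n_years
  z <- matrix(0L, n, T)
  z[, 1] <- stats::rbinom(n, 1L, initial_occupancy_prob(p, covs))
  if (T > 1) for (t in 2:T) {
    th <- theta_hat(z[, t - 1, drop = FALSE], grid)[, 1]
    pr <- transition_prob(p, covs, z[, t - 1], th, seq_len(n), t)
    z[, t] <- stats::rbinom(n, 1L, pr)
  }
  z
}

#' Simulate the observation process
#'
#' Cell-years are visited with probability increasing in developed land
#' cover; surveyed weeks (drawn independently given the cell's effort
#' propensity) yield at least one congener record (a zero-truncated
#' overdispersed count: a week in which nothing was recorded is
#' indistinguishable from no survey) and, when the cell is occupied, a focal
#' detection with the weekly detection probability, whose effort covariate
#' is the standardized seasonal congener count. The weekly lattice is coded
#' by the same rule the history builder applies: 1 where a focal record
#' exists, 0 where only congener records exist, missing where no record
#' maps; survey timing is therefore exogenous to the focal detections, as
#' the fitted model assumes. Point-record streams equivalent to the lattice
#' are emitted so the record-to-history pipeline can be round-trip tested.
#'
#' @param scenario an [sim_scenario()].
#' @param z binary occupancy truth `cells x years`.
#' @param covs an `occu_covariates`.
#' @param grid an `occu_grid`.
#' @param coords emit lon/lat points inside cells instead of cell ids.
#' @return list: `history` (`occu_history`), `focal`/`nonfocal` record data
#'   frames, `count_std` (effort covariate used), `p_det` (true weekly
#'   detection probabilities at visited weeks).
#' @export
simulate_observations <- function(scenario, z, covs, grid, coords = FALSE) {
  ef <- scenario$effort
  pars <- scenario$params
  n <- grid$n; T <- scenario$n_years; J <- scenario$n_weeks
  active <- matrix(stats::rbinom(n * T, 1L,
                                 stats::plogis(ef$active_int + ef$active_dev * covs$dev_s)),
                   n, T)
  surveyed <- array(stats::rbinom(n * T * J, 1L, ef$p_week), c(n, T, J)) *
    as.vector(active)
  cong <- array(0L, c(n, T, J))
  sv <- which(surveyed == 1L)
  cong[sv] <- 1L + stats::rnbinom(length(sv), mu = max(ef$congener_mu - 1, 0.01),
                                  size = ef$congener_size)
  count <- apply(cong, c(1, 2), sum)

  # standardize effort over surveyed cell-years, exactly as the model will
  prov <- apply(surveyed == 1L, c(1, 2), any)
  count_std <- matrix(0, n, T)
  vals <- count[prov]
  if (length(unique(vals)) >= 2) count_std[prov] <- as.numeric(standardize(vals))

  pdet <- array(0, c(n, T, J))
  for (t in seq_len(T)) for (j in seq_len(J))
    pdet[, t, j] <- stats::plogis(pars$a_p[j, t] + pars$b_p * count_std[, t])
  det <- array(0L, c(n, T, J))
  zi <- array(rep(z, J), c(n, T, J))
  det[sv] <- stats::rbinom(length(sv), 1L, zi[sv] * pdet[sv])

  y <- array(NA_integer_, c(n, T, J))
  y[det == 1L] <- 1L
  y[det == 0L & cong >= 1L] <- 0L
  history <- occu_history(y, count, scenario$years, grid$cell_ids)

  emit <- function(w, n_rec) {
    # w: (cell, year, week) indices; n_rec: records per entry
    rep_idx <- rep(seq_along(n_rec), n_rec)
    i <- w[rep_idx, 1]; t <- w[rep_idx, 2]; j <- w[rep_idx, 3]
    start <- as.Date(sprintf("%d-06-01", as.integer(scenario$years)))[t]
    max_off <- ifelse(j == 18L, 2L, 6L)
    off <- floor(stats::runif(length(i)) * (pmin(max_off, 121L - 7L * (j - 1L)) + 1L))
    date <- start + 7L * (j - 1L) + off
    if (coords) {
      data.frame(lon = grid$origin[1] + (grid$col[i] - 1 + stats::runif(length(i))) * grid$cellsize,
                 lat = grid$origin[2] + (grid$row[i] - 1 + stats::runif(length(i))) * grid$cellsize,
                 date = date)
    } else {
      data.frame(cell_id = grid$cell_ids[i], date = date)
    }
  }
  wno <- which(cong >= 1L, arr.ind = TRUE)
  nonfocal <- emit(wno, cong[wno])
  nonfocal$species_tag <- rep("nonfocal", nrow(nonfocal))
  wfo <- which(det == 1L, arr.ind = TRUE)
  nf <- 1L + stats::rnbinom(nrow(wfo), mu = ef$focal_extra_mu, size = ef$focal_extra_size)
  focal <- emit(wfo, nf)
  focal$species_tag <- rep("focal", nrow(focal))

  list(history = history, focal = focal, nonfocal = nonfocal,
       count_std = count_std, p_det = pdet)
}

#' Simulate a complete data set from a scenario
#'
#' Seeds the generator from the scenario seed and chains covariate, latent
#' occupancy and observation simulation; everything is reproducible
#' bit-for-bit from the scenario.
#'
#' @param scenario an [sim_scenario()].
#' @param coords emit coordinate records instead of cell ids.
#' @return list with `grid`, `covariates`, `z` (truth), `history`, `focal`,
#'   `nonfocal`, `count_std`, `params`, `scenario`.
#' @export
simulate_dataset <- function(scenario, coords = FALSE) {
  set.seed(scenario$seed)
  grid <- lattice_grid(scenario$nrow, scenario$ncol)
  covs <- simulate_covariates(scenario, grid)
  z <- simulate_occupancy(scenario, covs, grid)
  obs <- simulate_observations(scenario, z, covs, grid, coords = coords)
  c(list(grid = grid, covariates = covs, z = z, params = scenario$params,
         scenario = scenario), obs)
}

#' Write a simulated data set to CSV files
#'
#' Emits the point-record, grid, land-cover-free covariate and truth tables
#' for a simulated data set, so the full record-to-fit pipeline can be run
#' from files.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$focal, file.path(dir, "records_focal.csv"), row.names = FALSE)
  utils::write.csv(sim$nonfocal, file.path(dir, "records_nonfocal.csv"), row.names = FALSE)
  g <- sim$grid
  utils::write.csv(data.frame(cell_id = g$cell_ids, cu = g$cu, row = g$row, col = g$col),
                   file.path(dir, "grid.csv"), row.names = FALSE)
  write_history(sim$history, dir)
  invisible(dir)
}

#' Build a small instance with its exact posterior by enumeration
#'
#' Generates a tiny data set (at most 4 cells, 3 seasons, 2 weeks, i.e. at
#' most 2^12 latent configurations) and computes, by brute-force summation of
#' the product of Bernoulli factors over every latent configuration, the
#' exact marginal posterior `P(z[i,t] = 1 | y)` and the exact marginal
#' likelihood at the given parameters. Used as the independent oracle for
#' the Gibbs machinery.
#'
#' @param n_cells,n_years,n_weeks instance dimensions (2^(cells x years)
#'   must not exceed 4096).
#' @param params generating [occu_params()]; default draws moderate random
#'   coefficients.
#' @param seed RNG seed for instance generation.
#' @return list: `grid`, `covs`, `history`, `params`, `z_true`,
#'   `count_std`, and `exact` (list with `marginal`, a cells x years matrix,
#'   and `logml`).
#' @export
make_oracle_instance <- function(n_cells = 4L, n_years = 2L, n_weeks = 2L,
                                 params = NULL, seed = NULL) {
  if (2^(n_cells * n_years) > 4096) stop("instance too large to enumerate")
  if (!is.null(seed)) set.seed(seed)
  grid <- if (n_cells == 4L) lattice_grid(2, 2) else lattice_grid(1, n_cells)
  n <- grid$n; T <- n_years; J <- n_weeks
  if (is.null(params)) {
    params <- occu_params(
      T, J,
      a_psi = stats::rnorm(1, 0, 0.8), b_psi = stats::rnorm(4, 0, 0.6),
      a_eps = stats::rnorm(max(T - 1, 0), 0, 0.8), b_eps = stats::rnorm(3, 0, 0.5),
      a_gam = stats::rnorm(max(T - 1, 0), -0.5, 0.8), b_gam = stats::rnorm(3, 0, 0.5),
      a_p = matrix(stats::rnorm(J * T, -0.5, 0.8), J, T),
      b_p = stats::rnorm(1, 0, 0.3), sigma_p = 0.5
    )
  }
  covs <- occu_covariates(
    herb_s = stats::rnorm(n), dev_s = stats::rnorm(n), hay_s = stats::rnorm(n),
    cu = grid$cu, pdsi_s = matrix(stats::rnorm(n * T), n, T),
    years = seq_len(T)
  )
  # observation pattern and effort
  attempt <- array(stats::rbinom(n * T * J, 1L, 0.7), c(n, T, J))
  count <- matrix(0L, n, T)
  sv <- apply(attempt == 1L, c(1, 2), any)
  count[sv] <- stats::rpois(sum(sv), 6)
  # latent truth and observations (p uses the effort covariate the fit will see)
  h0 <- occu_history(array(ifelse(attempt == 1L, 0L, NA_integer_), c(n, T, J)),
                     count, seq_len(T), grid$cell_ids)
  count_std <- effort_std(h0)
  z <- matrix(0L, n, T)
  z[, 1] <- stats::rbinom(n, 1L, initial_occupancy_prob(params, covs))
  if (T > 1) for (t in 2:T) {
    th <- theta_hat(z[, t - 1, drop = FALSE], grid)[, 1]
    z[, t] <- stats::rbinom(n, 1L, transition_prob(params, covs, z[, t - 1], th,
                                                   seq_len(n), t))
  }
  y <- array(NA_integer_, c(n, T, J))
  for (i in seq_len(n)) for (t in seq_len(T)) for (j in seq_len(J)) {
    if (attempt[i, t, j] == 1L) {
      pdet <- detection_prob(params, count_std[i, t], j, t)
      y[i, t, j] <- stats::rbinom(1, 1L, z[i, t] * pdet)
    }
  }
  history <- occu_history(y, count, seq_len(T), grid$cell_ids)
  exact <- enumerate_exact(history, covs, grid, params, effort_std(history))
  list(grid = grid, covs = covs, history = history, params = params,
       z_true = z, count_std = effort_std(history), exact = exact)
}

#' Exact posterior over latent states by enumeration
#'
#' Independent brute-force oracle: sums the product of Bernoulli factors
#' (initial occupancy, transitions, detections) over all `2^(cells x years)`
#' latent configurations. Works directly in probabilities and never calls
#' the model's log-density code.
#'
#' @param history,covs,grid,params model inputs.
#' @param count_std standardized effort matrix.
#' @return list: `marginal` (cells x years matrix of exact
#'   `P(z[i,t] = 1 | y)`) and `logml` (log marginal likelihood).
#' @export
enumerate_exact <- function(history, covs, grid, params,
                            count_std = effort_std(history)) {
  n <- grid$n; T <- length(history$years); J <- history$n_weeks
  M <- n * T
  if (2^M > 4096) stop("instance too large to enumerate")
  psi <- initial_occupancy_prob(params, covs)
  configs <- as.matrix(expand.grid(rep(list(0:1), M)))
  w <- numeric(nrow(configs))
  for (k in seq_len(nrow(configs))) {
    zc <- matrix(configs[k, ], n, T)
    pr <- 1
    for (i in seq_len(n))
      pr <- pr * (if (zc[i, 1] == 1) psi[i] else 1 - psi[i])
    if (T > 1) for (t in 2:T) for (i in seq_len(n)) {
      th <- sum(zc[grid$adj[[i]], t - 1])
      e <- extirpation_prob(params, covs, th, i, t)
      g <- colonization_prob(params, covs, th, i, t)
      p1 <- if (zc[i, t - 1] == 1) 1 - e else g
      pr <- pr * (if (zc[i, t] == 1) p1 else 1 - p1)
    }
    for (i in seq_len(n)) for (t in seq_len(T)) for (j in seq_len(J)) {
      yv <- history$y[i, t, j]
      if (is.na(yv)) next
      pd <- zc[i, t] * detection_prob(params, count_std[i, t], j, t)
      pr <- pr * (if (yv == 1) pd else 1 - pd)
    }
    w[k] <- pr
  }
  ml <- sum(w)
  marg <- matrix(colSums(configs * w) / ml, n, T)
  list(marginal = marg, logml = log(ml))
}
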