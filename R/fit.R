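#' MCMC configuration
#'
#' Defaults follow the full fitting protocol: 4 chains of 20,000 iterations
#' with 5,000 discarded as burn-in, thinned to 5,000 retained draws in total
#' across chains.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations per chain (must be `< n_iter`).
#' @param n_thin_total retained draws in total across chains.
#' @param seed master seed; per-chain streams are spawned from it.
#' @param adapt adapt random-walk proposal scales during burn-in
#'   (Robbins-Monro toward `target_accept`).
#' @param target_accept target acceptance probability for scalar updates.
#' @param init_scale initial proposal standard deviation.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 20000L, n_burnin = 5000L,
                        n_thin_total = 5000L, seed = 1L, adapt = TRUE,
                        target_accept = 0.35, init_scale = 0.15) {
  stopifnot(n_burnin < n_iter, n_chains >= 1,
            n_thin_total <= n_chains * (n_iter - n_burnin))
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 n_thin_total = as.integer(n_thin_total), seed = as.integer(seed),
                 adapt = adapt, target_accept = target_accept,
                 init_scale = init_scale),
            class = "mcmc_config")
}

# Pack model inputs into the flat arrays the C++ sampler consumes.
pack_data <- function(history, covs, grid, priors, dynamics, detection,
                      count_std) {
  n <- grid$n; T <- length(history$years); J <- history$n_weeks
  deg <- lengths(grid$adj)
  adj_ptr <- c(0L, cumsum(deg))
  adj_idx <- as.integer(unlist(grid$adj, use.names = FALSE) - 1L)

  obs_ptr <- integer(n * T + 1L)
  obs_week <- integer(0); obs_y <- integer(0)
  ow <- vector("list", n * T)
  oy <- vector("list", n * T)
  for (t in seq_len(T)) for (i in seq_len(n)) {
    q <- i + n * (t - 1L)
    wk <- which(!is.na(history$y[i, t, ]))
    ow[[q]] <- wk - 1L
    oy[[q]] <- history$y[i, t, wk]
  }
  cnts <- lengths(ow)
  obs_ptr <- c(0L, cumsum(cnts))
  obs_week <- as.integer(unlist(ow, use.names = FALSE))
  obs_y <- as.integer(unlist(oy, use.names = FALSE))

  # regroup by (week, year) for the weekly-intercept updates
  wkey <- integer(0); wcell <- integer(0); wy <- integer(0)
  for (t in seq_len(T)) for (i in seq_len(n)) {
    q <- i + n * (t - 1L)
    if (!cnts[q]) next
    wkey <- c(wkey, ow[[q]] + J * (t - 1L))
    wcell <- c(wcell, rep(i - 1L, cnts[q]))
    wy <- c(wy, oy[[q]])
  }
  o <- order(wkey)
  wkey <- wkey[o]; wcell <- wcell[o]; wy <- wy[o]
  wobs_ptr <- integer(J * T + 1L)
  tab <- tabulate(wkey + 1L, nbins = J * T)
  wobs_ptr <- c(0L, cumsum(tab))

  has_det <- apply(history$y == 1L, c(1, 2), any)
  has_det[is.na(has_det)] <- FALSE

  list(n = n, T = T, J = J,
       adj_ptr = adj_ptr, adj_idx = adj_idx,
       obs_ptr = as.integer(obs_ptr), obs_week = obs_week, obs_y = obs_y,
       wobs_ptr = as.integer(wobs_ptr), wobs_cell = as.integer(wcell),
       wobs_y = as.integer(wy),
       surveyed = as.integer(history$surveyed), has_det = as.integer(has_det),
       count_std = as.numeric(count_std), pdsi = as.numeric(covs$pdsi_s),
       cu = as.numeric(covs$cu), herb = covs$herb_s, dev = covs$dev_s,
       hay = covs$hay_s,
       dyn_auto = dynamics == "autologistic",
       det_weekly = detection == "weekly",
       coef_sd = priors$coef_sd, sig_sd = priors$sigma_p_sd)
}

#' Fit the autologistic dynamic occupancy model
#'
#' Fits the hierarchical dynamic occupancy model by Metropolis-within-Gibbs
#' MCMC: the latent occupancy lattice `z` is updated by Gibbs sampling from
#' its exact full conditionals; coefficients by adaptive random-walk
#' Metropolis. Initial occupancy depends on land cover and conservation
#' unit; extirpation and colonization depend on the occupied-neighbor count
#' of the previous year, destination-year drought, and conservation unit
#' (`dynamics = "autologistic"`) or on year intercepts only
#' (`dynamics = "intercept"`); detection depends on an AR(1) weekly intercept
#' and standardized congener-count effort (`detection = "weekly"`) or a
#' single intercept plus effort (`detection = "constant"`).
#'
#' Latent states are initialized at 1 wherever the cell-year has a
#' detection, Bernoulli(0.5) elsewhere; detected cell-years stay pinned at
#' `z = 1`. Convergence is checked with the Gelman-Rubin statistic on all
#' coefficient parameters; values at or above 1.1 trigger a prominent
#' warning (the fit is still returned, flagged).
#'
#' @param history an `occu_history` (see [build_history()]).
#' @param covariates an `occu_covariates` (see [covariate_set()]).
#' @param grid an `occu_grid`.
#' @param dynamics `"autologistic"` (full model) or `"intercept"`.
#' @param detection `"weekly"` (AR(1) week-by-year intercepts) or
#'   `"constant"`.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param init_params optional `occu_params` used (jittered) to start every
#'   chain; default draws overdispersed starts.
#' @param fix_params if `TRUE`, coefficients stay at `init_params` and only
#'   the latent states are sampled (used to validate the Gibbs machinery
#'   against exact enumeration).
#' @return An object of class `autoccu`.
#' @export
autoccu <- function(history, covariates, grid,
                    dynamics = c("autologistic", "intercept"),
                    detection = c("weekly", "constant"),
                    priors = prior_spec(), config = mcmc_config(),
                    init_params = NULL, fix_params = FALSE) {
  dynamics <- match.arg(dynamics)
  detection <- match.arg(detection)
  stopifnot(inherits(history, "occu_history"), inherits(covariates, "occu_covariates"),
            inherits(grid, "occu_grid"))
  if (!any(!is.na(history$y)))
    warning("no non-missing observations: sampling from the prior", call. = FALSE)
  n <- grid$n; T <- length(history$years); J <- history$n_weeks
  count_std <- effort_std(history)
  dat <- pack_data(history, covariates, grid, priors, dynamics, detection, count_std)
  nap <- if (detection == "weekly") J * T else 1L
  np <- 1L + 4L + 2L * max(T - 1L, 0L) + 6L + 2L + nap
  pnames <- param_names(T, J, detection)
  if (fix_params && is.null(init_params))
    stop("fix_params = TRUE requires init_params")

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  keep_per <- diff(round(seq(0, config$n_thin_total, length.out = config$n_chains + 1)))
  stride <- pmax(1L, (config$n_iter - config$n_burnin) %/% pmax(keep_per, 1L))

  par_draws <- vector("list", config$n_chains)
  z_draws <- vector("list", config$n_chains)
  accept <- NULL
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    if (is.null(init_params)) {
      ip <- c(stats::rnorm(np - nap - 1L, 0, 1),       # coefficients through beta_p
              exp(stats::rnorm(1, -0.5, 0.3)),         # sigma_p
              stats::rnorm(nap, 0, 0.5))               # weekly intercepts
    } else {
      ip <- unname(flatten_params(init_params, detection))
      if (!fix_params) {
        jit <- stats::rnorm(np, 0, 0.1)
        jit[np - nap] <- 0  # keep sigma_p positive
        ip <- ip + jit
      }
    }
    z0 <- matrix(stats::rbinom(n * T, 1L, 0.5), n, T)
    det_any <- apply(history$y == 1L, c(1, 2), any)
    det_any[is.na(det_any)] <- FALSE
    z0[det_any] <- 1L
    res <- run_chain_cpp(dat, as.numeric(ip), as.integer(z0),
                         list(n_iter = config$n_iter, n_burnin = config$n_burnin,
                              stride = stride[ch],
                              n_keep = keep_per[ch], adapt = config$adapt,
                              fix_params = fix_params,
                              target_accept = config$target_accept,
                              init_scale = config$init_scale))
    par_draws[[ch]] <- res$params[seq_len(res$kept), , drop = FALSE]
    z_draws[[ch]] <- res$z[seq_len(res$kept), , drop = FALSE]
    if (is.null(accept)) accept <- res$accept / config$n_chains
    else accept <- accept + res$accept / config$n_chains
  }

  params_mat <- do.call(rbind, par_draws)
  colnames(params_mat) <- pnames
  z_mat <- do.call(rbind, z_draws)
  chain_id <- rep(seq_len(config$n_chains), vapply(par_draws, nrow, 1L))

  monitored <- pnames[!startsWith(pnames, "alpha_p[")]
  rhat <- rep(NA_real_, length(pnames))
  names(rhat) <- pnames
  if (config$n_chains >= 2 && !fix_params) {
    for (pn in pnames) {
      tr <- split(params_mat[, pn], chain_id)
      rhat[pn] <- gelman_rubin(tr)
    }
  }
  converged <- if (config$n_chains >= 2 && !fix_params)
    all(rhat[monitored] < 1.1, na.rm = TRUE) else NA
  if (isFALSE(converged)) {
    bad <- monitored[which(rhat[monitored] >= 1.1)]
    warning("convergence not reached: Gelman-Rubin >= 1.1 for ",
            paste(utils::head(bad, 8), collapse = ", "),
            if (length(bad) > 8) ", ..." else "", call. = FALSE)
  }

  structure(list(
    draws = list(params = params_mat, z = z_mat, chain = chain_id),
    par_names = pnames, monitored = monitored,
    history = history, covariates = covariates, grid = grid,
    dynamics = dynamics, detection = detection,
    priors = priors, config = config, count_std = count_std,
    rhat = rhat, converged = converged, accept = accept,
    fix_params = fix_params, call = match.call()
  ), class = "autoccu")
}

#' Reconstruct an `occu_params` from one posterior draw
#' @param fit an `autoccu` fit.
#' @param draw draw index (row of `fit$draws$params`).
#' @export
params_from_draw <- function(fit, draw) {
  T <- length(fit$history$years); J <- fit$history$n_weeks
  unflatten_params(unname(fit$draws$params[draw, ]), T, J, fit$detection)
}

z_from_draw <- function(fit, draw) {
  matrix(fit$draws$z[draw, ], fit$grid$n, length(fit$history$years))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-estimator diagnostic from parallel chains: compares the
#' between-chain variance of chain means with the mean within-chain
#' variance. Values near 1 indicate the chains sample the same
#' distribution; the conventional convergence cutoff is 1.1. Chains that are
#' all constant and identical give 1.
#'
#' @param chains a list of equal-length numeric vectors (one per chain), or
#'   a matrix with one column per chain.
#' @return the potential scale reduction factor (>= 1 up to rounding).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  nn <- min(lengths(chains))
  if (nn < 10) stop("need at least 10 draws per chain")
  chains <- lapply(chains, function(v) v[seq_len(nn)])
  means <- vapply(chains, mean, 1)
  W <- mean(vapply(chains, stats::var, 1))
  B <- nn * stats::var(means)
  if (!is.finite(W) || W == 0) {
    if (!is.finite(B) || B == 0) return(1)
    return(Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
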