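#' Finite-sample occupancy per posterior draw
#'
#' For each retained draw and each season, the fraction of *surveyed* cells
#' whose latent state is occupied: `psi_fs[t] = (1/R) * sum_i z[i,t]` over
#' the R cells with any non-missing week that year. Computed per draw and
#' only then summarized, never as a summary of summaries.
#'
#' @param fit an `autoccu` fit.
#' @param surveyed optional logical `cells x years` matrix; defaults to the
#'   fit's detection-history survey flags.
#' @return matrix `draws x years` of finite-sample occupancy.
#' @export
finite_sample_occupancy <- function(fit, surveyed = fit$history$surveyed) {
  T <- length(fit$history$years); n <- fit$grid$n
  R <- colSums(surveyed)
  if (any(R == 0)) stop("a year has zero surveyed cells")
  out <- matrix(NA_real_, nrow(fit$draws$z), T)
  for (t in seq_len(T)) {
    idx <- which(surveyed[, t]) + n * (t - 1L)
    out[, t] <- rowSums(fit$draws$z[, idx, drop = FALSE]) / R[t]
  }
  colnames(out) <- as.character(fit$history$years)
  out
}

#' Unconditional occupancy per posterior draw
#'
#' The fraction of *all* grid cells occupied each season, sampled and
#' unsampled alike. Under preferential sampling of occupied areas the
#' finite-sample occupancy typically exceeds this (reported, not enforced).
#'
#' @param fit an `autoccu` fit.
#' @return matrix `draws x years`.
#' @export
unconditional_occupancy <- function(fit) {
  T <- length(fit$history$years); n <- fit$grid$n
  out <- matrix(NA_real_, nrow(fit$draws$z), T)
  for (t in seq_len(T))
    out[, t] <- rowSums(fit$draws$z[, seq_len(n) + n * (t - 1L), drop = FALSE]) / n
  colnames(out) <- as.character(fit$history$years)
  out
}

#' Occupied-cell count per posterior draw
#' @param fit an `autoccu` fit.
#' @return integer matrix `draws x years` of `sum_i z[i,t]`.
#' @export
occupied_cell_count <- function(fit) {
  n <- fit$grid$n
  round(unconditional_occupancy(fit) * n)
}

#' Summarize per-draw quantities with equal-tailed credible intervals
#'
#' @param x matrix `draws x quantities` (e.g. from
#'   [finite_sample_occupancy()]).
#' @param probs quantile pairs; defaults give 66% and 95% equal-tailed
#'   intervals.
#' @return data frame with mean and the requested quantiles per column.
#' @export
summarize_draws <- function(x, probs = c(0.025, 0.17, 0.83, 0.975)) {
  qs <- t(apply(x, 2, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(mean = colMeans(x), qs)
  names(out) <- c("mean", paste0("q", format(probs * 100, trim = TRUE)))
  out
}

#' Extirpation / colonization response curves
#'
#' Posterior response curves of the dynamic rates against the number of
#' occupied neighboring cells (at reference drought conditions) or against
#' the drought index (at a reference neighbor count). For each grid point
#' the inverse-logit rate is averaged over year-specific intercepts and over
#' the two conservation units (weighted by their cell shares), per posterior
#' draw; the curve reports posterior mean and equal-tailed intervals.
#'
#' @param fit an `autoccu` fit with `dynamics = "autologistic"`.
#' @param target `"extirpation"` or `"colonization"`.
#' @param vary `"theta"` (neighbor count grid `0:8`) or `"pdsi"`.
#' @param theta grid of neighbor counts (when `vary = "theta"`), or the
#'   reference count (when `vary = "pdsi"`; default: posterior mean
#'   occupied-neighbor count over cells, years and draws).
#' @param pdsi standardized drought grid (when `vary = "pdsi"`), or the
#'   reference value (when `vary = "theta"`; default 0, the pooled mean).
#' @param probs interval quantiles.
#' @return data frame: the varying covariate, posterior `mean`, and interval
#'   columns.
#' @export
response_curve <- function(fit, target = c("extirpation", "colonization"),
                           vary = c("theta", "pdsi"), theta = NULL, pdsi = NULL,
                           probs = c(0.025, 0.975)) {
  target <- match.arg(target)
  vary <- match.arg(vary)
  T <- length(fit$history$years)
  if (T < 2) stop("response curves need at least 2 seasons")
  pars <- fit$draws$params
  a <- pars[, grep(if (target == "extirpation") "^alpha_eps\\[" else "^alpha_gam\\[",
                   colnames(pars)), drop = FALSE]
  b <- pars[, paste0(if (target == "extirpation") "beta_eps_" else "beta_gam_",
                     c("theta", "pdsi", "cu")), drop = FALSE]
  cu_share <- mean(fit$covariates$cu)
  if (vary == "theta") {
    grid_v <- if (is.null(theta)) 0:8 else theta
    ref <- if (is.null(pdsi)) 0 else pdsi
  } else {
    grid_v <- if (is.null(pdsi)) stop("supply a pdsi grid") else pdsi
    ref <- if (is.null(theta)) mean(theta_mean(fit)) else theta
  }
  if (length(grid_v) == 0) stop("empty covariate grid")
  curves <- matrix(NA_real_, nrow(pars), length(grid_v))
  for (g in seq_along(grid_v)) {
    thv <- if (vary == "theta") grid_v[g] else ref
    pdv <- if (vary == "pdsi") grid_v[g] else ref
    # average inverse-logit over year intercepts and conservation units
    pr <- 0
    for (t in seq_len(ncol(a))) {
      eta0 <- a[, t] + b[, 1] * thv + b[, 2] * pdv
      pr <- pr + (1 - cu_share) * stats::plogis(eta0) +
        cu_share * stats::plogis(eta0 + b[, 3])
    }
    curves[, g] <- pr / ncol(a)
  }
  qs <- t(apply(curves, 2, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(grid_v, colMeans(curves), qs)
  names(out) <- c(vary, "mean", paste0("q", format(probs * 100, trim = TRUE)))
  out
}

#' Posterior mean occupied-neighbor count
#' @param fit an `autoccu` fit.
#' @return matrix `cells x years` of posterior mean neighbor counts.
#' @export
theta_mean <- function(fit) {
  n <- fit$grid$n; T <- length(fit$history$years)
  zbar <- matrix(colMeans(fit$draws$z), n, T)
  theta_hat(zbar, fit$grid)
}

# per-draw detection probabilities and observation bookkeeping
obs_index <- function(fit) {
  idx <- which(!is.na(fit$history$y), arr.ind = TRUE)
  colnames(idx) <- c("cell", "year", "week")
  idx
}

#' Widely applicable information criterion
#'
#' WAIC over the non-missing weekly observations:
#' `WAIC = -2 (lppd - p_waic)`, with `lppd` the log pointwise predictive
#' density and `p_waic` the summed posterior variance of the pointwise log
#' likelihood; lower is better. Two pointwise likelihoods are available:
#' `"conditional"` scores each observation given that draw's latent state,
#' `Bernoulli(y | z * p)`; `"marginal"` integrates the latent state out per
#' draw via the forward occupancy recursion, `Bernoulli(y | psi * p)`. The
#' conditional form scores the detection layer only and has essentially no
#' power to compare latent-dynamics structures (any draw with `z = 0` scores
#' a nondetection perfectly, whatever the dynamics); use `"marginal"` when
#' ranking models that differ in their occupancy dynamics.
#'
#' @param fit an `autoccu` fit (at least 2 retained draws).
#' @param likelihood pointwise likelihood: `"conditional"` (on the draw's
#'   latent state) or `"marginal"` (latent state integrated out per draw).
#' @return list with `waic`, `lppd`, `p_waic`, `n_obs`.
#' @export
waic <- function(fit, likelihood = c("conditional", "marginal")) {
  likelihood <- match.arg(likelihood)
  nd <- nrow(fit$draws$params)
  if (nd < 2) stop("need at least 2 draws for WAIC")
  idx <- obs_index(fit)
  yv <- fit$history$y[idx]
  n <- fit$grid$n
  cs <- fit$count_std[idx[, c("cell", "year")]]
  # Welford accumulation across draws: mean of lik, mean/var of log lik
  mean_lik <- numeric(nrow(idx))
  m_ll <- numeric(nrow(idx)); s_ll <- numeric(nrow(idx))
  for (d in seq_len(nd)) {
    p <- params_from_draw(fit, d)
    pv <- stats::plogis(p$a_p[cbind(idx[, "week"], idx[, "year"])] + p$b_p * cs)
    if (likelihood == "conditional") {
      zv <- fit$draws$z[d, idx[, "cell"] + n * (idx[, "year"] - 1L)]
      q <- zv * pv
    } else {
      psi <- psi_recursion(fit, p, z_from_draw(fit, d))
      q <- pmin(pmax(psi[idx[, c("cell", "year")]] * pv, 1e-12), 1 - 1e-12)
    }
    lik <- ifelse(yv == 1L, q, 1 - q)
    ll <- log(lik)
    mean_lik <- mean_lik + (lik - mean_lik) / d
    delta <- ll - m_ll
    m_ll <- m_ll + delta / d
    s_ll <- s_ll + delta * (ll - m_ll)
  }
  lppd <- sum(log(mean_lik))
  p_waic <- sum(s_ll / (nd - 1))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic, n_obs = nrow(idx))
}

# Forward occupancy-probability recursion for one draw:
# psi[,1] from the initial model; psi[,t] = psi[,t-1](1-eps) + (1-psi[,t-1])gam,
# with eps/gam evaluated at the draw's realized neighbor counts.
psi_recursion <- function(fit, params, z) {
  n <- fit$grid$n; T <- length(fit$history$years)
  psi <- matrix(NA_real_, n, T)
  psi[, 1] <- initial_occupancy_prob(params, fit$covariates)
  if (T > 1) {
    th <- theta_hat(z, fit$grid)
    for (t in 2:T) {
      eps <- extirpation_prob(params, fit$covariates, th[, t - 1], seq_len(n), t)
      gam <- colonization_prob(params, fit$covariates, th[, t - 1], seq_len(n), t)
      psi[, t] <- psi[, t - 1] * (1 - eps) + (1 - psi[, t - 1]) * gam
    }
  }
  psi
}

#' Posterior predictive goodness of fit (Bayesian p-value)
#'
#' For each draw, the deviance of the observed detection data under the
#' marginal success probabilities `psi[i,t] * p[i,j,t]` (occupancy
#' probability from the forward recursion at the draw's parameters and
#' realized neighbor counts) is compared with the deviance of a replicate
#' data set simulated under the same probabilities. The Bayesian p-value is
#' the fraction of draws whose replicate deviance exceeds the observed one
#' (ties count one half). Values near 0.5 indicate adequate fit; values near
#' 0 or 1 indicate misfit.
#'
#' Two aggregation units are available. `unit = "visit"` (the default)
#' scores every non-missing weekly observation against `psi * p`.
#' `unit = "cellyear"` scores the season-level detected/not-detected
#' indicator of each surveyed cell-year against
#' `psi[i,t] * (1 - prod_j (1 - p[i,j,t]))`. Both are calibrated (near 0.5)
#' under a correctly specified model; neither has much power against misfit
#' that the fitted detection layer can absorb on the scored margin, such as
#' purely week-level detection heterogeneity — see the package vignette.
#'
#' @param fit an `autoccu` fit.
#' @param unit deviance aggregation: `"visit"` (weekly observations) or
#'   `"cellyear"` (season-level detection indicators).
#' @param n_draws number of posterior draws to use (spread evenly; default
#'   all, capped at 1000).
#' @param seed RNG seed for the replicate simulations.
#' @return list with `p` (the Bayesian p-value) and per-draw deviances
#'   `dev_obs`, `dev_rep`.
#' @export
bayes_pvalue <- function(fit, unit = c("visit", "cellyear"), n_draws = NULL,
                         seed = 1L) {
  unit <- match.arg(unit)
  nd_all <- nrow(fit$draws$params)
  if (is.null(n_draws)) n_draws <- min(nd_all, 1000L)
  use <- unique(round(seq(1, nd_all, length.out = n_draws)))
  set.seed(seed)
  idx <- obs_index(fit)
  yv <- fit$history$y[idx]
  n <- fit$grid$n
  cs <- fit$count_std[idx[, c("cell", "year")]]
  bernoulli_dev <- function(x, q) -2 * sum(x * log(q) + (1 - x) * log1p(-q))
  if (unit == "cellyear") {
    sv <- which(fit$history$surveyed)
    det_cy <- apply(fit$history$y == 1L, c(1, 2), any)
    det_cy[is.na(det_cy)] <- FALSE
    x_obs <- as.numeric(det_cy[sv])
    # aggregate weekly miss probabilities per cell-year: prod over (1 - p)
    cy_of_obs <- idx[, "cell"] + n * (idx[, "year"] - 1L)
  }
  dev_obs <- dev_rep <- numeric(length(use))
  for (k in seq_along(use)) {
    d <- use[k]
    p <- params_from_draw(fit, d)
    z <- z_from_draw(fit, d)
    psi <- psi_recursion(fit, p, z)
    pv <- stats::plogis(p$a_p[cbind(idx[, "week"], idx[, "year"])] + p$b_p * cs)
    if (unit == "visit") {
      q <- pmin(pmax(psi[idx[, c("cell", "year")]] * pv, 1e-12), 1 - 1e-12)
      dev_obs[k] <- bernoulli_dev(yv, q)
      dev_rep[k] <- bernoulli_dev(stats::rbinom(length(q), 1L, q), q)
    } else {
      miss <- vapply(split(log1p(-pv), cy_of_obs), sum, 1)
      q_cy <- psi[sv] * (1 - exp(miss[as.character(sv)]))
      q_cy <- pmin(pmax(q_cy, 1e-12), 1 - 1e-12)
      dev_obs[k] <- bernoulli_dev(x_obs, q_cy)
      dev_rep[k] <- bernoulli_dev(stats::rbinom(length(q_cy), 1L, q_cy), q_cy)
    }
  }
  p <- mean(dev_rep > dev_obs) + 0.5 * mean(dev_rep == dev_obs)
  list(p = p, dev_obs = dev_obs, dev_rep = dev_rep, n_draws = length(use),
       unit = unit)
}
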