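#' Model parameters for the autologistic dynamic occupancy model
#'
#' Collects every coefficient of the model: initial-occupancy intercept and
#' land-cover/conservation-unit effects; year-specific extirpation and
#' colonization intercepts with neighbor-count, drought and conservation-unit
#' effects; weekly detection intercepts (one per week x year, tied by an
#' AR(1) random walk with scale `sigma_p`) and the effort-count effect.
#'
#' @param n_years number of seasons T.
#' @param n_weeks weekly occasions per season J.
#' @param a_psi initial-occupancy intercept (logit scale).
#' @param b_psi length-4 effects: herb, dev, hay, cu.
#' @param a_eps,a_gam length `T-1` year-specific extirpation / colonization
#'   intercepts (entry t governs the transition from year t to t+1).
#' @param b_eps,b_gam length-3 effects: occupied-neighbor count (raw 0-8),
#'   standardized drought index of the destination year, conservation unit.
#' @param a_p `J x T` matrix of weekly detection intercepts (logit scale).
#' @param b_p effect of the standardized seasonal congener count (effort).
#' @param sigma_p positive random-walk standard deviation for the weekly
#'   detection intercepts.
#' @return An object of class `occu_params`.
#' @export
occu_params <- function(n_years, n_weeks = 18L,
                        a_psi = 0, b_psi = numeric(4),
                        a_eps = numeric(max(n_years - 1L, 0L)), b_eps = numeric(3),
                        a_gam = numeric(max(n_years - 1L, 0L)), b_gam = numeric(3),
                        a_p = matrix(0, n_weeks, n_years), b_p = 0, sigma_p = 1) {
  a_p <- matrix(a_p, n_weeks, n_years)
  stopifnot(length(b_psi) == 4, length(b_eps) == 3, length(b_gam) == 3,
            length(a_eps) == max(n_years - 1L, 0L),
            length(a_gam) == max(n_years - 1L, 0L),
            sigma_p > 0, is.finite(a_psi), all(is.finite(a_p)))
  structure(list(n_years = as.integer(n_years), n_weeks = as.integer(n_weeks),
                 a_psi = a_psi, b_psi = as.numeric(b_psi),
                 a_eps = as.numeric(a_eps), b_eps = as.numeric(b_eps),
                 a_gam = as.numeric(a_gam), b_gam = as.numeric(b_gam),
                 a_p = a_p, b_p = b_p, sigma_p = sigma_p),
            class = "occu_params")
}

#' Prior specification
#'
#' Vague normal(0, 2) priors on every intercept and slope, and a
#' half-normal(2) prior on the weekly random-walk scale `sigma_p`. The
#' first-week detection intercept of each year has a normal(0, 2) prior;
#' later weeks follow the AR(1) walk `a_p[j,t] ~ N(a_p[j-1,t], sigma_p)`.
#'
#' @param coef_sd prior sd for coefficients.
#' @param sigma_p_sd half-normal scale for `sigma_p`.
#' @export
prior_spec <- function(coef_sd = 2, sigma_p_sd = 2) {
  stopifnot(coef_sd > 0, sigma_p_sd > 0)
  structure(list(coef_sd = coef_sd, sigma_p_sd = sigma_p_sd), class = "occu_priors")
}

param_names <- function(n_years, n_weeks, detection = "weekly") {
  T <- n_years
  c("alpha_psi", paste0("beta_psi_", c("herb", "dev", "hay", "cu")),
    if (T > 1) paste0("alpha_eps[", seq_len(T - 1), "]"),
    paste0("beta_eps_", c("theta", "pdsi", "cu")),
    if (T > 1) paste0("alpha_gam[", seq_len(T - 1), "]"),
    paste0("beta_gam_", c("theta", "pdsi", "cu")),
    "beta_p", "sigma_p",
    if (detection == "weekly")
      paste0("alpha_p[", rep(seq_len(n_weeks), T), ",", rep(seq_len(T), each = n_weeks), "]")
    else "alpha_p")
}

flatten_params <- function(p, detection = "weekly") {
  v <- c(p$a_psi, p$b_psi, p$a_eps, p$b_eps, p$a_gam, p$b_gam, p$b_p, p$sigma_p,
         if (detection == "weekly") as.numeric(p$a_p) else p$a_p[1, 1])
  stats::setNames(v, param_names(p$n_years, p$n_weeks, detection))
}

unflatten_params <- function(v, n_years, n_weeks, detection = "weekly") {
  T <- n_years; k <- 0L
  take <- function(m) { out <- v[k + seq_len(m)]; k <<- k + m; out }
  a_psi <- take(1); b_psi <- take(4)
  a_eps <- if (T > 1) take(T - 1) else numeric(0)
  b_eps <- take(3)
  a_gam <- if (T > 1) take(T - 1) else numeric(0)
  b_gam <- take(3)
  b_p <- take(1); sigma_p <- take(1)
  a_p <- if (detection == "weekly") matrix(take(n_weeks * T), n_weeks, T)
         else matrix(take(1), n_weeks, T)
  occu_params(T, n_weeks, a_psi, b_psi, a_eps, b_eps, a_gam, b_gam, a_p, b_p, sigma_p)
}

#' Initial-season occupancy probability
#'
#' Inverse-logit of the first-season linear predictor:
#' intercept + effects of standardized herbaceous, developed and pasture/hay
#' proportions plus the conservation-unit indicator.
#'
#' @param params an `occu_params`.
#' @param covs an `occu_covariates`.
#' @param cells integer cell indices (default: all).
#' @return occupancy probabilities in (0, 1).
#' @export
initial_occupancy_prob <- function(params, covs, cells = NULL) {
  if (is.null(cells)) cells <- seq_along(covs$herb_s)
  eta <- params$a_psi +
    params$b_psi[1] * covs$herb_s[cells] +
    params$b_psi[2] * covs$dev_s[cells] +
    params$b_psi[3] * covs$hay_s[cells] +
    params$b_psi[4] * covs$cu[cells]
  if (anyNA(eta)) stop("missing covariate for requested cell")
  stats::plogis(eta)
}

#' Count of occupied neighboring cells
#'
#' The autologistic term: the number of occupied cells among the (up to 8)
#' Moore neighbors. Edge and corner cells use their true, smaller neighbor
#' sets with no rescaling. This count enters the dynamics linear predictors
#' unstandardized.
#'
#' @param z binary occupancy matrix `cells x years`.
#' @param grid an `occu_grid`.
#' @param cell,year scalar indices; omit both for the full `cells x years`
#'   matrix (see [theta_hat()]).
#' @export
neighbor_count <- function(z, grid, cell, year) {
  sum(z[grid$adj[[cell]], year])
}

#' @rdname neighbor_count
#' @export
theta_hat <- function(z, grid) {
  z <- as.matrix(z)
  out <- matrix(0, nrow(z), ncol(z))
  for (i in seq_len(nrow(z)))
    out[i, ] <- if (length(grid$adj[[i]]))
      colSums(z[grid$adj[[i]], , drop = FALSE]) else 0
  if (is.integer(z)) storage.mode(out) <- "integer"
  out
}

#' Extirpation and colonization probabilities
#'
#' Logit-linear in the (raw) occupied-neighbor count of the origin year, the
#' standardized drought index of the destination year, and the
#' conservation-unit indicator, with a year-specific intercept.
#'
#' @param params an `occu_params`.
#' @param covs an `occu_covariates`.
#' @param theta occupied-neighbor count(s), 0-8.
#' @param cell cell index (scalar or vector recycled with `theta`).
#' @param year destination year t (2..T); the governing intercept is
#'   `a_eps[t-1]` / `a_gam[t-1]`.
#' @export
extirpation_prob <- function(params, covs, theta, cell, year) {
  stopifnot(year >= 2)
  stats::plogis(params$a_eps[year - 1] + params$b_eps[1] * theta +
                params$b_eps[2] * covs$pdsi_s[cell, year] +
                params$b_eps[3] * covs$cu[cell])
}

#' @rdname extirpation_prob
#' @export
colonization_prob <- function(params, covs, theta, cell, year) {
  stopifnot(year >= 2)
  stats::plogis(params$a_gam[year - 1] + params$b_gam[1] * theta +
                params$b_gam[2] * covs$pdsi_s[cell, year] +
                params$b_gam[3] * covs$cu[cell])
}

#' Year-to-year transition probability
#'
#' Probability the cell is occupied in year `year` given its state and
#' occupied-neighbor count in year `year - 1`: persistence `1 - eps` when
#' previously occupied, colonization `gamma` otherwise.
#'
#' @inheritParams extirpation_prob
#' @param z_prev occupancy state (0/1) at `year - 1`.
#' @param theta_prev occupied-neighbor count at `year - 1`.
#' @export
transition_prob <- function(params, covs, z_prev, theta_prev, cell, year) {
  if (year < 2) stop("no transition into the first year; use initial_occupancy_prob")
  eps <- extirpation_prob(params, covs, theta_prev, cell, year)
  gam <- colonization_prob(params, covs, theta_prev, cell, year)
  z_prev * (1 - eps) + (1 - z_prev) * gam
}

#' Weekly detection probability
#'
#' Inverse-logit of the week-by-year intercept plus the effort effect of the
#' standardized seasonal congener count.
#'
#' @param params an `occu_params`.
#' @param effort_count_std standardized seasonal congener count of the
#'   cell-year.
#' @param week,year occasion indices.
#' @export
detection_prob <- function(params, effort_count_std, week, year) {
  stats::plogis(params$a_p[week, year] + params$b_p * effort_count_std)
}

#' Complete-data log likelihood
#'
#' Sum of the initial-state Bernoulli terms, the transition terms (using the
#' occupied-neighbor counts implied by `z` at the origin year), and the
#' detection terms over non-missing observations with success probability
#' `z * p`. Returns `-Inf` when `z = 0` contradicts a detection.
#'
#' @param params an `occu_params`.
#' @param z binary matrix `cells x years`.
#' @param history an `occu_history`.
#' @param covs an `occu_covariates`.
#' @param grid an `occu_grid`.
#' @param count_std standardized effort matrix; default [effort_std()].
#' @export
log_lik_complete <- function(params, z, history, covs, grid,
                             count_std = effort_std(history)) {
  z <- as.matrix(z)
  n <- nrow(z); T <- ncol(z); J <- history$n_weeks
  psi <- initial_occupancy_prob(params, covs)
  ll <- sum(ifelse(z[, 1] == 1, log(psi), log1p(-psi)))
  if (T > 1) {
    th <- theta_hat(z, grid)
    for (t in 2:T) {
      pr <- transition_prob(params, covs, z[, t - 1], th[, t - 1], seq_len(n), t)
      ll <- ll + sum(ifelse(z[, t] == 1, log(pr), log1p(-pr)))
    }
  }
  for (i in seq_len(n)) for (t in seq_len(T)) {
    if (!history$surveyed[i, t]) next
    obs <- which(!is.na(history$y[i, t, ]))
    yv <- history$y[i, t, obs]
    if (z[i, t] == 0) {
      if (any(yv == 1)) return(-Inf)
      next  # P(y = 0 | z = 0) = 1
    }
    p <- detection_prob(params, count_std[i, t], obs, t)
    ll <- ll + sum(yv * log(p) + (1 - yv) * log1p(-p))
  }
  ll
}

#' Log prior density (including the AR(1) detection-week hierarchy)
#'
#' @param params an `occu_params`.
#' @param priors a [prior_spec()].
#' @export
log_prior <- function(params, priors = prior_spec()) {
  s <- priors$coef_sd
  lp <- sum(stats::dnorm(c(params$a_psi, params$b_psi, params$a_eps, params$b_eps,
                           params$a_gam, params$b_gam, params$b_p), 0, s, log = TRUE))
  if (params$sigma_p <= 0) return(-Inf)
  lp <- lp + log(2) + stats::dnorm(params$sigma_p, 0, priors$sigma_p_sd, log = TRUE)
  for (t in seq_len(params$n_years)) {
    lp <- lp + stats::dnorm(params$a_p[1, t], 0, s, log = TRUE)
    if (params$n_weeks > 1)
      lp <- lp + sum(stats::dnorm(params$a_p[-1, t], params$a_p[-params$n_weeks, t],
                                  params$sigma_p, log = TRUE))
  }
  lp
}

#' Complete-data log posterior (up to the normalizing constant)
#'
#' `log_lik_complete + log_prior`. A latent state contradicting a detection
#' (`z = 0` where `y = 1`) is flagged with a warning and returns `-Inf`.
#'
#' @inheritParams log_lik_complete
#' @param priors a [prior_spec()].
#' @export
log_joint <- function(params, z, history, covs, grid, priors = prior_spec(),
                      count_std = effort_std(history)) {
  ll <- log_lik_complete(params, z, history, covs, grid, count_std)
  if (identical(ll, -Inf)) {
    warning("latent state z = 0 contradicts a detection (y = 1); log_joint is -Inf")
    return(-Inf)
  }
  ll + log_prior(params, priors)
}

#' Full conditional probability of a single latent occupancy state
#'
#' Gibbs full conditional `P(z[cell, year] = 1 | everything else)`: the
#' product of the incoming initial/transition factor, the cell's own outgoing
#' transition, the transitions of neighboring cells into the next year (whose
#' occupied-neighbor counts depend on this cell), and the detection
#' likelihood of the cell-year. Equals 1 exactly when the cell-year has a
#' detection.
#'
#' @param cell,year indices of the targeted latent state.
#' @param z current binary matrix `cells x years` (the targeted entry is
#'   ignored).
#' @param params,history,covs,grid,count_std model objects as in
#'   [log_lik_complete()].
#' @return probability in `[0, 1]`.
#' @export
full_conditional_z <- function(cell, year, z, params, history, covs, grid,
                               count_std = effort_std(history)) {
  z <- as.matrix(z)
  T <- ncol(z)
  yv <- history$y[cell, year, ]
  if (any(yv == 1, na.rm = TRUE)) return(1)
  lo <- 0
  if (year == 1) {
    psi <- initial_occupancy_prob(params, covs, cell)
    lo <- lo + log(psi) - log1p(-psi)
  } else {
    th <- neighbor_count(z, grid, cell, year - 1)
    zp <- z[cell, year - 1]
    p1 <- transition_prob(params, covs, zp, th, cell, year)
    lo <- lo + log(p1) - log1p(-p1)
  }
  if (year < T) {
    th <- neighbor_count(z, grid, cell, year)
    zn <- z[cell, year + 1]
    pr1 <- transition_prob(params, covs, 1, th, cell, year + 1)
    pr0 <- transition_prob(params, covs, 0, th, cell, year + 1)
    f <- function(pr, zz) if (zz == 1) log(pr) else log1p(-pr)
    lo <- lo + f(pr1, zn) - f(pr0, zn)
    for (nb in grid$adj[[cell]]) {
      th_ex <- sum(z[setdiff(grid$adj[[nb]], cell), year])
      zn_nb <- z[nb, year + 1]
      pa <- transition_prob(params, covs, z[nb, year], th_ex + 1, nb, year + 1)
      pb <- transition_prob(params, covs, z[nb, year], th_ex, nb, year + 1)
      lo <- lo + f(pa, zn_nb) - f(pb, zn_nb)
    }
  }
  if (history$surveyed[cell, year]) {
    obs <- which(!is.na(yv))
    p <- detection_prob(params, count_std[cell, year], obs, year)
    lo <- lo + sum(yv[obs] * log(p) + (1 - yv[obs]) * log1p(-p))  # minus 0 for z = 0
  }
  stats::plogis(lo)
}
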