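#' @export
print.autoccu <- function(x, ...) {
  cat("Autologistic dynamic occupancy model (Bayesian fit)\n")
  cat(sprintf("  data: %d cells x %d seasons x %d weeks; %d surveyed cell-years\n",
              x$grid$n, length(x$history$years), x$history$n_weeks,
              sum(x$history$surveyed)))
  cat(sprintf("  dynamics: %s; detection: %s\n", x$dynamics, x$detection))
  cat(sprintf("  chains: %d; retained draws: %d\n",
              x$config$n_chains, nrow(x$draws$params)))
  if (!is.na(x$converged)) {
    cat(sprintf("  max Gelman-Rubin (coefficients): %.3f %s\n",
                max(x$rhat[x$monitored], na.rm = TRUE),
                if (x$converged) "(converged)" else "** NOT CONVERGED **"))
  }
  invisible(x)
}

#' Posterior summary of an autologistic occupancy fit
#'
#' Coefficient table (posterior mean, sd, equal-tailed 95% interval,
#' Gelman-Rubin statistic, and the posterior probability that the effect is
#' positive) plus per-season occupancy summaries: finite-sample occupancy
#' over surveyed cells, unconditional occupancy over all cells, and the
#' estimated number of occupied cells.
#'
#' @param object an `autoccu` fit.
#' @param ... unused.
#' @export
summary.autoccu <- function(object, ...) {
  pm <- object$draws$params[, object$monitored, drop = FALSE]
  coefs <- data.frame(
    mean = colMeans(pm),
    sd = apply(pm, 2, stats::sd),
    q2.5 = apply(pm, 2, stats::quantile, 0.025),
    q97.5 = apply(pm, 2, stats::quantile, 0.975),
    rhat = object$rhat[object$monitored],
    p_gt0 = colMeans(pm > 0)
  )
  psifs <- summarize_draws(finite_sample_occupancy(object))
  psi <- summarize_draws(unconditional_occupancy(object))
  nocc <- summarize_draws(occupied_cell_count(object))
  out <- list(coefficients = coefs, psi_fs = psifs, psi = psi,
              n_occupied = nocc, years = object$history$years,
              converged = object$converged)
  class(out) <- "summary.autoccu"
  out
}

#' @export
print.summary.autoccu <- function(x, digits = 3, ...) {
  cat("Coefficients (posterior):\n")
  print(round(x$coefficients, digits))
  cat("\nFinite-sample occupancy (surveyed cells):\n")
  print(round(cbind(year = as.integer(as.character(x$years)), x$psi_fs), digits))
  cat("\nUnconditional occupancy (all cells):\n")
  print(round(cbind(year = as.integer(as.character(x$years)), x$psi), digits))
  cat("\nEstimated occupied cells:\n")
  print(round(cbind(year = as.integer(as.character(x$years)), x$n_occupied), 1))
  invisible(x)
}

#' @export
coef.autoccu <- function(object, ...) {
  colMeans(object$draws$params[, object$monitored, drop = FALSE])
}

#' Posterior predictions from an occupancy fit
#'
#' @param object an `autoccu` fit.
#' @param type `"occupancy"` for per cell-year posterior occupancy
#'   probabilities (posterior mean of the latent state), `"psi_fs"` /
#'   `"psi"` for per-year summaries, or `"response"` for dynamic-rate
#'   response curves (forwarded to [response_curve()]).
#' @param ... passed to [response_curve()] for `type = "response"`.
#' @export
predict.autoccu <- function(object, type = c("occupancy", "psi_fs", "psi", "response"),
                            ...) {
  type <- match.arg(type)
  switch(type,
    occupancy = matrix(colMeans(object$draws$z), object$grid$n,
                       length(object$history$years),
                       dimnames = list(object$history$cell_ids,
                                       as.character(object$history$years))),
    psi_fs = summarize_draws(finite_sample_occupancy(object)),
    psi = summarize_draws(unconditional_occupancy(object)),
    response = response_curve(object, ...)
  )
}

#' Plot an occupancy fit
#'
#' @param x an `autoccu` fit.
#' @param type `"occupancy"` (annual occupancy with 66%/95% intervals),
#'   `"response"` (dynamic-rate response curves against the occupied-neighbor
#'   count), or `"trace"` (trace plots of selected coefficients).
#' @param pars coefficient names for `type = "trace"`.
#' @param ... further graphical arguments, unused.
#' @export
plot.autoccu <- function(x, type = c("occupancy", "response", "trace"),
                         pars = c("beta_gam_theta", "beta_eps_theta"), ...) {
  type <- match.arg(type)
  yrs <- as.integer(as.character(x$history$years))
  if (type == "occupancy") {
    s <- summarize_draws(finite_sample_occupancy(x))
    graphics::plot(yrs, s$mean, ylim = c(0, 1), pch = 16, xlab = "season",
                   ylab = "finite-sample occupancy")
    graphics::segments(yrs, s$q2.5, yrs, s$q97.5)
    graphics::segments(yrs, s$q17, yrs, s$q83, lwd = 3)
  } else if (type == "response") {
    ce <- response_curve(x, "extirpation", "theta")
    cg <- response_curve(x, "colonization", "theta")
    graphics::plot(ce$theta, ce$mean, type = "l", ylim = c(0, 1), col = 2,
                   xlab = "occupied neighbors", ylab = "probability")
    graphics::lines(cg$theta, cg$mean, col = 4)
    graphics::legend("topright", c("extirpation", "colonization"),
                     col = c(2, 4), lty = 1, bty = "n")
  } else {
    old <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 1, 1))
    on.exit(graphics::par(old))
    for (pn in pars) {
      graphics::plot(x$draws$params[, pn], type = "l", ylab = pn, xlab = "")
    }
  }
  invisible(x)
}

#' Posterior predictive detection histories
#'
#' Simulates replicate weekly detection data at the surveyed occasions:
#' for each replicate a posterior draw is selected and `y* ~
#' Bernoulli(z * p)` is drawn at every non-missing (cell, year, week).
#'
#' @param object an `autoccu` fit.
#' @param nsim number of replicate data sets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of arrays shaped like `object$history$y`.
#' @export
simulate.autoccu <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- obs_index(object)
  n <- object$grid$n
  cs <- object$count_std[idx[, c("cell", "year")]]
  nd <- nrow(object$draws$params)
  draws <- sample.int(nd, nsim, replace = nsim > nd)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    d <- draws[s]
    p <- params_from_draw(object, d)
    zv <- object$draws$z[d, idx[, "cell"] + n * (idx[, "year"] - 1L)]
    pv <- stats::plogis(p$a_p[cbind(idx[, "week"], idx[, "year"])] + p$b_p * cs)
    ystar <- object$history$y
    ystar[idx] <- stats::rbinom(nrow(idx), 1L, zv * pv)
    out[[s]] <- ystar
  }
  out
}

#' Residuals for an occupancy fit
#'
#' Pearson residuals of the weekly observations against their posterior
#' mean fitted detection probability `E[z * p | data]`.
#'
#' @param object an `autoccu` fit.
#' @param ... unused.
#' @return data frame with cell, year, week, `y`, `fitted`, `pearson`.
#' @export
residuals.autoccu <- function(object, ...) {
  idx <- obs_index(object)
  n <- object$grid$n
  cs <- object$count_std[idx[, c("cell", "year")]]
  nd <- nrow(object$draws$params)
  fitted <- numeric(nrow(idx))
  for (d in seq_len(nd)) {
    p <- params_from_draw(object, d)
    zv <- object$draws$z[d, idx[, "cell"] + n * (idx[, "year"] - 1L)]
    pv <- stats::plogis(p$a_p[cbind(idx[, "week"], idx[, "year"])] + p$b_p * cs)
    fitted <- fitted + zv * pv / nd
  }
  yv <- object$history$y[idx]
  data.frame(cell = idx[, "cell"], year = object$history$years[idx[, "year"]],
             week = idx[, "week"], y = yv, fitted = fitted,
             pearson = (yv - fitted) / sqrt(pmax(fitted * (1 - fitted), 1e-12)))
}
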