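# a small fully-specified model instance used across the model-core tests
model_fixture <- function(seed = 5, n_cells = 4, T = 2, J = 2) {
  set.seed(seed)
  make_oracle_instance(n_cells, T, J, seed = seed)
}

test_that("initial occupancy is the inverse-logit of the linear predictor", {
  m <- model_fixture()
  p0 <- occu_params(2, 2)  # all coefficients zero
  expect_equal(initial_occupancy_prob(p0, m$covs), rep(0.5, 4))
  p1 <- occu_params(2, 2, a_psi = 1)
  expect_equal(initial_occupancy_prob(p1, m$covs), rep(plogis(1), 4))
  expect_equal(plogis(1), 0.7310586, tolerance = 1e-7)
  # strictly increasing in hay when its effect is positive
  ph <- occu_params(2, 2, b_psi = c(0, 0, 1.3, 0))
  o <- order(m$covs$hay_s)
  expect_true(all(diff(initial_occupancy_prob(ph, m$covs)[o]) > 0))
})

test_that("neighbor counts respect the Moore neighborhood and its boundary truncation", {
  g <- lattice_grid(3, 3)
  z <- matrix(1L, 9, 1)
  expect_identical(neighbor_count(z, g, cell = 5, year = 1), 8L)  # interior
  expect_identical(neighbor_count(z, g, cell = 1, year = 1), 3L)  # corner
  expect_identical(neighbor_count(z, g, cell = 2, year = 1), 5L)  # edge
  z0 <- matrix(0L, 9, 1)
  expect_identical(neighbor_count(z0, g, cell = 5, year = 1), 0L)
  th <- theta_hat(z, g)
  expect_identical(as.vector(th), c(3L, 5L, 3L, 5L, 8L, 5L, 3L, 5L, 3L))
})

test_that("transition probability switches between persistence and colonization", {
  m <- model_fixture()
  p <- m$params
  # eps = 0 => certain persistence; gam = 0 => absorbing emptiness
  pe <- occu_params(2, 2, a_eps = -50, a_gam = -50)
  expect_equal(transition_prob(pe, m$covs, 1, 0, 1, 2), 1, tolerance = 1e-10)
  expect_equal(transition_prob(pe, m$covs, 0, 0, 1, 2), 0, tolerance = 1e-10)
  p0 <- occu_params(2, 2)
  expect_equal(transition_prob(p0, m$covs, 1, 0, 1, 2), 0.5)
  expect_error(transition_prob(p0, m$covs, 1, 0, 1, 1), "first year")
  # one step of the marginal recursion: psi1 = 0.5, eps = 0.2, gam = 0.1
  pr <- occu_params(2, 2, a_eps = qlogis(0.2), a_gam = qlogis(0.1))
  marg2 <- 0.5 * transition_prob(pr, m$covs, 1, 0, 1, 2) +
    0.5 * transition_prob(pr, m$covs, 0, 0, 1, 2)
  expect_equal(marg2, 0.45, tolerance = 1e-12)
})

test_that("dynamic rates are monotone in the neighbor count as the effect signs dictate", {
  m <- model_fixture()
  p <- occu_params(2, 2, b_eps = c(-0.5, 0, 0), b_gam = c(0.7, 0, 0))
  eps <- extirpation_prob(p, m$covs, 0:8, 1, 2)
  gam <- colonization_prob(p, m$covs, 0:8, 1, 2)
  expect_true(all(diff(eps) < 0))
  expect_true(all(diff(gam) > 0))
})

test_that("detection probability follows the week intercept and effort effect", {
  p <- occu_params(1, 2, a_p = matrix(-2.2, 2, 1), b_p = 0)
  expect_equal(detection_prob(p, 0.7, 1, 1), 0.09975049, tolerance = 1e-7)
  p2 <- occu_params(1, 2, a_p = matrix(0, 2, 1), b_p = 0.5)
  expect_equal(detection_prob(p2, 0, 1, 1), 0.5)
  expect_lt(detection_prob(p2, -1, 1, 1), detection_prob(p2, 1, 1, 1))
})

test_that("log_joint decomposes into its Bernoulli factors on minimal instances", {
  # single cell, single year, one surveyed week with a detection
  g <- lattice_grid(1, 2)
  y <- array(NA_integer_, c(2, 1, 1)); y[1, 1, 1] <- 1L
  h <- occu_history(y, matrix(c(3L, 0L), 2, 1), 1, g$cell_ids)
  covs <- occu_covariates(c(0.5, -0.5), c(0.5, -0.5), c(0.5, -0.5), g$cu,
                          matrix(0, 2, 1), 1)
  pars <- occu_params(1, 1, a_psi = 0.3, b_psi = c(0.1, 0.2, -0.1, 0.4),
                      a_p = matrix(-0.8, 1, 1), b_p = 0.2)
  z <- matrix(c(1L, 0L), 2, 1)
  cs <- effort_std(h)
  psi <- initial_occupancy_prob(pars, covs)
  pdet <- detection_prob(pars, cs[1, 1], 1, 1)
  expect_equal(log_lik_complete(pars, z, h, covs, g, cs),
               log(psi[1]) + log(1 - psi[2]) + log(pdet), tolerance = 1e-12)
  expect_equal(log_joint(pars, z, h, covs, g),
               log_lik_complete(pars, z, h, covs, g) + log_prior(pars),
               tolerance = 1e-12)
  # all observations missing: the detection term contributes exactly zero
  h0 <- occu_history(array(NA_integer_, c(2, 1, 1)), matrix(0L, 2, 1), 1, g$cell_ids)
  expect_equal(log_lik_complete(pars, z, h0, covs, g, cs),
               log(psi[1]) + log(1 - psi[2]), tolerance = 1e-12)
  # z = 0 contradicting y = 1 is flagged and -Inf
  zc <- matrix(c(0L, 0L), 2, 1)
  expect_warning(lj <- log_joint(pars, zc, h, covs, g), "contradicts")
  expect_identical(lj, -Inf)
})

test_that("exp(log_lik_complete) matches the independent enumeration oracle", {
  # likelihood route: sum exp(log_lik) over admissible configurations equals
  # the oracle's marginal likelihood; per-configuration factors agree to 1e-12
  for (seed in c(11, 12)) {
    m <- make_oracle_instance(2, 2, 2, seed = seed)
    M <- 4
    configs <- as.matrix(expand.grid(rep(list(0:1), M)))
    tot <- 0
    for (k in seq_len(nrow(configs))) {
      z <- matrix(configs[k, ], 2, 2)
      tot <- tot + exp(log_lik_complete(m$params, z, m$history, m$covs, m$grid,
                                        m$count_std))
    }
    expect_equal(log(tot), m$exact$logml, tolerance = 1e-10)
  }
})

test_that("log_joint is invariant under lattice automorphisms with exchangeable covariates", {
  g <- lattice_grid(3, 3, cu_cols = 1:3)  # homogeneous cu
  # constant covariates make cells exchangeable
  covs <- occu_covariates(rep(0, 9), rep(0, 9), rep(0, 9), g$cu,
                          matrix(0.3, 9, 2), 1:2)
  y <- array(NA_integer_, c(9, 2, 2))
  h <- occu_history(y, matrix(0L, 9, 2), 1:2, g$cell_ids)
  pars <- occu_params(2, 2, a_psi = -0.4, b_eps = c(-0.3, 0.2, 0),
                      b_gam = c(0.5, -0.1, 0), a_eps = 0.2, a_gam = -1)
  # rotate the lattice by 90 degrees: (r, c) -> (c, 4 - r)
  rot <- integer(9)
  for (i in 1:9) {
    r <- g$row[i]; c <- g$col[i]
    rot[i] <- (c - 1) * 3 + (4 - r)
  }
  set.seed(9)
  for (rep in 1:5) {
    z <- matrix(rbinom(18, 1, 0.5), 9, 2)
    zr <- z; zr[rot, ] <- z
    expect_equal(log_joint(pars, zr, h, covs, g), log_joint(pars, z, h, covs, g),
                 tolerance = 1e-10)
  }
})

test_that("flipping a detected cell-year's latent state sends the joint density to -Inf", {
  m <- model_fixture(seed = 21)
  det_any <- apply(m$history$y == 1, c(1, 2), any)
  det_any[is.na(det_any)] <- FALSE
  det <- which(det_any, arr.ind = TRUE)
  stopifnot(nrow(det) > 0)  # seed chosen so the instance has a detection
  z <- m$z_true  # admissible: the generator only emits detections where z = 1
  lj <- log_lik_complete(m$params, z, m$history, m$covs, m$grid, m$count_std)
  expect_true(is.finite(lj))
  z2 <- z; z2[det[1, 1], det[1, 2]] <- 0L
  expect_identical(log_lik_complete(m$params, z2, m$history, m$covs, m$grid,
                                    m$count_std), -Inf)
})

test_that("parameter vectors round-trip through flatten/unflatten", {
  p <- default_true_params(4, 6)
  v <- autoccu:::flatten_params(p, "weekly")
  p2 <- autoccu:::unflatten_params(unname(v), 4, 6, "weekly")
  expect_equal(p2[names(p2) != "n_weeks"], p[names(p) != "n_weeks"], tolerance = 1e-15)
})
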