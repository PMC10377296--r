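test_that("weighted prior is the Poisson mass times its coefficient of variation", {
  p <- growth_params(10, 4, 0.2, lambda_star = 2)
  # remaining malignant 2, rate 2: mean 4, c.v. = 1/2
  for (k in 0:6) {
    expect_equal(weighted_prior(k, p, M_star_prev = 2), dpois(k, 4) * 0.5)
  }
  # the weights sum to the c.v. itself (a constant times a pmf)
  total <- sum(vapply(0:200, weighted_prior, numeric(1), params = p,
                      M_star_prev = 2))
  expect_equal(total, 0.5, tolerance = 1e-10)
  expect_lt(total, 1)
  # c.v. strictly decreasing as the remaining count grows
  cv <- function(rem) {
    pp <- growth_params(100, rem, 0.2, lambda_star = 2)
    weighted_prior(0, pp) / dpois(0, rem * 2)
  }
  expect_true(all(diff(vapply(c(2, 5, 10, 20), cv, numeric(1))) < 0))
  # validity bound: prior mean must exceed 1
  expect_error(weighted_prior(1, growth_params(10, 4, 0.2, 0.2),
                              M_star_prev = 0), "exceed 1")
})

test_that("posterior weights normalize and bracket the mean", {
  truth <- growth_params(400, 160, 0.08, 2)
  for (s in 1:8) {
    traj <- simulate_trajectory(truth, n_steps = 7, seed = 100 + s)
    fit <- growth_fit(traj)
    post <- growth_posterior(fit)
    expect_equal(sum(post$step_weights), 1, tolerance = 1e-10)
    expect_gte(post$posterior_mean, min(traj$steps$m_star))
    expect_lte(post$posterior_mean, max(traj$steps$m_star))
  }
})

test_that("likelihood factor cancels: both posterior routes agree", {
  traj <- make_trajectory(seed = 8, n_steps = 5,
                          params = growth_params(400, 160, 0.08, 2))
  fit <- growth_fit(traj)
  cancelled <- growth_posterior(fit)
  literal <- growth_posterior(fit, include_likelihood = TRUE)
  expect_equal(cancelled$step_weights, literal$step_weights,
               tolerance = 1e-10)
  expect_equal(cancelled$posterior_mean, literal$posterior_mean,
               tolerance = 1e-10)
})

test_that("single-step posterior is degenerate at its observation", {
  traj <- cell_trajectory(m = 6, m_star = 4)
  params <- growth_params(20, 10, 0.3, lambda_star = 1.5)
  post <- growth_posterior(traj, params = params)
  expect_equal(post$step_weights, 1)
  expect_equal(post$posterior_mean, 4)
})

test_that("posterior is invariant to step metadata that carries no information", {
  # voxel increments and any time labels attached to steps play no role
  traj1 <- cell_trajectory(m = c(5, 3, 4), m_star = c(2, 1, 3),
                           delta_voxels = c(10, 20, 30))
  traj2 <- cell_trajectory(m = c(5, 3, 4), m_star = c(2, 1, 3),
                           delta_voxels = c(999, 1, 500))
  f1 <- growth_fit(traj1)
  f2 <- growth_fit(traj2)
  expect_equal(coef(f1), coef(f2))
  expect_equal(growth_posterior(f1)$step_weights,
               growth_posterior(f2)$step_weights)
})

test_that("eventual volume scales linearly and rounds in discrete mode", {
  expect_equal(eventual_volume(1, 100), 100)
  expect_equal(eventual_volume(0, 5000), 0)
  expect_equal(eventual_volume(2.5, 200), 2 * eventual_volume(2.5, 100))
  expect_equal(eventual_volume(1.23456, 1000, discrete = TRUE), 1235)
  expect_equal(eventual_volume(1.23456, 1000, c = 2), 2469.12)
  expect_error(eventual_volume(-1, 100), "negative")
  expect_error(eventual_volume(1, -100), "negative")
})

test_that("completeness probability follows the squared geometric form", {
  expect_equal(prob_no_undetected(0), 0)
  expect_equal(prob_no_undetected(3), 0.5625)
  expect_equal(prob_no_undetected(5), (5 / 6)^2)
  expect_equal(prob_no_undetected(5, r = 3), (5 / 6)^3)
  expect_gt(prob_no_undetected(10), prob_no_undetected(3))
  # vectorized and strictly increasing over a long range of counts
  k <- 0:1000
  p <- prob_no_undetected(k)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
  expect_error(prob_no_undetected(-1), "nonnegative")
  expect_error(prob_no_undetected(3, r = 0), "at least 1")
})
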