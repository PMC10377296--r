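test_that("the MLE attains at least the likelihood of the truth", {
  truth <- growth_params(300, 120, 0.06, 2)
  for (s in 1:10) {
    traj <- simulate_trajectory(truth, n_steps = 8, seed = s)
    fit <- growth_fit(traj)
    expect_gte(fit$logLik, growth_loglik(traj, truth) - 1e-6)
  }
})

test_that("fixed-rate fits match a dense grid-search oracle", {
  for (s in c(7, 13, 29)) {
    traj <- simulate_trajectory(growth_params(120, 50, 0.1, 2),
                                n_steps = 4, seed = s)
    fit <- growth_fit(traj, lambda_fixed = 0.1)
    oracle <- grid_mle_two_par(traj, lambda = 0.1, by = 1)
    # the continuous optimum may only beat the grid, never trail it beyond
    # grid resolution
    expect_gte(fit$logLik, oracle["ll"] - 1e-8)
    expect_lt(abs(coef(fit)["nu"] - oracle["nu"]), 2)
    expect_lt(abs(coef(fit)["nu_star"] - oracle["nu_star"]), 2)
  }
})

test_that("convergence report carries the optimizer diagnostics", {
  traj <- make_trajectory(seed = 2)
  fit <- growth_fit(traj)
  conv <- fit$convergence
  expect_true(is.numeric(conv$gradient_norm))
  expect_true(conv$iterations >= 1)
  expect_type(conv$step_halving, "logical")
  expect_type(conv$converged, "logical")
  expect_true(coef(fit)["nu_star"] <= coef(fit)["nu"])
  # feasibility of the estimate with respect to the cumulative counts
  expect_gte(coef(fit)["nu"], traj$M[traj$n_steps])
  expect_gte(coef(fit)["nu_star"], traj$M_star[traj$n_steps])
})

test_that("lambda_star Newton solution matches the closed-form root", {
  traj <- make_trajectory(seed = 5, n_steps = 6)
  nu_star <- 2 * traj$M_star[traj$n_steps]
  res <- fit_lambda_star(traj, nu_star)
  S <- sum(traj$steps$m_star)
  C <- sum(nu_star - c(0, traj$M_star[-traj$n_steps]))
  closed <- S / C
  if (closed > 1) {
    expect_equal(res$lambda_star, closed, tolerance = 1e-6)
    expect_false(res$boundary)
  } else {
    expect_equal(res$lambda_star, 1 + 1e-6)
    expect_true(res$boundary)
  }
})

test_that("on feasible detection data the rate sits at its boundary", {
  # sum(m*_t) = M*_T <= nu* bounds every remaining-count term from below,
  # so the unconstrained optimum never exceeds 1: the clip must trigger
  for (s in 1:5) {
    traj <- simulate_trajectory(growth_params(400, 180, 0.08, 2),
                                n_steps = 8, seed = s)
    fit <- growth_fit(traj)
    expect_true(fit$convergence$lambda_star_boundary)
    expect_equal(coef(fit)["lambda_star"], c(lambda_star = 1 + 1e-6))
  }
})

test_that("rate above one is recovered against an exogenous remaining schedule", {
  # malignant counts drawn from the weighted-prior law at lambda* = 2
  errs <- vapply(1:40, function(s) {
    set.seed(9000 + s)
    base <- simulate_trajectory(growth_params(800, 300, 0.06, 2),
                                n_steps = 8, seed = s)
    cc <- 300 - c(0, base$M_star[-base$n_steps])
    y <- rpois(8, cc * 2)
    traj <- cell_trajectory(m = y, m_star = y)
    fit <- fit_lambda_star(traj, nu_star = 300, remaining = cc)
    abs(fit$lambda_star - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.25)

  # scale equivariance: doubling every count doubles the estimate
  set.seed(77)
  cc <- c(300, 260, 210, 180)
  y <- rpois(4, cc * 1.5)
  f1 <- fit_lambda_star(cell_trajectory(y, y), 300, remaining = cc)
  f2 <- fit_lambda_star(cell_trajectory(2 * y, 2 * y), 300, remaining = cc)
  expect_equal(f2$lambda_star / f1$lambda_star, 2, tolerance = 1e-6)
})

test_that("all-zero malignant counts give a flagged boundary rate", {
  traj <- cell_trajectory(m = c(3, 4, 2), m_star = c(0, 0, 0))
  res <- fit_lambda_star(traj, nu_star = 10)
  expect_true(res$boundary)
  expect_equal(res$lambda_star, 1 + 1e-6)
})

test_that("model methods behave as a classed fit should", {
  traj <- make_trajectory(seed = 3)
  traj$v_initial <- 1000
  fit <- growth_fit(traj)
  expect_s3_class(fit, "growth_fit")
  expect_named(coef(fit), c("nu", "nu_star", "lambda", "lambda_star"))
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_output(print(fit), "Growth model fit")
  expect_output(print(summary(fit)), "Posterior")
  expect_length(residuals(fit), traj$n_steps)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "cell_trajectory")
  pred <- predict(fit)
  expect_true(pred$v_new >= 0)
  expect_length(pred$p_no_undetected, traj$n_steps)
})
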