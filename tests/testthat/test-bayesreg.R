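test_that("spike-and-slab posterior concentrates near a strong linear truth", {
  for (s in 1:3) {
    set.seed(s)
    x <- rnorm(200)
    y <- 2 + 3 * x + rnorm(200, sd = 0.5)
    fit <- fit_bayes_regression(y, cbind(x = x), n_draws = 1500,
                                burn_in = 300, seed = s)
    sm <- summary(fit)
    expect_lt(abs(sm["alpha", "mean"] - 2), 0.2)
    expect_lt(abs(sm["x", "mean"] - 3), 0.2)
    expect_true(sm["x", "lower"] <= 3 && 3 <= sm["x", "upper"])
  }
})

test_that("null covariates are excluded more often than included", {
  set.seed(9)
  X <- matrix(rnorm(600), 200)
  y <- rnorm(200)
  fit <- fit_bayes_regression(y, X, n_draws = 1500, burn_in = 300, seed = 2)
  expect_lt(mean(fit$inclusion), 0.5)
})

test_that("forcing the indicators on reduces the sampler to the slab", {
  set.seed(14)
  x <- rnorm(150)
  y <- 1 + 2 * x + rnorm(150, sd = 0.7)
  fit <- fit_bayes_regression(y, cbind(x = x), n_draws = 2000, burn_in = 500,
                              seed = 3, force_include = TRUE)
  expect_equal(unname(fit$inclusion), 1)
  # with a diffuse slab the posterior mean tracks least squares
  ols <- coef(lm(y ~ x))
  expect_lt(abs(coef(fit)["alpha"] - ols[1]), 0.1)
  expect_lt(abs(coef(fit)["x"] - ols[2]), 0.1)
})

test_that("literal Bernoulli mode matches the exhaustive vertex posterior", {
  set.seed(4)
  n <- 60; p <- 3
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("x", 1:p)
  y <- 1 + X %*% c(1, 0, 1) + rnorm(n, sd = 0.4)
  fit <- suppressWarnings(
    fit_bayes_regression(y, X, prior_mode = "literal", n_draws = 20000,
                         burn_in = 2000, seed = 1))
  oracle <- enum_literal_posterior(y, X)
  keys <- apply(oracle$verts, 1, paste, collapse = "")
  emp <- table(factor(apply(fit$draws[, 1:(p + 1)], 1, paste, collapse = ""),
                      levels = keys))
  emp <- as.numeric(emp) / sum(emp)
  expect_lt(0.5 * sum(abs(emp - oracle$prob)), 0.1)
  expect_equal(which.max(emp), which.max(oracle$prob))
  # the true vertex carries the mass
  expect_equal(unname(oracle$verts[which.max(emp), ]), c(1, 1, 0, 1))
  expect_true(is.finite(fit$diagnostics$acceptance_rate))
})

test_that("samplers are reproducible from their seed", {
  set.seed(5)
  x <- rnorm(80); y <- 1 + x + rnorm(80)
  f1 <- fit_bayes_regression(y, cbind(x = x), n_draws = 500, burn_in = 100,
                             seed = 11)
  f2 <- fit_bayes_regression(y, cbind(x = x), n_draws = 500, burn_in = 100,
                             seed = 11)
  expect_identical(f1$draws, f2$draws)
})

test_that("predictions come from the posterior and respect row structure", {
  set.seed(6)
  x <- rnorm(100); y <- 2 + 0 * x + rnorm(100, sd = 0.3)
  # a zero-information covariate: predictions equal the intercept mean
  fit <- fit_bayes_regression(y, cbind(z = rep(0, 100)), n_draws = 800,
                              burn_in = 200, seed = 7)
  expect_equal(unname(predict(fit)[1]), mean(fit$draws[, "alpha"]),
               tolerance = 1e-8)
  # duplicating a row at fixed posterior duplicates its prediction
  fit2 <- fit_bayes_regression(y, cbind(x = x), n_draws = 500,
                               burn_in = 100, seed = 8)
  pr <- predict(fit2, newdata = cbind(x = c(x[1], x[1], x[2])))
  expect_equal(pr[1], pr[2])
})

test_that("recomputed completeness probabilities use the implied counts", {
  set.seed(7)
  x <- rnorm(50)
  y <- 5000 + 1000 * x + rnorm(50, sd = 100)
  fit <- fit_bayes_regression(y, cbind(x = x), n_draws = 500, burn_in = 100,
                              seed = 9)
  v0 <- rep(1000, 50); v0[3] <- NA
  expect_message(out <- predict_with_covariates(fit, v_initial = v0),
                 "skipped")
  expect_true(is.na(out$p_no_undetected[3]))
  ok <- !is.na(out$p_no_undetected)
  expect_equal(out$p_no_undetected[ok],
               prob_no_undetected(round(out$v_pred[ok] / 1000)))
})

test_that("GLM baseline reports the closed-form summaries", {
  x <- 1:20
  y <- 3 + 2 * x
  fit <- fit_glm_baseline(y, cbind(x = x))
  expect_equal(fit$r_squared, 1)
  set.seed(8)
  X <- matrix(rnorm(2000), 500)
  y2 <- rnorm(500)
  expect_lt(fit_glm_baseline(y2, X)$r_squared, 0.05)
  # AIC formula oracle
  set.seed(9)
  x3 <- rnorm(40); y3 <- 1 + x3 + rnorm(40)
  f3 <- fit_glm_baseline(y3, cbind(x = x3))
  rss <- sum((y3 - f3$fitted)^2)
  expect_equal(f3$aic, 40 * log(rss / 40) + 2 * 2)
  # collinear design flagged
  f4 <- fit_glm_baseline(y3, cbind(a = x3, b = 2 * x3))
  expect_true(f4$aliased)
})

test_that("comparison harness is symmetric and label-driven", {
  tab <- generate_feature_table(n = 60, seed = 5)
  endo <- grep("^(volume|spatial|histology|morphology)_", names(tab),
               value = TRUE)
  covs <- c(endo, "survival_years", "age")
  same <- model_comparison(tab, c(WT = "y_WT"), covs,
                           models = c("glm", "glm"), folds = 4, seed = 2)
  expect_equal(same$r2_glm, same[[3]])
  expect_equal(same$cv_glm, same[[7]])
  ab <- model_comparison(tab, c(WT = "y_WT"), covs,
                         models = c("glm", "bayes"), folds = 4,
                         n_abc_sims = 500, n_draws = 300, burn_in = 100,
                         seed = 2)
  ba <- model_comparison(tab, c(WT = "y_WT"), covs,
                         models = c("bayes", "glm"), folds = 4,
                         n_abc_sims = 500, n_draws = 300, burn_in = 100,
                         seed = 2)
  expect_equal(ab$cv_glm, ba$cv_glm)
  expect_equal(ab$cv_bayes, ba$cv_bayes)
  expect_true(all(c(ab$cv_glm, ab$cv_bayes) >= 0))
  expect_error(model_comparison(tab[1:8, ], c(WT = "y_WT"), covs,
                                folds = 5), "fewer than 3")
})
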