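test_that("canonical correlations hit the self-correlation and null limits", {
  set.seed(1)
  x <- rnorm(100)
  cc <- canonical_correlations(cbind(x), cbind(x))
  expect_equal(cc$cor[1], 1, tolerance = 1e-8)
  # independent Gaussian blocks: leading correlation small at n = 500
  X <- matrix(rnorm(1500), 500); Y <- matrix(rnorm(1500), 500)
  expect_lt(canonical_correlations(X, Y)$cor[1], 0.2)
  expect_error(canonical_correlations(X, Y[1:10, ]), "same rows")
  expect_error(canonical_correlations(cbind(rep(1, 50)),
                                      cbind(rnorm(50))), "constant column")
})

test_that("two-column canonical correlation matches a direction grid search", {
  set.seed(3)
  Z <- matrix(rnorm(400), 200)
  X <- Z %*% matrix(c(1, .5, .3, 1), 2) + 0.6 * matrix(rnorm(400), 200)
  Y <- Z %*% matrix(c(.7, -.2, .4, .9), 2) + 0.6 * matrix(rnorm(400), 200)
  rho <- canonical_correlations(X, Y)$cor[1]
  angles <- seq(0, pi, length.out = 400)
  best <- 0
  for (a in angles) for (b in angles) {
    r <- abs(as.numeric(cor(X %*% c(cos(a), sin(a)), Y %*% c(cos(b), sin(b)))))
    if (r > best) best <- r
  }
  expect_equal(rho, best, tolerance = 1e-3)
})

test_that("Wilks' Lambda equals the determinant-ratio oracle and manova", {
  set.seed(5)
  X <- matrix(rnorm(240), 80); Y <- matrix(rnorm(240), 80)
  w <- wilks_lambda_test(X, Y)
  expect_equal(w$lambda, det_ratio_lambda(X, Y), tolerance = 1e-10)
  mv <- summary(manova(X ~ Y), test = "Wilks")$stats
  expect_equal(w$lambda, unname(mv[1, "Wilks"]), tolerance = 1e-10)
  expect_equal(w$F, unname(mv[1, "approx F"]), tolerance = 1e-8)
  expect_equal(w$p_value, unname(mv[1, "Pr(>F)"]), tolerance = 1e-8)
  expect_true(w$lambda >= 0 && w$lambda <= 1)
})

test_that("a perfectly correlated pair drives Lambda to zero", {
  set.seed(6)
  x <- rnorm(60)
  w <- wilks_lambda_test(cbind(x), cbind(2 * x))
  expect_lt(w$lambda, 1e-10)
  expect_lt(w$p_value, 1e-10)
})

test_that("Lambda is invariant to within-block linear reparameterization", {
  set.seed(7)
  X <- matrix(rnorm(300), 100); Y <- matrix(rnorm(300), 100)
  A <- matrix(c(2, 1, 0, 0, 1, 3, 1, 0, 2), 3)
  B <- matrix(c(1, 0, 2, 1, 1, 0, 0, 2, 1), 3)
  w1 <- wilks_lambda_test(X, Y)
  w2 <- wilks_lambda_test(X %*% A, Y %*% B)
  expect_equal(w1$lambda, w2$lambda, tolerance = 1e-10)
  expect_equal(w1$F, w2$F, tolerance = 1e-8)
})

test_that("the F test refuses designs without enough error df", {
  X <- matrix(rnorm(24), 8); Y <- matrix(rnorm(24), 8)
  expect_error(wilks_lambda_test(X[1:6, ], Y[1:6, ]), "n > p \\+ q|complete")
})

test_that("correlation screen matches direct covariance computation", {
  X <- matrix(c(1, 2, 3, 4, 5,
                2, 1, 4, 3, 5,
                5, 4, 3, 2, 1), 5)
  Y <- X[, 1:2] + 0
  sc <- correlation_screen(X, Y)
  for (i in 1:3) for (j in 1:2) {
    num <- sum((X[, i] - mean(X[, i])) * (Y[, j] - mean(Y[, j])))
    den <- sqrt(sum((X[, i] - mean(X[, i]))^2) *
                  sum((Y[, j] - mean(Y[, j]))^2))
    expect_equal(sc$r[i, j], num / den, tolerance = 1e-12)
  }
  expect_equal(sc$r[1, 1], 1)
  # anti-correlated constructed pair
  anti <- correlation_screen(cbind(1:6), cbind(6:1))
  expect_equal(anti$r[1, 1], -1)
  expect_equal(anti$stars[1, 1], "***")
  # constant column flagged undefined
  flagged <- correlation_screen(cbind(rep(2, 6)), cbind(1:6))
  expect_true(is.na(flagged$r[1, 1]))
  expect_equal(flagged$stars[1, 1], "undefined")
})
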