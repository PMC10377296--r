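test_that("detection pmf matches enumeration and normalizes", {
  # 2 of 5 remaining cells malignant, draw 2, exactly 1 malignant
  expect_equal(detection_pmf(1, 2, 5, 2), enum_detection_pmf(1, 2, 5, 2))
  expect_equal(detection_pmf(1, 2, 5, 2), 0.6)
  # no malignant cells remain: only benign draws possible
  expect_equal(detection_pmf(0, 2, 5, 0), 1)
  # normalization over the support
  for (case in list(c(m = 3, N = 8, K = 3), c(m = 5, N = 12, K = 7),
                    c(m = 2, N = 6, K = 6))) {
    total <- sum(vapply(0:case["m"], detection_pmf, numeric(1),
                        m = case["m"], remaining_total = case["N"],
                        remaining_malignant = case["K"]))
    expect_equal(total, 1, tolerance = 1e-12)
  }
  # out-of-support draws are zero, not errors
  expect_equal(detection_pmf(3, 3, 10, 2), 0)
  expect_equal(detection_pmf(0, 5, 10, 7), 0)
  # domain errors
  expect_error(detection_pmf(-1, 2, 5, 2), "nonnegative")
  expect_error(detection_pmf(1, 6, 5, 2), "more cells than remain")
  expect_error(detection_pmf(1, 2, 5, 6), "exceeds remaining_total")
  expect_error(detection_pmf(3, 2, 5, 3), "m_star exceeds m")
})

test_that("proliferation pmf follows the Poisson law in both mean modes", {
  p <- growth_params(10, 4, 0.2)
  expect_equal(proliferation_pmf(0, p), exp(-2))
  expect_equal(proliferation_pmf(2, p), 2^2 * exp(-2) / 2)
  # no depletion yet: modes agree
  expect_equal(proliferation_pmf(3, p, M_prev = 0, mode = "depleted"),
               proliferation_pmf(3, p, M_prev = 0, mode = "literal"))
  # depleted mean shrinks with the cumulative count
  expect_equal(proliferation_pmf(0, p, M_prev = 5, mode = "depleted"),
               exp(-(10 - 5) * 0.2))
  expect_error(proliferation_pmf(1, growth_params(10, 4, 0.2), M_prev = 10,
                                 mode = "depleted"), "positive")
})

test_that("joint step pmf factorizes and normalizes under truncation", {
  p <- growth_params(5, 2, 0.4)
  expect_equal(joint_step_pmf(2, 1, p),
               detection_pmf(1, 2, 5, 2) * dpois(2, 2))
  expect_equal(joint_step_pmf(2, 1, p), 0.6 * dpois(2, 2))
  # with a detection factor of 1 the joint equals the Poisson factor alone
  p0 <- growth_params(5, 0, 0.4)
  expect_equal(joint_step_pmf(3, 0, p0), proliferation_pmf(3, p0))
  # brute-force enumeration: truncating the Poisson at N and renormalizing
  # makes the joint sum to 1 over all (m <= N, m_star <= m)
  for (nu in c(8, 15, 20)) {
    pN <- growth_params(nu, floor(nu / 2), 0.3)
    z <- sum(dpois(0:nu, nu * 0.3))
    total <- 0
    for (m in 0:nu) for (k in 0:m) {
      val <- tryCatch(joint_step_pmf(m, k, pN), error = function(e) 0)
      total <- total + val
    }
    expect_equal(total / z, 1, tolerance = 1e-10)
  }
})

test_that("log-likelihood decomposes over steps and barriers infeasibility", {
  traj <- make_trajectory(seed = 21, n_steps = 5)
  p <- growth_params(220, 90, 0.07)
  M_prev <- c(0, traj$M[-5]); Ms_prev <- c(0, traj$M_star[-5])
  two_route <- sum(vapply(1:5, function(t) {
    joint_step_pmf(traj$steps$m[t], traj$steps$m_star[t], p,
                   M_prev[t], Ms_prev[t], log = TRUE)
  }, numeric(1)))
  expect_equal(growth_loglik(traj, p), two_route, tolerance = 1e-12)

  one <- cell_trajectory(m = 4, m_star = 2)
  p1 <- growth_params(20, 8, 0.2)
  expect_equal(growth_loglik(one, p1), joint_step_pmf(4, 2, p1, log = TRUE))

  # infeasible parameters give -Inf, not an error
  expect_identical(growth_loglik(traj, growth_params(traj$M[5] - 1, 10, 0.1)),
                   -Inf)

  # appending a silent step multiplies the literal likelihood by exp(-nu*lambda)
  ext <- cell_trajectory(c(traj$steps$m, 0), c(traj$steps$m_star, 0))
  expect_equal(growth_loglik(ext, p), growth_loglik(traj, p) - p$nu * p$lambda,
               tolerance = 1e-10)
})

test_that("analytic score matches the numeric gradient in both modes", {
  traj <- make_trajectory(seed = 4, n_steps = 6)
  for (mode in c("literal", "depleted")) {
    p <- growth_params(230, 95, 0.06)
    g <- gbmgrowth:::growth_score(traj, p, mode)
    num <- vapply(1:3, function(i) {
      x <- c(p$nu, p$nu_star, p$lambda)
      h <- 1e-6 * x[i]
      up <- x; up[i] <- up[i] + h
      dn <- x; dn[i] <- dn[i] - h
      (growth_loglik(traj, growth_params(up[1], up[2], up[3]), mode) -
         growth_loglik(traj, growth_params(dn[1], dn[2], dn[3]), mode)) /
        (2 * h)
    }, numeric(1))
    expect_equal(unname(g), num, tolerance = 1e-5)
  }
})
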