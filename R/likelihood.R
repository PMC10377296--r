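#' Growth model parameters
#'
#' Bundle of the four population/rate parameters of the growth model:
#' \code{nu} (total cells that can proliferate by the final migration step),
#' \code{nu_star} (the malignant subset, \code{nu_star <= nu}), \code{lambda}
#' (per-step proliferation rate, > 0) and \code{lambda_star} (prior rate for
#' malignant proliferation, constrained > 1 where it is used).
#'
#' @param nu,nu_star,lambda,lambda_star numeric scalars.
#' @return an object of class \code{growth_params} (a named list).
#' @export
growth_params <- function(nu, nu_star, lambda, lambda_star = NA_real_) {
  if (!is.finite(nu) || nu <= 0) stop("'nu' must be positive")
  if (!is.finite(nu_star) || nu_star < 0) stop("'nu_star' must be nonnegative")
  if (nu_star > nu) stop("'nu_star' cannot exceed 'nu'")
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be positive")
  structure(list(nu = nu, nu_star = nu_star, lambda = lambda,
                 lambda_star = lambda_star),
            class = "growth_params")
}

#' Hypergeometric detection probability for one migration step
#'
#' Probability that exactly \code{m_star} of the \code{m} cells detected in
#' the incremental region are malignant, when \code{remaining_malignant} of
#' the \code{remaining_total} still-undetected cells are malignant. This is
#' the hypergeometric law
#' \deqn{P = C(K, k) C(N-K, m-k) / C(N, m)}
#' with \eqn{N} the remaining total, \eqn{K} the remaining malignant count
#' and \eqn{k} = \code{m_star}. Real-valued (continuously relaxed) \eqn{N},
#' \eqn{K} are accepted so the likelihood is differentiable in the
#' population sizes.
#'
#' @param m_star malignant cells detected at the step.
#' @param m total cells detected at the step.
#' @param remaining_total undetected cells before the step
#'   (\eqn{\nu - M_{t-1}}).
#' @param remaining_malignant undetected malignant cells before the step
#'   (\eqn{\nu^* - M^*_{t-1}}).
#' @param log logical; return the log probability.
#' @return probability in [0, 1] (or its log).
#' @examples
#' detection_pmf(1, 2, 5, 2)  # 0.6
#' @export
detection_pmf <- function(m_star, m, remaining_total, remaining_malignant,
                          log = FALSE) {
  if (any(c(m_star, m, remaining_total, remaining_malignant) < 0)) {
    stop("detection_pmf: all arguments must be nonnegative")
  }
  if (remaining_malignant > remaining_total) {
    stop("detection_pmf: remaining_malignant exceeds remaining_total")
  }
  if (m > remaining_total) {
    stop("detection_pmf: cannot detect more cells than remain")
  }
  if (m_star > m) stop("detection_pmf: m_star exceeds m")
  # out-of-support draws have probability zero, not an error
  if (m_star > remaining_malignant ||
      (m - m_star) > (remaining_total - remaining_malignant)) {
    return(if (log) -Inf else 0)
  }
  lp <- lchoose(remaining_malignant, m_star) +
    lchoose(remaining_total - remaining_malignant, m - m_star) -
    lchoose(remaining_total, m)
  if (log) lp else exp(lp)
}

#' Poisson proliferation probability for one migration step
#'
#' Probability mass at \code{m} cells proliferating in the incremental
#' region. The default mean is \eqn{\nu\lambda} (mode \code{"literal"});
#' mode \code{"depleted"} uses \eqn{(\nu - M_{t-1})\lambda} so the mean
#' shrinks as the population is consumed.
#'
#' @param m cells proliferating at the step.
#' @param params a \code{\link{growth_params}} object.
#' @param M_prev cumulative detected total before the step.
#' @param mode \code{"literal"} or \code{"depleted"}.
#' @param log logical; return the log probability.
#' @return probability (or its log).
#' @export
proliferation_pmf <- function(m, params, M_prev = 0,
                              mode = c("literal", "depleted"), log = FALSE) {
  mode <- match.arg(mode)
  if (m < 0 || M_prev < 0) stop("proliferation_pmf: negative input")
  mu <- if (mode == "literal") params$nu * params$lambda
        else (params$nu - M_prev) * params$lambda
  if (!is.finite(mu) || mu <= 0) {
    stop("proliferation_pmf: Poisson mean must be positive (got ", mu, ")")
  }
  stats::dpois(m, mu, log = log)
}

#' Joint step probability: detection times proliferation
#'
#' The per-step factor of the growth likelihood: the hypergeometric
#' detection probability of the malignant/benign split times the Poisson
#' probability of the total count.
#'
#' @inheritParams proliferation_pmf
#' @param m_star malignant cells detected at the step.
#' @param M_star_prev cumulative malignant count before the step.
#' @return probability (or its log).
#' @export
joint_step_pmf <- function(m, m_star, params, M_prev = 0, M_star_prev = 0,
                           mode = c("literal", "depleted"), log = FALSE) {
  mode <- match.arg(mode)
  N <- params$nu - M_prev
  K <- params$nu_star - M_star_prev
  ld <- detection_pmf(m_star, m, N, K, log = TRUE)
  lp <- proliferation_pmf(m, params, M_prev, mode, log = TRUE)
  if (log) ld + lp else exp(ld + lp)
}

#' Log-likelihood of a trajectory under the growth model
#'
#' Sum over migration steps of the log joint step probabilities. A
#' trajectory that is infeasible under \code{params} (cumulative counts
#' exceeding \code{nu} or \code{nu_star}, or an impossible malignant split)
#' yields \code{-Inf} rather than an error, so optimizers can use the value
#' as a barrier.
#'
#' @param traj a \code{\link{cell_trajectory}}.
#' @param params a \code{\link{growth_params}}.
#' @param mode Poisson-mean convention, see \code{\link{proliferation_pmf}}.
#' @return the log-likelihood (possibly \code{-Inf}).
#' @export
growth_loglik <- function(traj, params, mode = c("literal", "depleted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "cell_trajectory"))
  m <- traj$steps$m
  ms <- traj$steps$m_star
  M_prev <- c(0, traj$M[-traj$n_steps])
  Ms_prev <- c(0, traj$M_star[-traj$n_steps])
  N <- params$nu - M_prev
  K <- params$nu_star - Ms_prev
  # feasibility barrier: every step must be drawable
  if (any(N <= 0) || any(K < 0) || any(m > N) || any(ms > K) ||
      any((m - ms) > (N - K))) {
    return(-Inf)
  }
  mu <- if (mode == "literal") rep(params$nu * params$lambda, length(m))
        else N * params$lambda
  if (any(mu <= 0)) return(-Inf)
  sum(lchoose(K, ms) + lchoose(N - K, m - ms) - lchoose(N, m)) +
    sum(stats::dpois(m, mu, log = TRUE))
}

# Analytic score of growth_loglik in (nu, nu_star, lambda); digamma terms
# come from differentiating the lchoose factors in the population sizes.
growth_score <- function(traj, params, mode = "literal") {
  m <- traj$steps$m
  ms <- traj$steps$m_star
  M_prev <- c(0, traj$M[-traj$n_steps])
  Ms_prev <- c(0, traj$M_star[-traj$n_steps])
  N <- params$nu - M_prev
  K <- params$nu_star - Ms_prev
  a <- digamma(K + 1) - digamma(K - ms + 1)
  b <- digamma(N - K + 1) - digamma(N - K - (m - ms) + 1)
  cc <- digamma(N + 1) - digamma(N - m + 1)
  Tn <- traj$n_steps
  if (mode == "literal") {
    d_nu <- sum(b - cc) + sum(m) / params$nu - Tn * params$lambda
    d_lam <- sum(m) / params$lambda - Tn * params$nu
  } else {
    d_nu <- sum(b - cc) + sum(m / N) - Tn * params$lambda
    d_lam <- sum(m) / params$lambda - sum(N)
  }
  c(nu = d_nu, nu_star = sum(a - b), lambda = d_lam)
}
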