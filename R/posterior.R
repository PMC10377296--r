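#' Coefficient-of-variation weighted Poisson prior weight
#'
#' The prior over the eventual number of malignant cells proliferating at a
#' step is the Poisson law with mean \eqn{\mu = (\nu^* - M^*_{prev})
#' \lambda^*} multiplied by its coefficient of variation
#' \eqn{\mu^{-1/2}}. The model requires \eqn{\mu > 1} so the coefficient of
#' variation is below 1. The weight is unnormalized; normalization happens
#' in \code{\link{growth_posterior}}.
#'
#' @param m_star malignant count at which to evaluate the weight.
#' @param params a \code{\link{growth_params}} with \code{lambda_star} set.
#' @param M_star_prev cumulative malignant count before the step.
#' @return nonnegative weight \eqn{g(m^*) = f(m^*; \mu) \mu^{-1/2}}.
#' @export
weighted_prior <- function(m_star, params, M_star_prev = 0) {
  mu <- (params$nu_star - M_star_prev) * params$lambda_star
  if (!is.finite(mu) || mu <= 1) {
    stop("weighted prior undefined: (nu_star - M_star_prev) * lambda_star = ",
         format(mu), " must exceed 1")
  }
  stats::dpois(m_star, mu) * mu^(-0.5)
}

#' Posterior over per-step malignant counts
#'
#' Normalized posterior weights \eqn{H_t} over the migration steps,
#' proportional to the weighted prior evaluated at the observed malignant
#' counts times the maximized likelihood. The likelihood factor
#' \eqn{L(\hat\nu, \hat\nu^*; \hat\lambda)} is constant across steps and
#' cancels in the normalization; both the cancelled route (the default) and
#' the literal route that multiplies the likelihood back in are available
#' and agree to machine precision.
#'
#' @param object a \code{\link{growth_fit}}, or a \code{cell_trajectory}
#'   when \code{params} is supplied.
#' @param params a fitted \code{\link{growth_params}} (ignored when
#'   \code{object} is a \code{growth_fit}).
#' @param include_likelihood multiply each weight by the (step-constant)
#'   maximized likelihood before normalizing; numerically identical to the
#'   default cancelled route.
#' @return object of class \code{growth_posterior}: list with
#'   \code{step_weights} (normalized \eqn{H_t}, summing to 1),
#'   \code{posterior_mean} (\eqn{\sum_t m^*_t H_t}), \code{prior_means}
#'   (the per-step \eqn{\mu_t}), \code{m_star} (observed counts).
#' @export
growth_posterior <- function(object, params = NULL,
                             include_likelihood = FALSE) {
  if (inherits(object, "growth_fit")) {
    traj <- object$trajectory
    params <- object$params
    loglik <- object$logLik
  } else {
    traj <- object
    stopifnot(inherits(traj, "cell_trajectory"), inherits(params, "growth_params"))
    loglik <- NA_real_
  }
  ms <- traj$steps$m_star
  Ms_prev <- c(0, traj$M_star[-traj$n_steps])
  mu <- (params$nu_star - Ms_prev) * params$lambda_star
  if (any(!is.finite(mu)) || any(mu <= 1)) {
    stop("weighted prior undefined at step(s) ",
         paste(which(!is.finite(mu) | mu <= 1), collapse = ", "),
         ": prior mean (nu_star - M*_prev) * lambda_star must exceed 1")
  }
  # work in logs: log g_t = log f(m*_t; mu_t) - log(mu_t)/2
  lg <- stats::dpois(ms, mu, log = TRUE) - 0.5 * log(mu)
  if (include_likelihood) {
    if (!is.finite(loglik)) {
      loglik <- growth_loglik(traj, params)
    }
    lg <- lg + loglik  # step-constant; cancels in normalization
  }
  if (all(lg == -Inf)) stop("degenerate posterior: all step weights are zero")
  w <- exp(lg - max(lg))
  H <- w / sum(w)
  structure(
    list(step_weights = H,
         posterior_mean = sum(ms * H),
         prior_means = mu,
         m_star = ms),
    class = "growth_posterior")
}

#' @export
print.growth_posterior <- function(x, ...) {
  cat("Posterior over per-step malignant counts (",
      length(x$step_weights), " steps)\n", sep = "")
  cat("  posterior mean:", format(x$posterior_mean), "\n")
  cat("  weights:", paste(round(x$step_weights, 4), collapse = " "), "\n")
  invisible(x)
}

#' Eventual malignant volume
#'
#' Scales the posterior mean malignant count by the initial ROI volume:
#' \eqn{V_{new} = c \, H_{mean} V_{initial}} with proportionality constant
#' \code{c = 1} by default, so \eqn{H_{mean} = 1} returns the initial
#' volume unchanged. With \code{discrete = TRUE} the result is rounded to
#' the nearest integer cubic millimetre, mirroring volume measurements
#' truncated to discrete values.
#'
#' @param posterior_mean posterior mean \eqn{H_{mean}}.
#' @param v_initial initial ROI volume, mm^3.
#' @param c proportionality constant.
#' @param discrete round to nearest integer mm^3.
#' @return eventual volume in mm^3.
#' @export
eventual_volume <- function(posterior_mean, v_initial, c = 1,
                            discrete = FALSE) {
  if (posterior_mean < 0 || v_initial < 0 || c < 0) {
    stop("eventual_volume: negative input")
  }
  v <- c * posterior_mean * v_initial
  if (discrete) round(v) else v
}

#' Probability that no malignant cell remained undetected
#'
#' Per-step completeness probability built from the geometric law: a step
#' that detected \eqn{k} malignant cells is treated as \eqn{r} consecutive
#' failures-to-miss under success probability \eqn{1/(k+1)}, giving
#' \deqn{P = (k / (k+1))^r,}
#' the survival function at \eqn{r} of a geometric distribution. \eqn{P}
#' is 0 at \eqn{k = 0}, strictly increasing in \eqn{k}, and approaches 1
#' for large detected counts: the more malignant cells a step detected, the
#' likelier it is that none escaped detection.
#'
#' @param detected_malignant vector of nonnegative per-step malignant
#'   detected counts.
#' @param r geometric exponent (default 2).
#' @return vector of probabilities in [0, 1).
#' @examples
#' prob_no_undetected(c(0, 3, 5))  # 0, 0.5625, 0.6944...
#' @export
prob_no_undetected <- function(detected_malignant, r = 2L) {
  k <- as.numeric(detected_malignant)
  if (any(k < 0)) stop("detected counts must be nonnegative")
  if (r < 1) stop("'r' must be at least 1")
  (k / (k + 1))^r
}
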