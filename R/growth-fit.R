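# Newton-Raphson maximisation with numeric derivatives, feasibility barrier
# (-Inf log-likelihood) and step-halving. Used for the (nu, nu_star, lambda)
# MLE; kept generic over the objective.

numeric_gradient <- function(fn, x, scale) {
  h <- 1e-5 * pmax(abs(x), scale)
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h[i]
    repeat {
      xp <- x; xp[i] <- x[i] + hi
      xm <- x; xm[i] <- x[i] - hi
      fp <- fn(xp); fm <- fn(xm)
      if (is.finite(fp) && is.finite(fm)) {
        g[i] <- (fp - fm) / (2 * hi)
        break
      }
      hi <- hi / 4
      if (hi < .Machine$double.eps * max(abs(x[i]), 1)) { g[i] <- 0; break }
    }
  }
  g
}

numeric_hessian <- function(grad_fn, x, scale) {
  p <- length(x)
  H <- matrix(0, p, p)
  g0 <- grad_fn(x)
  h <- 1e-6 * pmax(abs(x), scale)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + h[i]
    gi <- grad_fn(xp)
    if (any(!is.finite(gi))) {
      xp[i] <- x[i] - h[i]
      gi <- grad_fn(xp)
      if (any(!is.finite(gi))) gi <- g0
      H[i, ] <- (g0 - gi) / h[i]
    } else {
      H[i, ] <- (gi - g0) / h[i]
    }
  }
  (H + t(H)) / 2
}

newton_raphson <- function(fn, x0, gr = NULL, scale = pmax(abs(x0), 1),
                           tol = 1e-8, max_iter = 200L) {
  if (is.null(gr)) gr <- function(x) numeric_gradient(fn, x, scale)
  x <- x0
  f <- fn(x)
  if (!is.finite(f)) stop("infeasible starting point for Newton-Raphson")
  halved <- FALSE
  grad_fallback <- FALSE
  iter <- 0L
  gnorm <- Inf
  reason <- "max_iter"
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- gr(x)
    gnorm <- sqrt(sum((g * scale)^2))
    if (gnorm < tol * (1 + abs(f))) { reason <- "gradient"; break }
    H <- numeric_hessian(gr, x, scale)
    # modified Newton step: damp eigenvalues so the direction is always
    # an ascent direction even where the Hessian is indefinite (the
    # nu-lambda ridge of the literal-mode likelihood)
    eg <- eigen(H, symmetric = TRUE)
    floor_ev <- 1e-6 * max(abs(eg$values), 1)
    damped <- any(eg$values > -floor_ev)
    dinv <- 1 / pmax(-eg$values, floor_ev)
    step <- eg$vectors %*% (dinv * crossprod(eg$vectors, g))
    step <- as.numeric(step)
    if (damped) grad_fallback <- TRUE
    if (!all(is.finite(step)) || sum(step * g) <= 0) {
      step <- g * scale^2 / max(gnorm, 1e-12)
    }
    alpha <- 1
    repeat {
      xn <- x + alpha * step
      fn_val <- fn(xn)
      if (is.finite(fn_val) && fn_val >= f - 1e-12) break
      alpha <- alpha / 2
      halved <- TRUE
      if (alpha < 1e-12) { xn <- x; fn_val <- f; break }
    }
    moved <- sqrt(sum(((xn - x) / scale)^2))
    x <- xn
    f <- fn_val
    # a collapsed step means the iterate is pinned, typically against the
    # feasibility barrier: stop, report as a stall rather than convergence
    if (moved < .Machine$double.eps^0.75) { reason <- "stall"; break }
  }
  g <- gr(x)
  gnorm <- sqrt(sum((g * scale)^2))
  converged <- gnorm < tol * (1 + abs(f))
  if (converged) reason <- "gradient"
  list(par = x, value = f, iterations = iter, gradient_norm = gnorm,
       converged = converged, reason = reason,
       step_halving = halved, gradient_fallback = grad_fallback)
}

#' Fit the Bayesian growth model to a detection trajectory
#'
#' Maximum-likelihood estimation of the population sizes \eqn{(\nu, \nu^*)}
#' and proliferation rate \eqn{\lambda} of the step-wise
#' hypergeometric/Poisson detection likelihood by Newton-Raphson on the
#' continuous relaxation of the population sizes, followed by
#' Newton-Raphson estimation of the prior rate \eqn{\lambda^*} from the
#' malignant counts (see \code{\link{fit_lambda_star}}).
#'
#' Defaults: initial values \eqn{\nu_0 = 2 M_T}, \eqn{\nu^*_0 = 2 M^*_T},
#' \eqn{\lambda_0 = \bar m / \nu_0}; convergence when the scaled gradient
#' norm drops below \code{tol * (1 + |logLik|)}; step-halving whenever a
#' Newton step would decrease the likelihood or leave the feasible region
#' (where the log-likelihood is \code{-Inf}).
#'
#' @param traj a \code{\link{cell_trajectory}}.
#' @param mode Poisson-mean convention: \code{"literal"} (mean
#'   \eqn{\nu\lambda}, the default) or \code{"depleted"} (mean
#'   \eqn{(\nu - M_{t-1})\lambda}).
#' @param init optional \code{\link{growth_params}} starting values.
#' @param lambda_fixed optional known proliferation rate; when supplied
#'   only the population sizes \eqn{(\nu, \nu^*)} are estimated (the
#'   well-posed two-parameter sub-problem).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return an object of class \code{growth_fit} with components
#'   \code{params} (fitted \code{growth_params} including
#'   \code{lambda_star}), \code{logLik}, \code{convergence} (iterations,
#'   gradient norm, step-halving and fallback flags, for both optimizations),
#'   \code{trajectory}, \code{mode}.
#' @examples
#' set.seed(1)
#' traj <- simulate_trajectory(growth_params(500, 200, 0.05, 2), n_steps = 10)
#' fit <- growth_fit(traj)
#' coef(fit)
#' @export
growth_fit <- function(traj, mode = c("literal", "depleted"), init = NULL,
                       lambda_fixed = NULL, tol = 1e-8, max_iter = 200L) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "cell_trajectory"), tol > 0)
  M_T <- traj$M[traj$n_steps]
  Ms_T <- traj$M_star[traj$n_steps]
  if (M_T < 1) stop("cannot fit a trajectory with no detected cells")
  if (is.null(init)) {
    nu0 <- 2 * M_T
    init <- growth_params(nu = nu0,
                          nu_star = max(2 * Ms_T, 1e-3),
                          lambda = mean(traj$steps$m) / nu0)
  }
  stopifnot(inherits(init, "growth_params"))

  # optimize in log space so positivity is automatic; the feasibility
  # constraints (nu >= M_T etc.) act through the -Inf barrier
  two_par <- !is.null(lambda_fixed)
  to_par <- function(theta) {
    lam <- if (two_par) lambda_fixed else exp(theta[3])
    growth_params(exp(theta[1]), exp(theta[2]), lam)
  }
  obj <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50) ||
        theta[2] > theta[1]) {
      return(-Inf)
    }
    growth_loglik(traj, to_par(theta), mode)
  }
  # analytic score; chain rule to log-parameters
  np <- if (two_par) 2L else 3L
  grad <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50) ||
        theta[2] > theta[1]) {
      return(rep(NA_real_, np))
    }
    p <- to_par(theta)
    if (!is.finite(growth_loglik(traj, p, mode))) return(rep(NA_real_, np))
    g <- growth_score(traj, p, mode) * c(p$nu, p$nu_star, p$lambda)
    g[seq_len(np)]
  }
  theta0 <- log(c(init$nu, init$nu_star, init$lambda))[seq_len(np)]
  if (!is.finite(obj(theta0))) {
    theta0 <- log(c(2 * M_T, max(2 * Ms_T, 1e-3),
                    mean(traj$steps$m) / (2 * M_T)))[seq_len(np)]
  }
  opt <- newton_raphson(obj, theta0, gr = grad, scale = rep(1, np), tol = tol,
                        max_iter = max_iter)
  est <- to_par(opt$par)

  ls <- fit_lambda_star(traj, nu_star = est$nu_star, tol = tol,
                        max_iter = max_iter)
  est$lambda_star <- ls$lambda_star

  structure(
    list(params = est,
         logLik = opt$value,
         convergence = list(
           iterations = opt$iterations,
           gradient_norm = opt$gradient_norm,
           converged = opt$converged,
           reason = opt$reason,
           step_halving = opt$step_halving,
           gradient_fallback = opt$gradient_fallback,
           lambda_star_boundary = ls$boundary,
           lambda_star_iterations = ls$iterations),
         trajectory = traj,
         mode = mode),
    class = "growth_fit")
}

#' Estimate the prior proliferation rate of malignant cells
#'
#' Newton-Raphson maximization of the Poisson likelihood of the malignant
#' per-step counts \eqn{m^*_t} with means \eqn{c_t \lambda^*}, where
#' \eqn{c_t} is the remaining malignant population before step \eqn{t},
#' subject to the model constraint \eqn{\lambda^* > 1}. When the
#' unconstrained optimum falls at or below 1 the estimate is clipped to
#' \code{1 + 1e-6} and flagged as a boundary solution (this includes the
#' degenerate all-zero malignant trajectory).
#'
#' By default \eqn{c_t = \nu^* - M^*_{t-1}} is derived from the
#' trajectory's own cumulative counts. In that case the unconstrained
#' optimum \eqn{\hat\lambda^* = \sum_t m^*_t / \sum_t c_t} never exceeds 1
#' for a feasible trajectory (the detected total cannot exceed
#' \eqn{\nu^*}, which every \eqn{c_t} also bounds from below), so the
#' boundary flag is the expected outcome on detection data; a rate above 1
#' is identifiable only when the malignant counts are modelled against an
#' exogenous \code{remaining} schedule, which can be supplied directly.
#'
#' @param traj a \code{\link{cell_trajectory}}.
#' @param nu_star fitted malignant population size.
#' @param remaining optional vector of per-step remaining malignant
#'   counts \eqn{c_t}; default \eqn{\nu^* - M^*_{t-1}}.
#' @param tol convergence tolerance on the score.
#' @param max_iter maximum Newton iterations.
#' @return list with \code{lambda_star}, \code{boundary} flag,
#'   \code{iterations}.
#' @export
fit_lambda_star <- function(traj, nu_star, remaining = NULL, tol = 1e-8,
                            max_iter = 200L) {
  stopifnot(inherits(traj, "cell_trajectory"))
  ms <- traj$steps$m_star
  if (is.null(remaining)) {
    Ms_prev <- c(0, traj$M_star[-traj$n_steps])
    cc <- nu_star - Ms_prev        # remaining malignant before each step
  } else {
    if (length(remaining) != traj$n_steps) {
      stop("'remaining' must have one entry per step")
    }
    cc <- as.numeric(remaining)
  }
  if (any(cc < 0)) stop("nu_star infeasible for this trajectory")
  S <- sum(ms)
  C <- sum(cc)
  if (S == 0 || C <= 0) {
    return(list(lambda_star = 1 + 1e-6, boundary = TRUE, iterations = 0L))
  }
  # score: S/lambda - C; concave log-likelihood in lambda
  lam <- max(S / C, 1.5)  # start near the root
  iter <- 0L
  repeat {
    iter <- iter + 1L
    score <- S / lam - C
    hess <- -S / lam^2
    lam_new <- lam - score / hess
    if (lam_new <= 0) lam_new <- lam / 2
    if (abs(lam_new - lam) < tol * (1 + lam) || iter >= max_iter) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  if (lam <= 1) {
    list(lambda_star = 1 + 1e-6, boundary = TRUE, iterations = iter)
  } else {
    list(lambda_star = lam, boundary = FALSE, iterations = iter)
  }
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth model fit (", x$mode, " Poisson mean)\n", sep = "")
  print(round(coef(x), 6))
  cat("log-likelihood:", format(x$logLik), "\n")
  status <- switch(x$convergence$reason,
                   gradient = "(converged)",
                   stall = "(stalled at a constrained optimum)",
                   "(NOT converged: iteration limit)")
  cat("Newton-Raphson:", x$convergence$iterations, "iterations, |grad| =",
      format(x$convergence$gradient_norm, digits = 3), status, "\n")
  if (x$convergence$lambda_star_boundary) {
    cat("note: lambda_star at its lower boundary (constraint lambda* > 1)\n")
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  with(object$params, c(nu = nu, nu_star = nu_star, lambda = lambda,
                        lambda_star = lambda_star))
}

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$logLik, df = 4L, class = "logLik")
}

#' @export
summary.growth_fit <- function(object, ...) {
  post <- growth_posterior(object)
  out <- list(fit = object, posterior = post)
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior over per-step malignant counts:\n")
  cat("  posterior mean:", format(x$posterior$posterior_mean), "\n")
  cat("  step weights:", paste(round(x$posterior$step_weights, 4),
                               collapse = " "), "\n")
  invisible(x)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  traj <- object$trajectory
  p <- object$params
  M_prev <- c(0, traj$M[-traj$n_steps])
  mu <- if (object$mode == "literal") rep(p$nu * p$lambda, traj$n_steps)
        else (p$nu - M_prev) * p$lambda
  (traj$steps$m - mu) / sqrt(mu)  # Pearson residuals of the Poisson factor
}

#' Simulate new trajectories from a fitted growth model
#'
#' @param object a \code{growth_fit}.
#' @param nsim number of trajectories.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of \code{\link{cell_trajectory}} objects.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i) {
    simulate_trajectory(object$params, n_steps = object$trajectory$n_steps,
                        seed = seed + i - 1L, mode = object$mode)
  })
}

#' Predict the eventual malignant volume from a fitted growth model
#'
#' Computes the weighted-prior posterior over per-step malignant counts and
#' scales its mean by the initial ROI volume.
#'
#' @param object a \code{growth_fit}.
#' @param v_initial initial ROI volume in cubic millimetres; defaults to the
#'   volume stored on the trajectory.
#' @param c proportionality constant linking posterior mean and volume.
#' @param discrete round the predicted volume to the nearest integer mm^3.
#' @param r exponent of the geometric no-undetected-cell probability.
#' @param ... unused.
#' @return a list with \code{v_new} (predicted eventual volume, mm^3),
#'   \code{posterior} (a \code{\link{growth_posterior}} summary) and
#'   \code{p_no_undetected} (per-step probabilities).
#' @export
predict.growth_fit <- function(object, v_initial = NULL, c = 1,
                               discrete = FALSE, r = 2L, ...) {
  if (is.null(v_initial)) v_initial <- object$trajectory$v_initial
  if (is.null(v_initial)) {
    stop("no 'v_initial' supplied and none stored on the trajectory")
  }
  post <- growth_posterior(object)
  v_new <- eventual_volume(post$posterior_mean, v_initial, c = c,
                           discrete = discrete)
  p <- prob_no_undetected(object$trajectory$steps$m_star, r = r)
  list(v_new = v_new, posterior = post, p_no_undetected = p)
}

#' @export
plot.growth_fit <- function(x, ...) {
  post <- growth_posterior(x)
  graphics::barplot(post$step_weights,
                    names.arg = seq_along(post$step_weights),
                    xlab = "migration step", ylab = "posterior weight",
                    main = "Posterior step weights", ...)
  invisible(x)
}
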