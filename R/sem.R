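#' Fit the latent-factor measurement model of a feature block
#'
#' Gaussian factor-analysis measurement model
#' \deqn{x = \gamma + \Lambda \eta + \delta, \quad \eta \sim N(0, I_d),
#'   \quad \delta \sim N(0, \Theta)}
#' with diagonal error covariance \eqn{\Theta}, estimated by EM
#' (expectation over the latent scores, closed-form M-step). After
#' convergence each factor is rescaled so the anchor (first) manifest's
#' loading equals 1, the usual SEM identification convention, with the
#' latent scores rescaled compensatingly. Near-zero error variances
#' (Heywood cases) are floored at 1e-6 and flagged.
#'
#' @param X numeric matrix or data frame of manifest variables (complete
#'   cases are used; the count is reported).
#' @param d number of latent factors (default 1).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed (EM start is deterministic; the seed fixes the
#'   small random jitter used when the PCA start is degenerate).
#' @return an object of class \code{sem_fit}: \code{gamma} (intercepts),
#'   \code{lambda} (q x d loadings, anchor row = 1), \code{theta} (error
#'   variances), \code{scores} (n x d posterior-mean latent scores),
#'   \code{loglik_trace}, \code{converged}, \code{heywood}, \code{n_used}.
#' @export
fit_sem_measurement <- function(X, d = 1L, tol = 1e-8, max_iter = 500L,
                                seed = 1L) {
  X <- as.matrix(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); q <- ncol(X)
  if (n <= q) stop("need more complete rows than manifest variables")
  if (d < 1 || d >= q) stop("'d' must be in [1, ncol(X) - 1]")
  set.seed(seed)
  gamma <- colMeans(X)
  Xc <- sweep(X, 2, gamma)
  S <- crossprod(Xc) / n
  # PCA start for the loadings
  eig <- eigen(S, symmetric = TRUE)
  L <- eig$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(d)], 1e-8)), d)
  if (any(!is.finite(L)) || all(abs(L) < 1e-12)) {
    L <- matrix(stats::rnorm(q * d, sd = 0.1), q, d)
  }
  theta <- pmax(diag(S) - rowSums(L^2), 1e-3)
  loglik <- function(L, theta) {
    Sigma <- tcrossprod(L) + diag(theta, q)
    ch <- chol(Sigma)
    logdet <- 2 * sum(log(diag(ch)))
    quad <- sum(backsolve(ch, t(Xc), transpose = TRUE)^2)
    -0.5 * (n * q * log(2 * pi) + n * logdet + quad)
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step via Woodbury: stable when theta is tiny (near-Heywood)
    Ti <- 1 / theta
    A <- diag(d) + t(L) %*% (L * Ti)            # I + L' Theta^-1 L
    Ainv <- solve(A)
    B <- Ainv %*% t(L * Ti)                     # d x q: E[eta|x] = B x
    Ez <- Xc %*% t(B)                           # n x d
    Vz <- Ainv                                  # posterior covariance
    Ezz <- n * Vz + crossprod(Ez)
    # M-step
    L_new <- t(Xc) %*% Ez %*% solve(Ezz)
    theta_new <- diag(S) - 2 * rowSums((t(Xc) %*% Ez / n) * L_new) +
      rowSums((L_new %*% (Ezz / n)) * L_new)
    heywood_now <- theta_new < 1e-6
    theta_new <- pmax(theta_new, 1e-6)
    L <- L_new; theta <- theta_new
    ll <- loglik(L, theta)
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # identification: rescale each factor so its anchor loading is 1
  Ti <- 1 / theta
  A <- diag(d) + t(L) %*% (L * Ti)
  scores <- Xc %*% t(solve(A) %*% t(L * Ti))
  scaling <- numeric(d)
  for (j in seq_len(d)) {
    anchor <- L[j, j]
    if (abs(anchor) < 1e-10) anchor <- sign(L[which.max(abs(L[, j])), j]) *
        max(abs(L[, j]), 1e-10)
    scaling[j] <- anchor
    L[, j] <- L[, j] / anchor
    scores[, j] <- scores[, j] * anchor
  }
  structure(
    list(gamma = gamma, lambda = L, theta = theta, scores = scores,
         scaling = scaling, loglik_trace = trace, converged = converged,
         heywood = any(theta <= 1e-6), n_used = n,
         d = d, manifest_names = colnames(X)),
    class = "sem_fit")
}

#' Latent scores for new manifest rows under a fitted measurement model
#'
#' Posterior-mean latent scores \eqn{E[\eta \mid x]} for new rows, using
#' the loadings, intercepts and error variances estimated on the training
#' data (on the anchored scale).
#'
#' @param object a \code{sem_fit}.
#' @param newdata matrix or data frame with the same manifest columns.
#' @param ... unused.
#' @return n x d matrix of latent scores.
#' @export
predict.sem_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$gamma)) {
    stop("newdata must have the same manifest columns as the fit")
  }
  # undo the anchor rescale to recover the eta ~ N(0, I) parameterization
  L <- sweep(object$lambda, 2, object$scaling, "*")
  Ti <- 1 / object$theta
  A <- diag(object$d) + t(L) %*% (L * Ti)
  Xc <- sweep(X, 2, object$gamma)
  scores <- Xc %*% t(solve(A) %*% t(L * Ti))
  sweep(scores, 2, object$scaling, "*")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Latent-factor measurement model:", length(x$gamma), "manifests,",
      x$d, "factor(s),", x$n_used, "complete rows\n")
  cat("loadings (anchor = 1):\n")
  print(round(x$lambda, 4))
  if (x$heywood) cat("note: Heywood case floored (error variance at 1e-6)\n")
  if (!x$converged) cat("note: EM did not converge\n")
  invisible(x)
}

#' Reconstruct manifests from a fitted measurement model
#'
#' @param object a \code{sem_fit}.
#' @param ... unused.
#' @return fitted manifest matrix \eqn{\hat\gamma + \hat\Lambda \hat\eta}.
#' @export
fitted.sem_fit <- function(object, ...) {
  sweep(object$scores %*% t(object$lambda), 2, object$gamma, "+")
}
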