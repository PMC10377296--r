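#' Bayesian regression of predicted eventual volume on radiomic covariates
#'
#' Fits \eqn{y = \alpha + x^T \beta + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma^2)} i.i.d., with one of two priors on the coefficients:
#' \describe{
#'   \item{\code{spike_slab} (default)}{Bernoulli(0.5) inclusion
#'     indicators on each covariate with a diffuse normal slab on included
#'     coefficients; sampled by Gibbs (stochastic-search variable
#'     selection). The Bernoulli(0.5) mass acts on inclusion, the workable
#'     reading of a Bernoulli prior for real-valued effects.}
#'   \item{\code{literal}}{the coefficients themselves, intercept included,
#'     are restricted to \{0, 1\} with independent Bernoulli(0.5) mass, as
#'     literally printed; the vertex posterior (error variance marginalized
#'     under the Jeffreys prior, giving \eqn{p(v|y) \propto RSS(v)^{-n/2}})
#'     is sampled by single-flip Metropolis.}
#' }
#'
#' @param response numeric response vector (predicted eventual volumes).
#' @param covariates numeric matrix or data frame of covariates.
#' @param sem optional \code{\link{fit_sem_measurement}} fit (or list of
#'   them); when supplied, the latent scores replace \code{covariates}.
#' @param prior_mode \code{"spike_slab"} or \code{"literal"}.
#' @param n_draws posterior draws kept after burn-in.
#' @param burn_in discarded initial draws.
#' @param seed integer seed; the chain is reproducible from it.
#' @param slab_scale slab SD in units of \code{sd(response)} per
#'   standardized covariate.
#' @param force_include logical; force all inclusion indicators on (the
#'   sampler then reduces to Bayesian linear regression under the slab).
#' @return an object of class \code{bayes_volreg}: \code{draws} (matrix of
#'   \code{alpha}, \code{beta_*}, \code{sigma2}), \code{inclusion}
#'   (posterior inclusion probabilities), \code{fitted} (posterior
#'   predictive mean at the training rows), \code{diagnostics} (acceptance
#'   rate for the Metropolis mode, draw counts, a mixing warning flag),
#'   plus centering/scaling info used by \code{predict}.
#' @export
fit_bayes_regression <- function(response, covariates, sem = NULL,
                                 prior_mode = c("spike_slab", "literal"),
                                 n_draws = 2000L, burn_in = 500L, seed = 1L,
                                 slab_scale = 10, force_include = FALSE) {
  prior_mode <- match.arg(prior_mode)
  y <- as.numeric(response)
  if (!is.null(sem)) {
    if (inherits(sem, "sem_fit")) sem <- list(sem)
    covariates <- do.call(cbind, lapply(sem, function(s) s$scores))
    colnames(covariates) <- paste0("eta", seq_len(ncol(covariates)))
  }
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n < p + 2) stop("too few complete rows to fit the regression")
  set.seed(seed)

  if (prior_mode == "literal") {
    fit <- literal_bernoulli_sampler(y, X, n_draws, burn_in)
  } else {
    fit <- spike_slab_sampler(y, X, n_draws, burn_in, slab_scale,
                              force_include)
  }
  draws <- fit$draws
  beta_mean <- colMeans(draws[, 1 + seq_len(p), drop = FALSE])
  alpha_mean <- mean(draws[, 1])
  fitted <- alpha_mean + as.numeric(X %*% beta_mean)
  acc <- fit$acceptance
  mixing_warn <- !is.na(acc) && (acc < 0.1 || acc > 0.6)
  if (mixing_warn) {
    warning("Metropolis acceptance rate ", round(acc, 3),
            " outside [0.1, 0.6]; inspect the chain")
  }
  structure(
    list(draws = draws, inclusion = fit$inclusion,
         fitted = fitted, response = y, X = X,
         coef_names = c("alpha", colnames(X)),
         prior_mode = prior_mode,
         diagnostics = list(acceptance_rate = acc, n_draws = nrow(draws),
                            burn_in = burn_in, mixing_warning = mixing_warn),
         seed = seed),
    class = "bayes_volreg")
}

# Gibbs sampler for spike-and-slab linear regression (SSVS with a point
# mass at zero). Covariates standardized internally; draws reported on the
# original scale.
spike_slab_sampler <- function(y, X, n_draws, burn_in, slab_scale,
                               force_include) {
  n <- length(y); p <- ncol(X)
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  Z <- sweep(sweep(X, 2, xm), 2, xs, "/")
  sy <- stats::sd(y); if (sy == 0) sy <- 1
  tau2 <- (slab_scale * sy)^2
  ztz <- colSums(Z^2)
  # start from the least-squares fit for fast settling
  b <- tryCatch(stats::coef(stats::lm.fit(cbind(1, Z), y))[-1],
                error = function(e) rep(0, p))
  b[!is.finite(b)] <- 0
  g <- rep(1L, p)
  a <- mean(y)
  resid <- y - a - as.numeric(Z %*% b)
  sig2 <- max(stats::var(resid), 1e-8)
  total <- burn_in + n_draws
  out <- matrix(NA_real_, n_draws, p + 2)
  incl <- matrix(NA_real_, n_draws, p)
  for (it in seq_len(total)) {
    for (j in seq_len(p)) {
      resid <- resid + Z[, j] * b[j]        # remove j's contribution
      v <- 1 / (ztz[j] / sig2 + 1 / tau2)
      m <- v * sum(Z[, j] * resid) / sig2
      if (force_include) {
        g[j] <- 1L
      } else {
        log_bf <- 0.5 * log(v / tau2) + 0.5 * m^2 / v
        g[j] <- as.integer(stats::runif(1) < 1 / (1 + exp(-log_bf)))
      }
      b[j] <- if (g[j] == 1L) stats::rnorm(1, m, sqrt(v)) else 0
      resid <- resid - Z[, j] * b[j]
    }
    a_new <- stats::rnorm(1, mean(y - as.numeric(Z %*% b)), sqrt(sig2 / n))
    resid <- resid + a - a_new
    a <- a_new
    rss <- sum(resid^2)
    sig2 <- 1 / stats::rgamma(1, 0.01 + n / 2, 0.01 + rss / 2)
    if (it > burn_in) {
      k <- it - burn_in
      beta_raw <- b / xs
      alpha_raw <- a - sum(beta_raw * xm)
      out[k, ] <- c(alpha_raw, beta_raw, sig2)
      incl[k, ] <- g
    }
  }
  colnames(out) <- c("alpha", colnames(X), "sigma2")
  list(draws = out, inclusion = colMeans(incl), acceptance = NA_real_)
}

# Single-flip Metropolis over coefficient vertices in {0,1}^(p+1), with
# sigma^2 marginalized under the Jeffreys prior: p(v | y) ~ RSS(v)^(-n/2).
literal_bernoulli_sampler <- function(y, X, n_draws, burn_in) {
  n <- length(y); p <- ncol(X)
  Xa <- cbind(1, X)
  rss_of <- function(v) max(sum((y - as.numeric(Xa %*% v))^2), 1e-12)
  v <- rep(0, p + 1)
  rss <- rss_of(v)
  total <- burn_in + n_draws
  out <- matrix(NA_real_, n_draws, p + 2)
  incl <- matrix(NA_real_, n_draws, p)
  accepted <- 0L
  for (it in seq_len(total)) {
    j <- sample.int(p + 1, 1)
    v_new <- v; v_new[j] <- 1 - v_new[j]
    rss_new <- rss_of(v_new)
    if (log(stats::runif(1)) < (n / 2) * (log(rss) - log(rss_new))) {
      v <- v_new; rss <- rss_new; accepted <- accepted + 1L
    }
    if (it > burn_in) {
      k <- it - burn_in
      sig2 <- 1 / stats::rgamma(1, n / 2, rss / 2)
      out[k, ] <- c(v, sig2)
      incl[k, ] <- v[-1]
    }
  }
  colnames(out) <- c("alpha", colnames(X), "sigma2")
  list(draws = out, inclusion = colMeans(incl), acceptance = accepted / total)
}

#' @export
print.bayes_volreg <- function(x, ...) {
  cat("Bayesian volume regression (", x$prior_mode, " prior), ",
      nrow(x$draws), " draws\n", sep = "")
  print(round(coef(x), 6))
  if (!is.null(x$inclusion)) {
    cat("posterior inclusion probabilities:\n")
    print(round(stats::setNames(x$inclusion, x$coef_names[-1]), 3))
  }
  if (x$diagnostics$mixing_warning) cat("warning: poor mixing flagged\n")
  invisible(x)
}

#' @export
coef.bayes_volreg <- function(object, ...) {
  cm <- colMeans(object$draws)
  cm[-length(cm)]  # drop sigma2
}

#' @export
summary.bayes_volreg <- function(object, level = 0.95, ...) {
  qs <- apply(object$draws, 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  out <- data.frame(mean = colMeans(object$draws),
                    lower = qs[1, ], upper = qs[2, ])
  rownames(out) <- colnames(object$draws)
  out
}

#' @export
predict.bayes_volreg <- function(object, newdata = NULL, draws = FALSE, ...) {
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  p <- length(object$coef_names) - 1L
  B <- object$draws[, seq_len(p + 1), drop = FALSE]
  pred_draws <- cbind(1, X) %*% t(B)   # n x n_draws
  if (draws) pred_draws else rowMeans(pred_draws)
}

#' Posterior predictive volumes and recomputed detection probabilities
#'
#' For each subject, the posterior predictive mean eventual volume from the
#' regression and the recomputed probability that no malignant cell
#' remained undetected: the predicted volume divided by the subject's
#' initial volume gives the implied posterior-mean malignant count, which
#' is rounded and pushed through the geometric completeness probability.
#' Subjects without an initial volume are skipped with a message.
#'
#' @param object a \code{\link{fit_bayes_regression}} fit.
#' @param covariates covariate matrix for the subjects to predict
#'   (default: the training rows).
#' @param v_initial vector of initial ROI volumes (mm^3) per subject.
#' @param r geometric exponent for \code{\link{prob_no_undetected}}.
#' @return data.frame with \code{v_pred}, \code{implied_count},
#'   \code{p_no_undetected}; skipped subjects carry \code{NA}.
#' @export
predict_with_covariates <- function(object, covariates = NULL, v_initial,
                                    r = 2L) {
  pred <- predict(object, newdata = covariates)
  n <- length(pred)
  if (length(v_initial) != n) {
    stop("'v_initial' must have one entry per predicted subject")
  }
  out <- data.frame(v_pred = pred, implied_count = NA_real_,
                    p_no_undetected = NA_real_)
  usable <- is.finite(v_initial) & v_initial > 0
  if (any(!usable)) {
    message(sum(!usable), " subject(s) without an initial volume skipped")
  }
  k <- round(pmax(pred[usable], 0) / v_initial[usable])
  out$implied_count[usable] <- k
  out$p_no_undetected[usable] <- prob_no_undetected(k, r = r)
  out
}

#' Gaussian GLM baseline fit
#'
#' Ordinary least-squares (Gaussian-family GLM) baseline with the
#' goodness-of-fit summaries used by the comparison harness:
#' \eqn{R^2 = 1 - RSS/TSS} and \eqn{AIC = n \log(RSS/n) + 2p} with
#' \eqn{p} the number of mean parameters. Aliased (collinear) columns are
#' dropped by the QR fit and flagged.
#'
#' @param response numeric response vector.
#' @param covariates covariate matrix or data frame.
#' @return list with \code{coefficients}, \code{r_squared}, \code{aic},
#'   \code{fitted}, \code{aliased} flag, \code{n}, \code{p}.
#' @export
fit_glm_baseline <- function(response, covariates) {
  y <- as.numeric(response)
  X <- as.matrix(covariates)
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  aliased <- any(is.na(cf))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  p <- sum(!is.na(cf))
  list(coefficients = cf, r_squared = 1 - rss / tss,
       aic = n * log(rss / n) + 2 * p,
       fitted = stats::fitted(fit), aliased = aliased, n = n, p = p,
       lm = fit)
}

#' GLM-versus-Bayesian model comparison with ABC cross-validation
#'
#' For each region of interest, fits the two candidate models to the ROI's
#' eventual-volume response and reports \eqn{R^2}, AIC and a k-fold
#' cross-validation error. The GLM column scores held-out subjects by the
#' normalized absolute distance of its point predictions; the Bayesian
#' column scores them by rejection Approximate Bayesian Computation:
#' posterior predictive replicates are simulated for the held-out
#' subjects, replicates within the \code{abc_quantile} quantile of the
#' normalized distances are accepted, and the error is the normalized
#' distance between the held-out responses and the accepted-replicate
#' mean (the ABC point prediction). The Bayesian AIC uses the
#' posterior-mean predictions with the expected included-parameter count.
#'
#' @param table data.frame holding response and covariate columns.
#' @param response_cols named character vector: ROI label -> response
#'   column.
#' @param covariate_cols character vector of covariate columns.
#' @param models length-2 character vector choosing each column's model
#'   (\code{"glm"} or \code{"bayes"}); swapping the entries swaps the
#'   output columns.
#' @param sem_split optional list with character vectors \code{endo} and
#'   \code{exo} naming covariate columns; when supplied, the Bayesian
#'   candidate restructures each block into one latent factor fitted on
#'   the training rows (the heterogeneity-accommodating model) and
#'   regresses on the latent scores, while the GLM keeps the raw
#'   covariates.
#' @param folds number of cross-validation folds (>= 2).
#' @param abc_quantile acceptance quantile of the simulated distances.
#' @param n_abc_sims posterior predictive replicates per fold.
#' @param n_draws,burn_in sampler settings for the Bayesian column.
#' @param seed integer seed (controls the fold split and the samplers).
#' @return data.frame with one row per ROI and columns \code{roi},
#'   \code{r2_<model1>}, \code{r2_<model2>}, \code{aic_*}, \code{cv_*}.
#' @export
model_comparison <- function(table, response_cols, covariate_cols,
                             models = c("glm", "bayes"), sem_split = NULL,
                             folds = 5L,
                             abc_quantile = 0.1, n_abc_sims = 10000L,
                             n_draws = 1500L, burn_in = 500L, seed = 1L) {
  stopifnot(length(models) == 2L, all(models %in% c("glm", "bayes")),
            folds >= 2L)
  if (is.null(names(response_cols))) names(response_cols) <- response_cols
  rows <- vector("list", length(response_cols))
  for (i in seq_along(response_cols)) {
    roi <- names(response_cols)[i]
    y <- table[[response_cols[i]]]
    X <- as.matrix(table[, covariate_cols, drop = FALSE])
    ok <- is.finite(y) & stats::complete.cases(X)
    y <- y[ok]; X <- X[ok, , drop = FALSE]
    n <- length(y)
    set.seed(seed + i)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    if (min(tabulate(fold_id, folds)) < 3) {
      stop("a fold has fewer than 3 subjects; reduce 'folds'")
    }
    cols <- lapply(seq_along(models), function(mi) {
      evaluate_candidate(models[mi], y, X, fold_id, abc_quantile,
                         n_abc_sims, n_draws, burn_in, seed = seed + i,
                         sem_split = sem_split)
    })
    rows[[i]] <- data.frame(
      roi = roi,
      r2_1 = cols[[1]]$r2, r2_2 = cols[[2]]$r2,
      aic_1 = cols[[1]]$aic, aic_2 = cols[[2]]$aic,
      cv_1 = cols[[1]]$cv, cv_2 = cols[[2]]$cv)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("roi",
                  paste0("r2_", models[1]), paste0("r2_", models[2]),
                  paste0("aic_", models[1]), paste0("aic_", models[2]),
                  paste0("cv_", models[1]), paste0("cv_", models[2]))
  out
}

evaluate_candidate <- function(model, y, X, fold_id, abc_quantile,
                               n_abc_sims, n_draws, burn_in, seed,
                               sem_split = NULL) {
  n <- length(y)
  folds <- max(fold_id)
  if (model == "glm") {
    full <- fit_glm_baseline(y, X)
    cv <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_glm_baseline(y[tr], X[tr, , drop = FALSE])
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      pred <- as.numeric(cbind(1, X[!tr, , drop = FALSE]) %*% cf)
      cv[f] <- mean(abs(y[!tr] - pred)) / stats::sd(y[tr])
    }
    list(r2 = full$r_squared, aic = full$aic, cv = mean(cv))
  } else {
    # optional SEM restructuring: latent scores learned on the fit rows
    restructure <- function(rows) {
      if (is.null(sem_split)) {
        list(train = X[rows, , drop = FALSE],
             score = function(newrows) X[newrows, , drop = FALSE])
      } else {
        se <- fit_sem_measurement(X[rows, sem_split$endo, drop = FALSE],
                                  d = 1, seed = seed)
        sx <- fit_sem_measurement(X[rows, sem_split$exo, drop = FALSE],
                                  d = 1, seed = seed)
        list(train = cbind(eta_endo = se$scores[, 1],
                           eta_exo = sx$scores[, 1]),
             score = function(newrows) cbind(
               eta_endo = predict(se, X[newrows, sem_split$endo,
                                        drop = FALSE])[, 1],
               eta_exo = predict(sx, X[newrows, sem_split$exo,
                                       drop = FALSE])[, 1]))
      }
    }
    all_rows <- seq_len(n)
    rs <- restructure(all_rows)
    full <- fit_bayes_regression(y, rs$train, n_draws = n_draws,
                                 burn_in = burn_in, seed = seed)
    rss <- sum((y - full$fitted)^2)
    p_eff <- 1 + sum(full$inclusion)
    cv <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      rsf <- restructure(tr)
      fit <- fit_bayes_regression(y[tr], rsf$train, n_draws = n_draws,
                                  burn_in = burn_in, seed = seed + f)
      Zte <- rsf$score(te)
      sims <- sample.int(nrow(fit$draws), n_abc_sims, replace = TRUE)
      D <- fit$draws[sims, , drop = FALSE]
      p <- ncol(Zte)
      pred <- cbind(1, Zte) %*% t(D[, seq_len(p + 1), drop = FALSE])
      noise <- matrix(stats::rnorm(length(pred)), nrow(pred)) *
        rep(sqrt(D[, p + 2]), each = nrow(pred))
      yrep <- pred + noise
      dist <- colMeans(abs(yrep - y[te])) / stats::sd(y[tr])
      tol <- stats::quantile(dist, abc_quantile)
      accepted <- yrep[, dist <= tol, drop = FALSE]
      # rejection-ABC point prediction: mean of the accepted replicates
      cv[f] <- mean(abs(y[te] - rowMeans(accepted))) / stats::sd(y[tr])
    }
    list(r2 = 1 - rss / sum((y - mean(y))^2),
         aic = n * log(rss / n) + 2 * p_eff,
         cv = mean(cv))
  }
}
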