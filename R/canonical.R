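#' Canonical correlations between two feature blocks
#'
#' Canonical correlations \eqn{\rho_i} between an n x p block \code{X}
#' (e.g. ROI volumes) and an n x q block \code{Y} (e.g. spatial or
#' histology features), in descending order. Rows with missing values in
#' either block are dropped (complete-case per block pair) and the number
#' of complete rows is reported. Rank deficiency reduces the number of
#' correlations with a warning.
#'
#' @param X,Y numeric matrices (or data frames) with equal row counts.
#' @return list with \code{cor} (descending canonical correlations, in
#'   [0, 1]), \code{n} (complete rows used), \code{p}, \code{q}.
#' @export
canonical_correlations <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("'X' and 'Y' must have the same rows")
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n <= max(p, q)) stop("too few complete rows for canonical analysis")
  if (any(apply(X, 2, stats::sd) == 0) || any(apply(Y, 2, stats::sd) == 0)) {
    stop("constant column: canonical correlations undefined")
  }
  cc <- stats::cancor(X, Y)
  rho <- sort(pmin(pmax(cc$cor, 0), 1), decreasing = TRUE)
  full <- min(p, q)
  if (length(rho) < full) {
    warning("rank deficiency: only ", length(rho),
            " canonical correlation(s) available (expected ", full, ")")
  }
  list(cor = rho, n = n, p = p, q = q)
}

#' Wilks' Lambda test of association between two feature blocks
#'
#' Tests independence of two multivariate blocks through
#' \eqn{\Lambda = \prod_i (1 - \rho_i^2)} over the canonical correlations,
#' using Rao's F approximation (exact when \eqn{\min(p, q) \le 2}). The
#' returned row mirrors the usual reporting shape: F statistic, degrees of
#' freedom, p-value, and the leading canonical correlation.
#'
#' @inheritParams canonical_correlations
#' @return list with \code{lambda}, \code{F}, \code{df1}, \code{df2},
#'   \code{p_value}, \code{rho} (leading canonical correlation), \code{n}.
#' @export
wilks_lambda_test <- function(X, Y) {
  cc <- canonical_correlations(X, Y)
  n <- cc$n; p <- cc$p; q <- cc$q
  if (n <= p + q) {
    stop("Wilks' F approximation needs n > p + q (got n = ", n,
         ", p + q = ", p + q, ")")
  }
  lambda <- prod(1 - cc$cor^2)
  # Rao's approximation with hypothesis df q and error df n - 1 - q
  t_exp <- if (p^2 + q^2 - 5 > 0) {
    sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
  } else 1
  df1 <- p * q
  w <- (n - 1 - q) + q - (p + q + 1) / 2
  df2 <- w * t_exp - (p * q - 2) / 2
  lam_t <- lambda^(1 / t_exp)
  Fstat <- if (lambda <= 0) Inf else (1 - lam_t) / lam_t * df2 / df1
  p_val <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2, p_value = p_val,
       rho = cc$cor[1], n = n)
}

#' Pairwise Pearson correlation screen between two blocks
#'
#' Pairwise correlations between the columns of two blocks with
#' significance stars at the usual figure thresholds (* p < 0.05,
#' ** p < 0.01, *** p < 0.001). A constant column yields \code{NA} entries
#' flagged in the output.
#'
#' @inheritParams canonical_correlations
#' @return list with \code{r} (correlation matrix, rows = columns of
#'   \code{X}), \code{p} (p-value matrix), \code{stars} (character matrix),
#'   \code{n} (complete rows per pair).
#' @export
correlation_screen <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("'X' and 'Y' must have the same rows")
  p <- ncol(X); q <- ncol(Y)
  r <- pv <- matrix(NA_real_, p, q,
                    dimnames = list(colnames(X), colnames(Y)))
  nmat <- matrix(0L, p, q)
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      ok <- is.finite(X[, i]) & is.finite(Y[, j])
      nmat[i, j] <- sum(ok)
      if (sum(ok) < 3 || stats::sd(X[ok, i]) == 0 || stats::sd(Y[ok, j]) == 0) {
        next  # undefined entry stays NA
      }
      ct <- stats::cor.test(X[ok, i], Y[ok, j])
      r[i, j] <- unname(ct$estimate)
      pv[i, j] <- ct$p.value
    }
  }
  stars <- matrix("", p, q, dimnames = dimnames(r))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  stars[!is.na(pv) & pv < 0.001] <- "***"
  stars[is.na(pv)] <- "undefined"
  list(r = r, p = pv, stars = stars, n = nmat)
}
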