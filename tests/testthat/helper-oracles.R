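# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Hypergeometric pmf by exhaustive enumeration of unordered draws: label
# the N remaining cells (first K malignant) and count the m-subsets with
# exactly k malignant members.
enum_detection_pmf <- function(k, m, N, K) {
  if (m == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, m)
  mean(apply(draws, 2, function(d) sum(d <= K) == k))
}

# Exact posterior over the {0,1}^(p+1) coefficient vertices with sigma^2
# marginalized under the Jeffreys prior.
enum_literal_posterior <- function(y, X) {
  p <- ncol(X)
  verts <- as.matrix(expand.grid(rep(list(0:1), p + 1)))
  lp <- apply(verts, 1, function(v) {
    -length(y) / 2 * log(max(sum((y - cbind(1, X) %*% v)^2), 1e-12))
  })
  post <- exp(lp - max(lp))
  list(verts = verts, prob = post / sum(post))
}

# Dense grid argmax of the fixed-lambda growth likelihood.
grid_mle_two_par <- function(traj, lambda, by = 1) {
  M_T <- traj$M[traj$n_steps]
  Ms_T <- traj$M_star[traj$n_steps]
  best <- c(ll = -Inf, nu = NA, nu_star = NA)
  for (nu in seq(M_T + 0.5, 3 * M_T, by = by)) {
    for (ns in seq(Ms_T + 0.5, nu - (M_T - Ms_T), by = by)) {
      ll <- growth_loglik(traj, growth_params(nu, ns, lambda))
      if (ll > best[1]) best <- c(ll = ll, nu = nu, nu_star = ns)
    }
  }
  best
}

# Wilks' Lambda as a determinant ratio from the multivariate regression
# error and hypothesis SSCP matrices.
det_ratio_lambda <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  P <- Yc %*% solve(crossprod(Yc)) %*% t(Yc)
  H <- t(Xc) %*% P %*% Xc
  E <- crossprod(Xc) - H
  det(E) / det(E + H)
}

make_trajectory <- function(seed = 1, n_steps = 5,
                            params = growth_params(200, 80, 0.08, 2)) {
  simulate_trajectory(params, n_steps = n_steps, seed = seed)
}
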