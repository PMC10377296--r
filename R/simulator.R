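#' Simulation configuration for synthetic cohorts
#'
#' Ranges from which per-subject growth parameters are drawn uniformly. The
#' defaults describe a realistic spread of tumor cell populations and
#' per-step proliferation rates for a cohort of the study's size
#' (102 subjects).
#'
#' @param n_subjects cohort size.
#' @param nu_range range of the total population size \eqn{\nu}.
#' @param nu_star_frac_range range of the malignant fraction
#'   \eqn{\nu^*/\nu}.
#' @param lambda_range range of the proliferation rate \eqn{\lambda}.
#' @param lambda_star_range range of the prior rate \eqn{\lambda^*}.
#' @param n_steps_range integer range of migration-step counts.
#' @param voxel_increment_range integer range of incremental region sizes.
#' @param seed master seed.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_subjects = 102L,
                              nu_range = c(500, 10000),
                              nu_star_frac_range = c(0.2, 0.8),
                              lambda_range = c(0.01, 0.2),
                              lambda_star_range = c(1.1, 3),
                              n_steps_range = c(3L, 12L),
                              voxel_increment_range = c(50L, 500L),
                              seed = 1L) {
  ranges <- list(nu_range = nu_range, nu_star_frac_range = nu_star_frac_range,
                 lambda_range = lambda_range,
                 lambda_star_range = lambda_star_range,
                 n_steps_range = n_steps_range,
                 voxel_increment_range = voxel_increment_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[2] < r[1]) {
      stop("invalid range for ", nm)
    }
  }
  if (n_subjects < 0) stop("'n_subjects' must be nonnegative")
  structure(c(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
              ranges),
            class = "simulation_config")
}

#' Simulate one detection trajectory from the growth model
#'
#' Generative reading of the detection likelihood: at each step the total
#' count is drawn from the configured Poisson (capped at the remaining
#' population so the trajectory stays feasible) and the malignant split is
#' drawn from the hypergeometric law over the remaining cells. If the
#' population is exhausted before the requested number of steps the
#' trajectory is truncated and flagged.
#'
#' @param params a \code{\link{growth_params}} (with \code{lambda_star} used
#'   only by downstream estimation, not by simulation).
#' @param n_steps requested number of migration steps.
#' @param seed integer seed; the trajectory is fully reproducible from it.
#' @param mode Poisson-mean convention, see \code{\link{proliferation_pmf}}.
#' @param v_initial optional initial volume attached to the trajectory.
#' @param voxel_increment_range integer range for \eqn{|\Delta R(t)|}.
#' @return a \code{\link{cell_trajectory}}.
#' @export
simulate_trajectory <- function(params, n_steps, seed = NULL,
                                mode = c("literal", "depleted"),
                                v_initial = NULL,
                                voxel_increment_range = c(50L, 500L)) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "growth_params"), n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  nu <- params$nu
  nu_star <- params$nu_star
  m <- ms <- dv <- numeric(0)
  M <- Ms <- 0
  truncated <- FALSE
  for (t in seq_len(n_steps)) {
    N <- nu - M
    K <- nu_star - Ms
    if (N < 1) { truncated <- TRUE; break }
    mu <- if (mode == "literal") nu * params$lambda else N * params$lambda
    mt <- min(stats::rpois(1, mu), floor(N))
    # a zero-detection step is allowed; the malignant split needs mt >= 0
    kt <- if (mt > 0) {
      stats::rhyper(1, floor(K), floor(N) - floor(K), mt)
    } else 0
    m <- c(m, mt); ms <- c(ms, kt)
    dv <- c(dv, sample(seq(voxel_increment_range[1], voxel_increment_range[2]), 1))
    M <- M + mt; Ms <- Ms + kt
  }
  if (length(m) == 0L) {
    stop("population exhausted before the first step")
  }
  cell_trajectory(m, ms, dv, v_initial = v_initial, truncated = truncated)
}

#' Simulate a cohort of detection trajectories
#'
#' Draws per-subject growth parameters uniformly from the configured
#' ranges and simulates one trajectory per subject. Each subject gets a
#' deterministic sub-seed derived from the master seed, so the cohort is
#' byte-identical across runs with the same configuration.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param mode Poisson-mean convention.
#' @return list with \code{subjects} (list of lists: \code{id},
#'   \code{trajectory}, \code{v_initial}, \code{true_params}, \code{seed})
#'   and \code{config}.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            mode = c("literal", "depleted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  if (n == 0L) return(list(subjects = list(), config = config))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  nu <- stats::runif(n, config$nu_range[1], config$nu_range[2])
  frac <- stats::runif(n, config$nu_star_frac_range[1],
                       config$nu_star_frac_range[2])
  lambda <- stats::runif(n, config$lambda_range[1], config$lambda_range[2])
  lambda_star <- stats::runif(n, config$lambda_star_range[1],
                              config$lambda_star_range[2])
  n_steps <- sample(seq(config$n_steps_range[1], config$n_steps_range[2]),
                    n, replace = TRUE)
  # initial volumes lognormal: heavy right tail like observed ROI volumes
  v_init <- stats::rlnorm(n, meanlog = log(3e4), sdlog = 0.8)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    p <- growth_params(nu[i], frac[i] * nu[i], lambda[i], lambda_star[i])
    traj <- simulate_trajectory(
      p, n_steps = n_steps[i], seed = sub_seeds[i], mode = mode,
      v_initial = v_init[i],
      voxel_increment_range = config$voxel_increment_range)
    subjects[[i]] <- list(id = sprintf("subj%03d", i), trajectory = traj,
                          v_initial = v_init[i], true_params = p,
                          seed = sub_seeds[i])
  }
  list(subjects = subjects, config = config)
}
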