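#' Run the growth-analysis pipeline
#'
#' Orchestrates the stage chain simulate -> fit -> predict -> regress ->
#' compare on a synthetic cohort, writing each stage's outputs in the
#' documented formats under \code{out_dir}. Every output embeds a
#' provenance block (package version, seed, config checksum); no
#' timestamps, so a seeded run is byte-identical across invocations.
#'
#' Subjects whose fitted prior means fall below the validity bound of the
#' weighted prior (remaining malignant count times \eqn{\lambda^*} not
#' exceeding 1) cannot be given a posterior; they are recorded with
#' \code{NA} predictions and counted in the returned summary.
#'
#' @param config list with entries \code{out_dir}, \code{seed},
#'   \code{n_subjects}, \code{stages} (subset of \code{c("simulate",
#'   "fit", "predict", "regress", "compare")}, run in that order),
#'   \code{mode} (Poisson-mean convention), \code{r} (geometric exponent),
#'   \code{c} (volume proportionality), \code{discrete} (round volumes),
#'   \code{folds}. Missing entries take the defaults of
#'   \code{\link{pipeline_config}}.
#' @return invisibly, a list with the per-stage results: \code{fixture},
#'   \code{predictions} (data.frame), \code{regression},
#'   \code{comparison}, \code{n_failed}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- utils::modifyList(pipeline_config(), config)
  stages <- match.arg(config$stages,
                      c("simulate", "fit", "predict", "regress", "compare"),
                      several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(
    package = "gbmgrowth",
    version = as.character(utils::packageVersion("gbmgrowth")),
    seed = config$seed,
    config_md5 = config_checksum(config))
  result <- list(provenance = provenance)

  fixture_dir <- file.path(config$out_dir, "fixture")
  if ("simulate" %in% stages) {
    sim_cfg <- simulation_config(n_subjects = config$n_subjects,
                                 seed = config$seed)
    result$fixture <- generate_cohort_fixture(fixture_dir, sim_cfg)
    message("simulate: wrote cohort fixture for ", config$n_subjects,
            " subject(s)")
  }

  if (any(c("fit", "predict") %in% stages)) {
    traj_dir <- file.path(fixture_dir, "trajectories")
    if (!dir.exists(traj_dir)) {
      stop("missing input: ", traj_dir,
           " (run the 'simulate' stage or point 'out_dir' at a fixture)")
    }
    files <- sort(list.files(traj_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      warning("empty cohort: nothing to fit")
      result$predictions <- data.frame()
    } else {
      rows <- vector("list", length(files))
      n_failed <- 0L
      for (i in seq_along(files)) {
        traj <- read_trajectory_csv(files[i])
        id <- sub("\\.csv$", "", basename(files[i]))
        fit <- growth_fit(traj, mode = config$mode)
        pred <- tryCatch(
          predict(fit, c = config$c, discrete = config$discrete,
                  r = config$r),
          error = function(e) NULL)
        if (is.null(pred)) {
          n_failed <- n_failed + 1L
          rows[[i]] <- data.frame(
            id = id, nu = fit$params$nu, nu_star = fit$params$nu_star,
            lambda = fit$params$lambda,
            lambda_star = fit$params$lambda_star,
            v_initial = traj$v_initial, posterior_mean = NA_real_,
            v_new = NA_real_, p_min = NA_real_, p_final = NA_real_)
        } else {
          pmin_t <- min(pred$p_no_undetected)
          rows[[i]] <- data.frame(
            id = id, nu = fit$params$nu, nu_star = fit$params$nu_star,
            lambda = fit$params$lambda,
            lambda_star = fit$params$lambda_star,
            v_initial = traj$v_initial,
            posterior_mean = pred$posterior$posterior_mean,
            v_new = pred$v_new, p_min = pmin_t,
            p_final = pred$p_no_undetected[length(pred$p_no_undetected)])
        }
      }
      preds <- do.call(rbind, rows)
      result$predictions <- preds
      result$n_failed <- n_failed
      if ("predict" %in% stages) {
        utils::write.csv(format(preds, digits = 17),
                         file.path(config$out_dir, "predictions.csv"),
                         row.names = FALSE, quote = FALSE)
        jsonlite::write_json(
          list(provenance = provenance, n_failed = n_failed,
               subjects = preds),
          file.path(config$out_dir, "predictions.json"),
          auto_unbox = TRUE, digits = NA, dataframe = "rows")
        message("predict: ", nrow(preds) - n_failed, " subject(s) predicted, ",
                n_failed, " failed the prior validity bound")
      }
    }
  }

  if (any(c("regress", "compare") %in% stages)) {
    fpath <- file.path(fixture_dir, "features.csv")
    if (!file.exists(fpath)) {
      stop("missing input: ", fpath, " (run the 'simulate' stage first)")
    }
    features <- utils::read.csv(fpath)
    required <- c(paste0("volume_", c("WT", "ED", "TC", "NET", "ET")),
                  "survival_years", "age")
    miss <- setdiff(required, names(features))
    if (length(miss)) {
      stop("feature table ", fpath, " lacks column(s): ",
           paste(miss, collapse = ", "))
    }
    endo_cols <- grep("^(volume|spatial|histology|morphology)_",
                      names(features), value = TRUE)
    exo_cols <- c("survival_years", "age")

    if ("regress" %in% stages) {
      preds <- result$predictions
      if (is.null(preds) || nrow(preds) == 0L) {
        stop("the 'regress' stage needs predictions from the 'fit' stage")
      }
      n <- min(nrow(preds), nrow(features))
      ok <- which(is.finite(preds$v_new[seq_len(n)]))
      sem_endo <- fit_sem_measurement(features[ok, endo_cols], d = 1,
                                      seed = config$seed)
      sem_exo <- fit_sem_measurement(features[ok, exo_cols,
                                              drop = FALSE], d = 1,
                                     seed = config$seed)
      reg <- fit_bayes_regression(preds$v_new[ok],
                                  covariates = NULL,
                                  sem = list(sem_endo, sem_exo),
                                  seed = config$seed)
      adj <- predict_with_covariates(reg, v_initial = preds$v_initial[ok],
                                     r = config$r)
      result$regression <- list(fit = reg, adjusted = adj,
                                subjects = preds$id[ok])
      jsonlite::write_json(
        list(provenance = provenance,
             posterior_mean_coefficients = as.list(coef(reg)),
             inclusion = as.list(stats::setNames(reg$inclusion,
                                                 reg$coef_names[-1])),
             min_adjusted_probability = min(adj$p_no_undetected,
                                            na.rm = TRUE)),
        file.path(config$out_dir, "regression.json"),
        auto_unbox = TRUE, digits = NA)
      message("regress: fitted Bayesian regression on ", length(ok),
              " subject(s)")
    }

    if ("compare" %in% stages) {
      rois <- c(ED = "y_ED", ET = "y_ET", NET = "y_NET", TC = "y_TC",
                WT = "y_WT")
      rois <- rois[rois %in% names(features)]
      if (length(rois) == 0L) stop("feature table has no response columns")
      cmp <- model_comparison(features, rois,
                              covariate_cols = c(endo_cols, exo_cols),
                              folds = config$folds, seed = config$seed)
      result$comparison <- cmp
      utils::write.csv(format(cmp, digits = 17),
                       file.path(config$out_dir, "comparison.csv"),
                       row.names = FALSE, quote = FALSE)
      message("compare: wrote comparison table for ",
              nrow(cmp), " ROI(s)")
    }
  }

  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' @rdname run_pipeline
#' @export
pipeline_config <- function() {
  list(out_dir = file.path(tempdir(), "gbmgrowth-run"),
       seed = 1L,
       n_subjects = 102L,
       stages = c("simulate", "fit", "predict"),
       mode = "literal",
       r = 2L,
       c = 1,
       discrete = FALSE,
       folds = 5L)
}

config_checksum <- function(config) {
  config$out_dir <- NULL  # path-independent provenance
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
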