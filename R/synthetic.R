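# Default marginal targets for the synthetic radiomic feature table:
# means/SDs on the scale of an adult GBM cohort (volumes in mm^3, spatial
# and histology scores unitless, survival in years).
feature_targets <- function() {
  list(
    volumes = data.frame(
      roi = c("WT", "ED", "TC", "NET", "ET"),
      mean = c(107999.84, 62139.61, 45560.24, 15578.29, 29981.94),
      sd = c(52700.74, 35360.39, 31424.16, 17475.42, 22104.20)),
    spatial = data.frame(
      name = c("frontal", "temporal", "occipital", "insula", "fornix",
               "parietal", "brain_stem"),
      mean = c(25.64, 42.39, 4.22, 2.95, 1.19, 18.34, 0.25),
      sd = c(35.69, 38.89, 14.13, 5.76, 3.04, 29.50, 0.71)),
    histology = data.frame(
      name = c("occipital_cortex", "temporal_cortex", "basal_ganglia"),
      mean = c(0.375, 0.146, 0.681),
      sd = c(0.8097, 0.3546, 1.508)),
    morphology = data.frame(
      name = c("eccentricity", "solidity"),
      mean = c(0.68, 0.40),
      sd = c(0.09, 0.14)),
    survival = c(mean = 1.5, sd = 1.4),
    age = c(mean = 58, sd = 12))
}

#' Generate a synthetic radiomic feature table
#'
#' Builds a subject-by-feature table with the structure of a GBM radiomics
#' cohort: ROI volumes (whole tumor, edema, tumor core, non-enhancing and
#' GD-enhancing tumor), spatial and histology scores, morphology, survival
#' length and age. All radiomic manifests load on one endogenous latent
#' factor and the clinical variables (survival, age) on one exogenous
#' factor, so correlations between features are induced only through the
#' latent structure. Marginal means and SDs match the configured targets:
#' volumes are lognormal (respecting nonnegativity and the large observed
#' SDs, via a Gaussian copula on the latent factor), survival is
#' moment-matched gamma, other features Gaussian.
#'
#' The response columns \code{y_<ROI>} are eventual volumes generated
#' linearly from the two latent factors plus noise, providing ground truth
#' for regression recovery.
#'
#' @param n number of subjects.
#' @param loading common loading of the radiomic manifests on the
#'   endogenous factor (0 < loading < 1).
#' @param noise_sd scale of the unique (non-factor) variation; 1 keeps the
#'   marginal SDs at their targets, 0 makes every manifest an exact linear
#'   function of its factor.
#' @param reg_truth list with \code{alpha}, \code{b1}, \code{b2},
#'   \code{sigma}: response = roi mean x (alpha + b1 eta1 + b2 eta2 +
#'   sigma noise).
#' @param miss_prob probability that any one radiomic entry is missing.
#' @param targets marginal targets, see \code{gbmgrowth:::feature_targets}.
#' @param seed integer seed.
#' @return a data.frame with attribute \code{"truth"} (latent scores,
#'   loadings, regression coefficients).
#' @export
generate_feature_table <- function(n = 102L, loading = 0.7, noise_sd = 1,
                                   reg_truth = list(alpha = 2, b1 = 0.8,
                                                    b2 = 0.4, sigma = 0.1),
                                   miss_prob = 0, targets = feature_targets(),
                                   seed = 1L) {
  stopifnot(n >= 1, loading > 0, loading < 1, noise_sd >= 0)
  set.seed(seed)
  eta1 <- stats::rnorm(n)   # endogenous radiomic factor
  eta2 <- stats::rnorm(n)   # exogenous clinical factor

  # standardized manifest: loading * eta + scaled unique error, unit variance
  manifest_z <- function(eta, a) {
    u <- noise_sd * sqrt(1 - a^2)
    (a * eta + u * stats::rnorm(n)) / sqrt(a^2 + u^2)
  }

  out <- data.frame(subject_id = sprintf("subj%03d", seq_len(n)))
  for (i in seq_len(nrow(targets$volumes))) {
    mu <- targets$volumes$mean[i]; sd <- targets$volumes$sd[i]
    s2 <- log(1 + (sd / mu)^2)
    z <- manifest_z(eta1, loading)
    out[[paste0("volume_", targets$volumes$roi[i])]] <-
      exp(log(mu) - s2 / 2 + sqrt(s2) * z)
  }
  for (i in seq_len(nrow(targets$spatial))) {
    out[[paste0("spatial_", targets$spatial$name[i])]] <-
      targets$spatial$mean[i] + targets$spatial$sd[i] * manifest_z(eta1, loading)
  }
  for (i in seq_len(nrow(targets$histology))) {
    out[[paste0("histology_", targets$histology$name[i])]] <-
      targets$histology$mean[i] +
      targets$histology$sd[i] * manifest_z(eta1, loading)
  }
  for (i in seq_len(nrow(targets$morphology))) {
    out[[paste0("morphology_", targets$morphology$name[i])]] <-
      targets$morphology$mean[i] +
      targets$morphology$sd[i] * manifest_z(eta1, loading)
  }
  # survival: gamma marginal via Gaussian copula on the exogenous factor
  sv <- targets$survival
  shape <- (sv["mean"] / sv["sd"])^2
  rate <- sv["mean"] / sv["sd"]^2
  out$survival_years <- unname(stats::qgamma(
    stats::pnorm(manifest_z(eta2, loading)), shape = shape, rate = rate))
  out$age <- unname(targets$age["mean"] +
                      targets$age["sd"] * manifest_z(eta2, loading))

  for (i in seq_len(nrow(targets$volumes))) {
    roi <- targets$volumes$roi[i]
    out[[paste0("y_", roi)]] <- targets$volumes$mean[i] *
      (reg_truth$alpha + reg_truth$b1 * eta1 + reg_truth$b2 * eta2 +
         reg_truth$sigma * stats::rnorm(n))
  }

  if (miss_prob > 0) {
    radiomic_cols <- grep("^(volume|spatial|histology|morphology)_", names(out))
    for (j in radiomic_cols) {
      drop <- stats::runif(n) < miss_prob
      out[[j]][drop] <- NA_real_
    }
  }
  attr(out, "truth") <- list(eta1 = eta1, eta2 = eta2, loading = loading,
                             reg_truth = reg_truth, seed = seed)
  out
}

#' Generate a multimodal 3-D phantom with an ellipsoidal lesion
#'
#' Synthetic stand-in for a preprocessed multimodal MRI study: a brain-like
#' tissue ellipsoid with a CSF-like inclusion on a dark background, plus an
#' ellipsoidal lesion whose contrast over tissue differs per modality
#' (strongest on T1-Gd and FLAIR, as for an enhancing GBM). Gaussian noise
#' is added at \code{noise_sd} intensity units. The ground-truth lesion
#' mask is returned alongside the volume.
#'
#' @param shape integer vector of array dimensions.
#' @param center lesion centre (voxel coordinates).
#' @param radii lesion semi-axes in voxels.
#' @param contrast named intensity increment of the lesion over tissue per
#'   modality.
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param spacing voxel spacing in mm.
#' @param seed integer seed.
#' @return list with \code{volume} (a \code{\link{multimodal_volume}}) and
#'   \code{truth} (a \code{\link{tumor_mask}}).
#' @export
generate_phantom <- function(shape = c(40L, 40L, 28L),
                             center = shape / 2 + c(4, -3, 1),
                             radii = c(8, 6, 5),
                             contrast = c(T1 = 40, T1Gd = 100, T2 = 80,
                                          FLAIR = 90),
                             noise_sd = 0, spacing = c(1, 1, 1), seed = 1L) {
  stopifnot(length(shape) == 3L, all(radii > 0))
  if (any(center - radii < 1) || any(center + radii > shape)) {
    stop("lesion extends outside the volume bounds")
  }
  set.seed(seed)
  ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
  ellipsoid <- function(ctr, rad) {
    dx2 <- ((ax - ctr[1]) / rad[1])^2
    dy2 <- ((ay - ctr[2]) / rad[2])^2
    dz2 <- ((az - ctr[3]) / rad[3])^2
    outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  }
  brain <- ellipsoid(shape / 2, shape / 2 - 2)
  csf <- ellipsoid(shape / 2 - c(6, 5, 2), pmax(shape / 10, 2))
  lesion <- ellipsoid(center, radii)
  base <- array(10, shape)          # air
  base[brain] <- 100                # tissue
  base[csf & brain] <- 60           # CSF-like
  mods <- lapply(c(T1 = "T1", T1Gd = "T1Gd", T2 = "T2", FLAIR = "FLAIR"),
                 function(nm) {
    v <- base
    v[lesion] <- 100 + contrast[[nm]]
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
    v
  })
  vol <- multimodal_volume(mods$T1, mods$T1Gd, mods$T2, mods$FLAIR,
                           spacing = spacing)
  list(volume = vol, truth = tumor_mask(lesion, spacing))
}

#' Generate a reproducible cohort fixture directory
#'
#' Bundles a simulated trajectory cohort, a synthetic radiomic feature
#' table and (optionally) multimodal phantoms into one directory:
#' \code{manifest.json}, \code{trajectories/*.csv}, \code{features.csv},
#' \code{truth.json} and \code{phantoms/*.nii.gz}. The manifest records the
#' seed and the MD5 checksum of every file, so identical seeds give
#' identical manifests.
#'
#' @param dir output directory (created if needed).
#' @param config a \code{\link{simulation_config}}.
#' @param with_phantom also write one multimodal phantom per the first
#'   \code{n_phantoms} subjects.
#' @param n_phantoms number of phantoms when \code{with_phantom}.
#' @param seed master seed (overrides the one in \code{config}).
#' @return invisibly, a list with \code{dir}, \code{manifest} (parsed) and
#'   \code{manifest_md5}.
#' @export
generate_cohort_fixture <- function(dir, config = simulation_config(),
                                    with_phantom = FALSE, n_phantoms = 1L,
                                    seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(file.path(dir, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  traj_files <- character(0)
  for (s in cohort$subjects) {
    f <- file.path(dir, "trajectories", paste0(s$id, ".csv"))
    write_trajectory_csv(s$trajectory, f)
    traj_files <- c(traj_files, f)
  }
  features <- generate_feature_table(n = max(config$n_subjects, 1L),
                                     seed = config$seed)
  features <- features[seq_len(config$n_subjects), , drop = FALSE]
  fpath <- file.path(dir, "features.csv")
  utils::write.csv(features, fpath, row.names = FALSE)

  truth <- list(
    subjects = lapply(cohort$subjects, function(s) {
      c(list(id = s$id, seed = s$seed, v_initial = s$v_initial),
        unclass(s$true_params))
    }),
    feature_truth = attr(features, "truth")[c("loading", "reg_truth", "seed")])
  tpath <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tpath, auto_unbox = TRUE, digits = NA)

  phantom_files <- character(0)
  if (with_phantom) {
    dir.create(file.path(dir, "phantoms"), showWarnings = FALSE)
    for (i in seq_len(n_phantoms)) {
      ph <- generate_phantom(seed = config$seed + i)
      for (nm in names(ph$volume$modalities)) {
        f <- file.path(dir, "phantoms",
                       sprintf("phantom%02d_%s.nii.gz", i, nm))
        write_nifti_volume(ph$volume$modalities[[nm]], f,
                           spacing = ph$volume$spacing)
        phantom_files <- c(phantom_files, f)
      }
      f <- file.path(dir, "phantoms", sprintf("phantom%02d_truth.nii.gz", i))
      write_nifti_volume(ph$truth$mask * 1, f, spacing = ph$truth$spacing)
      phantom_files <- c(phantom_files, f)
    }
  }

  files <- c(traj_files, fpath, tpath, phantom_files)
  rel <- sub(paste0("^", normalizePath(dir), "/?"), "",
             normalizePath(files))
  sums <- unname(tools::md5sum(files))
  manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                   files = stats::setNames(as.list(sums), rel))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, manifest = manifest,
                 manifest_md5 = unname(tools::md5sum(mpath))))
}
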