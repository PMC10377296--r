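#' Write / read growth-model results as JSON
#'
#' Serializes a fitted growth model and its volume prediction with full
#' numeric precision (17 significant digits). Keys: \code{nu},
#' \code{nu_star}, \code{lambda}, \code{lambda_star}, \code{step_weights},
#' \code{posterior_mean}, \code{v_initial}, \code{v_new},
#' \code{p_no_undetected}, \code{convergence}.
#'
#' @param fit a \code{\link{growth_fit}}.
#' @param prediction result of \code{\link{predict.growth_fit}}; computed
#'   here when omitted and the trajectory carries an initial volume.
#' @param path output file.
#' @return \code{write_growth_json} returns \code{path} invisibly;
#'   \code{read_growth_json} returns the parsed list.
#' @export
write_growth_json <- function(fit, path, prediction = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.null(prediction) && !is.null(fit$trajectory$v_initial)) {
    prediction <- predict(fit)
  }
  out <- list(nu = fit$params$nu, nu_star = fit$params$nu_star,
              lambda = fit$params$lambda,
              lambda_star = fit$params$lambda_star,
              convergence = fit$convergence)
  if (!is.null(prediction)) {
    out$step_weights <- prediction$posterior$step_weights
    out$posterior_mean <- prediction$posterior$posterior_mean
    out$v_initial <- fit$trajectory$v_initial
    out$v_new <- prediction$v_new
    out$p_no_undetected <- prediction$p_no_undetected
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_growth_json
#' @export
read_growth_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read / write a 3-D volume as NIfTI
#'
#' Thin wrappers over RNifti preserving voxel spacing. Masks round-trip as
#' 0/1 arrays.
#'
#' @param path a .nii or .nii.gz file.
#' @param data 3-D numeric array.
#' @param spacing voxel spacing in mm.
#' @return \code{read_nifti_volume}: list with \code{data} (array) and
#'   \code{spacing}; \code{write_nifti_volume}: \code{path} invisibly.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname read_nifti_volume
#' @export
write_nifti_volume <- function(data, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(data, dim = dim(data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
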