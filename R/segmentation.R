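#' Multimodal MRI volume
#'
#' Bundle of co-registered 3-D intensity arrays for the four standard
#' modalities (T1, T1-Gd, T2, FLAIR) sharing one shape and voxel spacing.
#'
#' @param t1,t1gd,t2,flair 3-D numeric arrays of identical dimensions.
#' @param spacing voxel spacing in mm (length 3, positive).
#' @param orientation free-form orientation tag (recorded, not enforced).
#' @return an object of class \code{multimodal_volume}.
#' @export
multimodal_volume <- function(t1, t1gd, t2, flair, spacing = c(1, 1, 1),
                              orientation = "LPS") {
  mods <- list(T1 = t1, T1Gd = t1gd, T2 = t2, FLAIR = flair)
  d <- dim(mods[[1]])
  if (length(d) != 3L) stop("modalities must be 3-D arrays")
  for (nm in names(mods)) {
    if (!identical(dim(mods[[nm]]), d)) {
      stop("modality ", nm, " does not share the common shape")
    }
    if (any(!is.finite(mods[[nm]]))) stop("modality ", nm,
                                          " contains non-finite intensities")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("'spacing' must be three positive mm values")
  }
  structure(list(modalities = mods, spacing = as.numeric(spacing),
                 orientation = orientation),
            class = "multimodal_volume")
}

#' Binary tumor mask
#'
#' @param mask logical (or 0/1) 3-D array.
#' @param spacing voxel spacing in mm.
#' @return an object of class \code{tumor_mask} with elements \code{mask}
#'   (logical array), \code{spacing}, \code{n_components}.
#' @export
tumor_mask <- function(mask, spacing = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  m <- array(as.logical(mask), dim = dim(mask))
  if (any(is.na(m))) stop("mask values must be 0/1")
  structure(list(mask = m, spacing = as.numeric(spacing),
                 n_components = n_components_3d(m)),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat("Tumor mask:", paste(dim(x$mask), collapse = "x"), "voxels,",
      sum(x$mask), "in mask,", x$n_components, "component(s)\n")
  invisible(x)
}

# ---- 3-D binary morphology (vectorised array shifts) ----

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

shift_array <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
  out
}

dilate_3d <- function(mask, radius = 1L) {
  off <- ball_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_array(mask, off$dx[i], off$dy[i], off$dz[i])
  }
  out
}

erode_3d <- function(mask, radius = 1L) {
  off <- ball_offsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_array(mask, off$dx[i], off$dy[i], off$dz[i])
  }
  out
}

# 6-connected component labelling by vectorised frontier expansion
label_components_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  if (!any(mask)) return(labels)
  nx <- d[1]; nxy <- d[1] * d[2]
  idx_all <- which(mask)
  coords <- arrayInd(idx_all, d)
  # neighbor linear offsets; boundary crossings filtered via coordinates
  current <- 0L
  visited <- array(FALSE, d)
  for (start in idx_all) {
    if (visited[start]) next
    current <- current + 1L
    frontier <- start
    visited[start] <- TRUE
    labels[start] <- current
    while (length(frontier)) {
      ci <- arrayInd(frontier, d)
      nbrs <- rbind(
        cbind(ci[, 1] - 1L, ci[, 2], ci[, 3]),
        cbind(ci[, 1] + 1L, ci[, 2], ci[, 3]),
        cbind(ci[, 1], ci[, 2] - 1L, ci[, 3]),
        cbind(ci[, 1], ci[, 2] + 1L, ci[, 3]),
        cbind(ci[, 1], ci[, 2], ci[, 3] - 1L),
        cbind(ci[, 1], ci[, 2], ci[, 3] + 1L))
      keep <- nbrs[, 1] >= 1L & nbrs[, 1] <= d[1] &
        nbrs[, 2] >= 1L & nbrs[, 2] <= d[2] &
        nbrs[, 3] >= 1L & nbrs[, 3] <= d[3]
      nbrs <- nbrs[keep, , drop = FALSE]
      lin <- nbrs[, 1] + (nbrs[, 2] - 1L) * nx + (nbrs[, 3] - 1L) * nxy
      lin <- unique(lin[mask[lin] & !visited[lin]])
      visited[lin] <- TRUE
      labels[lin] <- current
      frontier <- lin
    }
  }
  labels
}

n_components_3d <- function(mask) {
  max(label_components_3d(mask))
}

largest_component_3d <- function(mask) {
  labels <- label_components_3d(mask)
  if (max(labels) == 0L) return(mask & FALSE)
  counts <- tabulate(labels[labels > 0L])
  labels == which.max(counts)
}

#' Morphological cleaning of a binary tumor mask
#'
#' Binary opening (erosion then dilation) followed by closing (dilation
#' then erosion) with a ball structuring element, then retention of the
#' largest 6-connected component. Opening removes speckle smaller than the
#' ball; closing fills comparable holes.
#'
#' @param mask a \code{\link{tumor_mask}} or logical 3-D array.
#' @param radius_voxels ball radius in voxels (>= 1).
#' @return a \code{\link{tumor_mask}}.
#' @export
morphological_clean <- function(mask, radius_voxels = 1L) {
  if (radius_voxels < 1) stop("'radius_voxels' must be at least 1")
  spacing <- c(1, 1, 1)
  m <- mask
  if (inherits(mask, "tumor_mask")) { m <- mask$mask; spacing <- mask$spacing }
  opened <- dilate_3d(erode_3d(m, radius_voxels), radius_voxels)
  closed <- erode_3d(dilate_3d(opened, radius_voxels), radius_voxels)
  tumor_mask(largest_component_3d(closed), spacing)
}

#' Two-step K-means tumor localization on multimodal MRI
#'
#' Step 1 clusters each modality's intensities with K-means and flags the
#' highest-mean cluster as that modality's lesion candidate (gadolinium
#' enhancement and FLAIR hyperintensity make the lesion the brightest
#' tissue class). Step 2 fuses the per-modality candidate maps by
#' voxel-wise voting (a voxel is kept when at least \code{fuse_min}
#' modalities flag it) and applies morphological cleaning. Deterministic
#' given \code{seed}.
#'
#' @param vol a \code{\link{multimodal_volume}}.
#' @param k number of intensity clusters per modality (default 4:
#'   background, CSF-like, tissue-like, lesion-like).
#' @param seed integer seed for the K-means initialization.
#' @param fuse_min minimum number of modality votes to keep a voxel.
#' @param clean_radius ball radius for \code{\link{morphological_clean}}.
#' @return a \code{\link{tumor_mask}}.
#' @export
localize_tumor <- function(vol, k = 4L, seed = 1L, fuse_min = 2L,
                           clean_radius = 1L) {
  stopifnot(inherits(vol, "multimodal_volume"))
  if (k < 2) stop("'k' must be at least 2")
  d <- dim(vol$modalities[[1]])
  votes <- array(0L, d)
  n_usable <- 0L
  for (j in seq_along(vol$modalities)) {
    v <- as.vector(vol$modalities[[j]])
    n_distinct <- length(unique(v))
    if (n_distinct < 2L) next  # constant modality carries no contrast
    k_eff <- min(k, n_distinct)
    set.seed(seed + j)
    km <- stats::kmeans(v, centers = k_eff, iter.max = 100L, nstart = 5L)
    lesion_cluster <- which.max(km$centers)
    votes <- votes + array(as.integer(km$cluster == lesion_cluster), d)
    n_usable <- n_usable + 1L
  }
  if (n_usable == 0L) {
    stop("degenerate volume: all modalities are constant, empty mask")
  }
  fused <- votes >= min(fuse_min, n_usable)
  cleaned <- morphological_clean(tumor_mask(fused, vol$spacing), clean_radius)
  if (!any(cleaned$mask)) {
    stop("empty mask: no voxel survived fusion and cleaning")
  }
  cleaned
}

#' Mask a multimodal volume
#'
#' Voxel-wise product of every modality with the binary mask.
#'
#' @param vol a \code{\link{multimodal_volume}}.
#' @param mask a \code{\link{tumor_mask}} of the same shape.
#' @return a masked \code{\link{multimodal_volume}}.
#' @export
apply_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "multimodal_volume"), inherits(mask, "tumor_mask"))
  if (!identical(dim(vol$modalities[[1]]), dim(mask$mask))) {
    stop("mask shape does not match the volume")
  }
  out <- vol
  for (nm in names(out$modalities)) {
    out$modalities[[nm]] <- out$modalities[[nm]] * mask$mask
  }
  out
}

#' ROI volume of a mask in cubic millimetres
#'
#' Voxel count times voxel volume; at the 1 mm isotropic resolution used
#' throughout, this equals the voxel count.
#'
#' @param mask a \code{\link{tumor_mask}} or logical array.
#' @param spacing voxel spacing in mm (taken from the mask when omitted).
#' @return volume in mm^3.
#' @export
roi_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "tumor_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    mask <- mask$mask
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (any(spacing <= 0)) stop("'spacing' must be positive")
  sum(mask) * prod(spacing)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b \code{\link{tumor_mask}} objects or logical arrays.
#' @return \eqn{2|A \cap B| / (|A| + |B|)}.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "tumor_mask")) a <- a$mask
  if (inherits(b, "tumor_mask")) b <- b$mask
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
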