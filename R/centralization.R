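# Centralization of perfusion: hilum-to-pleura attenuation slope.
#
# The relative position of a lung voxel between hilum and pleura is built from
# two anisotropy-aware Euclidean distance maps: distance to the lung boundary
# (periphery) and distance to the hilar point, the centroid of extrapulmonary
# pulmonary-vein voxels assigned to that lung. Normalizing the ratio as
# d_hilum / (d_hilum + d_periphery) gives a map in [0, 1] (0 at the hilum,
# 1 at the pleura). Mean attenuation in 21 equal-width shells of this map is
# fitted with a straight line; a negative slope (attenuation falling toward
# the periphery) is the CTEPH centralization pattern.

#' Euclidean distance to the nearest voxel of a mask
#'
#' Exact separable Euclidean distance transform in physical units, honoring
#' anisotropic voxel spacing (0.9-mm slices vs sub-mm in-plane pixels would
#' otherwise bias the axial direction).
#'
#' @param mask logical 3-D array of seed voxels.
#' @param spacing per-axis voxel size (mm).
#' @return Array of distances (mm) from every voxel center to the nearest
#'   seed voxel center; `Inf` when the mask is empty.
#' @export
distance_to_mask <- function(mask, spacing) {
  d2 <- edt_squared_cpp(as.logical(mask), as.integer(dim(mask)),
                        as.numeric(spacing))
  array(sqrt(d2), dim = dim(mask))
}

#' Detect the hilar point of one lung
#'
#' The hilar point is the arithmetic-mean physical coordinate of the
#' pulmonary-vein voxels lying outside both lungs that are nearer (in mm, to
#' the lung-mask surface) to the requested lung than to the other one.
#'
#' @param seg a [segmentation_set()].
#' @param side `"left"` or `"right"`.
#' @param spacing voxel spacing (mm); defaults to the segmentation's.
#' @return A `hilar_point` list: `side`, `position_mm`, `n_vein_voxels_used`.
#' @export
detect_hilar_point <- function(seg, side = c("left", "right"),
                               spacing = seg$spacing) {
  side <- match.arg(side)
  extra <- seg$veins & !seg$lung_left & !seg$lung_right
  lin <- which(extra)
  if (!length(lin)) stopf("no extrapulmonary vein voxels")
  d_left <- distance_to_mask(seg$lung_left, spacing)[lin]
  d_right <- distance_to_mask(seg$lung_right, spacing)[lin]
  mine <- if (side == "left") d_left <= d_right else d_right < d_left
  if (!any(mine))
    stopf("no extrapulmonary vein voxels assigned to the %s lung", side)
  co <- coords_mm_from_lin(lin[mine], dim(seg$veins), spacing)
  structure(list(side = side, position_mm = colMeans(co),
                 n_vein_voxels_used = sum(mine)),
            class = "hilar_point")
}

#' Distance from lung voxels to the lung periphery
#'
#' @param lung_mask logical 3-D array of one lung.
#' @param spacing voxel spacing (mm).
#' @return Array with, over lung voxels, the Euclidean distance (mm) to the
#'   nearest non-lung voxel; `NA` outside the lung.
#' @export
distance_map_periphery <- function(lung_mask, spacing) {
  if (!any(lung_mask)) stopf("lung mask is empty")
  d <- distance_to_mask(!lung_mask, spacing)
  d[!lung_mask] <- NA_real_
  d
}

#' Distance from lung voxels to the hilar point
#'
#' @param lung_mask logical 3-D array of one lung.
#' @param hilar a [detect_hilar_point()] result (or a length-3 mm coordinate).
#' @param spacing voxel spacing (mm).
#' @return Array with the Euclidean distance (mm) from each lung voxel center
#'   to the hilar point; `NA` outside the lung.
#' @export
distance_map_hilum <- function(lung_mask, hilar, spacing) {
  pos <- if (inherits(hilar, "hilar_point")) hilar$position_mm else hilar
  lin <- which(lung_mask)
  co <- coords_mm_from_lin(lin, dim(lung_mask), spacing)
  d <- array(NA_real_, dim = dim(lung_mask))
  d[lin] <- sqrt((co[, 1] - pos[1])^2 + (co[, 2] - pos[2])^2 +
                   (co[, 3] - pos[3])^2)
  d
}

#' Relative hilum-to-pleura distance map
#'
#' `rel = d_hilum / (d_hilum + d_periphery)`: 0 at the hilum, 1 at the pleura,
#' bounded in `[0, 1]`. Voxels where both distances are 0 get 0.5.
#'
#' @param d_hilum,d_periphery distance maps from [distance_map_hilum()] and
#'   [distance_map_periphery()] on the same lung.
#' @return Array of relative distances (`NA` outside the lung).
#' @export
centralization_map <- function(d_hilum, d_periphery) {
  tot <- d_hilum + d_periphery
  rel <- d_hilum / tot
  rel[!is.na(tot) & tot == 0] <- 0.5
  rel
}

#' Radial attenuation profile over centralization shells
#'
#' Splits `[0, 1]` into `n_regions` equal-width shells of the centralization
#' map (shell `j` covers `[j/n, (j+1)/n)`, last shell closed) and averages the
#' attenuation of the lung samples falling in each.
#'
#' @param samples a [extract_lung_samples()] result.
#' @param cmap centralization map covering the sampled voxels.
#' @param n_regions number of shells (default 21).
#' @return A `radial_profile` data frame: `region` (1-based), `bin_center`
#'   (`(j + 0.5)/n`), `mean_hu`, `n_voxels`; attribute `side`. Empty shells
#'   keep `n_voxels = 0` and `NA` mean; a warning is raised when more than 10
#'   shells are empty.
#' @export
radial_profile <- function(samples, cmap, n_regions = 21L) {
  rel <- cmap[samples$lin_idx]
  if (any(is.na(rel)))
    stopf("centralization map does not cover %d sampled voxels",
          sum(is.na(rel)))
  n_regions <- as.integer(n_regions)
  bin <- pmin(pmax(floor(rel * n_regions) + 1L, 1L), n_regions)  # 1.0 -> last
  n_vox <- tabulate(bin, nbins = n_regions)
  sums <- vapply(seq_len(n_regions),
                 function(j) sum(samples$values[bin == j]), numeric(1))
  prof <- data.frame(region = seq_len(n_regions),
                     bin_center = (seq_len(n_regions) - 0.5) / n_regions,
                     mean_hu = ifelse(n_vox > 0, sums / pmax(n_vox, 1), NA),
                     n_voxels = n_vox)
  if (sum(n_vox == 0) > 10)
    warnf("%d of %d radial regions are empty; profile unreliable",
          sum(n_vox == 0), n_regions)
  attr(prof, "side") <- samples$side
  class(prof) <- c("radial_profile", class(prof))
  prof
}

#' Linear fit of the radial attenuation profile
#'
#' Degree-1 unweighted least squares of mean attenuation on shell center over
#' the nonempty shells. The slope is in HU per unit relative hilum-to-pleura
#' distance; empty shells are dropped, not interpolated.
#'
#' @param profile a [radial_profile()].
#' @return List: `slope`, `intercept`, `r2`, `n_regions_used`.
#' @export
fit_slope <- function(profile) {
  use <- profile$n_voxels > 0 & is.finite(profile$mean_hu)
  if (sum(use) < 3)
    stopf("need at least 3 nonempty radial regions, got %d", sum(use))
  fit <- lm(mean_hu ~ bin_center, data = profile[use, ])
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((profile$mean_hu[use] - mean(profile$mean_hu[use]))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_regions_used = sum(use))
}

#' Centralization metric: per-lung slope, averaged
#'
#' Runs the full chain per lung — hilar-point detection, both distance maps,
#' centralization map, radial profile, linear fit — and averages the two
#' slopes.
#'
#' @param volume a [ct_volume()].
#' @param seg a [segmentation_set()].
#' @param clip_range HU window for the attenuation samples.
#' @param n_regions number of radial shells.
#' @return A `centralization_result` list: `slope_left/right/mean`,
#'   `intercept_left/right`, `r2_left/right`, `n_regions_used_left/right`,
#'   `hilar_points`, `profiles`.
#' @export
centralization_metric <- function(volume, seg, clip_range = c(-1024, 100),
                                  n_regions = 21L) {
  out <- list()
  profs <- list()
  hps <- list()
  for (side in c("left", "right")) {
    lung <- if (side == "left") seg$lung_left else seg$lung_right
    hp <- detect_hilar_point(seg, side)
    dh <- distance_map_hilum(lung, hp, seg$spacing)
    dp <- distance_map_periphery(lung, seg$spacing)
    cmap <- centralization_map(dh, dp)
    smp <- extract_lung_samples(volume, seg, side, clip_range)
    prof <- radial_profile(smp, cmap, n_regions)
    fit <- fit_slope(prof)
    out[[paste0("slope_", side)]] <- fit$slope
    out[[paste0("intercept_", side)]] <- fit$intercept
    out[[paste0("r2_", side)]] <- fit$r2
    out[[paste0("n_regions_used_", side)]] <- fit$n_regions_used
    profs[[side]] <- prof
    hps[[side]] <- hp
  }
  out$slope_mean <- (out$slope_left + out$slope_right) / 2
  out$hilar_points <- hps
  out$profiles <- profs
  structure(out, class = "centralization_result")
}
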