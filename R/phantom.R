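# Synthetic CTPA-like chest phantoms with known ground truth.
#
# A phantom is a soft-tissue body ellipsoid on air background containing two
# ellipsoidal lungs. Each lung voxel gets a perfusion compartment (oligemic /
# normal / hyperemic) by quantile-thresholding a seeded smooth random field
# (white noise blurred with a Gaussian kernel of physical width blob_scale),
# so compartment proportions are controlled exactly and patch size directly.
# Voxel HU is drawn from the compartment's Gaussian, plus an optional linear
# center-to-periphery gradient in the true relative hilum-to-pleura distance.
# Tubular pulmonary-vein markers run from each lung to the mediastinum; the
# centroid of their extrapulmonary segments is recorded as ground truth.

#' Phantom specification
#'
#' @param grid_shape integer length-3 grid size.
#' @param spacing voxel spacing (mm); slightly anisotropic by default, like
#'   reconstructed CTPA.
#' @param body_hu soft-tissue attenuation (HU).
#' @param weights,means,sds the three-compartment mixture (low to high mean).
#' @param blob_scale spatial correlation length (mm) of compartment patches;
#'   smaller values give more, smaller patches.
#' @param radial_gradient HU per unit relative hilum-to-pleura distance added
#'   deterministically to lung voxels (negative = central hyperemia with
#'   peripheral oligemia, the CTEPH centralization pattern).
#' @param vein_hu attenuation of the vein markers (contrast-enhanced blood).
#' @param mirror make the volume exactly mirror-symmetric about the sagittal
#'   midplane (right side copied from the left), for symmetry checks.
#' @param seed RNG seed; the phantom is fully reproducible from it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 56L),
                         spacing = c(3, 3, 3.5),
                         body_hu = 40,
                         weights = c(0.2, 0.6, 0.2),
                         means = c(-900, -780, -620),
                         sds = c(30, 40, 50),
                         blob_scale = 12,
                         radial_gradient = 0,
                         vein_hu = 300,
                         mirror = FALSE,
                         seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-9) stopf("compartment weights must sum to 1")
  if (any(sds <= 0)) stopf("compartment sds must be positive")
  if (blob_scale <= 0) stopf("blob_scale must be positive")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), body_hu = body_hu,
                 weights = weights, means = means, sds = sds,
                 blob_scale = blob_scale, radial_gradient = radial_gradient,
                 vein_hu = vein_hu, mirror = isTRUE(mirror),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Preset phantom specifications
#'
#' `"severe"` mimics marked perfusion changes: a strong negative
#' center-to-periphery gradient (central hyperemia, peripheral oligemia), a
#' reduced normal compartment, and small scattered patches. `"minimal"` mimics
#' near-normal lungs: a dominant normal compartment and a near-zero gradient.
#'
#' @param name `"severe"` or `"minimal"`.
#' @param seed RNG seed for the returned spec.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("severe", "minimal"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    severe = phantom_spec(weights = c(0.30, 0.40, 0.30),
                          means = c(-860, -745, -615),
                          sds = c(30, 35, 45),
                          blob_scale = 9, radial_gradient = -120, seed = seed),
    minimal = phantom_spec(weights = c(0.05, 0.90, 0.05),
                           means = c(-920, -800, -640),
                           sds = c(30, 40, 45),
                           blob_scale = 12, radial_gradient = 0, seed = seed))
}

# Separable Gaussian blur with edge renormalization, sigma per axis in voxels.
gaussian_blur3d <- function(arr, sigma_vox) {
  blur_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    n <- dim(a)[axis]
    i <- seq_len(n)
    B <- exp(-outer(i, i, `-`)^2 / (2 * sigma^2))
    B <- B / rowSums(B)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    out <- array(B %*% m, dim = dim(ap))
    aperm(out, order(perm))
  }
  for (ax in 1:3) arr <- blur_axis(arr, ax, sigma_vox[ax])
  arr
}

# TRUE inside an ellipsoid given per-axis center/semi-axes in mm.
ellipsoid_mask <- function(dims, spacing, center_mm, semi_mm) {
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  ex <- ((cx - center_mm[1]) / semi_mm[1])^2
  ey <- ((cy - center_mm[2]) / semi_mm[2])^2
  ez <- ((cz - center_mm[3]) / semi_mm[3])^2
  outer(outer(ex, ey, `+`), ez, `+`) < 1
}

# Mirror an array about the sagittal (x) midplane.
mirror_x <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]

#' Generate a synthetic chest phantom
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [ct_volume()]), `seg` (a
#'   [segmentation_set()]), and `truth`: compartment `labels` array (0 outside
#'   lungs; 1/2/3 oligemic/normal/hyperemic), realized `proportions`, the
#'   generating `gradient`, `rel_distance` (true relative hilum-to-pleura map),
#'   and `vein_entry` centroids (mm) per side.
#' @export
generate_chest_phantom <- function(spec = phantom_spec()) {
  dims <- spec$grid_shape
  sp <- spec$spacing
  ext <- dims * sp
  center <- ext / 2

  body <- ellipsoid_mask(dims, sp, center, ext * c(0.47, 0.42, 0.48))
  lung_semi <- ext * c(0.17, 0.29, 0.38)
  lung_off <- ext[1] * 0.24
  lungL <- ellipsoid_mask(dims, sp, center - c(lung_off, 0, 0), lung_semi)
  lungR <- ellipsoid_mask(dims, sp, center + c(lung_off, 0, 0), lung_semi)
  if (any(lungL & lungR)) stopf("phantom lungs overlap; shrink the lungs")
  if (!all(body[lungL | lungR])) stopf("phantom lungs exceed the body")
  lungs <- lungL | lungR
  on_face <- any(lungs[c(1, dims[1]), , ]) || any(lungs[, c(1, dims[2]), ]) ||
    any(lungs[, , c(1, dims[3])])
  if (on_face) stopf("phantom lungs exceed the grid")

  # Vein tubes: from each lung center toward the sagittal midline, 1-voxel
  # radius in y/z. The extrapulmonary segment (outside the lung, inside the
  # mediastinum) defines the true hilar entry.
  mk_tube <- function(x_from, x_to, yc, zc) {
    xs <- seq(min(x_from, x_to), max(x_from, x_to))
    ys <- pmax(1, yc + (-1:1)); zs <- pmax(1, zc + (-1:1))
    v <- array(FALSE, dim = dims)
    v[xs, ys, zs] <- TRUE
    v
  }
  yc <- round(dims[2] / 2); zc <- round(dims[3] / 2)
  ilc <- round((center[1] - lung_off) / sp[1])      # left lung center index
  irc <- round((center[1] + lung_off) / sp[1])
  mid <- dims[1] %/% 2
  # tubes end a couple of voxels beyond the medial lung surface, so the
  # extrapulmonary entry centroid (the true hilar point) hugs the lung
  edgeL <- max(which(lungL[, yc, zc]))
  veinL <- mk_tube(ilc, min(edgeL + 3L, mid), yc, zc)
  veinR <- if (spec$mirror) {
    mirror_x(veinL)
  } else {
    edgeR <- min(which(lungR[, yc, zc]))
    mk_tube(max(edgeR - 3L, mid + 1L), irc, yc, zc)
  }
  vein <- veinL | veinR

  if (spec$mirror) {
    lungR <- mirror_x(lungL)
    if (any(lungL & lungR)) stopf("mirrored phantom lungs overlap")
  }

  lung <- lungL | lungR

  # True relative hilum-to-pleura distance from the scripted geometry
  entry <- list()
  rel <- array(NA_real_, dim = dims)
  for (side in c("left", "right")) {
    lmask <- if (side == "left") lungL else lungR
    vmask <- if (side == "left") veinL else veinR
    ex_lin <- which(vmask & !lung)
    if (!length(ex_lin)) stopf("phantom veins have no extrapulmonary segment")
    entry[[side]] <- colMeans(coords_mm_from_lin(ex_lin, dims, sp))
    dp <- distance_map_periphery(lmask, sp)
    dh <- distance_map_hilum(lmask, entry[[side]], sp)
    rel[lmask] <- (dh / (dh + dp))[lmask]
  }

  vol <- with_seed(spec$seed, {
    # Smooth field -> compartment labels by quantile cuts of the field taken
    # within each radial shell of each lung, so the compartment mix is uniform
    # along the radial coordinate by construction: patchiness and the imposed
    # radial gradient are independent controls, and realized proportions match
    # the requested weights exactly up to per-shell rounding.
    noise <- array(rnorm(prod(dims)), dim = dims)
    field <- gaussian_blur3d(noise, spec$blob_scale / sp)
    if (spec$mirror) field <- (field + mirror_x(field)) / 2
    labels <- array(0L, dim = dims)
    cw <- cumsum(spec$weights)
    for (lmask in if (spec$mirror) list(lungL) else list(lungL, lungR)) {
      lin <- which(lmask)
      shell <- pmin(floor(rel[lin] * 21) + 1L, 21L)
      f <- field[lin]
      lab <- integer(length(lin))
      for (s in unique(shell)) {
        i <- which(shell == s)
        rk <- rank(f[i], ties.method = "first")
        # randomized rounding of the per-shell compartment counts: unbiased
        # composition on average instead of a fixed rounding pattern
        u <- runif(2)
        n1 <- floor(length(i) * cw[1] + u[1])
        n2 <- max(floor(length(i) * cw[2] + u[2]), n1)
        lab[i] <- 1L + (rk > n1) + (rk > n2)
      }
      labels[lin] <- lab
    }
    if (spec$mirror) {
      lm <- mirror_x(labels)
      labels[lungR] <- lm[lungR]
    }
    lab_l <- labels[lung]

    hu <- array(-1000, dim = dims)
    hu[body] <- spec$body_hu
    noise_hu <- rnorm(sum(lung), spec$means[lab_l], spec$sds[lab_l])
    if (spec$mirror) {
      # identical draws on mirrored voxels: draw on the left, copy across
      tmp <- array(NA_real_, dim = dims)
      tmp[lung] <- noise_hu
      tmpm <- mirror_x(tmp)
      right_half <- slice.index(tmp, 1) > dims[1] / 2
      tmp[right_half & lung] <- tmpm[right_half & lung]
      noise_hu <- tmp[lung]
    }
    hu[lung] <- noise_hu
    list(hu = hu, labels = labels)
  })
  hu <- vol$hu
  labels <- vol$labels

  if (spec$radial_gradient != 0)
    hu[lung] <- hu[lung] + spec$radial_gradient * rel[lung]
  hu[vein] <- spec$vein_hu
  hu <- round(hu)   # CT attenuation is integer-quantized

  volume <- ct_volume(hu, sp)
  seg <- segmentation_set(lungL, lungR, vein, volume)
  props <- tabulate(labels[lung], nbins = 3L) / sum(lung)
  truth <- list(labels = labels,
                proportions = setNames(props, COMPARTMENTS),
                gradient = spec$radial_gradient,
                rel_distance = rel,
                vein_entry = entry,
                n_lung_voxels = sum(lung),
                spec = spec)
  list(volume = volume, seg = seg, truth = truth)
}

#' Write a phantom to disk
#'
#' Writes `ct.nii.gz`, `seg.nii.gz` (multi-label: 1 left lung, 2 right lung,
#' 3 veins) and `truth.json` into `dir`.
#'
#' @param phantom a [generate_chest_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_volume(phantom$volume, file.path(dir, "ct.nii.gz"))
  lab <- array(0L, dim = dim(phantom$volume$data))
  lab[phantom$seg$lung_left] <- 1L
  lab[phantom$seg$lung_right] <- 2L
  lab[phantom$seg$veins & !phantom$seg$lung_left &
        !phantom$seg$lung_right] <- 3L
  write_ct_volume(lab, file.path(dir, "seg.nii.gz"),
                  spacing = phantom$volume$spacing, datatype = "uint8")
  tr <- phantom$truth
  jsonlite::write_json(
    list(proportions = as.list(tr$proportions), gradient = tr$gradient,
         vein_entry = lapply(tr$vein_entry, as.numeric),
         n_lung_voxels = tr$n_lung_voxels,
         spec = unclass(tr$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
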