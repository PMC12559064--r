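# Spatial heterogeneity of perfusion compartments.
#
# Dispersion of a compartment inside one lung is measured as the Shannon
# entropy (bits) of a 32 x 32 x 32 histogram of the compartment voxels'
# physical coordinates, binned over that lung's axis-aligned bounding box.
# A compact compartment occupies few bins (low entropy); a scattered mosaic
# pattern spreads over many (high entropy, up to log2(32^3) = 15 bits).

#' 3-D spatial histogram of voxel coordinates
#'
#' Equal-width bins per axis spanning `box`; coordinates exactly on the upper
#' boundary fall in the last bin.
#'
#' @param coords_mm n x 3 matrix of physical coordinates (mm).
#' @param box 2 x 3 matrix (or list of 3 `c(lo, hi)`) of per-axis bounds (mm);
#'   every axis must have positive extent.
#' @param bins bins per axis (default 32).
#' @return A `spatial_histogram`: `counts` (bins^3 array), `bounds`, `n_total`,
#'   `empty` flag.
#' @export
spatial_histogram <- function(coords_mm, box, bins = 32L) {
  box <- matrix(unlist(box), nrow = 2)
  if (any(box[2, ] <= box[1, ]))
    stopf("binning box must have positive extent on every axis")
  bins <- as.integer(bins)
  counts <- array(0L, dim = rep(bins, 3))
  n <- if (is.null(coords_mm)) 0L else nrow(coords_mm)
  if (n > 0) {
    idx <- sapply(1:3, function(a) {
      i <- floor((coords_mm[, a] - box[1, a]) /
                   (box[2, a] - box[1, a]) * bins) + 1
      pmin(pmax(i, 1L), bins)   # upper boundary -> last bin
    })
    idx <- matrix(idx, ncol = 3)
    lin <- (idx[, 3] - 1) * bins^2 + (idx[, 2] - 1) * bins + idx[, 1]
    counts <- array(tabulate(lin, nbins = bins^3), dim = rep(bins, 3))
  }
  structure(list(counts = counts, bounds = box, n_total = sum(counts),
                 empty = n == 0), class = "spatial_histogram")
}

#' Shannon entropy of a spatial histogram, in bits
#'
#' `H = -sum p_i log2 p_i` over occupied bins with `p_i = count_i / n_total`.
#' An empty histogram (absent compartment: maximally homogeneous) returns 0.
#'
#' @param hist a [spatial_histogram()], or a vector/array of counts.
#' @return Entropy in bits, in `[0, 3 log2(bins)]`.
#' @export
shannon_entropy <- function(hist) {
  counts <- if (inherits(hist, "spatial_histogram")) hist$counts else hist
  n <- sum(counts)
  if (n < 1) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Axis-aligned bounding box (mm, voxel centers) of a logical mask; degenerate
# axes are widened by half a voxel so the box always has positive extent.
mask_bounding_box <- function(mask, spacing) {
  lin <- which(mask)
  if (!length(lin)) stopf("cannot take the bounding box of an empty mask")
  co <- coords_mm_from_lin(lin, dim(mask), spacing)
  box <- rbind(apply(co, 2, min), apply(co, 2, max))
  flat <- box[2, ] <= box[1, ]
  box[1, flat] <- box[1, flat] - spacing[flat] / 2
  box[2, flat] <- box[2, flat] + spacing[flat] / 2
  box
}

#' Per-lung spatial-entropy heterogeneity of compartments
#'
#' For each lung and each of the hyperemic and normal compartments, bins that
#' compartment's voxel coordinates into a `bins`^3 histogram over the lung's
#' bounding box and takes the Shannon entropy; per-lung values are averaged
#' arithmetically. A compartment absent from a lung scores 0 bits and raises a
#' flag. The oligemic compartment is computed only when `include_oligemic`.
#'
#' @param mask a `compartment_mask` from [classify_voxels()].
#' @param seg a [segmentation_set()].
#' @param spacing voxel spacing (mm); defaults to the segmentation's.
#' @param bins bins per axis (default 32).
#' @param include_oligemic also report the oligemic compartment (off the
#'   headline metrics).
#' @return A `heterogeneity_result` list: `entropy_high_left/right/mean`,
#'   `entropy_medium_left/right/mean` (bits), optional `entropy_low_*`, and
#'   `flags` naming lung/compartment pairs that were empty.
#' @export
heterogeneity_metrics <- function(mask, seg, spacing = seg$spacing,
                                  bins = 32L, include_oligemic = FALSE) {
  comps <- c(high = 3L, medium = 2L)
  if (include_oligemic) comps <- c(comps, low = 1L)
  out <- list()
  flags <- character(0)
  for (side in c("left", "right")) {
    lung <- if (side == "left") seg$lung_left else seg$lung_right
    box <- mask_bounding_box(lung, spacing)
    for (cn in names(comps)) {
      lin <- which(lung & mask == comps[[cn]])
      if (!length(lin)) {
        flags <- c(flags, sprintf("%s compartment empty in %s lung", cn, side))
        h <- 0
      } else {
        co <- coords_mm_from_lin(lin, dim(mask), spacing)
        h <- shannon_entropy(spatial_histogram(co, box, bins))
      }
      out[[sprintf("entropy_%s_%s", cn, side)]] <- h
    }
  }
  for (cn in names(comps))
    out[[sprintf("entropy_%s_mean", cn)]] <-
      (out[[sprintf("entropy_%s_left", cn)]] +
         out[[sprintf("entropy_%s_right", cn)]]) / 2
  out$flags <- flags
  structure(out, class = "heterogeneity_result")
}
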