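#' CT volume container
#'
#' Wraps a 3-D grid of attenuation values (Hounsfield units) together with its
#' physical voxel spacing. Voxel indices are 0-based internally; the physical
#' coordinate of a voxel center is `(index + 0.5) * spacing` per axis, in mm.
#' Grids are always used as stored — the package never reorients, so masks must
#' come from the same geometry as the CT.
#'
#' @param data numeric 3-D array of attenuation values (HU).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param orientation_tag label recording the axis convention of the grid.
#' @return An object of class `ct_volume` with elements `data`, `spacing`,
#'   `orientation_tag`, and `qc` (character vector of QC flags; values outside
#'   \[-1100, 3100\] HU are flagged as suspect but retained).
#' @export
ct_volume <- function(data, spacing, orientation_tag = "as-stored") {
  if (length(dim(data)) != 3L)
    stopf("expected 3 spatial dimensions, got %d", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive values (got: %s)",
          paste(signif(spacing, 4), collapse = ", "))
  if (any(!is.finite(data)))
    stopf("volume contains non-finite attenuation values")
  qc <- character(0)
  n_out <- sum(data < -1100 | data > 3100)
  if (n_out > 0)
    qc <- sprintf("%d voxels outside plausible HU range [-1100, 3100]", n_out)
  structure(list(data = data, spacing = spacing,
                 orientation_tag = orientation_tag, qc = qc),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  if (length(x$qc)) cat(" QC:", paste(x$qc, collapse = "; "), "\n")
  invisible(x)
}

#' Read a CT volume from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file with 3 spatial dimensions;
#'   stored values are taken as Hounsfield units, spacing from the header.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) stopf("CT file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stopf("expected 3 spatial dimensions in %s, got %d", path, length(dim(arr)))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  ct_volume(arr, sp)
}

#' Write a CT volume (or any 3-D array) to NIfTI
#'
#' @param volume a [ct_volume()], or a plain 3-D array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing voxel spacing, required when `volume` is a bare array.
#' @param datatype NIfTI on-disk type (e.g. `"float"`, `"uint8"`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path, spacing = NULL, datatype = "float") {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$data
    spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stopf("spacing required when writing a bare array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Segmentation set: left lung, right lung, pulmonary veins
#'
#' Binary masks on the same grid as the CT. The lungs must be disjoint and each
#' must contain at least `min_lung_voxels` voxels for analysis to proceed. In
#' production these masks come from an external segmentation network; this
#' package consumes them, it does not produce them.
#'
#' @param lung_left,lung_right,veins logical 3-D arrays (or 0/1 arrays).
#' @param volume the [ct_volume()] defining the reference grid.
#' @param min_lung_voxels minimum voxel count per lung (default 1000).
#' @return An object of class `segmentation_set`.
#' @export
segmentation_set <- function(lung_left, lung_right, veins, volume,
                             min_lung_voxels = 1000) {
  dims <- dim(volume$data)
  as_mask <- function(m, name) {
    if (!identical(dim(m), dims))
      stopf("mask grid differs from CT grid (%s: %s vs %s)", name,
            paste(dim(m), collapse = "x"), paste(dims, collapse = "x"))
    array(as.logical(m), dim = dims)
  }
  ll <- as_mask(lung_left, "lung_left")
  lr <- as_mask(lung_right, "lung_right")
  vn <- as_mask(veins, "veins")
  if (any(ll & lr)) stopf("lung masks overlap (%d voxels)", sum(ll & lr))
  for (s in c("left", "right")) {
    n <- if (s == "left") sum(ll) else sum(lr)
    if (n < min_lung_voxels)
      stopf("%s lung mask too small (%d < %d voxels)", s, n, min_lung_voxels)
  }
  structure(list(lung_left = ll, lung_right = lr, veins = vn,
                 dim = dims, spacing = volume$spacing),
            class = "segmentation_set")
}

#' Read lung/vein segmentation masks
#'
#' Accepts either one multi-label NIfTI (labels resolved through `label_map`)
#' or three separate binary-mask files.
#'
#' @param path a single multi-label mask path, or a named list/vector with
#'   entries `lung_left`, `lung_right`, `veins` of per-structure mask paths.
#' @param volume the [ct_volume()] the masks must match.
#' @param label_map named list mapping `lung_left`, `lung_right`, `veins` to
#'   integer labels in the multi-label file (default 1, 2, 3).
#' @param min_lung_voxels minimum voxel count per lung.
#' @return A [segmentation_set()].
#' @export
read_segmentation <- function(path, volume,
                              label_map = list(lung_left = 1L, lung_right = 2L,
                                               veins = 3L),
                              min_lung_voxels = 1000) {
  need <- c("lung_left", "lung_right", "veins")
  if (length(path) == 1L && is.character(path)) {
    if (!file.exists(path)) stopf("segmentation file not found: %s", path)
    lab <- as.array(RNifti::readNifti(path))
    if (length(dim(lab)) == 4L && dim(lab)[4] == 1L)
      lab <- lab[, , , 1, drop = TRUE]
    missing <- setdiff(need, names(label_map))
    if (length(missing))
      stopf("label_map missing entries: %s", paste(missing, collapse = ", "))
    masks <- lapply(label_map[need], function(l) lab == l)
  } else {
    paths <- as.list(path)
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stopf("segmentation paths missing entries: %s",
            paste(missing, collapse = ", "))
    masks <- lapply(paths[need], function(p) {
      if (!file.exists(p)) stopf("segmentation file not found: %s", p)
      as.array(RNifti::readNifti(p)) != 0
    })
  }
  segmentation_set(masks$lung_left, masks$lung_right, masks$veins, volume,
                   min_lung_voxels = min_lung_voxels)
}

#' Extract per-lung attenuation samples
#'
#' Returns the HU values and physical voxel-center coordinates (mm) of all
#' voxels of one lung whose value lies inside `clip_range`. The default window
#' \[-1024, 100\] HU retains hyperemic parenchyma and vessels while excluding
#' bone/metal spill. A warning is attached when clipping removes more than 20%
#' of the lung (possible mis-calibrated volume).
#'
#' @param volume a [ct_volume()].
#' @param seg a [segmentation_set()].
#' @param side `"left"` or `"right"`.
#' @param clip_range length-2 HU window `[lo, hi]`, inclusive.
#' @return An object of class `lung_samples`: `side`, `values`, `coords_mm`
#'   (n x 3 matrix), `clip_range`, `n_clipped`, `qc`.
#' @export
extract_lung_samples <- function(volume, seg, side = c("left", "right"),
                                 clip_range = c(-1024, 100)) {
  side <- match.arg(side)
  mask <- if (side == "left") seg$lung_left else seg$lung_right
  if (!any(mask)) stopf("%s lung mask is empty", side)
  lin <- which(mask)
  vals <- volume$data[lin]
  keep <- vals >= clip_range[1] & vals <= clip_range[2]
  n_clipped <- sum(!keep)
  qc <- character(0)
  if (n_clipped > 0.2 * length(lin)) {
    qc <- sprintf("clip_range removed %.1f%% of %s lung voxels",
                  100 * n_clipped / length(lin), side)
    warnf("%s", qc)
  }
  coords <- coords_mm_from_lin(lin[keep], dim(volume$data), volume$spacing)
  structure(list(side = side, values = vals[keep], coords_mm = coords,
                 lin_idx = lin[keep], clip_range = clip_range,
                 n_clipped = n_clipped, qc = qc),
            class = "lung_samples")
}
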