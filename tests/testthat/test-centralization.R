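test_that("distance transform matches the brute-force oracle with anisotropy", {
  for (s in 1:3) {
    dims <- c(9L, 7L, 6L)
    mask <- withr::with_seed(s, array(runif(prod(dims)) < 0.15, dims))
    if (!any(mask)) mask[3, 3, 3] <- TRUE
    spacing <- c(1.5, 2, 0.9)
    expect_equal(distance_to_mask(mask, spacing), brute_edt(mask, spacing),
                 tolerance = 1e-10)
  }
})

test_that("periphery map of a digital ball recovers its radius", {
  dims <- c(25L, 25L, 25L)
  sp <- c(1, 1, 1)
  ctr <- c(12.5, 12.5, 12.5)
  lin <- seq_len(prod(dims))
  co <- (arrayInd(lin, dims) - 0.5)
  ball <- array(sqrt(rowSums(sweep(co, 2, ctr)^2)) <= 10, dims)
  d <- distance_map_periphery(ball, sp)
  center_vox <- array(FALSE, dims); center_vox[13, 13, 13] <- TRUE
  expect_equal(d[13, 13, 13], 10, tolerance = sqrt(3) / 2 + 0.5)
  # boundary voxels sit within one voxel diagonal of the outside
  expect_gt(sum(ball & d <= sqrt(3)), 0)
  expect_true(all(d[ball] > 0))
  # single-voxel lung
  single <- array(FALSE, c(5L, 5L, 5L)); single[3, 3, 3] <- TRUE
  ds <- distance_map_periphery(single, c(1, 2, 3))
  expect_lte(ds[3, 3, 3], 1)
})

test_that("hilum distance map is plain 3-D Pythagoras on voxel centers", {
  dims <- c(10L, 10L, 10L)
  mask <- array(TRUE, dims)
  sp <- c(1.1, 0.9, 2)
  hp <- c(5, 5, 5)
  d <- distance_map_hilum(mask, hp, sp)
  co <- (arrayInd(seq_len(prod(dims)), dims) - 0.5) %*% diag(sp)
  expect_equal(as.vector(d), sqrt(rowSums(sweep(co, 2, hp)^2)))
  # voxel centered exactly on the hilar point, and a pure axial offset
  d2 <- distance_map_hilum(array(TRUE, c(8, 8, 8)), c(2.5, 2.5, 2.5),
                           c(1, 1, 1))
  expect_equal(d2[3, 3, 3], 0)
  expect_equal(d2[3, 3, 6], 3)   # 30/10 of a mm grid: 3 units along one axis
})

test_that("centralization map follows the bounded normalization exactly", {
  expect_equal(centralization_map(0, 20), 0)
  expect_equal(centralization_map(20, 0), 1)
  expect_equal(centralization_map(30, 10), 0.75)
  expect_equal(centralization_map(0, 0), 0.5)
  ph <- generate_chest_phantom(phantom_spec(seed = 6))
  hp <- detect_hilar_point(ph$seg, "left")
  dh <- distance_map_hilum(ph$seg$lung_left, hp, ph$seg$spacing)
  dp <- distance_map_periphery(ph$seg$lung_left, ph$seg$spacing)
  cm <- centralization_map(dh, dp)
  vals <- cm[ph$seg$lung_left]
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("hilar point is the centroid of assigned extrapulmonary vein voxels", {
  dims <- c(20L, 12L, 12L)
  ll <- array(FALSE, dims); ll[2:7, 3:10, 3:10] <- TRUE
  lr <- array(FALSE, dims); lr[14:19, 3:10, 3:10] <- TRUE
  vn <- array(FALSE, dims)
  vn[9:11, 5, 5] <- TRUE     # 9, 10 nearer the left lung; 11 nearer the right
  vol <- ct_volume(array(-800, dims), c(2, 2, 2))
  seg <- segmentation_set(ll, lr, vn, vol, min_lung_voxels = 1)
  hp <- detect_hilar_point(seg, "left")
  expect_equal(hp$n_vein_voxels_used, 2)
  expect_equal(hp$position_mm, c(mean(c(8.5, 9.5) * 2), 9, 9))
  hpr <- detect_hilar_point(seg, "right")
  expect_equal(hpr$n_vein_voxels_used, 1)
  expect_equal(hpr$position_mm, c(10.5 * 2, 9, 9))
  expect_error(detect_hilar_point(segmentation_set(ll, lr, array(FALSE, dims),
                                                   vol, min_lung_voxels = 1),
                                  "left"),
               "no extrapulmonary vein voxels")
  # veins entirely inside the lungs count as absent
  vin <- array(FALSE, dims); vin[3, 5, 5] <- TRUE
  expect_error(detect_hilar_point(segmentation_set(ll, lr, vin, vol,
                                                   min_lung_voxels = 1),
                                  "left"),
               "no extrapulmonary vein voxels")
  # phantom ground truth within one voxel diagonal
  ph <- generate_chest_phantom(phantom_spec(seed = 8))
  hpl <- detect_hilar_point(ph$seg, "left")
  expect_lt(sqrt(sum((hpl$position_mm - ph$truth$vein_entry$left)^2)),
            sqrt(sum(ph$volume$spacing^2)))
})

test_that("radial profile bins correctly and flat/linear cases fit exactly", {
  tc <- tiny_chest(hu_lung = -800)
  hp <- detect_hilar_point(tc$seg, "left")
  dh <- distance_map_hilum(tc$lung_left, hp, tc$seg$spacing)
  dp <- distance_map_periphery(tc$lung_left, tc$seg$spacing)
  cm <- centralization_map(dh, dp)
  smp <- extract_lung_samples(tc$volume, tc$seg, "left", c(-1000, 0))
  prof <- suppressWarnings(radial_profile(smp, cm))
  expect_equal(nrow(prof), 21)
  expect_equal(sum(prof$n_voxels), length(smp$values))
  expect_true(all(prof$mean_hu[prof$n_voxels > 0] == -800))
  # exact line through the 21 bin centers
  lin_prof <- data.frame(region = 1:21, bin_center = (1:21 - 0.5) / 21,
                         mean_hu = -800 + 100 * (1:21 - 0.5) / 21,
                         n_voxels = 50L)
  fit <- fit_slope(lin_prof)
  expect_equal(fit$slope, 100)
  expect_equal(fit$intercept, -800)
  expect_equal(fit$r2, 1)
  flat <- transform(lin_prof, mean_hu = -750)
  expect_equal(fit_slope(flat)$slope, 0)
  # fewer than 3 nonempty regions is a hard error
  sparse <- transform(lin_prof, n_voxels = c(3L, 4L, rep(0L, 19)))
  expect_error(fit_slope(sparse), "at least 3 nonempty")
  # slope equals the closed-form least squares on the same pairs
  noisy <- transform(lin_prof,
                     mean_hu = mean_hu + withr::with_seed(2, rnorm(21, 0, 6)))
  f2 <- fit_slope(noisy)
  xc <- noisy$bin_center; yc <- noisy$mean_hu
  beta <- sum((xc - mean(xc)) * (yc - mean(yc))) / sum((xc - mean(xc))^2)
  expect_equal(f2$slope, beta)
  # rel_distance exactly 1 falls in region 21
  cm1 <- cm; cm1[smp$lin_idx] <- 1
  prof1 <- suppressWarnings(radial_profile(smp, cm1))
  expect_equal(prof1$n_voxels[21], length(smp$values))
})

test_that("imposed gradients are recovered and a mirror phantom is symmetric", {
  ph <- generate_chest_phantom(
    phantom_spec(weights = c(0.2, 0.6, 0.2), means = c(-820, -750, -680),
                 sds = c(25, 30, 35), radial_gradient = -150, seed = 31))
  cen <- suppressWarnings(centralization_metric(ph$volume, ph$seg))
  expect_equal(cen$slope_mean, -150, tolerance = 15)
  expect_equal(cen$slope_mean, (cen$slope_left + cen$slope_right) / 2)
  ph0 <- generate_chest_phantom(
    phantom_spec(weights = c(0.2, 0.6, 0.2), means = c(-820, -750, -680),
                 sds = c(25, 30, 35), radial_gradient = 0, seed = 32))
  cen0 <- suppressWarnings(centralization_metric(ph0$volume, ph0$seg))
  expect_lt(abs(cen0$slope_mean), 10)
  phm <- generate_chest_phantom(phantom_spec(mirror = TRUE,
                                             radial_gradient = -80, seed = 33))
  cm <- suppressWarnings(centralization_metric(phm$volume, phm$seg))
  expect_lt(abs(cm$slope_left - cm$slope_right), 1e-6)
})

test_that("map is non-decreasing along the hilum-to-antipode ray of a ball", {
  # convex lung with the hilar point on its surface: along the diameter the
  # relative distance is 0.5 up to the center, then rises to 1 at the pleura
  dims <- c(31L, 31L, 31L)
  sp <- c(1, 1, 1)
  co <- arrayInd(seq_len(prod(dims)), dims) - 0.5
  ctr <- c(15.5, 15.5, 15.5)
  ball <- array(sqrt(rowSums(sweep(co, 2, ctr)^2)) <= 12, dims)
  hil <- c(15.5 - 12, 15.5, 15.5)   # on the boundary, along -x
  cmap <- centralization_map(distance_map_hilum(ball, hil, sp),
                             distance_map_periphery(ball, sp))
  ray <- cmap[, 16, 16]
  ray <- ray[!is.na(ray)]
  expect_gt(length(ray), 15)
  expect_true(all(diff(ray) >= -0.02))   # voxelization slack only
  expect_lte(ray[1], 0.1)                # zero at the hilar voxel itself
  expect_gt(ray[length(ray)], 0.85)
})
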