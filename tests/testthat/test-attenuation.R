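draw_mixture <- function(n, weights, means, sds, seed) {
  withr::with_seed(seed, {
    k <- sample.int(3, n, replace = TRUE, prob = weights)
    round(rnorm(n, means[k], sds[k]))
  })
}

test_that("VB mixture recovers the generating parameters of a large draw", {
  w <- c(0.20, 0.60, 0.20); mu <- c(-900, -780, -620); s <- c(30, 40, 50)
  x <- draw_mixture(2e5, w, mu, s, seed = 101)
  m <- fit_attenuation_model(x)
  expect_true(m$fit_info$converged)
  expect_lt(max(abs(m$components$weight - w)), 0.02)
  expect_lt(max(abs(m$components$mean - mu)), 5)
  expect_lt(max(abs(m$components$sd / s - 1)), 0.10)
  expect_equal(sum(m$components$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(m$components$mean) > 0))
})

test_that("degenerate single-valued input collapses to one component", {
  m <- suppressWarnings(fit_attenuation_model(rep(-800, 5000)))
  expect_gte(max(m$components$weight), 0.98)
  expect_true(all(m$components$sd > 0))
})

test_that("fit is deterministic and invariant to sample order", {
  x <- draw_mixture(5e4, c(0.3, 0.4, 0.3), c(-880, -760, -640),
                    c(25, 30, 35), seed = 7)
  m1 <- fit_attenuation_model(x)
  m2 <- fit_attenuation_model(x)
  expect_identical(m1$components, m2$components)
  m3 <- fit_attenuation_model(withr::with_seed(1, sample(x)))
  expect_equal(m1$components$mean, m3$components$mean, tolerance = 1e-6)
  expect_equal(m1$components$weight, m3$components$weight, tolerance = 1e-6)
})

test_that("fit agrees with an independent EM fit on well-separated data", {
  suppressMessages(library(mclust))
  x <- draw_mixture(5e4, c(0.25, 0.5, 0.25), c(-920, -780, -600),
                    c(20, 25, 30), seed = 11)
  m <- fit_attenuation_model(x)
  em <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(m$components$mean), sort(as.numeric(em$parameters$mean)),
               tolerance = 1)
  expect_equal(sort(m$components$weight), sort(em$parameters$pro),
               tolerance = 0.01)
})

test_that("sample-size contracts: hard floor at 30, warning below 10k", {
  expect_error(fit_attenuation_model(rnorm(10)), "at least 30")
  w <- capture_warnings(fit_attenuation_model(rnorm(500, -800, 40)))
  expect_match(w, "unstable", all = FALSE)
})

test_that("voxel classification matches direct weighted-density evaluation", {
  m <- list(components = data.frame(
    label = c("oligemic", "normal", "hyperemic"),
    weight = rep(1 / 3, 3), mean = c(-900, -780, -620), sd = c(30, 40, 50)))
  class(m) <- "attenuation_model"
  tc <- tiny_chest(hu_lung = -905)
  cm <- classify_voxels(tc$volume, tc$seg, m)
  expect_true(all(cm[tc$lung_left] == 1))          # -905 -> oligemic
  tc2 <- tiny_chest(hu_lung = -780)
  expect_true(all(classify_voxels(tc2$volume, tc2$seg, m)[tc2$lung_left] == 2))
  tc3 <- tiny_chest(hu_lung = -600)
  expect_true(all(classify_voxels(tc3$volume, tc3$seg, m)[tc3$lung_left] == 3))
  # background voxels stay 0
  expect_true(all(cm[!(tc$lung_left | tc$lung_right)] == 0))
  # oracle equivalence on random HU values
  hu <- withr::with_seed(3, round(runif(500, -1000, 0)))
  dens <- sapply(1:3, function(k)
    m$components$weight[k] * dnorm(hu, m$components$mean[k],
                                   m$components$sd[k]))
  oracle <- max.col(dens, ties.method = "first")
  arr <- array(40, c(30, 30, 4)); ll <- lr <- array(FALSE, c(30, 30, 4))
  ll[1:15, , 1] <- TRUE; lr[16:30, , 1] <- TRUE
  arr[1:500] <- hu
  vol <- ct_volume(arr, c(1, 1, 1))
  seg <- segmentation_set(ll, lr, array(FALSE, c(30, 30, 4)), vol,
                          min_lung_voxels = 1)
  got <- classify_voxels(vol, seg, m)
  expect_equal(as.vector(got)[1:500], oracle)
})

test_that("exact decision boundary goes to the lower-mean component", {
  m <- list(components = data.frame(
    label = c("oligemic", "normal", "hyperemic"),
    weight = rep(1 / 3, 3), mean = c(-900, -800, -700), sd = c(10, 10, 10)))
  class(m) <- "attenuation_model"
  tc <- tiny_chest(hu_lung = -850)   # equidistant between first two
  cm <- classify_voxels(tc$volume, tc$seg, m)
  expect_true(all(cm[tc$lung_left] == 1))
})

test_that("proportions come from weights and counts, both summing to 1", {
  ph <- generate_chest_phantom(
    phantom_spec(weights = c(0.25, 0.5, 0.25), means = c(-920, -780, -600),
                 sds = c(20, 25, 30), seed = 13))
  sl <- extract_lung_samples(ph$volume, ph$seg, "left")
  sr <- extract_lung_samples(ph$volume, ph$seg, "right")
  m <- fit_attenuation_model(c(sl$values, sr$values))
  cm <- classify_voxels(ph$volume, ph$seg, m)
  pr <- compartment_proportions(m, cm)
  expect_equal(sum(pr$weight_based), 1, tolerance = 1e-6)
  expect_equal(sum(pr$count_based), 1, tolerance = 1e-6)
  # >= 4-SD separation: weight- and count-based proportions agree closely
  expect_lt(max(abs(pr$weight_based - pr$count_based)), 0.01)
  expect_equal(pr$weight_based, unname(ph$truth$proportions),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("parameter recovery holds across many seeded draws", {
  w <- c(0.2, 0.6, 0.2); mu <- c(-900, -780, -620); s <- c(30, 40, 50)
  errs <- sapply(1:8, function(sd_i) {
    x <- draw_mixture(1e5, w, mu, s, seed = 200 + sd_i)
    m <- fit_attenuation_model(x)
    c(mean(abs(m$components$weight - w)), mean(abs(m$components$mean - mu)))
  })
  expect_lt(mean(errs[1, ]), 0.02)
  expect_lt(mean(errs[2, ]), 5)
})
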