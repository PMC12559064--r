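test_that("Spearman handles monotone, tied, and degenerate inputs", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(3, 2, 1, 0))$rho, -1)
  r <- spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, brute_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4)))
  expect_equal(r$rho, 0.9486833, tolerance = 1e-6)
  expect_false(spearman_cor(c(1, 2, 3), c(3, 2, 1))$ok)   # < 4 pairs
  expect_false(spearman_cor(rep(2, 6), 1:6)$ok)           # zero variance
  # missing values: pairwise deletion
  r2 <- spearman_cor(c(1, 2, NA, 4, 5), c(5, 4, 1, NA, 1))
  expect_equal(r2$n, 3)
  expect_false(r2$ok)
})

test_that("Spearman equals the midrank oracle and matches cor.test", {
  for (s in 1:20) {
    n <- withr::with_seed(s, sample(5:10, 1))
    x <- withr::with_seed(s * 2 + 1, sample(1:5, n, TRUE))
    y <- withr::with_seed(s * 2 + 2, rnorm(n))
    got <- spearman_cor(x, y)
    expect_equal(got$rho, brute_spearman(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  x <- withr::with_seed(9, rlnorm(40)); y <- withr::with_seed(10, rnorm(40))
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(log(x), y)$rho, base)
  expect_equal(spearman_cor(x, exp(y))$rho, base)
  expect_equal(spearman_cor(rank(x), y)$rho, base)
})

test_that("BH flags equal brute-force enumeration and p.adjust", {
  r <- bh_adjust(c(0.001, 0.01, 0.02, 0.04, 0.2), 0.05)
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$critical_p, 0.04)
  expect_equal(bh_adjust(rep(0.9, 6))$critical_p, 0)
  expect_false(any(bh_adjust(rep(0.9, 6))$significant))
  for (s in 1:25) {
    m <- withr::with_seed(s, sample(1:10, 1))
    p <- withr::with_seed(100 + s, round(runif(m), 3))
    got <- bh_adjust(p, 0.05)
    oracle <- brute_bh(p, 0.05)
    expect_identical(got$significant, oracle$significant)
    expect_equal(got$critical_p, oracle$critical_p)
    expect_identical(got$significant, p.adjust(p, "BH") <= 0.05)
  }
})

test_that("BH flags are monotone when any p-value is lowered", {
  p <- c(0.021, 0.049, 0.003, 0.2, 0.8, 0.04)
  base <- bh_adjust(p, 0.05)$significant
  for (i in seq_along(p)) {
    p2 <- p; p2[i] <- p[i] / 10
    lowered <- bh_adjust(p2, 0.05)$significant
    expect_true(all(lowered[base]))   # nothing flagged gets de-flagged
  }
})

test_that("Grubbs screen flags a gross outlier and respects contracts", {
  x <- c(10.1, 10.2, 9.9, 10.0, 10.15, 9.95, 10.05, 42)
  g <- grubbs_screen(x)
  expect_equal(g$outlier_index, 8L)
  expect_gt(g$G, g$critical)
  sym <- c(9, 10, 11, 10, 9, 11, 10)
  expect_true(is.na(grubbs_screen(sym)$outlier_index))
  expect_false(grubbs_screen(rep(5, 9))$ok)
  expect_false(grubbs_screen(c(1, 2, 3))$ok)
  # oracle: direct G against the t-based critical value
  n <- length(x)
  G <- max(abs(x - mean(x))) / sd(x)
  tc <- qt(1 - 0.05 / (2 * n), n - 2)
  expect_equal(g$G, G)
  expect_equal(g$critical, (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2)))
})

test_that("normality screen reproduces independent reference values", {
  # frozen from an independent omnibus-test implementation
  y <- round(exp(qnorm((1:25) / 26) * 1.5), 6)
  ry <- normality_screen(y)
  expect_equal(ry$K2, 30.4277922531, tolerance = 1e-8)
  expect_equal(ry$p, 2.469954e-07, tolerance = 1e-6)
  z <- round(c(qnorm((1:14) / 15), 4.5), 6)
  rz <- normality_screen(z)
  expect_equal(rz$K2, 15.5037835731, tolerance = 1e-8)
  expect_equal(rz$p, 0.0004299284, tolerance = 1e-6)
  expect_false(normality_screen(rnorm(5))$ok)
})

test_that("normality screen holds its level and has power", {
  ps_norm <- sapply(1:100, function(s)
    normality_screen(withr::with_seed(s, rnorm(5000)))$p)
  expect_gte(mean(ps_norm > 0.01), 0.95)
  ps_ln <- sapply(1:100, function(s)
    normality_screen(withr::with_seed(1000 + s, rlnorm(5000)))$p)
  expect_gte(mean(ps_ln < 0.001), 0.99)
})

test_that("correlation report joins tables, applies BH, and self-correlates", {
  tg <- spearman_targets(c("prop_normal", "probnp", "pvr"),
                         data.frame(a = "prop_normal",
                                    b = c("probnp", "pvr"),
                                    rho = c(-0.5, -0.45)))
  tab <- generate_clinical_table(tg, n_patients = 2000, seed = 4)
  metrics <- tab[, c("patient_id", "prop_normal")]
  clinical <- tab[, c("patient_id", "probnp", "pvr")]
  rep <- correlation_report(metrics, clinical)
  row <- rep[rep$metric == "prop_normal" & rep$variable == "probnp", ]
  expect_equal(row$rho, -0.5, tolerance = 0.05)
  expect_true(row$significant)
  expect_gt(attr(rep, "critical_p"), 0)
  # a metric against itself is a perfect correlation
  self <- correlation_report(metrics,
                             cbind(clinical, prop_self = tab$prop_normal))
  expect_equal(self$rho[self$variable == "prop_self"], 1)
  expect_error(correlation_report(metrics,
                                  transform(clinical,
                                            patient_id = paste0("X", patient_id))),
               "no overlapping patients")
})
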