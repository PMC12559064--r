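# Synthetic clinical/radiologist tables with prescribed rank correlations.
#
# A Gaussian copula: target Spearman correlations are converted to latent
# Pearson correlations via r = 2 sin(pi * rho_s / 6), a joint normal draw is
# taken, and each column is pushed through a monotone marginal transform
# (heavy-tailed for proBNP-like labs, 4-level ordinal for Likert-type
# radiologist scores, plain normal for the rest). Monotone transforms leave
# Spearman correlations of the continuous columns untouched; ordinal
# discretization attenuates them slightly.

#' Marginal specifications for the simulated clinical variables
#'
#' The 13 comparison variables — four radiologist Likert scores (mosaic
#' attenuation, perfusion centralization, distribution of perfusion defects,
#' subpleural perfusion deficit), PA/aorta diameter ratio, RV diameter, RA
#' area, 6-min walk distance, proBNP, mean PA pressure, wedge pressure,
#' vascular resistance, arterial O2 saturation — with location/scale typical
#' of a CTEPH cohort, plus the six pipeline metrics as metric-like columns.
#'
#' @return Named list; each element is `list(type=, ...)` with `type` one of
#'   `"normal"` (`mean`, `sd`), `"lognormal"` (`meanlog`, `sdlog`),
#'   `"likert"` (4 levels, 0-3).
#' @export
clinical_marginals <- function() {
  list(
    prop_oligemic  = list(type = "normal", mean = 0.22, sd = 0.10),
    prop_normal    = list(type = "normal", mean = 0.55, sd = 0.15),
    prop_hyperemic = list(type = "normal", mean = 0.23, sd = 0.10),
    entropy_high   = list(type = "normal", mean = 10.5, sd = 1.5),
    entropy_medium = list(type = "normal", mean = 11.5, sd = 1.2),
    slope_mean     = list(type = "normal", mean = -60, sd = 55),
    mosaic_attenuation  = list(type = "likert"),
    centralization      = list(type = "likert"),
    defect_distribution = list(type = "likert"),
    subpleural_deficit  = list(type = "likert"),
    pa_aorta_ratio = list(type = "normal", mean = 1.05, sd = 0.15),
    rv_diameter    = list(type = "normal", mean = 45, sd = 8),
    ra_area        = list(type = "normal", mean = 7, sd = 3),
    six_mwd        = list(type = "normal", mean = 398, sd = 111),
    probnp         = list(type = "lognormal", meanlog = log(1010), sdlog = 1.3),
    pamp           = list(type = "normal", mean = 43, sd = 13),
    pcwp           = list(type = "normal", mean = 10, sd = 4),
    pvr            = list(type = "normal", mean = 8.0, sd = 3.6),
    sao2           = list(type = "normal", mean = 93.5, sd = 3)
  )
}

#' Generate a synthetic clinical table by Gaussian copula
#'
#' @param targets square target Spearman correlation matrix with dimnames
#'   naming the variables; must be positive semi-definite after the latent
#'   conversion `r = 2 sin(pi * rho_s / 6)`. Defaults to the identity over
#'   [clinical_marginals()] (independent columns).
#' @param n_patients rows to draw.
#' @param seed RNG seed; the table is reproducible from it.
#' @param marginals named list of marginal specs (see [clinical_marginals()]);
#'   variables missing from it get a standard-normal marginal.
#' @return Data frame with `patient_id` plus one column per target variable.
#' @export
generate_clinical_table <- function(targets = NULL, n_patients = 52,
                                    seed = 1L,
                                    marginals = clinical_marginals()) {
  if (is.null(targets)) {
    vars <- names(marginals)
    targets <- diag(length(vars))
    dimnames(targets) <- list(vars, vars)
  }
  vars <- rownames(targets)
  if (is.null(vars) || !identical(vars, colnames(targets)))
    stopf("targets must be a square matrix with matching dimnames")
  if (any(abs(targets - t(targets)) > 1e-12) || any(abs(diag(targets) - 1) > 1e-12))
    stopf("targets must be symmetric with unit diagonal")
  latent <- 2 * sin(pi * targets / 6)
  diag(latent) <- 1
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf("target correlation matrix is not positive semi-definite after latent conversion (smallest eigenvalue %.3g)",
          min(ev))
  # PSD but possibly singular: factor via eigen to tolerate zero eigenvalues
  ee <- eigen(latent, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), nrow(latent))

  z <- with_seed(seed,
    matrix(rnorm(n_patients * nrow(latent)), nrow = n_patients) %*% t(L))
  u <- pnorm(z)
  cols <- lapply(seq_along(vars), function(j) {
    m <- marginals[[vars[j]]]
    if (is.null(m)) m <- list(type = "normal", mean = 0, sd = 1)
    switch(m$type,
      normal = stats::qnorm(u[, j], m$mean, m$sd),
      lognormal = stats::qlnorm(u[, j], m$meanlog, m$sdlog),
      likert = findInterval(u[, j], c(0.25, 0.5, 0.75)),
      stopf("unknown marginal type '%s' for %s", m$type, vars[j]))
  })
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)), cols)
  names(out) <- c("patient_id", vars)
  out
}

#' Build a target Spearman matrix from selected pairs
#'
#' Convenience builder: identity matrix over `vars` with the given pairwise
#' targets filled in symmetrically.
#'
#' @param vars character vector of variable names.
#' @param pairs data frame with columns `a`, `b`, `rho`.
#' @return Square matrix with dimnames.
#' @export
spearman_targets <- function(vars, pairs = NULL) {
  m <- diag(length(vars))
  dimnames(m) <- list(vars, vars)
  if (!is.null(pairs))
    for (i in seq_len(nrow(pairs))) {
      m[pairs$a[i], pairs$b[i]] <- pairs$rho[i]
      m[pairs$b[i], pairs$a[i]] <- pairs$rho[i]
    }
  m
}
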