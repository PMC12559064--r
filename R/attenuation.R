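# Three-compartment attenuation model.
#
# A 1-D Gaussian mixture with exactly three components is fitted to the pooled
# attenuation samples of both lungs by variational Bayesian estimation
# (Dirichlet prior on the weights, Normal-Gamma prior on each mean/precision).
# After fitting, components are ordered by mean and mapped
# low -> oligemic, middle -> normal, high -> hyperemic.
#
# CT attenuation is integer-quantized at source, so the samples are collapsed
# to a weighted histogram (default bin width 1 HU) before fitting; the VB
# updates below carry the bin weights exactly. This makes the fit O(#bins),
# independent of sample order, and deterministic.

COMPARTMENTS <- c("oligemic", "normal", "hyperemic")

#' Prior and optimizer settings for the attenuation mixture
#'
#' @param alpha0 Dirichlet weight-concentration per component. The default 1/3
#'   is weakly sparsity-inducing: it lets a component vanish gracefully in
#'   near-unimodal lungs instead of splitting the dominant mode.
#' @param beta0 prior relative precision of each component mean around the
#'   sample mean (weak by default).
#' @param a0,b0 shape/rate of the Gamma prior on each component precision
#'   (HU^-2); the defaults are close to flat.
#' @param max_iter maximum VB iterations.
#' @param tol convergence threshold on the per-sample change of the evidence
#'   lower bound.
#' @param hist_bin_width HU width of the histogram bins the fit runs on.
#' @param subsample_cap samples above this count are reduced to a seeded
#'   uniform subsample before fitting (classification always uses the full
#'   volume).
#' @return A list of class `vb_config`.
#' @export
vb_config <- function(alpha0 = 1 / 3, beta0 = 1e-3, a0 = 1e-3, b0 = 1e-3,
                      max_iter = 500L, tol = 1e-8, hist_bin_width = 1,
                      subsample_cap = 2e6) {
  structure(list(alpha0 = alpha0, beta0 = beta0, a0 = a0, b0 = b0,
                 max_iter = as.integer(max_iter), tol = tol,
                 hist_bin_width = hist_bin_width,
                 subsample_cap = subsample_cap),
            class = "vb_config")
}

#' Fit the three-compartment attenuation mixture
#'
#' Variational Bayesian estimation of a three-component 1-D Gaussian mixture on
#' the pooled attenuation samples of both lungs. Initialization is
#' deterministic: component means start at the 10th/50th/90th percentiles of
#' the samples with each sample hard-assigned to its nearest initial mean
#' (ties to the lower mean), so repeated runs with the same seed and
#' configuration are bitwise identical; the seed only governs the optional
#' subsampling step.
#'
#' @param values numeric vector of HU samples from both lungs (>= 30 required;
#'   a warning is issued below 10,000).
#' @param config a [vb_config()].
#' @param seed integer seed used only if subsampling triggers.
#' @return An object of class `attenuation_model`: `components` (data frame
#'   with `label`, `weight`, `mean`, `sd`, ordered by increasing mean) and
#'   `fit_info` (`n_samples_used`, `n_iterations`, `converged`,
#'   `lower_bound_trace`).
#' @export
fit_attenuation_model <- function(values, config = vb_config(), seed = 1L) {
  values <- values[is.finite(values)]
  n_all <- length(values)
  if (n_all < 30) stopf("need at least 30 attenuation samples, got %d", n_all)
  if (n_all < 10000)
    warnf("only %d attenuation samples; mixture fit may be unstable", n_all)
  if (n_all > config$subsample_cap) {
    values <- with_seed(seed,
      values[sample.int(n_all, config$subsample_cap)])
  }

  # Collapse to a weighted histogram on a regular HU grid.
  bw <- config$hist_bin_width
  bin <- round(values / bw)
  tab <- sort(unique(bin))
  w <- tabulate(match(bin, tab))
  x <- tab * bw
  N <- sum(w)

  K <- 3L
  alpha0 <- config$alpha0; beta0 <- config$beta0
  a0 <- config$a0; b0 <- config$b0
  m0 <- sum(w * x) / N

  # Deterministic init: percentile means, hard nearest-mean responsibilities.
  qs <- as.numeric(quantile(rep.int(x, w), probs = c(0.1, 0.5, 0.9),
                            type = 7, names = FALSE))
  d2 <- abs(outer(x, qs, `-`))
  init_k <- max.col(-d2, ties.method = "first")   # tie -> lower-mean init
  r <- matrix(0, nrow = length(x), ncol = K)
  r[cbind(seq_along(x), init_k)] <- 1

  lb_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  ak <- bk <- betak <- mk <- alphak <- rep(NA_real_, K)

  for (iter in seq_len(config$max_iter)) {
    # M-step (weighted)
    Nk <- colSums(w * r)
    Nk_safe <- pmax(Nk, 1e-12)
    xbar <- colSums(w * r * x) / Nk_safe
    Sk <- colSums(w * r * (outer(x, xbar, `-`)^2)) / Nk_safe
    alphak <- alpha0 + Nk
    betak <- beta0 + Nk
    mk <- (beta0 * m0 + Nk * xbar) / betak
    ak <- a0 + Nk / 2
    bk <- b0 + 0.5 * (Nk * Sk + beta0 * Nk / betak * (xbar - m0)^2)

    # E-step
    Elnpi <- digamma(alphak) - digamma(sum(alphak))
    Elnlam <- digamma(ak) - log(bk)
    Elam <- ak / bk
    base_k <- Elnpi + 0.5 * Elnlam - 0.5 * log(2 * pi) - 0.5 / betak
    lrho <- sweep(-0.5 * sweep(outer(x, mk, `-`)^2, 2, Elam, `*`),
                  2, base_k, `+`)
    mx <- apply(lrho, 1, max)
    lZ <- mx + log(rowSums(exp(lrho - mx)))
    r <- exp(lrho - lZ)

    # ELBO = sum_b w_b ln Z_b - KL(q(pi)||p(pi)) - sum_k KL(q(mu,lam)||p)
    kl_dir <- lgamma(sum(alphak)) - sum(lgamma(alphak)) -
      lgamma(K * alpha0) + K * lgamma(alpha0) +
      sum((alphak - alpha0) * (digamma(alphak) - digamma(sum(alphak))))
    kl_gamma <- (ak - a0) * digamma(ak) - lgamma(ak) + lgamma(a0) +
      a0 * (log(bk) - log(b0)) + ak * (b0 - bk) / bk
    kl_norm <- 0.5 * (log(betak / beta0) + beta0 / betak - 1 +
                        beta0 * (mk - m0)^2 * Elam)
    lb <- (sum(w * lZ) - kl_dir - sum(kl_gamma + kl_norm)) / N
    lb_trace <- c(lb_trace, lb)
    if (iter > 1 && abs(lb - lb_trace[iter - 1]) < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warnf("attenuation mixture did not converge within %d iterations",
          config$max_iter)

  comp <- data.frame(
    weight = alphak / sum(alphak),
    mean = mk,
    sd = sqrt(bk / ak)
  )
  ord <- order(comp$mean, seq_len(K))   # stable: ties keep lower index first
  comp <- comp[ord, , drop = FALSE]
  comp <- cbind(label = COMPARTMENTS, comp)
  rownames(comp) <- NULL

  structure(list(
    components = comp,
    fit_info = list(n_samples_used = length(values), n_iterations = iter,
                    converged = converged, lower_bound_trace = lb_trace)
  ), class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat("<attenuation_model> 3-component VB Gaussian mixture\n")
  print(transform(x$components, weight = round(weight, 4),
                  mean = round(mean, 1), sd = round(sd, 1)))
  cat(sprintf(" fit: n=%d, %d iterations, converged=%s\n",
              x$fit_info$n_samples_used, x$fit_info$n_iterations,
              x$fit_info$converged))
  invisible(x)
}

# Per-component log weighted Gaussian density at x (n x 3 matrix).
component_log_scores <- function(model, x) {
  cm <- model$components
  vapply(seq_len(nrow(cm)), function(k) {
    log(cm$weight[k]) + dnorm(x, cm$mean[k], cm$sd[k], log = TRUE)
  }, numeric(length(x)))
}

#' Classify lung voxels into perfusion compartments
#'
#' Assigns each in-scope voxel (inside either lung, attenuation within
#' `clip_range`) to the mixture component with the highest posterior
#' responsibility, i.e. the largest weight x Gaussian density at the voxel's
#' HU. Ties go to the lower-mean component.
#'
#' @param volume a [ct_volume()].
#' @param seg a [segmentation_set()].
#' @param model an [fit_attenuation_model()] result.
#' @param clip_range HU window; voxels outside stay background.
#' @return A `compartment_mask`: integer 3-D array with 0 = background,
#'   1 = oligemic, 2 = normal, 3 = hyperemic.
#' @export
classify_voxels <- function(volume, seg, model, clip_range = c(-1024, 100)) {
  lung <- seg$lung_left | seg$lung_right
  lin <- which(lung)
  vals <- volume$data[lin]
  keep <- vals >= clip_range[1] & vals <= clip_range[2]
  lin <- lin[keep]
  scores <- component_log_scores(model, vals[keep])
  lab <- max.col(scores, ties.method = "first")  # components ordered by mean
  out <- array(0L, dim = dim(volume$data))
  out[lin] <- lab
  structure(out, class = c("compartment_mask", class(out)))
}

#' Relative compartment proportions
#'
#' The headline proportion of each compartment is its mixture weight (its
#' relative proportion in the attenuation histogram); the voxel-count fraction
#' from the MAP classification mask is reported alongside for QC.
#'
#' @param model an [fit_attenuation_model()] result.
#' @param mask optional `compartment_mask` from [classify_voxels()].
#' @return Data frame with columns `compartment`, `weight_based` and (when a
#'   mask is supplied) `count_based`; both columns sum to 1.
#' @export
compartment_proportions <- function(model, mask = NULL) {
  out <- data.frame(compartment = COMPARTMENTS,
                    weight_based = model$components$weight)
  if (!is.null(mask)) {
    counts <- tabulate(mask[mask > 0L], nbins = 3L)
    out$count_based <- counts / sum(counts)
  }
  out
}
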