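# Correlation reporting: Spearman rho with Benjamini-Hochberg FDR control,
# plus the screening checks used for descriptive reporting (Grubbs outlier
# screen, D'Agostino-Pearson normality screen).

#' Spearman rank correlation with t-approximation p-value
#'
#' Midrank-tied Spearman rho (Pearson correlation of midranks) on the
#' complete pairs; p from the t approximation on n - 2 degrees of freedom
#' (adequate at n >= 10; use `exact = TRUE` for an exact permutation p at
#' tiny n).
#'
#' @param x,y numeric vectors of equal length; incomplete pairs are dropped.
#' @param exact compute the p-value by full permutation enumeration
#'   (only allowed for n <= 8).
#' @return List: `rho`, `p`, `n`, `ok` (FALSE with `reason` when fewer than 4
#'   complete pairs or a variable has zero variance).
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 4)
    return(list(rho = NA_real_, p = NA_real_, n = n, ok = FALSE,
                reason = "fewer than 4 complete pairs"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, ok = FALSE,
                reason = "zero variance"))
  rho <- cor(rank(x), rank(y))
  if (exact) {
    if (n > 8) stopf("exact permutation p only supported for n <= 8")
    perms <- permutations_of(n)
    rx <- rank(x)
    stats_all <- apply(perms, 1, function(p) cor(rx, rank(y)[p]))
    p_val <- mean(abs(stats_all) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p_val <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_val <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = p_val, n = n, ok = TRUE, reason = NA_character_)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Standard step-up rule at level `alpha`: with ordered p-values `p_(1) <=
#' ... <= p_(m)`, the critical p is the largest `p_(k)` with
#' `p_(k) <= alpha * k / m` (0 if none); every p at or below it is flagged.
#'
#' @param p numeric p-values in `[0, 1]`; `NA`s are carried through unflagged
#'   and excluded from the family size.
#' @param alpha FDR level.
#' @return List: `significant` (logical, same length as `p`), `critical_p`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0) stopf("empty p-value list")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  m <- sum(ok)
  sig <- rep(FALSE, length(p))
  crit <- 0
  if (m > 0) {
    ps <- sort(p[ok])
    pass <- which(ps <= alpha * seq_len(m) / m)
    if (length(pass)) crit <- ps[max(pass)]
    sig[ok] <- p[ok] <= crit & crit > 0
  }
  list(significant = sig, critical_p = crit)
}

#' Grubbs screen for a single outlier
#'
#' Two-sided single-Grubbs statistic `G = max |x_i - mean| / sd` against the
#' t-based critical value at level `alpha`. Screening only: the flagged value
#' is reported, never removed.
#'
#' @param values numeric vector (>= 7 non-missing values required).
#' @param alpha test level.
#' @return List: `outlier_index` (index into `values`, or `NA` if none),
#'   `G`, `critical`, `ok` (`FALSE` with `reason` when not computable).
#' @export
grubbs_screen <- function(values, alpha = 0.05) {
  idx <- which(!is.na(values))
  x <- values[idx]
  n <- length(x)
  if (n < 7)
    return(list(outlier_index = NA_integer_, G = NA_real_,
                critical = NA_real_, ok = FALSE,
                reason = "fewer than 7 values"))
  if (sd(x) == 0)
    return(list(outlier_index = NA_integer_, G = NA_real_,
                critical = NA_real_, ok = FALSE, reason = "zero variance"))
  dev <- abs(x - mean(x))
  G <- max(dev) / sd(x)
  tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  out_i <- if (G > crit) idx[which.max(dev)] else NA_integer_
  list(outlier_index = out_i, G = G, critical = crit, ok = TRUE,
       reason = NA_character_)
}

#' D'Agostino-Pearson omnibus normality screen
#'
#' Combines the skewness Z (D'Agostino 1970) and kurtosis Z (Anscombe-Glynn
#' 1983) transforms into the omnibus statistic `K2 = Z1^2 + Z2^2 ~ chi^2(2)`.
#' Used only to choose mean +/- SD vs median (IQR) in descriptive reporting.
#'
#' @param values numeric vector (>= 8 non-missing values required).
#' @return List: `p`, `K2`, `z_skew`, `z_kurt`, `ok` (`FALSE` with `reason`
#'   when not computable).
#' @export
normality_screen <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8)
    return(list(p = NA_real_, K2 = NA_real_, z_skew = NA_real_,
                z_kurt = NA_real_, ok = FALSE,
                reason = "fewer than 8 values"))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5                       # sample skewness g1
  b2 <- m4 / m2^2                         # sample kurtosis g2 (non-excess)

  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z1^2 + z2^2
  list(p = pchisq(K2, df = 2, lower.tail = FALSE), K2 = K2,
       z_skew = z1, z_kurt = z2, ok = TRUE, reason = NA_character_)
}

#' Spearman cross-correlation report with FDR control
#'
#' Correlates every metric column against every clinical variable across
#' patients (pairwise deletion of missing values) and applies
#' Benjamini-Hochberg across the whole family of reported pairs; the
#' data-derived critical p is returned alongside, mirroring a corrected
#' critical p-value printed in a report header.
#'
#' @param metrics data frame with a `patient_id` column plus metric columns.
#' @param clinical data frame with a `patient_id` column plus clinical
#'   variables.
#' @param alpha FDR level.
#' @param metric_cols,clinical_cols column selections; default every numeric
#'   column of each table.
#' @return A `correlation_report`: data frame in long format (`metric`,
#'   `variable`, `rho`, `p`, `n`, `significant`) with attributes
#'   `critical_p` and `alpha`.
#' @export
correlation_report <- function(metrics, clinical, alpha = 0.05,
                               metric_cols = NULL, clinical_cols = NULL) {
  if (!"patient_id" %in% names(metrics) || !"patient_id" %in% names(clinical))
    stopf("both tables need a patient_id column")
  merged <- merge(metrics, clinical, by = "patient_id",
                  suffixes = c("", ".clin"))
  if (nrow(merged) == 0) stopf("no overlapping patients between the tables")
  num_cols <- function(df, skip) names(df)[vapply(df, is.numeric, TRUE) &
                                             !names(df) %in% skip]
  if (is.null(metric_cols)) metric_cols <- num_cols(metrics, "patient_id")
  if (is.null(clinical_cols))
    clinical_cols <- setdiff(num_cols(clinical, "patient_id"), metric_cols)
  grid <- expand.grid(metric = metric_cols, variable = clinical_cols,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$variable[i]
    if (!v %in% names(merged)) v <- paste0(v, ".clin")
    spearman_cor(merged[[grid$metric[i]]], merged[[v]])
  })
  out <- data.frame(grid,
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    n = vapply(res, `[[`, numeric(1), "n"))
  bh <- bh_adjust(out$p, alpha)
  out$significant <- bh$significant
  attr(out, "critical_p") <- bh$critical_p
  attr(out, "alpha") <- alpha
  class(out) <- c("correlation_report", class(out))
  out
}
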