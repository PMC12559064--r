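# Small programmatic fixtures shared across test files.

# A minimal valid chest: two lung boxes inside a body, optional veins.
tiny_chest <- function(hu_lung = -800, dims = c(12L, 10L, 8L),
                       spacing = c(2, 2, 2), veins = TRUE) {
  arr <- array(40, dim = dims)
  ll <- array(FALSE, dims); ll[2:5, 3:8, 2:7] <- TRUE
  lr <- array(FALSE, dims); lr[8:11, 3:8, 2:7] <- TRUE
  vn <- array(FALSE, dims)
  if (veins) vn[6:7, 5, 4] <- TRUE
  arr[ll | lr] <- hu_lung
  vol <- ct_volume(arr, spacing)
  seg <- segmentation_set(ll, lr, vn, vol, min_lung_voxels = 1)
  list(volume = vol, seg = seg, lung_left = ll, lung_right = lr, veins = vn)
}

# O(n * m) brute-force Euclidean distance transform oracle.
brute_edt <- function(mask, spacing) {
  dims <- dim(mask)
  seeds <- which(mask)
  stopifnot(length(seeds) > 0)
  sc <- arrayInd(seeds, dims)
  out <- array(Inf, dims)
  all_idx <- arrayInd(seq_len(prod(dims)), dims)
  for (v in seq_len(prod(dims))) {
    d2 <- (sweep(sc, 2, all_idx[v, ]) %*% diag(spacing))^2
    out[v] <- sqrt(min(rowSums(d2)))
  }
  out
}

# Hand midrank-Spearman oracle: Pearson product-moment formula on midranks.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Step-up BH oracle by explicit enumeration over all k.
brute_bh <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  crit <- 0
  for (k in seq_len(m)) if (ps[k] <= alpha * k / m) crit <- ps[k]
  list(significant = p <= crit & crit > 0, critical_p = crit)
}
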