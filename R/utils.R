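# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG flow.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Physical coordinates of voxel centers: 0-based index -> (i + 0.5) * spacing.
voxel_centers <- function(idx0, spacing) {
  sweep(sweep(idx0 + 0.5, 2, spacing, `*`), 2, c(0, 0, 0), `+`)
}

# arrayInd (1-based) -> n x 3 matrix of physical mm coordinates.
coords_mm_from_lin <- function(lin_idx, dim, spacing) {
  ai <- arrayInd(lin_idx, .dim = dim)
  voxel_centers(ai - 1, spacing)
}

# 32-bit FNV-1a over a character scalar; provenance fingerprint for configs.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # bitwXor needs values < 2^31; split off the top bit first
    hi <- h >= 2147483648
    h <- bitwXor(as.integer(h - hi * 2147483648), b) + hi * 2147483648
    # h * p mod 2^32 in 16-bit limbs to stay within double precision
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + (h1 * p %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
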