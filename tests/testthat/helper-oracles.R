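# Independent oracles and shared fixtures.  Oracles are deliberately naive
# (brute force / closed form) and never call the code paths they check.

# Brute-force Euclidean distance (metres) to the nearest TRUE mask pixel.
bf_distance <- function(mask, cell_size) {
  tgt <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    out[r, c] <- sqrt(min((tgt[, 1] - r)^2 + (tgt[, 2] - c)^2)) * cell_size
  }
  out
}

# Brute-force top-k selection by potential (ties broken by the same seeded
# random key convention the allocator documents).
bf_topk <- function(tpm, pool, k, tie_seed) {
  set.seed(tie_seed)
  key <- stats::runif(length(pool))
  pool[order(-tpm[pool], key)][seq_len(k)]
}

# Closed-form per-pixel carbon projections (mirrors the published equations,
# written independently of the package implementation).
oracle_acd_old <- function(acd, csr, gp = 40) acd + csr * gp
oracle_acd_young <- function(acd, csr_y, csr_o) {
  g <- acd / csr_y
  acd21 <- acd + csr_y * (21 - g)
  acd21 + csr_o * (40 - (21 - g))
}
oracle_acd_new <- function(csr_y, gp = 17.5) csr_y * gp

# Cached fixtures: building a landscape is the expensive part of many tests.
.fixtures <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_bundle <- function() cached("b64", generate_landscape(c(64, 64), seed = 11))

# An fnf pair with a change grid where changed pixels carry NO driver signal
# (selected uniformly at random), for null-model checks.
random_change_bundle <- function(seed) {
  b <- generate_landscape(c(128, 128), seed = seed)
  fnf_mid <- reclassify_to_fnf(b$landcover[[2]], cell_size = b$cell_size)
  fnf <- reclassify_to_fnf(b$landcover[[3]], cell_size = b$cell_size)
  set.seed(seed + 500)
  forest <- which(unclass(fnf) == 1L)
  flip <- sample(forest, round(0.1 * length(forest)))
  fnf2 <- unclass(fnf)
  fnf2[flip] <- 0L
  list(bundle = b, fnf1 = fnf,
       fnf2 = fnf_grid(fnf2, cell_size = b$cell_size),
       change_prev = detect_change(fnf_mid, fnf))
}
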