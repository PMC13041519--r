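# Independent oracles and small fixtures used across the suite.

# Naive per-pixel window integral: walks every column of the discretized
# collision window and counts occupied pixels one by one. Deliberately
# mirrors only the *definition* (nearest-pixel center, L columns left-biased,
# out-of-bounds columns count zero but stay in the denominator), not the
# vectorized cumulative-sum implementation.
naive_window_probability <- function(mask, width_m, d_collision, l) {
  scale <- width_m / ncol(mask)
  L <- max(1L, as.integer(round(l / scale)))
  c0 <- round(d_collision / scale)          # 0-based center pixel
  start <- c0 - L %/% 2L
  occupied <- 0L
  for (j in seq_len(L)) {
    col0 <- start + j - 1L                  # 0-based column
    if (col0 >= 0 && col0 < ncol(mask)) {
      for (i in seq_len(nrow(mask))) {
        occupied <- occupied + mask[i, col0 + 1L]
      }
    }
  }
  occupied / (L * nrow(mask))
}

random_mask <- function(nr, nc, p = 0.4) {
  m <- matrix(rbinom(nr * nc, 1L, p), nr, nc)
  if (!any(m == 1L)) m[sample(length(m), 1L)] <- 1L
  m
}

test_silhouette <- function(resolution = 400L) {
  generate_silhouette(silhouette_spec_737(), resolution = resolution)
}

tiny_grid <- function(...) {
  build_grid(utils::modifyList(list(
    sa = list(from = 5, to = 9, by = 4),
    delta = list(from = 0, to = 0.5, by = 0.5),
    d_min = list(from = 2, to = 12, n = 2),
    sv = list(from = 70.47, to = 270.97, n = 2),
    beta = list(from = 0.5, to = 8.5, n = 2),
    iterations = 40L
  ), list(...)))
}
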