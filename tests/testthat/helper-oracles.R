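# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive formulations (explicit loops,
# exhaustive scans) so they share no code path with the implementation.

# Exhaustive Heaviside scan: evaluates the squared error at every candidate
# (unique-value midpoints plus 0 and 1) by direct elementwise comparison.
brute_heaviside <- function(a, S) {
  u <- sort(unique(a))
  cand <- c(0, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, 1)
  sse <- vapply(cand, function(ct) sum((S - as.numeric(a >= ct))^2),
                numeric(1))
  best <- which(sse == min(sse))[1]
  list(a_T = cand[best], sse = sse[best])
}

# O(n^2) pairwise means by explicit double loop.
brute_pair_dist <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  tot <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    cnt <- cnt + 1
  }
  tot / cnt
}

brute_pair_time <- function(t) {
  n <- length(t)
  if (n < 2) return(NA_real_)
  tot <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + abs(t[i] - t[j])
    cnt <- cnt + 1
  }
  tot / cnt
}

# Disc-shaped territory mask with given centre (0-based px) and radius (px).
disc_mask <- function(nrow, ncol, cx, cy, radius) {
  xs <- matrix(rep(0:(ncol - 1), each = nrow), nrow)
  ys <- matrix(rep(0:(nrow - 1), ncol), nrow)
  sqrt((xs - cx)^2 + (ys - cy)^2) <= radius
}

# Tiny single-astrocyte config for image-level tests.
tiny_config <- function(seed = 1L, n = 1L, ...) {
  sim_config(n_astrocytes = n, territory_radius_um = 20,
             soma_radius_um = 4, seed = seed, ...)
}
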