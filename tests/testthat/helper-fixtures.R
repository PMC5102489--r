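# Shared fixtures, all built in code.

# Small landscape with full observer coverage (sampling mask == valid mask).
tiny_stack <- function(seed = 7, n = 32)
  generate_layers(seed, n, n, sampling_km = 1e6)

# 4x4 station grid, `spacing` km apart.
grid_stations <- function(n_side = 4, spacing = 2.5, origin = 10) {
  g <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  data.frame(station_id = sprintf("S%02d", seq_len(n_side^2)),
             x_km = origin + (g$ix - 1) * spacing,
             y_km = origin + (g$iy - 1) * spacing)
}

# Simulate an M0/Mh encounter matrix directly: per-individual detection
# probability p (vector of length N), t occasions; rows with no capture
# dropped, as in real data.
sim_history <- function(N, p, t) {
  X <- matrix(rbinom(N * t, 1, rep(p, t)), nrow = N)
  X[rowSums(X) > 0, , drop = FALSE]
}

# Brute-force M0 likelihood grid search over integer N.
m0_grid_oracle <- function(X, n_max = 500) {
  t <- ncol(X); M <- nrow(X); n_tot <- sum(X)
  grid <- M:max(n_max, M + 1)
  ll <- vapply(grid, function(N) {
    p <- n_tot / (t * N)
    if (p <= 0 || p > 1) return(-Inf)
    if (p == 1) return(lgamma(N + 1) - lgamma(N - M + 1))
    lgamma(N + 1) - lgamma(N - M + 1) + n_tot * log(p) +
      (t * N - n_tot) * log(1 - p)
  }, 0.0)
  grid[which.max(ll)]
}

# Independent capture-frequency count.
capture_freq_oracle <- function(X) {
  cnt <- rowSums(X)
  vapply(seq_len(ncol(X)), function(k) sum(cnt == k), 0)
}

# Exhaustive Mann-Whitney pair count (ties = 1/2).
auc_pair_oracle <- function(p, b) {
  wins <- 0
  for (x in p) for (y in b)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(p) * length(b))
}
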