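# Shared fixtures, all built in code.

# Small uniformly scattered coordinate set.
toy_coords <- function(n = 20, extent = 100, seed = 1) {
  set.seed(seed)
  cbind(x_km = runif(n, 0, extent), y_km = runif(n, 0, extent))
}

# Minimal sample table from explicit pieces.
toy_sample_set <- function(response, coords, ...) {
  out <- data.frame(id = seq_along(response),
                    x_km = coords[, 1], y_km = coords[, 2],
                    response = response)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# Brute-force Matheron estimator: explicit double loop over all pairs,
# independent of the package's vectorized path.
brute_force_variogram <- function(values, coords, edges) {
  n <- length(values)
  n_bins <- length(edges) - 1
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      for (b in seq_len(n_bins)) {
        if (h >= edges[b] && h < edges[b + 1]) {
          sums[b] <- sums[b] + (values[i] - values[j])^2
          counts[b] <- counts[b] + 1L
          break
        }
      }
    }
  }
  list(semivariance = ifelse(counts > 0, sums / (2 * counts), NA_real_),
       pair_count = counts)
}

# Brute-force fold diameter.
brute_force_diameter <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  mx <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mx <- max(mx, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
  }
  mx
}
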