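# Sampling layouts over a rectangular study extent.
#
# The clustered layout emulates forest-inventory campaigns: plots aggregated
# into dense clusters along access routes, leaving large swaths of the
# region unsampled. This sampling geometry, combined with long-range
# autocorrelation, is what makes random train/test splits non-independent.

check_extent <- function(extent) {
  extent <- as.numeric(extent)
  if (length(extent) != 2L || !all(is.finite(extent)) || any(extent <= 0)) {
    stopf("extent must be two positive numbers (width_km, height_km)")
  }
  extent
}

#' Uniform random sampling layout
#'
#' @param extent rectangle dimensions `c(width_km, height_km)`; samples fall
#'   in `[0, width] x [0, height]`.
#' @param n number of sample locations.
#' @param seed integer seed.
#' @return two-column matrix of coordinates (`x_km`, `y_km`).
#' @export
sample_uniform_layout <- function(extent, n, seed = NULL) {
  extent <- check_extent(extent)
  if (n < 1) stopf("n must be >= 1")
  with_seed(seed, {
    cbind(x_km = stats::runif(n, 0, extent[1]),
          y_km = stats::runif(n, 0, extent[2]))
  })
}

#' Clustered sampling layout
#'
#' Draws `n_clusters` cluster centers uniformly over the extent, then places
#' exactly `points_per_cluster` members around each center with isotropic
#' Gaussian offsets of scale `cluster_radius` (km). Members falling outside
#' the extent are re-drawn, so all returned points lie inside. Member counts
#' are fixed (not Poisson) so a layout is fully reproducible from its seed.
#'
#' @param extent rectangle dimensions `c(width_km, height_km)`.
#' @param n_clusters number of clusters (>= 1).
#' @param points_per_cluster members per cluster.
#' @param cluster_radius isotropic offset scale (km); `0` collapses each
#'   cluster onto its center.
#' @param seed integer seed.
#' @return two-column matrix of `n_clusters * points_per_cluster` coordinates,
#'   with the generating cluster index attached as attribute `"cluster"`.
#' @export
sample_clustered_layout <- function(extent, n_clusters, points_per_cluster,
                                    cluster_radius, seed = NULL) {
  extent <- check_extent(extent)
  if (n_clusters < 1) stopf("n_clusters must be >= 1")
  if (points_per_cluster < 1) stopf("points_per_cluster must be >= 1")
  if (cluster_radius < 0) stopf("cluster_radius must be >= 0")
  with_seed(seed, {
    centers <- cbind(stats::runif(n_clusters, 0, extent[1]),
                     stats::runif(n_clusters, 0, extent[2]))
    n <- n_clusters * points_per_cluster
    out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x_km", "y_km")))
    cluster <- rep(seq_len(n_clusters), each = points_per_cluster)
    for (i in seq_len(n)) {
      center <- centers[cluster[i], ]
      repeat {
        p <- center + stats::rnorm(2, sd = cluster_radius)
        if (p[1] >= 0 && p[1] <= extent[1] && p[2] >= 0 && p[2] <= extent[2]) break
      }
      out[i, ] <- p
    }
    attr(out, "cluster") <- cluster
    out
  })
}
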