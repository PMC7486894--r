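# Fold construction for K-fold cross-validation.
#
# Random folds ignore location; spatial folds are compact geographic
# clusters obtained by cutting a complete-linkage dendrogram of the
# inter-sample distance matrix at height H, which guarantees that no two
# samples within a fold are farther apart than H.

new_spatial_folds <- function(fold_id, method, H = NA_real_, diameters = NULL) {
  structure(list(fold_id = as.integer(fold_id), K = max(as.integer(fold_id)),
                 method = method, H = H, fold_diameters = diameters),
            class = "spatial_folds")
}

#' Random K-fold assignment
#'
#' Uniform random partition into `K` folds whose sizes differ by at most
#' one; deterministic given `seed`.
#'
#' @param n number of samples.
#' @param K number of folds (default 10).
#' @param seed integer seed.
#' @return a `spatial_folds` object (`fold_id`, `K`, `method = "random"`).
#' @export
random_kfold_split <- function(n, K = 10, seed = NULL) {
  if (K < 2 || K > n) stopf("need 2 <= K <= n (K = %d, n = %d)", K, n)
  fold_id <- with_seed(seed, sample(rep(seq_len(K), length.out = n)))
  new_spatial_folds(fold_id, "random")
}

#' Spatial fold assignment by complete-linkage clustering
#'
#' Hierarchical clustering (complete linkage) of the pairwise distance
#' matrix, cut at height `H` km. Complete linkage makes the cut height an
#' upper bound on every within-fold pairwise distance, so each fold's
#' diameter is at most `H`. The number of folds K emerges from the data;
#' with `H` chosen slightly beyond the response's autocorrelation range,
#' folds are approximately spatially independent of one another.
#'
#' @param coords two-column matrix or data frame of planar coordinates (km).
#' @param H clustering height (km): maximum within-fold distance
#'   (default 150).
#' @return a `spatial_folds` object with per-fold diameters. A degenerate
#'   input whose points all fall within `H` of each other yields a single
#'   fold, flagged with a warning (unusable for cross-validation).
#' @export
spatial_kfold_split <- function(coords, H = 150) {
  coords <- as_coords(coords)
  n <- nrow(coords)
  if (n < 2) stopf("need at least 2 samples")
  if (!is.finite(H) || H <= 0) stopf("H must be > 0")
  d <- stats::dist(coords)
  hc <- stats::hclust(d, method = "complete")
  fold_id <- stats::cutree(hc, h = H)
  dm <- as.matrix(d)
  diameters <- vapply(seq_len(max(fold_id)), function(k) {
    idx <- which(fold_id == k)
    if (length(idx) < 2) 0 else max(dm[idx, idx])
  }, 0)
  if (max(fold_id) == 1L) {
    warning("all samples fall in a single spatial fold (every distance <= H); ",
            "unusable for cross-validation", call. = FALSE)
  }
  new_spatial_folds(fold_id, "clustered", H = H, diameters = diameters)
}

#' Manually supplied fold assignment
#'
#' Wraps an explicit fold-id vector (e.g. for worked examples or externally
#' defined blocks) in the `spatial_folds` container.
#'
#' @param fold_id integer vector of fold labels `1..K`.
#' @return a `spatial_folds` object (`method = "manual"`).
#' @export
manual_folds <- function(fold_id) {
  fold_id <- as.integer(fold_id)
  if (!setequal(unique(fold_id), seq_len(max(fold_id)))) {
    stopf("fold_id must use consecutive labels 1..K")
  }
  new_spatial_folds(fold_id, "manual")
}
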