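# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Coerce coordinates to a two-column numeric matrix and validate finiteness.
as_coords <- function(coords) {
  if (is.data.frame(coords)) {
    if (all(c("x_km", "y_km") %in% names(coords))) {
      coords <- cbind(coords$x_km, coords$y_km)
    } else {
      coords <- as.matrix(coords[, 1:2])
    }
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) {
    stop("coordinates must have two columns (x_km, y_km)", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  coords
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
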