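# Pixel quality-filter chain.
#
# Mirrors the exclusion sequence used to clean 1-km reference pixels before
# modeling: (1) drop pixels with low initial vegetation cover, (2) drop
# pixels backed by too few field plots, (3) drop disturbed pixels (forest
# loss or any fire occurrence during the composite period), (4) drop gross
# spectral outliers. Each stage reports removals as a percentage of its own
# input, matching how such audits are conventionally reported.

require_columns <- function(set, cols, stage) {
  missing <- setdiff(cols, names(set))
  if (length(missing)) {
    stopf("stage '%s' requires column(s): %s", stage,
          paste(missing, collapse = ", "))
  }
}

#' Remove pixels with low initial vegetation cover
#'
#' Removes rows with `forest_cover_pct` strictly below `min_cover_pct`
#' (boundary kept: "less than 89%" is removed, 89 itself is retained).
#'
#' @param set sample `data.frame` with a `forest_cover_pct` column.
#' @param min_cover_pct minimum cover retained (default 89).
#' @return filtered `data.frame`.
#' @export
filter_forest_cover <- function(set, min_cover_pct = 89) {
  require_columns(set, "forest_cover_pct", "cover")
  set[set$forest_cover_pct >= min_cover_pct, , drop = FALSE]
}

#' Remove pixels containing too few field plots
#'
#' Removes rows with `plot_count` below `min_plots` ("fewer than 3" removed;
#' exactly 3 retained).
#'
#' @param set sample `data.frame` with a `plot_count` column.
#' @param min_plots minimum plots retained (default 3).
#' @return filtered `data.frame`.
#' @export
filter_plot_count <- function(set, min_plots = 3) {
  require_columns(set, "plot_count", "plots")
  set[set$plot_count >= min_plots, , drop = FALSE]
}

#' Remove disturbed pixels
#'
#' Removes rows with cumulative forest loss strictly greater than
#' `max_loss_pct` OR any fire occurrence above `max_fire_pct` (default 0:
#' "nonnull" fire removed). Loss exactly at the threshold is kept.
#'
#' @param set sample `data.frame` with `forest_loss_pct` and `fire_pct`.
#' @param max_loss_pct maximum tolerated forest loss (%, default 5).
#' @param max_fire_pct maximum tolerated fire occurrence (%, default 0).
#' @return filtered `data.frame`.
#' @export
filter_disturbance <- function(set, max_loss_pct = 5, max_fire_pct = 0) {
  require_columns(set, c("forest_loss_pct", "fire_pct"), "disturbance")
  drop <- set$forest_loss_pct > max_loss_pct | set$fire_pct > max_fire_pct
  set[!drop, , drop = FALSE]
}

#' Remove gross spectral outliers
#'
#' Single-pass filter: for each named band, rows whose value deviates more
#' than `k_sd` standard deviations from the band mean are removed. Mean and
#' SD are the population statistics of the stage's *input* (no iteration);
#' re-running on the filtered output therefore removes nothing further only
#' when no new values cross the recomputed threshold. A zero-variance band
#' imposes no removals (with a message).
#'
#' @param set sample `data.frame`.
#' @param bands character vector of band column names to screen.
#' @param k_sd deviation threshold in SD units (default 10).
#' @return filtered `data.frame`.
#' @export
filter_spectral_outliers <- function(set, bands, k_sd = 10) {
  require_columns(set, bands, "outliers")
  if (nrow(set) < 2) stopf("outlier screening needs >= 2 rows")
  drop <- rep(FALSE, nrow(set))
  for (b in bands) {
    x <- set[[b]]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))   # population SD of the stage input
    if (s == 0) {
      message(sprintf("band '%s' has zero variance; no outlier removals", b))
      next
    }
    drop <- drop | abs(x - m) > k_sd * s
  }
  set[!drop, , drop = FALSE]
}

#' Configuration for the filter chain
#'
#' @param stages subset of `c("cover", "plots", "disturbance", "outliers")`,
#'   applied in this canonical order regardless of the order given.
#' @param min_cover_pct,min_plots,max_loss_pct,max_fire_pct,k_sd stage
#'   thresholds (see the individual filters).
#' @param outlier_bands band columns screened by the outlier stage.
#' @return a `filter_config` list.
#' @export
filter_config <- function(stages = c("cover", "plots", "disturbance", "outliers"),
                          min_cover_pct = 89, min_plots = 3, max_loss_pct = 5,
                          max_fire_pct = 0, outlier_bands = character(),
                          k_sd = 10) {
  known <- c("cover", "plots", "disturbance", "outliers")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown filter stage(s): %s", paste(bad, collapse = ", "))
  structure(list(stages = known[known %in% stages],
                 min_cover_pct = min_cover_pct, min_plots = min_plots,
                 max_loss_pct = max_loss_pct, max_fire_pct = max_fire_pct,
                 outlier_bands = outlier_bands, k_sd = k_sd),
            class = "filter_config")
}

#' Apply the pixel-filter chain with a per-stage audit report
#'
#' Applies the enabled stages in canonical order (cover -> plots ->
#' disturbance -> outliers). Percentages are computed against each stage's
#' input (the current filtered set), the convention used when auditing
#' pixel-exclusion chains.
#'
#' @param set sample `data.frame` with the QC columns the enabled stages need.
#' @param config a [filter_config()].
#' @return list with `set` (the filtered table) and `report` (a
#'   `filter_report` data frame: `stage`, `threshold`, `n_removed`,
#'   `pct_of_input`, with attributes `n_in`, `n_out`).
#' @export
apply_filters <- function(set, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n_in <- nrow(set)
  rows <- list()
  for (stage in config$stages) {
    n_before <- nrow(set)
    set <- switch(stage,
      cover = filter_forest_cover(set, config$min_cover_pct),
      plots = filter_plot_count(set, config$min_plots),
      disturbance = filter_disturbance(set, config$max_loss_pct, config$max_fire_pct),
      outliers = {
        if (length(config$outlier_bands) && n_before >= 2) {
          filter_spectral_outliers(set, config$outlier_bands, config$k_sd)
        } else {
          set
        }
      })
    removed <- n_before - nrow(set)
    threshold <- switch(stage,
      cover = config$min_cover_pct, plots = config$min_plots,
      disturbance = config$max_loss_pct, outliers = config$k_sd)
    rows[[stage]] <- data.frame(stage = stage, threshold = threshold,
                                n_removed = removed,
                                pct_of_input = if (n_before > 0) 100 * removed / n_before else 0)
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(report)) {
    report <- data.frame(stage = character(), threshold = numeric(),
                         n_removed = integer(), pct_of_input = numeric())
  }
  attr(report, "n_in") <- n_in
  attr(report, "n_out") <- nrow(set)
  class(report) <- c("filter_report", "data.frame")
  list(set = set, report = report)
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(list(n_in = attr(report, "n_in"),
                            n_out = attr(report, "n_out"),
                            stages = as.data.frame(report)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
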