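#' Map feature indices back to m/z intervals
#'
#' Inverts the window construction: a selected feature `F_index` corresponds
#' to the original mass interval starting at
#' `Original_mass = F_index * W_step + W_start`, of width one window step.
#' With the 54-1223 Da grid at step 1.0, `F_59` maps to 113-114 Da, `F_254`
#' to 308-309 Da, `F_256` to 310-311 Da.
#'
#' @param feature_index Integer vector of 0-based feature indices, each in
#'   `[0, n_windows - 1]`.
#' @param grid The [build_grid()] object the features were constructed with.
#' @return Tibble with columns `feature`, `feature_index`, `low`, `high`
#'   (Da; the window `[low, high)`).
#' @export
#' @examples
#' back_map(59, build_grid(54, 1223, 1.0))  # 113-114 Da
back_map <- function(feature_index, grid) {
  stopifnot(inherits(grid, "mz_grid"))
  feature_index <- as.integer(feature_index)
  if (any(feature_index < 0 | feature_index >= grid$n_windows)) {
    abort(sprintf("feature_index out of range [0, %d].", grid$n_windows - 1L))
  }
  low <- feature_index * grid$step + grid$start
  tibble(feature = paste0("F_", feature_index),
         feature_index = feature_index,
         low = low, high = low + grid$step)
}

#' Traverse common mass values inside a candidate interval
#'
#' Nominates marker masses within a back-mapped interval: all peaks of all
#' samples falling in `[low, high)` are grouped by their m/z rounded to
#' `decimals` places (substances closer than the rounding precision are
#' treated as the same species), and masses shared by at least
#' `min_support` of the samples are returned, ranked by the between-class
#' support gap (falling back to the standardized mean-height difference on
#' ties).
#'
#' @param cohort Peak-list cohort tibble.
#' @param interval One-row tibble with `low`/`high` (e.g. from
#'   [back_map()]), or a numeric `c(low, high)`.
#' @param decimals Rounding precision defining "the same mass" (default 3).
#' @param min_support Minimum fraction of all samples a mass must appear in
#'   (default 1, i.e. common to every sample).
#' @return Tibble ranked by `class_gap` descending: `mass`, `support`,
#'   `support_pos`, `support_neg`, `class_gap`, `mean_height_pos`,
#'   `mean_height_neg`.  Empty (zero rows) when no peak falls in the
#'   interval or no mass reaches `min_support`.
#' @export
common_mass_traversal <- function(cohort, interval, decimals = 3,
                                  min_support = 1) {
  check_cohort(cohort)
  if (is.data.frame(interval)) interval <- c(interval$low[1], interval$high[1])
  low <- interval[1]; high <- interval[2]

  samples <- cohort_samples(cohort)
  n_all <- nrow(samples)
  n_pos <- sum(normalize_label(samples$label) == "positive")
  n_neg <- n_all - n_pos

  hits <- cohort |>
    dplyr::filter(.data$mz >= low, .data$mz < high) |>
    dplyr::mutate(mass = round(.data$mz, decimals),
                  .pos = normalize_label(.data$label) == "positive")
  empty <- tibble(mass = numeric(), support = numeric(),
                  support_pos = numeric(), support_neg = numeric(),
                  class_gap = numeric(), mean_height_pos = numeric(),
                  mean_height_neg = numeric())
  if (nrow(hits) == 0) return(empty)

  pooled_sd <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) 1 else s
  }
  out <- hits |>
    dplyr::group_by(.data$mass) |>
    dplyr::summarise(
      support = dplyr::n_distinct(.data$sample_id) / n_all,
      support_pos = dplyr::n_distinct(.data$sample_id[.data$.pos]) /
        max(n_pos, 1),
      support_neg = dplyr::n_distinct(.data$sample_id[!.data$.pos]) /
        max(n_neg, 1),
      mean_height_pos = ifelse(any(.data$.pos),
                               mean(.data$height[.data$.pos]), 0),
      mean_height_neg = ifelse(any(!.data$.pos),
                               mean(.data$height[!.data$.pos]), 0),
      .std_gap = abs(.data$mean_height_pos - .data$mean_height_neg) /
        pooled_sd(.data$height),
      .groups = "drop"
    ) |>
    dplyr::mutate(class_gap = abs(.data$support_pos - .data$support_neg)) |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(dplyr::desc(.data$class_gap), dplyr::desc(.data$.std_gap),
                   .data$mass) |>
    dplyr::select("mass", "support", "support_pos", "support_neg",
                  "class_gap", "mean_height_pos", "mean_height_neg")
  out
}

#' Export a two-feature scatter table
#'
#' Coordinates of every sample in the plane of two selected windows — the
#' table behind the two-marker scatter visualizations (classes separate
#' along the planted/selected features; acquisition batches show as distinct
#' clusters when batch effects are present).  No rendering; see
#' [plot_feature_scatter()] for a ggplot layer on top.
#'
#' @param fm An [construct_features()] result.
#' @param index_pair Integer vector of two 0-based feature indices (a
#'   repeated index gives the degenerate diagonal).
#' @return Tibble `sample_id`, `x`, `y`, `label`, `batch`.
#' @export
scatter_export <- function(fm, index_pair) {
  stopifnot(inherits(fm, "ms_feature_matrix"), length(index_pair) == 2)
  if (any(index_pair < 0 | index_pair >= ncol(fm$values))) {
    abort("index_pair out of range.")
  }
  tibble(
    sample_id = rownames(fm$values),
    x = unname(fm$values[, index_pair[1] + 1L]),
    y = unname(fm$values[, index_pair[2] + 1L]),
    label = fm$samples$label[match(rownames(fm$values), fm$samples$sample_id)],
    batch = fm$samples$batch[match(rownames(fm$values), fm$samples$sample_id)]
  )
}
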