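#' Global m/z range of a cohort
#'
#' Traverses every peak of every sample and returns the global minimum and
#' maximum mass-to-charge ratio.  These bound the sliding-window grid: on the
#' coronary-heart-disease serum cohort the scan yields 54 and 1223 Da, on the
#' colorectal-liver-metastasis tissue cohort 400 and 1600 Da.
#'
#' @param cohort Peak-list cohort tibble (see [cohort_samples()]).
#' @return Named numeric vector `c(min_mz = , max_mz = )` in Da.
#' @export
#' @examples
#' cohort <- tibble::tibble(
#'   sample_id = "s1", label = "positive", batch = "b1",
#'   mz = c(54, 1223), rt = 1, height = 1, area = 1
#' )
#' scan_mz_range(cohort)
scan_mz_range <- function(cohort) {
  check_cohort(cohort)
  c(min_mz = min(cohort$mz), max_mz = max(cohort$mz))
}

#' Build a sliding-window m/z grid
#'
#' Partitions `[start, stop]` into `floor((stop - start) / step)` windows of
#' width `step`; window `i` (0-based) covers `[start + i*step,
#' start + (i+1)*step)` and the final window is right-closed at `stop` so the
#' maximum-m/z peak is never orphaned.  A degenerate range (or a step wider
#' than the range) yields a single window.  With the 54-1223 Da range, steps
#' 1.0, 1.5 and 2.0 give 1169, 779 and 584 windows.
#'
#' @param min_mz,max_mz Grid endpoints in Da (`max_mz >= min_mz`).
#' @param step Window width in Da, `> 0`.  The method's key tunable: small
#'   steps keep fine mass resolution but leave many windows empty, large
#'   steps average away between-class differences.
#' @return An object of class `mz_grid`: list with `start`, `stop`, `step`,
#'   `n_windows`.
#' @export
#' @examples
#' build_grid(54, 1223, 1.0)  # 1169 windows
build_grid <- function(min_mz, max_mz, step) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0) {
    abort("`step` must be a single positive number (Da).")
  }
  if (max_mz < min_mz) abort("`max_mz` must be >= `min_mz`.")
  # small tolerance so exactly-divisible ranges are not truncated by
  # floating-point representation (e.g. (1223 - 54) / 0.1)
  n <- max(1L, as.integer(floor((max_mz - min_mz) / step + 1e-9)))
  structure(
    list(start = as.numeric(min_mz), stop = as.numeric(max_mz),
         step = as.numeric(step), n_windows = n),
    class = "mz_grid"
  )
}

#' @export
print.mz_grid <- function(x, ...) {
  cat(sprintf("<mz_grid> %g-%g Da, step %g Da, %d windows (F_0..F_%d)\n",
              x$start, x$stop, x$step, x$n_windows, x$n_windows - 1L))
  invisible(x)
}

#' Window index of an m/z value
#'
#' `i = min(floor((mz - start) / step), n_windows - 1)`: each in-range peak
#' maps to exactly one window; the clamp implements the right-closure of the
#' last window.
#'
#' @param mz Numeric vector of m/z values inside `[start, stop]`.
#' @param grid An [build_grid()] object.
#' @return Integer vector of 0-based window indices.
#' @export
window_index <- function(mz, grid) {
  stopifnot(inherits(grid, "mz_grid"))
  pmin(as.integer(floor((mz - grid$start) / grid$step + 1e-9)),
       grid$n_windows - 1L)
}

#' Construct the aligned feature matrix
#'
#' The core alignment step: every sample's variable-length sparse peak list
#' becomes one fixed-length vector of per-window mean intensities.  Cell
#' `(s, i)` is the arithmetic mean of sample `s`'s peak heights (or areas)
#' whose m/z falls in window `i`; windows in which a sample detected no peak
#' are recorded in the missing mask and filled with `fill` (default 0,
#' reading "no signal detected").  No normalization or log transform is
#' applied.
#'
#' @param cohort Peak-list cohort tibble.
#' @param grid An [build_grid()] object covering every peak of the cohort.
#' @param peak_type `"height"` or `"area"`: which intensity channel to
#'   aggregate.
#' @param fill Value written into missing cells after masking (default 0).
#' @return An object of class `ms_feature_matrix`: list with `values`
#'   (samples x windows numeric matrix, rownames = sample ids, colnames
#'   `F_0...`), `missing` (logical matrix, same shape), `peak_type`,
#'   `grid`, and `samples` (the [cohort_samples()] tibble).
#' @export
construct_features <- function(cohort, grid, peak_type = c("height", "area"),
                               fill = 0) {
  check_cohort(cohort)
  stopifnot(inherits(grid, "mz_grid"))
  peak_type <- match.arg(peak_type)

  out_of_range <- cohort$mz < grid$start - 1e-9 | cohort$mz > grid$stop + 1e-9
  if (any(out_of_range)) {
    bad <- cohort[which(out_of_range)[1], ]
    abort(sprintf(
      "Peak outside grid range: sample '%s' has m/z %.6g (grid %g-%g). Rebuild the grid from scan_mz_range().",
      bad$sample_id, bad$mz, grid$start, grid$stop))
  }

  samples <- cohort_samples(cohort)
  n_s <- nrow(samples)
  n_w <- grid$n_windows

  agg <- cohort |>
    dplyr::mutate(.window = window_index(.data$mz, grid)) |>
    dplyr::group_by(.data$sample_id, .data$.window) |>
    dplyr::summarise(.value = mean(.data[[peak_type]]), .groups = "drop")

  values <- matrix(fill, nrow = n_s, ncol = n_w,
                   dimnames = list(samples$sample_id,
                                   paste0("F_", seq_len(n_w) - 1L)))
  missing <- matrix(TRUE, nrow = n_s, ncol = n_w,
                    dimnames = dimnames(values))
  idx <- cbind(match(agg$sample_id, samples$sample_id), agg$.window + 1L)
  values[idx] <- agg$.value
  missing[idx] <- FALSE

  structure(
    list(values = values, missing = missing, peak_type = peak_type,
         grid = grid, samples = samples),
    class = "ms_feature_matrix"
  )
}

#' @export
print.ms_feature_matrix <- function(x, ...) {
  cat(sprintf("<ms_feature_matrix> %d samples x %d windows (%s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$peak_type,
              100 * mean(x$missing)))
  print(x$grid)
  invisible(x)
}

#' @export
dim.ms_feature_matrix <- function(x) dim(x$values)

#' Long-format view of a feature matrix
#'
#' @param x An `ms_feature_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per (sample, window): `sample_id`, `label`,
#'   `batch`, `feature`, `feature_index`, `value`, `missing`.
#' @export
tidy.ms_feature_matrix <- function(x, ...) {
  vals <- as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature", values_to = "value")
  miss <- as_tibble(x$missing, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature", values_to = "missing")
  vals |>
    dplyr::left_join(miss, by = c("sample_id", "feature")) |>
    dplyr::mutate(feature_index = as.integer(sub("^F_", "", .data$feature))) |>
    dplyr::left_join(x$samples[, c("sample_id", "label", "batch")],
                     by = "sample_id") |>
    dplyr::select("sample_id", "label", "batch", "feature", "feature_index",
                  "value", "missing")
}

#' Per-class missingness summary
#'
#' Mean number of empty windows per sample, split by class — the statistic
#' that shows missingness shrinking as the window step grows (coarser grids
#' have fewer, fuller windows).
#'
#' @param fm An [construct_features()] result.
#' @return Tibble with columns `label`, `n_samples`, `mean_missing`
#'   (each value in `[0, n_windows]`).
#' @export
missing_stats <- function(fm) {
  stopifnot(inherits(fm, "ms_feature_matrix"))
  tibble(sample_id = rownames(fm$missing),
         n_missing = rowSums(fm$missing)) |>
    dplyr::left_join(fm$samples[, c("sample_id", "label")], by = "sample_id") |>
    dplyr::mutate(label = normalize_label(.data$label)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     mean_missing = mean(.data$n_missing),
                     .groups = "drop")
}
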