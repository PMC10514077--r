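#' Chi-square statistic of a 2x2 presence/class table
#'
#' For a feature F and class L, with `a` = samples in L having F, `b` =
#' samples outside L having F, `c` = samples in L lacking F and `d` = samples
#' outside L lacking F, computes
#' \deqn{\chi^2 = (ad - cb)^2 / ((a+c)(b+d)(a+b)(c+d)).}
#' This form omits the sample-size factor N of the classical Pearson
#' statistic; because N is constant across features it does not change any
#' ranking.  `classical = TRUE` multiplies by N, recovering the textbook
#' Pearson chi-square (no continuity correction).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param classical Multiply by `N = a+b+c+d`?  Default `FALSE` (the
#'   normalized form).
#' @return Non-negative scalar; 0 (with attribute `degenerate = TRUE`) when a
#'   marginal is zero, i.e. the feature is constant or a class is absent.
#' @export
#' @examples
#' chi2_contingency(10, 0, 0, 10)  # perfect association -> 1
#' chi2_contingency(5, 5, 5, 5)    # independence -> 0
chi2_contingency <- function(a, b, c, d, classical = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("Cell counts must be finite and non-negative.")
  }
  den <- (a + c) * (b + d) * (a + b) * (c + d)
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  val <- (a * d - c * b)^2 / den
  if (classical) val <- val * sum(counts)
  val
}

#' Presence/absence contingency counts for one feature column
#'
#' "Has feature F" means the sample's window is non-missing (equivalently
#' non-zero after the zero fill).
#'
#' @param x Numeric feature column (zero-filled).
#' @param labels Class labels, coerced via [normalize_label()].
#' @param missing Optional logical mask (`TRUE` = window empty for that
#'   sample); defaults to `x == 0`.
#' @return One-row tibble with columns `a`, `b`, `c`, `d` (a: positive &
#'   present, b: negative & present, c: positive & absent, d: negative &
#'   absent).
#' @export
presence_counts <- function(x, labels, missing = NULL) {
  labels <- normalize_label(labels)
  if (length(x) != length(labels)) abort("`x` and `labels` lengths differ.")
  present <- if (is.null(missing)) x != 0 else !missing
  pos <- labels == "positive"
  tibble(a = sum(present & pos), b = sum(present & !pos),
         c = sum(!present & pos), d = sum(!present & !pos))
}

#' Frequency-weighted chi-square score of one feature column
#'
#' The intensity-weighted variant (the form implemented by scikit-learn's
#' `chi2` scorer): observed per-class statistic is the sum of the feature's
#' values within the class, expected is the class sample-proportion times the
#' total sum, and the score is \eqn{\sum_k (O_k - E_k)^2 / E_k} over the two
#' classes.
#'
#' @param x Non-negative numeric feature column.
#' @param labels Class labels, coerced via [normalize_label()].
#' @return Non-negative scalar; 0 (attribute `degenerate = TRUE`) for an
#'   all-zero column.
#' @export
#' @examples
#' chi2_frequency(c(2, 2, 0, 0), c("P", "P", "N", "N"))  # 4
chi2_frequency <- function(x, labels) {
  labels <- normalize_label(labels)
  if (length(x) != length(labels)) abort("`x` and `labels` lengths differ.")
  if (any(x < 0)) abort("Feature values must be non-negative.")
  total <- sum(x)
  if (total == 0) return(structure(0, degenerate = TRUE))
  pos <- labels == "positive"
  obs <- c(sum(x[pos]), sum(x[!pos]))
  expd <- c(mean(pos), mean(!pos)) * total
  sum((obs - expd)^2 / expd)
}

#' Rank windows by chi-square association with the class
#'
#' Scores every constructed window and returns the deterministic ranking:
#' descending by chi-square, ties broken by ascending feature index.
#'
#' @param fm An [construct_features()] result.
#' @param method `"frequency"` (intensity-weighted, the default) or
#'   `"contingency"` (presence/absence 2x2 form).
#' @param rows Optional integer vector of sample rows to score on (e.g. the
#'   training partition); default all samples.
#' @param classical Passed to [chi2_contingency()] when
#'   `method = "contingency"`.
#' @return Tibble ordered by rank: `rank`, `feature`, `feature_index`
#'   (0-based), `chi2`.
#' @export
rank_features <- function(fm, method = c("frequency", "contingency"),
                          rows = NULL, classical = FALSE) {
  stopifnot(inherits(fm, "ms_feature_matrix"))
  method <- match.arg(method)
  rows <- rows %||% seq_len(nrow(fm$values))
  labels <- normalize_label(fm$samples$label[rows])
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present to rank features.")
  }
  vals <- fm$values[rows, , drop = FALSE]
  miss <- fm$missing[rows, , drop = FALSE]

  score_one <- function(j) {
    if (method == "frequency") {
      as.numeric(chi2_frequency(vals[, j], labels))
    } else {
      cc <- presence_counts(vals[, j], labels, missing = miss[, j])
      as.numeric(chi2_contingency(cc$a, cc$b, cc$c, cc$d, classical = classical))
    }
  }
  chi2 <- vapply(seq_len(ncol(vals)), score_one, numeric(1))

  tibble(feature = colnames(vals),
         feature_index = seq_along(chi2) - 1L,
         chi2 = chi2) |>
    dplyr::arrange(dplyr::desc(.data$chi2), .data$feature_index) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Search for the minimal discriminative feature subset
#'
#' Ranks windows by chi-square on the training side, then for each
#' `k = 1..k_max` and each model of the zoo fits on the training partition
#' using the top-k windows and scores accuracy on the validation partition.
#' The winner is the smallest `k` — then the earliest model in zoo order —
#' attaining the maximum validation accuracy.  The chosen model is refit on
#' train + validation and evaluated once on the held-out test partition.
#'
#' @param fm An [construct_features()] result.
#' @param split A [split_spec()]; partitions are produced by [make_splits()].
#' @param models Model zoo, default [model_zoo()] in its fixed order.
#' @param k_max Upper bound of the subset-size sweep (default 20, covering
#'   every subset size the method typically selects).
#' @param method Chi-square scoring method, see [rank_features()].
#' @param standardize Standardize features using training-side means/SDs
#'   before model fitting (off by default; the pipeline applies no scaling).
#' @return An object of class `mzbin_subset`: list with `k`,
#'   `feature_indices` (0-based), `features`, `model_name`, `val_accuracy`,
#'   `test_metrics` (one-row tibble of the seven metrics), `sweep` (tibble of
#'   k x model validation accuracies), `ranking`, `splits`, `method`.
#' @export
minimal_subset_search <- function(fm, split = split_spec(), models = model_zoo(),
                                  k_max = 20, method = c("frequency", "contingency"),
                                  standardize = FALSE) {
  stopifnot(inherits(fm, "ms_feature_matrix"))
  method <- match.arg(method)
  if (!is.numeric(k_max) || k_max < 1) abort("`k_max` must be >= 1.")
  k_max <- min(as.integer(k_max), ncol(fm$values))

  splits <- make_splits(fm$samples, split)
  role_of <- splits$role[match(fm$samples$sample_id, splits$sample_id)]
  i_train <- which(role_of == "train")
  i_valid <- which(role_of == "validation")
  i_test  <- which(role_of == "test")

  ranking <- rank_features(fm, method = method,
                           rows = c(i_train, i_valid))
  top <- ranking$feature_index + 1L  # 1-based column order

  labels <- normalize_label(fm$samples$label)
  y_train <- labels[i_train]
  y_valid <- labels[i_valid]
  y_test  <- labels[i_test]

  sweep <- tidyr::expand_grid(k = seq_len(k_max),
                              model_name = names(models)) |>
    dplyr::mutate(val_accuracy = NA_real_)

  for (r in seq_len(nrow(sweep))) {
    k <- sweep$k[r]
    cols <- top[seq_len(k)]
    pred <- train_predict(models[[sweep$model_name[r]]],
                          fm$values[i_train, cols, drop = FALSE], y_train,
                          fm$values[i_valid, cols, drop = FALSE],
                          standardize = standardize)
    sweep$val_accuracy[r] <- mean(pred$pred == y_valid)
  }

  best_acc <- max(sweep$val_accuracy)
  model_order <- match(sweep$model_name, names(models))
  cand <- which(sweep$val_accuracy >= best_acc - 1e-12)
  cand <- cand[order(sweep$k[cand], model_order[cand])][1]
  k_star <- sweep$k[cand]
  model_star <- sweep$model_name[cand]

  cols <- top[seq_len(k_star)]
  i_fit <- c(i_train, i_valid)
  pred <- train_predict(models[[model_star]],
                        fm$values[i_fit, cols, drop = FALSE], labels[i_fit],
                        fm$values[i_test, cols, drop = FALSE],
                        standardize = standardize)
  test_metrics <- metric_report(y_test, pred$pred, pred$score)

  structure(
    list(k = k_star,
         feature_indices = ranking$feature_index[seq_len(k_star)],
         features = ranking$feature[seq_len(k_star)],
         model_name = model_star,
         val_accuracy = best_acc,
         test_metrics = test_metrics,
         sweep = sweep,
         ranking = ranking,
         splits = splits,
         method = method,
         peak_type = fm$peak_type,
         grid = fm$grid),
    class = "mzbin_subset"
  )
}

#' @export
print.mzbin_subset <- function(x, ...) {
  cat(sprintf("<mzbin_subset> k = %d (%s), model %s, validation accuracy %.3f\n",
              x$k, paste(x$features, collapse = ", "), x$model_name,
              x$val_accuracy))
  cat("test metrics:\n")
  print(x$test_metrics)
  invisible(x)
}

#' @rdname minimal_subset_search
#' @param x An `mzbin_subset` object.
#' @param ... Unused.
#' @export
tidy.mzbin_subset <- function(x, ...) x$sweep

#' @rdname minimal_subset_search
#' @export
glance.mzbin_subset <- function(x, ...) {
  dplyr::bind_cols(
    tibble(peak_type = x$peak_type, k = x$k, model = x$model_name,
           val_accuracy = x$val_accuracy),
    x$test_metrics
  )
}
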