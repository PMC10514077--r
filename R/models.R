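#' Specification of one supervised model
#'
#' @param name One of `"RF"`, `"DT"`, `"SVM"`, `"KNN"`, `"LR"`, `"GBM"`,
#'   `"NB"`, `"Bagging"`, `"AdaBoost"`, `"MLP"`.
#' @param params Named list of hyperparameter overrides (merged over the zoo
#'   defaults).
#' @param seed Integer seed making fit and prediction reproducible.
#' @return Object of class `mzbin_model_spec`.
#' @export
model_spec <- function(name, params = list(), seed = 1L) {
  name <- match.arg(name, c("RF", "DT", "SVM", "KNN", "LR", "GBM", "NB",
                            "Bagging", "AdaBoost", "MLP"))
  defaults <- switch(name,
    RF = list(n_trees = 10L),
    DT = list(),                       # stated "Penality = 1.0" has no rpart
                                       # analogue; tree defaults are used
    SVM = list(kernel = "radial", cache_size = 200, standardize = TRUE),
    KNN = list(k = 5L, standardize = TRUE),
    LR = list(),                       # plain L2-free logistic fit; the
                                       # stated penalty=l2 with C=1 is near
                                       # unpenalized at these sample sizes
    GBM = list(n_rounds = 100L, max_depth = 6L, eta = 0.3),
    NB = list(var_floor_frac = 1e-9),  # Gaussian NB; variance floored at
                                       # var_floor_frac * max feature variance
    Bagging = list(n_estimators = 100L),
    AdaBoost = list(n_estimators = 50L),
    MLP = list(hidden = 32L, decay = 1e-4, maxit = 500L, standardize = TRUE)
  )
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults, seed = as.integer(seed)),
            class = "mzbin_model_spec")
}

#' The fixed ten-model zoo
#'
#' Seven conventional learners, two ensemble frameworks and one neural
#' network, in a fixed order that also serves as the deterministic
#' tie-break in [minimal_subset_search()]: RF (random forest, 10 trees),
#' DT (decision tree), SVM (radial kernel, 200 MB kernel cache), KNN
#' (5 neighbours), LR (logistic regression), GBM (gradient-boosted trees,
#' 100 rounds), NB (Gaussian naive Bayes), Bagging (100 bootstrapped trees),
#' AdaBoost (50 stumps), MLP (one hidden layer of 32 units).
#'
#' @param seed Integer seed shared by every spec.
#' @return Named list of [model_spec()] objects in zoo order.
#' @export
model_zoo <- function(seed = 1L) {
  nm <- c("RF", "DT", "SVM", "KNN", "LR", "GBM", "NB", "Bagging",
          "AdaBoost", "MLP")
  stats::setNames(lapply(nm, model_spec, seed = seed), nm)
}

#' Train/validation/test split specification
#'
#' Three protocols: `"ratio"` (stratified random split by a train:test
#' ratio, e.g. 2:1 or 7:3), `"fixed_counts"` (exact per-class train/test
#' counts), and `"batch_holdout"` (an entire acquisition batch becomes the
#' test set; the remainder is split into train/validation).  In every
#' protocol a stratified validation fraction is carved out of the training
#' side so that subset search never touches the test partition.
#'
#' @param strategy One of `"ratio"`, `"fixed_counts"`, `"batch_holdout"`.
#' @param train_ratio,test_ratio Ratio parts for `"ratio"` (default 2:1).
#' @param counts For `"fixed_counts"`: named list
#'   `list(train = c(positive =, negative =), test = c(positive =, negative =))`.
#' @param holdout_batch Batch id put entirely in test for `"batch_holdout"`.
#' @param val_frac Fraction of the training side reserved for validation
#'   (default 0.25).
#' @param seed Integer seed.
#' @return Object of class `mzbin_split_spec`.
#' @export
split_spec <- function(strategy = c("ratio", "fixed_counts", "batch_holdout"),
                       train_ratio = 2, test_ratio = 1, counts = NULL,
                       holdout_batch = NULL, val_frac = 0.25, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed_counts" && is.null(counts)) {
    abort("`counts` is required for the fixed_counts strategy.")
  }
  if (strategy == "batch_holdout" && is.null(holdout_batch)) {
    abort("`holdout_batch` is required for the batch_holdout strategy.")
  }
  structure(list(strategy = strategy, train_ratio = train_ratio,
                 test_ratio = test_ratio, counts = counts,
                 holdout_batch = holdout_batch, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "mzbin_split_spec")
}

# stratified draw of n_take[class] indices from each class
.draw_stratified <- function(labels, n_take) {
  unlist(lapply(names(n_take), function(cl) {
    idx <- which(labels == cl)
    sample(idx, min(n_take[[cl]], length(idx)))
  }), use.names = FALSE)
}

#' Partition a cohort into train / validation / test
#'
#' Deterministic for a fixed seed.  Partitions are disjoint, cover the
#' cohort, and are stratified by class (ratio and fixed-counts strategies).
#' With `batch_holdout` the entire named batch forms the test set.
#'
#' @param samples Per-sample tibble (from [cohort_samples()] or an
#'   `ms_feature_matrix`'s `$samples`): columns `sample_id`, `label`, `batch`.
#' @param spec A [split_spec()].
#' @return Tibble `sample_id`, `role` (`train` / `validation` / `test`).
#' @export
make_splits <- function(samples, spec = split_spec()) {
  stopifnot(inherits(spec, "mzbin_split_spec"))
  labels <- normalize_label(samples$label)
  n <- nrow(samples)
  classes <- levels(labels)

  withr::with_seed(spec$seed, {
    if (spec$strategy == "ratio") {
      test_frac <- spec$test_ratio / (spec$train_ratio + spec$test_ratio)
      n_test <- vapply(classes, function(cl) {
        as.integer(round(sum(labels == cl) * test_frac))
      }, integer(1))
      i_test <- .draw_stratified(labels, as.list(n_test))
    } else if (spec$strategy == "fixed_counts") {
      want <- spec$counts
      for (part in c("train", "test")) {
        for (cl in classes) {
          if ((want[[part]][[cl]] %||% 0) > sum(labels == cl)) {
            abort(sprintf("Requested %s count for class '%s' exceeds cohort size.",
                          part, cl))
          }
        }
      }
      i_test <- .draw_stratified(labels, as.list(want$test))
      # train side restricted to the requested train counts
      rest <- setdiff(seq_len(n), i_test)
      i_train_side <- rest[.draw_stratified(labels[rest], as.list(want$train))]
    } else {  # batch_holdout
      if (!spec$holdout_batch %in% samples$batch) {
        abort(sprintf("Unknown batch id '%s'.", spec$holdout_batch))
      }
      i_test <- which(samples$batch == spec$holdout_batch)
    }

    if (spec$strategy != "fixed_counts") {
      i_train_side <- setdiff(seq_len(n), i_test)
    }
    side_labels <- labels[i_train_side]
    n_val <- vapply(classes, function(cl) {
      as.integer(floor(sum(side_labels == cl) * spec$val_frac))
    }, integer(1))
    i_val <- i_train_side[.draw_stratified(side_labels, as.list(n_val))]
    i_train <- setdiff(i_train_side, i_val)
  })

  role <- rep(NA_character_, n)
  role[i_train] <- "train"
  role[i_val] <- "validation"
  role[i_test] <- "test"
  out <- tibble(sample_id = samples$sample_id, role = role)
  out[!is.na(out$role), ]
}

# --- model backends ---------------------------------------------------------

.prep_xy <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  list(x = x, y = factor(y, levels = .mzbin_labels))
}

# positive-class probability column from an rpart-style prob matrix
.prob_pos <- function(p) {
  if ("positive" %in% colnames(p)) p[, "positive"] else rep(0, nrow(p))
}

.fit_bagging <- function(x, y, x_new, n_estimators) {
  df <- data.frame(.y = y, x)
  n <- nrow(df)
  newdf <- data.frame(x_new)
  probs <- vapply(seq_len(n_estimators), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(df$.y[idx])) < 2) {
      # degenerate bootstrap: the tree would be a constant vote anyway
      return(rep(as.numeric(df$.y[idx][1] == "positive"), nrow(newdf)))
    }
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class")
    .prob_pos(predict(fit, newdata = newdf, type = "prob"))
  }, numeric(nrow(newdf)))
  rowMeans(matrix(probs, nrow = nrow(newdf)))
}

.fit_adaboost <- function(x, y, x_new, n_estimators) {
  # discrete AdaBoost.M1 with depth-1 rpart stumps
  df <- data.frame(.y = y, x)
  newdf <- data.frame(x_new)
  n <- nrow(df)
  yi <- ifelse(y == "positive", 1, -1)
  w <- rep(1 / n, n)
  f_new <- rep(0, nrow(newdf))
  eps <- 1e-10
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2))
    h <- ifelse(predict(fit, newdata = df, type = "class") == "positive", 1, -1)
    err <- sum(w[h != yi])
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err + eps) / (err + eps))
    w <- w * exp(-alpha * yi * h)
    w <- w / sum(w)
    h_new <- ifelse(predict(fit, newdata = newdf, type = "class") == "positive", 1, -1)
    f_new <- f_new + alpha * h_new
    if (err <= eps) break  # perfect stump: committee already decided
  }
  1 / (1 + exp(-2 * f_new))  # logistic link on the additive margin
}

#' Fit one model and predict a test set
#'
#' Runs the named learner with its zoo hyperparameters under a fixed seed.
#' The score column is a positive-class probability where the backend has
#' one, otherwise a monotone decision value — either way usable by the
#' rank-based AUC, which only needs an ordering.
#'
#' @param spec A [model_spec()].
#' @param x_train,x_test Numeric feature matrices (dense; missing windows
#'   already zero-filled).
#' @param y_train Training labels, coerced via [normalize_label()].
#' @param standardize Center/scale columns by training-side statistics
#'   before fitting (default `FALSE`; no scaling, matching the pipeline's
#'   default of feeding raw aggregated intensities).
#' @return Tibble with one row per test sample: `pred` (factor
#'   negative/positive) and `score` (higher = more positive).
#' @export
train_predict <- function(spec, x_train, y_train, x_test,
                          standardize = FALSE) {
  stopifnot(inherits(spec, "mzbin_model_spec"))
  y_train <- normalize_label(y_train)
  tr <- .prep_xy(x_train, y_train)
  te <- as.matrix(x_test)
  storage.mode(te) <- "double"
  colnames(te) <- colnames(tr$x)
  if (length(unique(tr$y)) < 2) abort("Training labels contain a single class.")

  # distance/gradient-based learners standardize by default (their spec sets
  # standardize = TRUE); tree ensembles and the rest see raw intensities
  standardize <- standardize || isTRUE(spec$params$standardize)
  if (standardize) {
    mu <- colMeans(tr$x)
    sg <- apply(tr$x, 2, sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    tr$x <- scale(tr$x, center = mu, scale = sg)
    te <- scale(te, center = mu, scale = sg)
  }
  p <- spec$params

  score <- withr::with_seed(spec$seed, switch(spec$name,
    RF = {
      fit <- randomForest::randomForest(tr$x, tr$y, ntree = p$n_trees)
      predict(fit, newdata = te, type = "prob")[, "positive"]
    },
    DT = {
      fit <- rpart::rpart(.y ~ ., data = data.frame(.y = tr$y, tr$x),
                          method = "class")
      .prob_pos(predict(fit, newdata = data.frame(te), type = "prob"))
    },
    SVM = {
      fit <- e1071::svm(tr$x, tr$y, kernel = p$kernel,
                        cachesize = p$cache_size, scale = FALSE)
      dv <- attr(predict(fit, te, decision.values = TRUE), "decision.values")
      # orientation: the decision value is for the class named first
      if (startsWith(colnames(dv)[1], "positive")) dv[, 1] else -dv[, 1]
    },
    KNN = {
      pr <- class::knn(tr$x, te, tr$y, k = min(p$k, nrow(tr$x)), prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "positive", win, 1 - win)
    },
    LR = {
      fit <- suppressWarnings(glm(.y ~ ., data = data.frame(.y = tr$y, tr$x),
                                  family = binomial()))
      suppressWarnings(predict(fit, newdata = data.frame(te), type = "response"))
    },
    GBM = {
      dtr <- xgboost::xgb.DMatrix(tr$x, label = as.numeric(tr$y == "positive"))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = p$max_depth,
                      eta = p$eta, nthread = 1),
        data = dtr, nrounds = p$n_rounds, verbose = 0)
      predict(fit, xgboost::xgb.DMatrix(te))
    },
    NB = {
      fit <- e1071::naiveBayes(tr$x, tr$y)
      # Gaussian variance floor so zero-variance classes (a window absent in
      # every sample of one class) still yield finite densities
      floor_sd <- sqrt(p$var_floor_frac * max(apply(tr$x, 2, stats::var), 1e-12))
      # posterior in log space (raw-density products underflow on intensity-
      # scale features), positive-vs-negative log odds through the logistic
      loglik <- function(cl) {
        ll <- log(fit$apriori[cl] / sum(fit$apriori))
        for (j in seq_len(ncol(te))) {
          tab <- fit$tables[[j]]
          s <- max(tab[cl, 2], floor_sd, na.rm = TRUE)
          ll <- ll + stats::dnorm(te[, j], tab[cl, 1], s, log = TRUE)
        }
        ll
      }
      stats::plogis(loglik("positive") - loglik("negative"))
    },
    Bagging = .fit_bagging(tr$x, tr$y, te, p$n_estimators),
    AdaBoost = .fit_adaboost(tr$x, tr$y, te, p$n_estimators),
    MLP = {
      fit <- nnet::nnet(tr$x, as.numeric(tr$y == "positive"),
                        size = p$hidden, decay = p$decay, maxit = p$maxit,
                        entropy = TRUE, trace = FALSE, MaxNWts = 100000)
      as.numeric(predict(fit, te))
    }
  ))

  score <- as.numeric(score)
  score[!is.finite(score)] <- 0
  # SVM emits a decision value (threshold 0); everything else a probability
  cut <- if (spec$name == "SVM") 0 else 0.5
  pred <- factor(ifelse(score > cut, "positive", "negative"),
                 levels = .mzbin_labels)
  tibble(pred = pred, score = score)
}
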