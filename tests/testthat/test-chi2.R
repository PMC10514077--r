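test_that("contingency chi-square matches the printed form and flags degeneracy", {
  expect_equal(as.numeric(chi2_contingency(5, 5, 5, 5)), 0)
  expect_equal(as.numeric(chi2_contingency(10, 0, 0, 10)), 1)  # 100^2 / 10^4
  d <- chi2_contingency(5, 5, 0, 0)
  expect_equal(as.numeric(d), 0)
  expect_true(isTRUE(attr(d, "degenerate")))
  expect_error(chi2_contingency(-1, 2, 3, 4), "non-negative")
})

test_that("normalized form times N equals the classical Pearson statistic", {
  withr::with_seed(42, {
    for (i in 1:200) {
      tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
      v <- as.numeric(chi2_contingency(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
      oracle <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic)
      expect_equal(v * sum(tab), unname(oracle), tolerance = 1e-10)
      expect_equal(
        as.numeric(chi2_contingency(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                                    classical = TRUE)),
        unname(oracle), tolerance = 1e-10)
    }
  })
})

test_that("presence counts tally the four presence-by-class cells", {
  cc <- presence_counts(c(1.2, 0, 3.4, 0), c("P", "P", "N", "N"))
  expect_equal(unlist(cc), c(a = 1, b = 1, c = 1, d = 1))

  cc2 <- presence_counts(c(1, 2, 3, 4), c("P", "P", "N", "N"))
  expect_equal(cc2$c + cc2$d, 0L)

  # generator ground truth: marker present in all positives, no negatives
  cohort <- generate_cohort(planted_config(seed = 2, n = 10, background = 0))
  fm <- construct_features(cohort, build_grid(54, 1223, 1.0), "height")
  cc3 <- presence_counts(fm$values[, 60], fm$samples$label,
                         missing = fm$missing[, 60])
  expect_equal(unlist(cc3), c(a = 10, b = 0, c = 0, d = 10))
})

test_that("frequency chi-square equals the two-term (O-E)^2/E oracle", {
  expect_equal(as.numeric(chi2_frequency(c(2, 2, 0, 0), c("P", "P", "N", "N"))), 4)
  expect_equal(as.numeric(chi2_frequency(c(3, 3, 3, 3), c("P", "P", "N", "N"))), 0)
  z <- chi2_frequency(rep(0, 4), c("P", "P", "N", "N"))
  expect_true(isTRUE(attr(z, "degenerate")))

  oracle <- function(x, pos) {
    o <- c(sum(x[pos]), sum(x[!pos]))
    e <- c(mean(pos), 1 - mean(pos)) * sum(x)
    sum((o - e)^2 / e)
  }
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(6:40, 1)
      x <- runif(n, 0, 100) * rbinom(n, 1, 0.7)
      if (sum(x) == 0) next
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(pos) || !any(pos)) next
      lab <- ifelse(pos, "positive", "negative")
      expect_equal(as.numeric(chi2_frequency(x, lab)), oracle(x, pos),
                   tolerance = 1e-12)
    }
  })
})

test_that("feature ranking is deterministic, column-wise, and scale invariant", {
  cohort <- generate_cohort(planted_config(seed = 6, n = 15, background = 100))
  fm <- construct_features(cohort, build_grid(54, 1223, 1.0), "height")
  rk <- rank_features(fm)

  # planted marker window ranked first
  expect_equal(rk$feature_index[1], 59L)

  # equals brute-force per-column scoring
  labs <- fm$samples$label
  for (j in sample(seq_len(ncol(fm$values)), 25)) {
    expect_equal(rk$chi2[rk$feature_index == j - 1L],
                 as.numeric(chi2_frequency(fm$values[, j], labs)))
  }

  # global positive rescaling leaves the ranking unchanged
  fm2 <- fm
  fm2$values <- fm$values * 7.3
  expect_equal(rank_features(fm2)$feature_index, rk$feature_index)

  # ties broken by the lower feature index
  tiny <- fm
  tiny$values <- cbind(F_0 = c(1, 1, 0, 0), F_1 = c(1, 1, 0, 0),
                       F_2 = c(1, 1, 1, 1))[, , drop = FALSE]
  tiny$missing <- tiny$values == 0
  tiny$samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                                 label = c("P", "P", "N", "N"), batch = "b1",
                                 n_peaks = 1)
  rownames(tiny$values) <- tiny$samples$sample_id
  rk2 <- rank_features(tiny)
  expect_equal(rk2$feature_index[1:2], c(0L, 1L))

  # contingency method agrees with its own column oracle
  rkc <- rank_features(fm, method = "contingency")
  j <- rkc$feature_index[1] + 1L
  cc <- presence_counts(fm$values[, j], labs, missing = fm$missing[, j])
  expect_equal(rkc$chi2[1], as.numeric(chi2_contingency(cc$a, cc$b, cc$c, cc$d)))

  # single-class labels refused
  one <- fm
  one$samples$label <- "positive"
  expect_error(rank_features(one), "Both classes")
})

test_that("pure-noise columns do not displace the planted marker from rank 1", {
  wins <- vapply(1:20, function(r) {
    cohort <- generate_cohort(planted_config(seed = 100 + r, n = 20,
                                             background = 300))
    fm <- construct_features(cohort, build_grid(54, 1223, 1.0), "height")
    rank_features(fm)$feature_index[1] == 59L
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("subset search finds one separating feature at k = 1", {
  cohort <- generate_cohort(planted_config(seed = 13, n = 20, background = 200))
  fm <- construct_features(cohort, build_grid(54, 1223, 1.0), "height")
  fast_zoo <- model_zoo()[c("RF", "DT", "KNN")]
  res <- minimal_subset_search(fm, split = split_spec(seed = 3),
                               models = fast_zoo, k_max = 4)
  expect_equal(res$k, 1L)
  expect_equal(res$feature_indices, 59L)
  expect_equal(res$val_accuracy, 1)
  expect_lte(res$k, 4)
  # sweep covers every (k, model) pair and the winner is in zoo order
  expect_equal(nrow(res$sweep), 4 * 3)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$k, 1L)
  expect_error(minimal_subset_search(fm, k_max = 0), "k_max")
})

test_that("jointly discriminative marker pair is found at k = 2", {
  cohort <- paired_marker_cohort(seed = 21)
  fm <- construct_features(cohort, build_grid(54, 1223, 1.0), "height")
  rk <- rank_features(fm)
  expect_setequal(rk$feature_index[1:2], c(59L, 254L))
  res <- minimal_subset_search(fm, split = split_spec(seed = 4, val_frac = 0.375),
                               models = model_zoo()[c("RF", "DT", "KNN", "LR")],
                               k_max = 4)
  expect_equal(res$k, 2L)
  expect_setequal(res$feature_indices, c(59L, 254L))
})
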