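test_that("global m/z scan returns the cohort-wide extremes", {
  cohort <- toy_cohort(list(
    list(sample_id = "a", label = "P", mz = c(54, 700)),
    list(sample_id = "b", label = "N", mz = c(100, 1223))
  ))
  expect_equal(scan_mz_range(cohort), c(min_mz = 54, max_mz = 1223))

  single <- toy_cohort(list(list(sample_id = "a", label = "P", mz = 100)))
  expect_equal(scan_mz_range(single), c(min_mz = 100, max_mz = 100))
})

test_that("grid window counts follow the floor convention", {
  expect_equal(build_grid(54, 1223, 1.0)$n_windows, 1169)
  expect_equal(build_grid(54, 1223, 1.5)$n_windows, 779)
  expect_equal(build_grid(54, 1223, 2.0)$n_windows, 584)
  expect_equal(build_grid(400, 1600, 0.1)$n_windows, 12000)
  # degenerate: step exceeds range, or zero-width range
  expect_equal(build_grid(0, 10, 20)$n_windows, 1)
  expect_equal(build_grid(5, 5, 1)$n_windows, 1)
  expect_error(build_grid(0, 10, 0), "positive")
  expect_error(build_grid(0, 10, -1), "positive")
})

test_that("window assignment partitions in-range peaks, last window right-closed", {
  grid <- build_grid(54, 1223, 1.0)
  expect_equal(window_index(54, grid), 0L)
  expect_equal(window_index(54.999, grid), 0L)
  expect_equal(window_index(55, grid), 1L)
  expect_equal(window_index(113.02, grid), 59L)
  expect_equal(window_index(1223, grid), 1168L)  # clamped into final window
  withr::with_seed(1, {
    mz <- runif(500, 54, 1223)
    i <- window_index(mz, grid)
    expect_true(all(i >= 0 & i < grid$n_windows))
    bm <- back_map(i, grid)
    expect_true(all(mz >= bm$low & (mz < bm$high | i == grid$n_windows - 1L)))
  })
})

test_that("per-window aggregation is the arithmetic mean of in-window peaks", {
  grid <- build_grid(54, 1223, 1.0)
  cohort <- toy_cohort(list(
    list(sample_id = "a", label = "P", mz = c(54.2, 54.7),
         height = c(10, 20), area = c(100, 300)),
    list(sample_id = "b", label = "N", mz = 55.5, height = 5, area = 7)
  ))
  fm_h <- construct_features(cohort, grid, "height")
  expect_equal(fm_h$values["a", "F_0"], 15)
  expect_true(all(fm_h$missing["a", -1]))
  fm_a <- construct_features(cohort, grid, "area")
  expect_equal(fm_a$values["a", "F_0"], 200)
  expect_equal(fm_a$values["b", "F_1"], 7)
})

test_that("feature matrix equals a brute-force per-window group-by mean", {
  withr::with_seed(7, {
    cohort <- dplyr::bind_rows(lapply(1:6, function(i) {
      k <- sample(3:12, 1)
      tibble::tibble(sample_id = paste0("s", i),
                     label = ifelse(i <= 3, "P", "N"), batch = "b1",
                     mz = runif(k, 10, 20), rt = 1,
                     height = runif(k, 1, 100), area = runif(k, 1, 100))
    }))
  })
  grid <- build_grid(10, 20, 1.0)
  fm <- construct_features(cohort, grid, "height")

  # independent oracle: explicit double loop over (sample, window)
  ids <- unique(cohort$sample_id)
  for (s in ids) {
    for (w in seq_len(grid$n_windows) - 1L) {
      lo <- grid$start + w * grid$step
      hi <- lo + grid$step
      last <- w == grid$n_windows - 1L
      sel <- cohort$sample_id == s & cohort$mz >= lo &
        (cohort$mz < hi | (last & cohort$mz <= grid$stop))
      if (any(sel)) {
        expect_equal(fm$values[s, w + 1L], mean(cohort$height[sel]))
        expect_false(fm$missing[s, w + 1L])
      } else {
        expect_equal(fm$values[s, w + 1L], 0)
        expect_true(fm$missing[s, w + 1L])
      }
    }
  }
})

test_that("alignment, order independence and mass conservation hold", {
  cfg <- planted_config(seed = 9, n = 4, background = 80)
  cohort <- generate_cohort(cfg)
  grid <- build_grid(54, 1223, 1.0)
  fm <- construct_features(cohort, grid, "height")

  # unequal peak lists -> identical feature-vector lengths
  expect_gt(dplyr::n_distinct(cohort_samples(cohort)$n_peaks), 1)
  expect_equal(ncol(fm$values), grid$n_windows)
  expect_equal(nrow(fm$values), 8)

  # permuting peak rows changes nothing
  withr::with_seed(2, perm <- sample(nrow(cohort)))
  fm_p <- construct_features(cohort[perm, ], grid, "height")
  expect_equal(fm_p$values[rownames(fm$values), ], fm$values)

  # sum over windows of mean * count recovers each sample's total intensity
  counts <- cohort |>
    dplyr::mutate(w = window_index(mz, grid)) |>
    dplyr::count(sample_id, w)
  for (s in rownames(fm$values)) {
    cs <- counts[counts$sample_id == s, ]
    expect_equal(sum(fm$values[s, cs$w + 1L] * cs$n),
                 sum(cohort$height[cohort$sample_id == s]))
  }

  # peaks outside the grid are a hard error naming the culprit
  small <- build_grid(60, 100, 1)
  expect_error(construct_features(cohort, small, "height"), "outside grid")
})

test_that("missingness summary splits by class and shrinks as step grows", {
  # hand-built case: 2 positives missing 3 and 5 of 10 windows, 1 negative
  # missing 2
  grid <- build_grid(0, 10, 1)
  occupy <- function(k) (seq_len(k) - 1) + 0.5
  cohort <- toy_cohort(list(
    list(sample_id = "p1", label = "P", mz = occupy(7)),
    list(sample_id = "p2", label = "P", mz = occupy(5)),
    list(sample_id = "n1", label = "N", mz = occupy(8))
  ))
  ms <- missing_stats(construct_features(cohort, grid, "height"))
  expect_equal(ms$mean_missing[ms$label == "positive"], 4)
  expect_equal(ms$mean_missing[ms$label == "negative"], 2)

  # monotone missingness across nested steps on a generated cohort
  cohort2 <- generate_cohort(planted_config(seed = 5, n = 5, background = 150))
  per_sample_missing <- function(step) {
    rowSums(construct_features(cohort2, build_grid(54, 1223, step), "height")$missing)
  }
  m05 <- per_sample_missing(0.5)
  m10 <- per_sample_missing(1.0)
  m20 <- per_sample_missing(2.0)
  expect_true(all(m10 <= m05))
  expect_true(all(m20 <= m10))
})
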