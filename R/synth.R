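#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a two-batch serum metabolomics case/control study:
#' 59 disease and 43 healthy samples split over two acquisition batches of
#' 41 and 61 samples, peaks spread over 54-1223 Da, roughly a thousand
#' background peaks per sample (Poisson-distributed, so sample lengths
#' differ — the misalignment the windowing exists to fix), log-normal peak
#' heights, and one planted marker mass at 113.02 Da that is present in
#' every disease sample with elevated intensity.  Batch effects are a small
#' additive m/z shift plus a multiplicative intensity factor.
#'
#' @param n_pos,n_neg Samples per class (disease / health).
#' @param mz_range Numeric `c(low, high)` in Da for background peaks.
#' @param background_peaks Expected background peaks per sample (Poisson
#'   mean); 0 gives marker-only samples.
#' @param markers Tibble (or data.frame) with one row per planted marker:
#'   `mass` (Da), `presence_pos`, `presence_neg` (per-class presence
#'   probabilities), `effect` (intensity effect size in units of the
#'   log-normal sdlog, added on the log scale for positive samples).
#' @param batches Tibble with one row per batch: `batch`, `fraction`
#'   (must sum to 1), `mz_shift` (additive Da), `intensity_factor`
#'   (multiplicative).
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters for peak
#'   height (defaults give heights around 6e4 spanning roughly two decades,
#'   typical of centroided LC-MS peak heights).
#' @param rt_range Retention-time range, minutes (uniform).
#' @param mz_jitter SD of Gaussian jitter on marker masses, kept below the
#'   3-decimal rounding precision so a planted mass stays recognizable.
#' @param seed Integer seed.
#' @return Object of class `synth_config` (a named list).
#' @export
synth_config <- function(n_pos = 59, n_neg = 43,
                         mz_range = c(54, 1223),
                         background_peaks = 1000,
                         markers = tibble(mass = 113.02, presence_pos = 1,
                                          presence_neg = 0.2, effect = 3),
                         batches = tibble(batch = c("batch1", "batch2"),
                                          fraction = c(41, 61) / 102,
                                          mz_shift = c(0, 0.05),
                                          intensity_factor = c(1, 1.4)),
                         intensity_meanlog = 11, intensity_sdlog = 1,
                         rt_range = c(0.5, 15), mz_jitter = 2e-4,
                         seed = 1L) {
  if (n_pos < 1 || n_neg < 1) abort("Both classes need at least one sample.")
  if (mz_range[1] >= mz_range[2]) abort("`mz_range` must satisfy low < high.")
  if (abs(sum(batches$fraction) - 1) > 1e-8) abort("Batch fractions must sum to 1.")
  markers <- as_tibble(markers)
  if (nrow(markers) > 0 &&
      (any(markers$mass < mz_range[1]) || any(markers$mass > mz_range[2]))) {
    abort("Every marker mass must lie inside `mz_range`.")
  }
  if (nrow(markers) > 0 && any(markers$effect < 0)) {
    abort("Marker effect sizes must be >= 0.")
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         mz_range = mz_range, background_peaks = background_peaks,
         markers = markers, batches = as_tibble(batches),
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog,
         rt_range = rt_range, mz_jitter = mz_jitter,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a labeled, batched synthetic peak-list cohort
#'
#' Per sample: a Poisson number of background peaks with m/z uniform over
#' the configured range and log-normal heights; then each configured marker
#' is inserted with its class-conditional presence probability, at its mass
#' plus sub-precision jitter, with the class effect added on the log
#' intensity scale for positive samples.  Batch shifts (additive m/z,
#' multiplicative intensity) are applied last, to background and marker
#' peaks alike.  Peak area is height times a chromatographic width factor.
#' Fully reproducible for a fixed config seed.
#'
#' @param config A [synth_config()].
#' @return Peak-list cohort tibble: `sample_id`, `label`, `batch`, `mz`,
#'   `rt`, `height`, `area`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_pos = 5, n_neg = 5,
#'                                        background_peaks = 50))
#' cohort_samples(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_pos + config$n_neg
  labels <- c(rep("positive", config$n_pos), rep("negative", config$n_neg))

  withr::with_seed(config$seed, {
    # deterministic batch assignment by fraction, interleaved across classes
    n_per_batch <- diff(c(0, round(cumsum(config$batches$fraction) * n)))
    batch_of <- sample(rep(config$batches$batch, times = n_per_batch))

    rows <- purrr::map(seq_len(n), function(i) {
      lab <- labels[i]
      b <- config$batches[config$batches$batch == batch_of[i], ]
      k_bg <- rpois(1, config$background_peaks)
      mz <- runif(k_bg, config$mz_range[1], config$mz_range[2])
      h <- rlnorm(k_bg, config$intensity_meanlog, config$intensity_sdlog)

      if (nrow(config$markers) > 0) {
        pres_p <- ifelse(lab == "positive", config$markers$presence_pos,
                         config$markers$presence_neg)
        hit <- runif(nrow(config$markers)) < pres_p
        if (any(hit)) {
          mk <- config$markers[hit, ]
          mz <- c(mz, mk$mass + rnorm(nrow(mk), 0, config$mz_jitter))
          eff <- if (lab == "positive") mk$effect else 0
          h <- c(h, rlnorm(nrow(mk),
                           config$intensity_meanlog +
                             eff * config$intensity_sdlog,
                           config$intensity_sdlog))
        }
      }
      if (length(mz) == 0) {  # guarantee a non-empty peak list
        mz <- runif(1, config$mz_range[1], config$mz_range[2])
        h <- rlnorm(1, config$intensity_meanlog, config$intensity_sdlog)
      }
      mz <- pmin(pmax(mz + b$mz_shift, config$mz_range[1]), config$mz_range[2])
      h <- h * b$intensity_factor
      rt <- runif(length(mz), config$rt_range[1], config$rt_range[2])
      width <- runif(length(mz), 0.05, 0.3)  # min, chromatographic peak width
      tibble(sample_id = sprintf("S%03d", i), label = lab,
             batch = b$batch, mz = mz, rt = rt, height = h,
             area = h * width)
    })
    dplyr::bind_rows(rows)
  })
}

#' Ground-truth window of each planted marker
#'
#' @param config A [synth_config()].
#' @param grid An [build_grid()] object covering the marker masses.
#' @return Tibble `mass`, `feature_index` (0-based expected window),
#'   `feature`.
#' @export
#' @examples
#' truth_table(synth_config(), build_grid(54, 1223, 1.0))  # 113.02 -> F_59
truth_table <- function(config, grid) {
  stopifnot(inherits(config, "synth_config"), inherits(grid, "mz_grid"))
  if (nrow(config$markers) == 0) {
    return(tibble(mass = numeric(), feature_index = integer(),
                  feature = character()))
  }
  if (any(config$markers$mass < grid$start | config$markers$mass > grid$stop)) {
    abort("Marker mass outside the grid range.")
  }
  idx <- window_index(config$markers$mass, grid)
  tibble(mass = config$markers$mass, feature_index = idx,
         feature = paste0("F_", idx))
}
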