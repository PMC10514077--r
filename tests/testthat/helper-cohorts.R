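# in-code fixtures shared across test files

# a minimal hand-built peak-list cohort
toy_cohort <- function(peaks) {
  # peaks: list of lists with sample_id, label, batch, mz (vector), and
  # optional height/area/rt vectors
  dplyr::bind_rows(lapply(peaks, function(p) {
    k <- length(p$mz)
    tibble::tibble(
      sample_id = p$sample_id, label = p$label,
      batch = p$batch %||% "b1",
      mz = p$mz,
      rt = p$rt %||% rep(1, k),
      height = p$height %||% rep(1, k),
      area = p$area %||% rep(1, k)
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-batch generator config with one cleanly planted marker
planted_config <- function(seed, n = 20, background = 300,
                           presence_neg = 0, effect = 3,
                           markers = NULL) {
  markers <- markers %||% tibble::tibble(
    mass = 113.02, presence_pos = 1, presence_neg = presence_neg,
    effect = effect)
  synth_config(
    n_pos = n, n_neg = n, background_peaks = background,
    markers = markers,
    batches = tibble::tibble(batch = "b1", fraction = 1, mz_shift = 0,
                             intensity_factor = 1),
    seed = seed)
}

# a cohort where two windows separate the classes only jointly: positives
# are high in both planted masses, each half of the negatives is high in
# exactly one of them; marker draws use a tight intensity spread so the
# class-conditional window sums are cleanly 2:1
paired_marker_cohort <- function(seed, n = 24, background = 150) {
  base <- synth_config(
    n_pos = n, n_neg = n, background_peaks = background,
    markers = tibble::tibble(mass = numeric(), presence_pos = numeric(),
                             presence_neg = numeric(), effect = numeric()),
    batches = tibble::tibble(batch = "b1", fraction = 1, mz_shift = 0,
                             intensity_factor = 1),
    seed = seed)
  cohort <- generate_cohort(base)
  samples <- cohort_samples(cohort)
  withr::with_seed(seed + 1000L, {
    extra <- dplyr::bind_rows(lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      neg_half_a <- s$label == "negative" &&
        (match(s$sample_id, samples$sample_id[samples$label == "negative"]) %% 2 == 0)
      put_a <- s$label == "positive" || neg_half_a
      put_b <- s$label == "positive" || (s$label == "negative" && !neg_half_a)
      m <- c(if (put_a) 113.02, if (put_b) 308.50)
      if (length(m) == 0) return(NULL)
      h <- rlnorm(length(m), base$intensity_meanlog + 4, 0.1)
      tibble::tibble(sample_id = s$sample_id, label = s$label, batch = s$batch,
                     mz = m + rnorm(length(m), 0, 2e-4),
                     rt = runif(length(m), 0.5, 15),
                     height = h, area = h * 0.1)
    }))
  })
  dplyr::bind_rows(cohort, extra)
}
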