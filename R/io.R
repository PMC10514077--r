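#' Default column mapping for feature-list exports
#'
#' Export headers vary between peak-picking tool versions, so the mapping of
#' table columns onto the four peak roles is configuration, not
#' auto-detection.  The default targets MZmine-style exports, which carry
#' two dozen columns of which four matter here.
#'
#' @return Named character vector mapping roles `mz`, `rt`, `height`, `area`
#'   to column names.
#' @export
default_column_map <- function() {
  c(mz = "Mass", rt = "retention-time", height = "peak-height",
    area = "peak-area")
}

#' Read one per-sample feature-list export
#'
#' Parses an exported peak table into one peak record per row, keeping only
#' the four mapped roles (any other columns are ignored).  Rows whose mapped
#' cells fail numeric parsing, or carry a non-positive m/z or negative
#' intensity, are dropped with a warning giving the count — real exports
#' carry sentinel rows and dropping them must not kill a run.
#'
#' @param path CSV (or other delimited) file path.
#' @param column_map Named character vector with entries `mz`, `rt`,
#'   `height`, `area`; see [default_column_map()].
#' @param delim Field delimiter (default `","`).
#' @param sample_id Sample identifier; default the file name without
#'   extension.
#' @param label,batch Optional class label and batch id to attach.
#' @return Peak-list tibble: `sample_id`, `label`, `batch`, `mz`, `rt`,
#'   `height`, `area`, in file order.
#' @export
read_feature_list <- function(path, column_map = default_column_map(),
                              delim = ",", sample_id = NULL,
                              label = NA_character_, batch = NA_character_) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  roles <- c("mz", "rt", "height", "area")
  if (!all(roles %in% names(column_map))) {
    abort(paste0("column_map must name columns for roles: ",
                 paste(setdiff(roles, names(column_map)), collapse = ", ")))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  missing_cols <- setdiff(unname(column_map[roles]), names(raw))
  if (length(missing_cols) > 0) {
    bad_roles <- roles[column_map[roles] %in% missing_cols]
    abort(sprintf("Mapped column(s) absent from %s: %s (role(s): %s)",
                  path, paste(missing_cols, collapse = ", "),
                  paste(bad_roles, collapse = ", ")))
  }

  peaks <- tibble(
    mz = suppressWarnings(as.numeric(raw[[column_map[["mz"]]]])),
    rt = suppressWarnings(as.numeric(raw[[column_map[["rt"]]]])),
    height = suppressWarnings(as.numeric(raw[[column_map[["height"]]]])),
    area = suppressWarnings(as.numeric(raw[[column_map[["area"]]]]))
  )
  ok <- stats::complete.cases(peaks) & peaks$mz > 0 & peaks$rt >= 0 &
    peaks$height >= 0 & peaks$area >= 0
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    warn(sprintf("%s: dropped %d unparseable/invalid row(s) of %d.",
                 basename(path), n_drop, nrow(peaks)))
  }
  peaks <- peaks[ok, ]
  if (nrow(peaks) == 0) abort(sprintf("No valid peak rows in %s.", path))

  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  dplyr::bind_cols(
    tibble(sample_id = sample_id, label = label, batch = batch,
           .rows = nrow(peaks)),
    peaks
  )
}

#' Read a sample manifest and assemble a cohort
#'
#' The manifest is a CSV/TSV with columns `file`, `label`, `batch` and
#' optionally `sample_id` (default: file name without extension).  File
#' paths are resolved relative to the manifest's directory.  Labels are
#' normalized to positive/negative at read time; duplicate sample ids are
#' refused.
#'
#' @param path Manifest file path.
#' @param column_map,delim Passed to [read_feature_list()] for each listed
#'   file.
#' @return Peak-list cohort tibble (one row per peak).
#' @export
read_manifest <- function(path, column_map = default_column_map(),
                          delim = ",") {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  man_delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  man <- readr::read_delim(path, delim = man_delim, progress = FALSE,
                           show_col_types = FALSE)
  need <- c("file", "label", "batch")
  if (!all(need %in% names(man))) {
    abort(paste0("Manifest must have columns: ", paste(need, collapse = ", ")))
  }
  if (!"sample_id" %in% names(man)) {
    man$sample_id <- sub("\\.[^.]*$", "", basename(man$file))
  }
  if (anyDuplicated(man$sample_id)) {
    abort(paste0("Duplicate sample_id in manifest: ",
                 paste(unique(man$sample_id[duplicated(man$sample_id)]),
                       collapse = ", ")))
  }
  labels <- as.character(normalize_label(man$label))  # fail fast on tokens

  base_dir <- dirname(normalizePath(path))
  cohort <- purrr::pmap(
    list(man$file, man$sample_id, labels, as.character(man$batch)),
    function(f, sid, lab, bat) {
      fp <- if (file.exists(f)) f else file.path(base_dir, f)
      if (!file.exists(fp)) abort(sprintf("Listed file not readable: %s", f))
      read_feature_list(fp, column_map = column_map, delim = delim,
                        sample_id = sid, label = lab, batch = bat)
    }) |>
    dplyr::bind_rows()
  check_cohort(cohort)
  cohort
}

#' Write a cohort as per-sample feature lists plus a manifest
#'
#' The exact dialect [read_manifest()] consumes: one CSV per sample with the
#' four mapped columns, and `manifest.csv` listing `file`, `sample_id`,
#' `label`, `batch`.
#'
#' @param cohort Peak-list cohort tibble.
#' @param dir Output directory (created if absent).
#' @param column_map Header names to write, see [default_column_map()].
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, column_map = default_column_map()) {
  check_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- cohort_samples(cohort)
  files <- paste0(samples$sample_id, ".csv")
  for (i in seq_len(nrow(samples))) {
    sub <- cohort[cohort$sample_id == samples$sample_id[i],
                  c("mz", "rt", "height", "area")]
    names(sub) <- unname(column_map[c("mz", "rt", "height", "area")])
    readr::write_csv(sub, file.path(dir, files[i]), progress = FALSE)
  }
  man <- tibble(file = files, sample_id = samples$sample_id,
                label = samples$label, batch = samples$batch)
  man_path <- file.path(dir, "manifest.csv")
  readr::write_csv(man, man_path, progress = FALSE)
  invisible(man_path)
}

#' Write a feature matrix and its grid sidecar
#'
#' The matrix goes to `<path>` as CSV (`sample_id`, `label`, `batch`,
#' `F_0...`); the window grid goes to `<path>.grid.json` so back-mapping to
#' m/z intervals is always possible from the files alone.
#'
#' @param fm An [construct_features()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "ms_feature_matrix"))
  wide <- dplyr::bind_cols(
    fm$samples[, c("sample_id", "label", "batch")],
    as_tibble(fm$values)
  )
  readr::write_csv(wide, path, progress = FALSE)
  jsonlite::write_json(
    list(start = fm$grid$start, stop = fm$grid$stop, step = fm$grid$step,
         n_windows = fm$grid$n_windows, peak_type = fm$peak_type),
    paste0(path, ".grid.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid sidecar written by [write_feature_matrix()]
#'
#' @param path The sidecar JSON path (`<matrix>.grid.json`).
#' @return An `mz_grid` object.
#' @export
read_grid_sidecar <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_grid(g$start, g$stop, g$step)
}
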