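# Plain-text interchange layer: time series and confounds as TSV, matrices
# and manifests as CSV, configs as YAML/JSON. Doubles are serialized with 17
# significant digits so write-then-read restores them bit for bit.

full_precision <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
}

# Base-R reader: strtod parsing restores 17-digit decimals bit for bit,
# and malformed cells are reported with their data row and column.
read_numeric_table <- function(path, sep, id_cols = character()) {
  if (!file.exists(path))
    abort(paste0("File not found: ", path), class = "roinet_format_error")
  df <- tryCatch(
    utils::read.delim(path, sep = sep, check.names = FALSE, fill = FALSE,
                      colClasses = "character"),
    error = function(e)
      abort(paste0("Malformed table ", path, ": ", conditionMessage(e)),
            class = "roinet_format_error"))
  for (j in setdiff(names(df), id_cols)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) &
                   !(df[[j]] %in% c("NA", "NaN", "")))
    if (length(bad) > 0)
      abort(sprintf(
        "Malformed table %s: non-numeric value '%s' at data row %d, column '%s'.",
        path, df[[j]][bad[1]], bad[1], j), class = "roinet_format_error")
    df[[j]] <- v
  }
  tibble::as_tibble(df)
}

#' Read / write ROI time-series TSV (columns = ROI labels, rows = timepoints)
#'
#' @param ts T x N table of ROI series.
#' @param path File path.
#' @return `read_roi_ts` returns a tibble with double columns; malformed
#'   cells raise a format error naming the file and row.
#' @export
write_roi_ts <- function(ts, path) {
  readr::write_tsv(full_precision(tibble::as_tibble(ts)), path)
  invisible(path)
}

#' @rdname write_roi_ts
#' @export
read_roi_ts <- function(path) {
  read_numeric_table(path, sep = "\t")
}

#' Read / write a confound set as a single TSV
#'
#' Columns `trans_x..rot_z` hold the 6 motion parameters; `comp_*` columns
#' hold the nuisance component series.
#'
#' @param confounds A `confound_set`.
#' @param path File path.
#' @export
write_confounds <- function(confounds, path) {
  readr::write_tsv(full_precision(
    dplyr::bind_cols(confounds$motion, confounds$nuisance)), path)
  invisible(path)
}

#' @rdname write_confounds
#' @export
read_confounds <- function(path) {
  df <- read_roi_ts(path)
  motion_cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(motion_cols %in% names(df)))
    abort(paste0("Confound table ", path, " lacks the 6 motion columns."),
          class = "roinet_format_error")
  structure(list(motion = df[motion_cols],
                 nuisance = df[grep("^comp_", names(df), value = TRUE)]),
            class = "confound_set")
}

#' Read / write a connectivity matrix as CSV with a JSON sidecar
#'
#' The CSV carries an ROI-label header row and a leading `roi` label column;
#' the sidecar (`<path>.json`) records `kind`, `scale` and the label order.
#'
#' @param cm A `conn_matrix`.
#' @param path CSV file path.
#' @export
write_conn_matrix <- function(cm, path) {
  df <- tibble::as_tibble(cm$values)
  df <- dplyr::bind_cols(tibble::tibble(roi = cm$roi_labels), df)
  readr::write_csv(full_precision(df), path)
  jsonlite::write_json(list(kind = cm$kind, scale = cm$scale,
                            roi_labels = cm$roi_labels,
                            n_clipped = attr(cm, "n_clipped") %||% 0L),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
read_conn_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read_numeric_table(path, sep = ",", id_cols = "roi")
  values <- as.matrix(df[, -1])
  out <- new_conn_matrix(values, meta$kind, meta$scale, df$roi)
  attr(out, "n_clipped") <- meta$n_clipped
  out
}

#' Write a cohort to disk (per-subject TSVs plus a manifest CSV)
#'
#' @param cohort A `roi_cohort` tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series_path <- file.path(dir, paste0(cohort$subject_id, "_series.tsv"))
  conf_path <- file.path(dir, paste0(cohort$subject_id, "_confounds.tsv"))
  purrr::walk2(cohort$series, series_path, write_roi_ts)
  purrr::walk2(cohort$confounds, conf_path, write_confounds)
  manifest <- tibble::tibble(subject_id = cohort$subject_id,
                             group = cohort$group, tr = cohort$tr,
                             series_path = basename(series_path),
                             confounds_path = basename(conf_path))
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path Path to a manifest written by [write_cohort()]
#'   (columns subject_id, group, tr, series_path, confounds_path; paths
#'   relative to the manifest's directory).
#' @return A `roi_cohort`-shaped tibble with list-columns `series`,
#'   `confounds`.
#' @export
read_cohort <- function(manifest_path) {
  dir <- dirname(manifest_path)
  manifest <- read_numeric_table(
    manifest_path, sep = ",",
    id_cols = c("subject_id", "group", "series_path", "confounds_path"))
  need <- c("subject_id", "group", "tr", "series_path", "confounds_path")
  if (!all(need %in% names(manifest)))
    abort(paste0("Manifest ", manifest_path, " lacks required columns: ",
                 paste(setdiff(need, names(manifest)), collapse = ", ")),
          class = "roinet_format_error")
  missing <- !file.exists(file.path(dir, manifest$series_path))
  if (any(missing))
    abort(paste0("Missing series file for subject(s): ",
                 paste(manifest$subject_id[missing], collapse = ", ")),
          class = "roinet_format_error")
  out <- manifest |>
    dplyr::mutate(
      series = purrr::map(file.path(dir, .data$series_path), read_roi_ts),
      confounds = purrr::map(file.path(dir, .data$confounds_path),
                             read_confounds)) |>
    dplyr::select(-"series_path", -"confounds_path")
  class(out) <- c("roi_cohort", class(out))
  out
}

#' Write / read a group-stats table as TSV
#'
#' @param stats A `group_stats` tibble.
#' @param path TSV path.
#' @export
write_group_stats <- function(stats, path) {
  readr::write_tsv(full_precision(tidy(stats)), path)
  invisible(path)
}

#' @rdname write_group_stats
#' @export
read_group_stats <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  tibble::as_tibble(df)
}

#' Write / read per-subject node-metric tables as TSV
#'
#' @param metrics A [node_metrics()] tibble (rows = ROIs, 7 metric columns).
#' @param path TSV path.
#' @export
write_node_metrics <- function(metrics, path) {
  readr::write_tsv(full_precision(metrics), path)
  invisible(path)
}

#' @rdname write_node_metrics
#' @export
read_node_metrics <- function(path) {
  read_numeric_table(path, sep = "\t", id_cols = "roi")
}
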