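#' Multichannel EEG recording container
#'
#' A lightweight container for a labelled channel-by-time matrix in
#' microvolts with its sampling rate and optional subject metadata.
#'
#' @param data numeric matrix, channels x samples, microvolts; row names
#'   are channel labels (10-20 convention, upper-cased on input).
#' @param fs_hz sampling rate in Hz.
#' @param subject_id optional subject identifier.
#' @param group optional group label (`"HSG"` or `"LSG"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, subject_id = NA_character_,
                          group = NA_character_) {
  stopifnot(is.matrix(data), is.numeric(data), fs_hz > 0)
  if (is.null(rownames(data))) stop("channel labels (row names) required")
  rownames(data) <- toupper(rownames(data))
  if (anyDuplicated(rownames(data))) stop("channel labels must be unique")
  structure(
    list(data = data, fs_hz = fs_hz,
         subject_id = subject_id, group = group),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, duration_s(x)))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject: %s  group: %s\n", x$subject_id, x$group))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs_hz

channel_labels <- function(rec) rownames(rec$data)

#' Write / read a recording as delimited text with a JSON sidecar
#'
#' The canonical interchange format: a tab-separated matrix with a
#' `channel` label column followed by one column per sample, plus a
#' `<stem>.json` sidecar holding the sampling rate, labels, units and
#' group label.
#'
#' @param rec an `eeg_recording`.
#' @param stem output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return `write_recording_txt` returns the stem invisibly;
#'   `read_recording_txt` returns an `eeg_recording`.
#' @export
write_recording_txt <- function(rec, stem) {
  df <- data.frame(channel = channel_labels(rec), rec$data,
                   check.names = FALSE)
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(fs_hz = rec$fs_hz, unit = "uV",
               channel_labels = channel_labels(rec),
               subject_id = rec$subject_id, group = rec$group)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_recording_txt
#' @param unit_override unit for sidecar-less files; files that declare no
#'   unit are rejected unless this is given (`"uV"`, `"mV"` or `"V"`).
#' @export
read_recording_txt <- function(stem, unit_override = NULL) {
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  if (!file.exists(tsv)) stop("no such file: ", tsv)
  df <- utils::read.table(tsv, sep = "\t", header = TRUE,
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- list(toupper(df[[1]]), NULL)
  if (file.exists(js)) {
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    unit <- meta$unit
  } else {
    if (is.null(unit_override))
      stop("no sidecar and no unit_override: unit of ", tsv, " unknown")
    meta <- list(fs_hz = NULL); unit <- unit_override
  }
  if (is.null(meta$fs_hz))
    stop("sampling rate missing for ", stem)
  scale <- switch(unit, uV = 1, mV = 1e3, V = 1e6,
                  stop("unknown unit: ", unit))
  eeg_recording(mat * scale, fs_hz = meta$fs_hz,
                subject_id = meta$subject_id %||% NA_character_,
                group = meta$group %||% NA_character_)
}

#' Write / read a synthetic cohort as a directory of delimited files
#'
#' One `<subject_id>.tsv`/`.json` pair per recording plus
#' `ground_truth.tsv`.
#'
#' @param cohort a cohort as returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings)
    write_recording_txt(rec, file.path(dir, rec$subject_id))
  utils::write.table(cohort$ground_truth,
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.tsv")
  ground_truth <- if (file.exists(gt_path))
    tibble::as_tibble(utils::read.table(gt_path, sep = "\t", header = TRUE))
  else NULL
  stems <- sub("\\.tsv$", "",
               list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  stems <- stems[basename(stems) != "ground_truth"]
  recordings <- lapply(stems, read_recording_txt)
  list(recordings = recordings, ground_truth = ground_truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
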