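#' Extract the 14-dimensional alpha feature vector of one subject
#'
#' Runs the full single-subject pipeline: band-pass filtering (6-14 Hz),
#' optional resampling to 500 Hz and average re-referencing, ROI time
#' series (cluster average or component back-projection), 2000 ms
#' epoching, Welch spectra with Savitzky-Golay smoothing, IAF and alpha
#' amplitude per ROI, and cluster connectivity (wPLI/TLI) evaluated at
#' the mean posterior IAF.
#'
#' @param rec an [eeg_recording()].
#' @param mode ROI extraction mode, see [roi_time_series()].
#' @param components optional component set for backprojection mode.
#' @param band alpha search band for peak detection (default `c(7,13)`).
#' @param epoch_ms spectral epoch length (default 2000).
#' @param window_ms connectivity window length (default 2500).
#' @param rereference apply average re-referencing first (default FALSE;
#'   meaningful for dense montages).
#' @param target_fs resample to this rate when the recording differs
#'   (default 500 Hz).
#' @return One-row tibble: `subject_id`, `group`, the 8 activity
#'   features (`iaf_*`, `amp_*` per hemisphere x region) and the 6
#'   connectivity features.
#' @export
extract_subject_features <- function(rec, mode = "cluster-average",
                                     components = NULL, band = c(7, 13),
                                     epoch_ms = 2000, window_ms = 2500,
                                     rereference = FALSE,
                                     target_fs = 500) {
  if (rec$fs_hz != target_fs) rec <- resample_signal(rec, target_fs)
  if (rereference) rec <- rereference_average(rec)
  rec <- bandpass_filter(rec)
  roi <- roi_time_series(rec, mode = mode, components = components)
  out <- tibble::tibble(subject_id = rec$subject_id, group = rec$group)
  iafs <- c()
  for (r in rownames(roi$series)) {
    ep <- segment_series(roi$series[r, ], roi$fs_hz, epoch_ms)
    ps <- sgf_smooth(compute_power_spectrum(ep, roi$fs_hz))
    iaf <- detect_iaf(ps, band)
    out[[paste0("iaf_", r)]] <- iaf
    out[[paste0("amp_", r)]] <- alpha_amplitude(ps, band)
    iafs[r] <- iaf
  }
  post_iaf <- mean(c(iafs["posterior_L"], iafs["posterior_R"]), na.rm = TRUE)
  if (is.nan(post_iaf)) post_iaf <- NA_real_
  conn <- cluster_connectivity(rec, post_iaf, window_ms)
  dplyr::bind_cols(out, conn$features)
}

#' Extract the feature table of a whole cohort
#'
#' Maps [extract_subject_features()] over the recordings of a cohort and
#' reports how many subjects lack a detectable alpha peak (those are
#' excluded listwise by the downstream statistics/classifier when
#' `drop_missing = TRUE`).
#'
#' @param cohort list with `recordings` (e.g. from [generate_cohort()] or
#'   [read_cohort()]), or a bare list of recordings.
#' @param drop_missing drop subjects with any missing IAF
#'   (default TRUE).
#' @param ... passed to [extract_subject_features()].
#' @return Tibble, one row per retained subject.
#' @export
extract_cohort_features <- function(cohort, drop_missing = TRUE, ...) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  feats <- dplyr::bind_rows(lapply(recs, extract_subject_features, ...))
  iaf_cols <- grep("^iaf_", names(feats), value = TRUE)
  incomplete <- apply(is.na(feats[iaf_cols]), 1, any)
  if (any(incomplete)) {
    message(sum(incomplete), " subject(s) without a detectable alpha peak",
            if (drop_missing) " excluded listwise" else "")
    if (drop_missing) feats <- feats[!incomplete, ]
  }
  feats
}

#' Names of the 14 classifier input features
#' @return Character vector in fixed order.
#' @export
alpha_feature_names <- function() {
  c("iaf_posterior_L", "iaf_posterior_R", "iaf_frontal_L", "iaf_frontal_R",
    "amp_posterior_L", "amp_posterior_R", "amp_frontal_L", "amp_frontal_R",
    "wpli_intra_L", "wpli_intra_R", "wpli_inter",
    "tli_intra_L", "tli_intra_R", "tli_inter")
}

#' Reshape a feature table into a long frame for the mixed ANOVA
#'
#' One row per subject x hemisphere x region with the requested measure
#' (IAF in Hz or amplitude in dB) as `value`.
#'
#' @param features cohort feature tibble
#'   (see [extract_cohort_features()]).
#' @param measure `"iaf"` or `"amp"`.
#' @return Tibble with columns `subject_id`, `group`, `hemisphere`,
#'   `region`, `value`.
#' @export
make_feature_frame <- function(features, measure = c("iaf", "amp")) {
  measure <- match.arg(measure)
  cols <- grep(paste0("^", measure, "_(frontal|posterior)_[LR]$"),
               names(features), value = TRUE)
  long <- tidyr::pivot_longer(
    features[c("subject_id", "group", cols)], cols = dplyr::all_of(cols),
    names_to = c("region", "hemisphere"),
    names_pattern = paste0(measure, "_(frontal|posterior)_([LR])"),
    values_to = "value")
  long$region <- factor(long$region, c("frontal", "posterior"))
  long$hemisphere <- factor(long$hemisphere, c("L", "R"))
  long$group <- factor(long$group)
  long
}
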