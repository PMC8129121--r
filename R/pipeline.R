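#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with the published analysis
#' constants as defaults: 500 Hz / 120 s acquisition, 6-14 Hz band-pass,
#' 2000 ms spectral epochs, 0.80 template-matching threshold, 0.24 Hz /
#' order-5 Savitzky-Golay smoothing, 7-13 Hz peak search, 2500 ms
#' connectivity windows, C grid {0.1, 0.2, 0.3}, 10-fold nested CV.
#'
#' @param n_per_group subjects per simulated group.
#' @param duration_s,fs_hz recording length and sampling rate.
#' @param band_hz band-pass edges.
#' @param epoch_ms,window_ms spectral epoch / connectivity window (ms).
#' @param template_threshold correlation threshold for template matching.
#' @param sgf_resolution_hz,sgf_polyorder spectral smoothing parameters.
#' @param peak_band_hz alpha peak search band.
#' @param mode ROI extraction mode.
#' @param k_outer,k_inner,n_repeats,C nested-CV settings.
#' @param seed master RNG seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_group = 24, duration_s = 120,
                            fs_hz = 500, band_hz = c(6, 14),
                            epoch_ms = 2000, window_ms = 2500,
                            template_threshold = 0.80,
                            sgf_resolution_hz = 0.24, sgf_polyorder = 5,
                            peak_band_hz = c(7, 13),
                            mode = "cluster-average",
                            k_outer = 10, k_inner = 10, n_repeats = 50,
                            C = c(0.1, 0.2, 0.3), seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> extract features -> group statistics -> nested-CV
#' classification, returning all stage outputs and a run manifest
#' (configuration snapshot, seeds, per-stage row counts, warnings).
#'
#' @param config a [pipeline_config()].
#' @param configs generator group configurations
#'   (default [default_group_configs()]).
#' @param cohort optionally resume from an existing cohort instead of
#'   simulating.
#' @return List with `cohort`, `features`, `stats`, `cv`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         configs = default_group_configs(),
                         cohort = NULL) {
  warnings <- character()
  if (is.null(cohort))
    cohort <- generate_cohort(configs$HSG, configs$LSG,
                              n_per_group = config$n_per_group,
                              seed = config$seed,
                              duration_s = config$duration_s,
                              fs_hz = config$fs_hz)
  features <- withCallingHandlers(
    extract_cohort_features(cohort, mode = config$mode,
                            band = config$peak_band_hz,
                            epoch_ms = config$epoch_ms,
                            window_ms = config$window_ms),
    message = function(m) {
      warnings <<- c(warnings, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  stats <- stat_report(features)
  cv <- nested_cv(features, default_search_grid(C = config$C),
                  k_outer = config$k_outer, k_inner = config$k_inner,
                  n_repeats = config$n_repeats, seed = config$seed)
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("restingalpha")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_recordings = length(cohort$recordings),
    n_subjects_retained = nrow(features),
    warnings = warnings)
  list(cohort = cohort, features = features, stats = stats, cv = cv,
       manifest = manifest)
}
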