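#' Group-level generative configuration for synthetic resting EEG
#'
#' Defines the distribution from which per-subject generative parameters
#' are drawn for one group: individual alpha frequency (IAF) and alpha
#' source amplitude per ROI, intra-hemispheric fronto-posterior coupling
#' and lag per hemisphere, and the background/sensor noise levels.
#'
#' @param group_label `"HSG"` or `"LSG"`.
#' @param iaf_mean_hz,iaf_sd_hz named numeric vectors over
#'   `c("frontal_L","frontal_R","posterior_L","posterior_R")`, Hz.
#'   Means must lie in \[7, 13\].
#' @param amp_mean_uv,amp_sd_uv alpha source RMS amplitude per ROI,
#'   microvolts.
#' @param coupling named numeric vector over `c("L","R")` in \[0, 1\]:
#'   fraction of the frontal alpha component shared (time-shifted) with
#'   the posterior driver.
#' @param lag_ms_mean,lag_ms_sd named numeric over `c("L","R")`, signed
#'   milliseconds; positive means the frontal signal lags the posterior
#'   (posterior leads).
#' @param noise_exponent 1/f background spectral slope.
#' @param background_uv broadband 1/f background RMS per source,
#'   microvolts.
#' @param sensor_noise_uv white sensor noise RMS per channel, microvolts.
#' @return A `group_gen_config` object.
#' @export
group_gen_config <- function(group_label,
                             iaf_mean_hz, iaf_sd_hz,
                             amp_mean_uv, amp_sd_uv,
                             coupling, lag_ms_mean, lag_ms_sd,
                             noise_exponent = 1,
                             background_uv = 5,
                             sensor_noise_uv = 1.5) {
  rois <- c("frontal_L", "frontal_R", "posterior_L", "posterior_R")
  hems <- c("L", "R")
  chk <- function(x, nm, what) {
    if (!all(nm %in% names(x)))
      stop(what, " must be named over ", paste(nm, collapse = ", "))
    x[nm]
  }
  iaf_mean_hz <- chk(iaf_mean_hz, rois, "iaf_mean_hz")
  iaf_sd_hz   <- chk(iaf_sd_hz, rois, "iaf_sd_hz")
  amp_mean_uv <- chk(amp_mean_uv, rois, "amp_mean_uv")
  amp_sd_uv   <- chk(amp_sd_uv, rois, "amp_sd_uv")
  coupling    <- chk(coupling, hems, "coupling")
  lag_ms_mean <- chk(lag_ms_mean, hems, "lag_ms_mean")
  lag_ms_sd   <- chk(lag_ms_sd, hems, "lag_ms_sd")
  if (any(iaf_mean_hz < 7 | iaf_mean_hz > 13))
    stop("iaf_mean_hz must lie in [7, 13]")
  if (any(c(iaf_sd_hz, amp_sd_uv, lag_ms_sd) < 0))
    stop("standard deviations must be >= 0")
  if (any(coupling < 0 | coupling > 1))
    stop("coupling must lie in [0, 1]")
  if (any(amp_mean_uv <= 0)) stop("amp_mean_uv must be positive")
  structure(list(
    group_label = group_label,
    iaf_mean_hz = iaf_mean_hz, iaf_sd_hz = iaf_sd_hz,
    amp_mean_uv = amp_mean_uv, amp_sd_uv = amp_sd_uv,
    coupling = coupling, lag_ms_mean = lag_ms_mean, lag_ms_sd = lag_ms_sd,
    noise_exponent = noise_exponent, background_uv = background_uv,
    sensor_noise_uv = sensor_noise_uv), class = "group_gen_config")
}

#' Default group configurations emulating the reported group effects
#'
#' Parameter means encode the reported group-level alpha statistics
#' (posterior IAF slower and posterior amplitude lower on the right in
#' the high-schizotypy group; lower right intra-hemispheric coupling;
#' right fronto-posterior lag of opposite sign in the two groups).
#' Dispersion choices are documented in the package vignette.
#'
#' @return Named list with elements `HSG` and `LSG`.
#' @export
default_group_configs <- function() {
  rois <- c(frontal_L = NA, frontal_R = NA, posterior_L = NA, posterior_R = NA)
  mk <- function(label, iaf, amp, coupling, lag_mean, lag_sd) {
    group_gen_config(
      group_label = label,
      iaf_mean_hz = iaf,
      iaf_sd_hz = c(frontal_L = 0.69, frontal_R = 0.69,
                    posterior_L = 0.69, posterior_R = 0.83),
      amp_mean_uv = amp,
      amp_sd_uv = 0.2 * amp,
      coupling = coupling,
      lag_ms_mean = lag_mean, lag_ms_sd = lag_sd
    )
  }
  list(
    HSG = mk("HSG",
             iaf = c(frontal_L = 10.11, frontal_R = 10.37,
                     posterior_L = 10.39, posterior_R = 10.09),
             amp = c(frontal_L = 1.11, frontal_R = 1.11,
                     posterior_L = 2.95, posterior_R = 2.62),
             coupling = c(L = 0.30, R = 0.12),
             lag_mean = c(L = -8, R = 7.04),
             lag_sd = c(L = 21, R = 22.9)),
    LSG = mk("LSG",
             iaf = c(frontal_L = 10.11, frontal_R = 10.37,
                     posterior_L = 10.39, posterior_R = 10.70),
             amp = c(frontal_L = 1.26, frontal_R = 1.14,
                     posterior_L = 3.20, posterior_R = 3.20),
             coupling = c(L = 0.30, R = 0.40),
             lag_mean = c(L = -8, R = -11.21),
             lag_sd = c(L = 21, R = 21.4))
  )
}

#' Draw per-subject generative parameters for one group
#'
#' Each per-ROI / per-hemisphere parameter is drawn independently from
#' its configured normal distribution. Drawn IAFs are clipped to
#' \[7, 13\] Hz, amplitudes below 5% of their mean are clipped up, and
#' lags are clipped inside the half-period wrap-ambiguity bound at the
#' subject's posterior alpha frequency (at most +/- 45 ms).
#'
#' @param config a [group_gen_config()].
#' @param n_subjects number of subjects to draw (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Tibble, one row per subject.
#' @export
sample_subject_params <- function(config, n_subjects, seed = NULL) {
  stopifnot(inherits(config, "group_gen_config"), n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  rois <- names(config$iaf_mean_hz)
  out <- tibble::tibble(subject_id = sprintf("%s%02d", config$group_label,
                                             seq_len(n_subjects)),
                        group = config$group_label)
  for (r in rois) {
    iaf <- stats::rnorm(n_subjects, config$iaf_mean_hz[[r]],
                        config$iaf_sd_hz[[r]])
    out[[paste0("iaf_", r)]] <- pmin(pmax(iaf, 7), 13)
    amp <- stats::rnorm(n_subjects, config$amp_mean_uv[[r]],
                        config$amp_sd_uv[[r]])
    out[[paste0("amp_", r)]] <- pmax(amp, 0.05 * config$amp_mean_uv[[r]])
  }
  for (h in c("L", "R")) {
    lag <- stats::rnorm(n_subjects, config$lag_ms_mean[[h]],
                        config$lag_ms_sd[[h]])
    # keep each subject's lag inside the wrap-ambiguity bound (half the
    # alpha period at that subject's posterior IAF, with 10% margin)
    bound <- pmin(45, 0.9 * 500 / out[[paste0("iaf_posterior_", h)]])
    out[[paste0("lag_ms_", h)]] <- pmin(pmax(lag, -bound), bound)
    out[[paste0("coupling_", h)]] <- config$coupling[[h]]
  }
  out
}

# Narrow-band random process around a centre frequency: white noise
# spectrally shaped by a Gaussian mask (sd sigma_f, so ~ +/- 2*sigma_f
# support). Returns the complex spectrum so that exactly time-shifted
# copies can be produced by phase rotation.
nb_spectrum <- function(n, fs, center_hz, sigma_f = 0.25) {
  z <- stats::fft(stats::rnorm(n))
  f <- fs * seq(0, n - 1) / n
  f_signed <- ifelse(f > fs / 2, f - fs, f)
  mask <- exp(-(abs(f_signed) - center_hz)^2 / (2 * sigma_f^2))
  z * mask
}

spectrum_to_series <- function(zs, lag_ms = 0, fs = NULL, n = length(zs)) {
  if (lag_ms != 0) {
    f <- fs * seq(0, n - 1) / n
    f_signed <- ifelse(f > fs / 2, f - fs, f)
    zs <- zs * exp(-2i * pi * f_signed * lag_ms / 1000)
  }
  x <- Re(stats::fft(zs, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Pure sinusoid variant (exact oracle mode): unit-RMS tone with a random
# phase; lag applied analytically.
sin_series <- function(n, fs, freq_hz, phase, lag_ms = 0) {
  t <- seq(0, n - 1) / fs
  sqrt(2) * cos(2 * pi * freq_hz * (t - lag_ms / 1000) - phase)
}

one_over_f_noise <- function(n, fs, exponent = 1, rms = 1, f_lo = 0.5) {
  z <- stats::fft(stats::rnorm(n))
  f <- fs * seq(0, n - 1) / n
  f_signed <- abs(ifelse(f > fs / 2, f - fs, f))
  shape <- ifelse(f_signed >= f_lo, f_signed^(-exponent / 2), 0)
  x <- Re(stats::fft(z * shape, inverse = TRUE)) / n
  rms * x / stats::sd(x)
}

#' Synthesize the four ROI source time series of one subject
#'
#' Each source is a narrow-band alpha oscillation at the ROI's IAF
#' (bandwidth ~1 Hz) scaled to its configured RMS amplitude, plus an
#' independent 1/f background. Within each hemisphere the frontal alpha
#' component mixes a time-shifted copy of the posterior driver (weight
#' `coupling`) with an independent component (weight
#' `sqrt(1 - coupling^2)`); a positive lag means the frontal signal lags
#' the posterior.
#'
#' @param params one row of [sample_subject_params()] (list or tibble).
#' @param duration_s,fs_hz recording length and sampling rate.
#' @param mode `"narrowband"` (default) or `"sinusoid"` (pure tones, for
#'   exact oracle checks).
#' @param noise_exponent,background_uv 1/f background slope and RMS; set
#'   `background_uv = 0` for clean sources.
#' @return 4 x samples numeric matrix with ROI row names.
#' @export
synthesize_sources <- function(params, duration_s, fs_hz,
                               mode = c("narrowband", "sinusoid"),
                               noise_exponent = 1, background_uv = 5) {
  mode <- match.arg(mode)
  params <- as.list(params)
  n <- round(duration_s * fs_hz)
  if (n < round(2.5 * fs_hz))
    stop("recording must cover at least one 2500 ms window")
  src <- matrix(0, 4, n,
                dimnames = list(c("frontal_L", "frontal_R",
                                  "posterior_L", "posterior_R"), NULL))
  for (h in c("L", "R")) {
    iaf_p <- params[[paste0("iaf_posterior_", h)]]
    iaf_f <- params[[paste0("iaf_frontal_", h)]]
    lag <- params[[paste0("lag_ms_", h)]]
    cpl <- params[[paste0("coupling_", h)]]
    if (abs(lag) > 500 / iaf_p)
      stop(sprintf(
        "lag %.1f ms exceeds half the alpha period (%.1f ms): wrap-ambiguous",
        lag, 500 / iaf_p))
    if (mode == "narrowband") {
      zs <- nb_spectrum(n, fs_hz, iaf_p)
      post <- spectrum_to_series(zs)
      shared <- spectrum_to_series(zs, lag_ms = lag, fs = fs_hz)
      indep <- spectrum_to_series(nb_spectrum(n, fs_hz, iaf_f))
    } else {
      phase <- stats::runif(1, 0, 2 * pi)
      post <- sin_series(n, fs_hz, iaf_p, phase)
      shared <- sin_series(n, fs_hz, iaf_p, phase, lag_ms = lag)
      indep <- sin_series(n, fs_hz, iaf_f, stats::runif(1, 0, 2 * pi))
    }
    front <- cpl * shared + sqrt(1 - cpl^2) * indep
    amp_p <- params[[paste0("amp_posterior_", h)]]
    amp_f <- params[[paste0("amp_frontal_", h)]]
    src[paste0("posterior_", h), ] <- amp_p * post
    src[paste0("frontal_", h), ] <- amp_f * front
    if (background_uv > 0) {
      src[paste0("posterior_", h), ] <- src[paste0("posterior_", h), ] +
        one_over_f_noise(n, fs_hz, noise_exponent, background_uv)
      src[paste0("frontal_", h), ] <- src[paste0("frontal_", h), ] +
        one_over_f_noise(n, fs_hz, noise_exponent, background_uv)
    }
  }
  src
}

#' Project ROI sources to scalp channels
#'
#' Each source is mixed onto the montage with a fixed Gaussian-falloff
#' weight pattern peaking over its own electrode cluster
#' ([source_topography()]); independent white sensor noise is added per
#' channel.
#'
#' @param sources 4 x samples matrix from [synthesize_sources()].
#' @param montage channel label vector; must contain all 14 cluster
#'   electrodes.
#' @param sensor_noise_uv white noise RMS per channel (microvolts).
#' @param fs_hz sampling rate of the sources.
#' @param subject_id,group metadata carried into the recording.
#' @return An [eeg_recording()].
#' @export
project_to_scalp <- function(sources, montage, sensor_noise_uv = 1.5,
                             fs_hz = 500, subject_id = NA_character_,
                             group = NA_character_) {
  montage <- toupper(montage)
  cl <- electrode_clusters()
  missing <- setdiff(unlist(cl), montage)
  if (length(missing) > 0)
    stop("montage missing cluster electrodes: ", paste(missing, collapse = ", "))
  W <- vapply(names(cl), function(roi) source_topography(montage, cl[[roi]]),
              numeric(length(montage)))
  data <- W[, rownames(sources), drop = FALSE] %*% sources
  if (sensor_noise_uv > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, sensor_noise_uv),
                          nrow(data), ncol(data))
  rownames(data) <- montage
  eeg_recording(data, fs_hz, subject_id = subject_id, group = group)
}

#' Generate a balanced two-group synthetic cohort
#'
#' Draws per-subject parameters for both groups, synthesizes and projects
#' every recording, and returns the recordings together with the
#' ground-truth parameter table for recovery tests. Identical
#' `(configs, seed)` give bit-identical output.
#'
#' @param config_hsg,config_lsg [group_gen_config()] objects; default
#'   [default_group_configs()].
#' @param n_per_group subjects per group (>= 2).
#' @param seed integer RNG seed.
#' @param duration_s,fs_hz recording length (s) and sampling rate (Hz).
#' @param montage channel labels; default the 14 cluster electrodes.
#' @param mode source model, see [synthesize_sources()].
#' @return List with `recordings` (list of [eeg_recording()]) and
#'   `ground_truth` (tibble, one row per subject).
#' @export
generate_cohort <- function(config_hsg = default_group_configs()$HSG,
                            config_lsg = default_group_configs()$LSG,
                            n_per_group = 24, seed = 1,
                            duration_s = 120, fs_hz = 500,
                            montage = montage_cluster14(),
                            mode = "narrowband") {
  stopifnot(n_per_group >= 2)
  set.seed(seed)
  params <- dplyr::bind_rows(
    sample_subject_params(config_hsg, n_per_group),
    sample_subject_params(config_lsg, n_per_group)
  )
  cfg_of <- list(HSG = config_hsg, LSG = config_lsg)
  recordings <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    cfg <- cfg_of[[p$group]]
    src <- synthesize_sources(p, duration_s, fs_hz, mode = mode,
                              noise_exponent = cfg$noise_exponent,
                              background_uv = cfg$background_uv)
    project_to_scalp(src, montage, sensor_noise_uv = cfg$sensor_noise_uv,
                     fs_hz = fs_hz, subject_id = p$subject_id,
                     group = p$group)
  })
  list(recordings = recordings, ground_truth = params)
}
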