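# shared fixtures and a lazy cache for expensive simulations

acc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = acc_cache))
    assign(key, force(expr), envir = acc_cache)
  get(key, envir = acc_cache)
}

# flat per-subject generative parameters with overridable fields
subject_params <- function(...) {
  p <- list(iaf_frontal_L = 10, iaf_frontal_R = 10,
            iaf_posterior_L = 10, iaf_posterior_R = 10,
            amp_frontal_L = 1, amp_frontal_R = 1,
            amp_posterior_L = 1, amp_posterior_R = 1,
            lag_ms_L = 0, lag_ms_R = 0,
            coupling_L = 0, coupling_R = 0)
  utils::modifyList(p, list(...))
}

# single-channel recording holding one sinusoid
tone_recording <- function(freq_hz, amp = 1, fs = 500, duration_s = 10,
                           n_chan = 1, labels = paste0("C", seq_len(n_chan))) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq_hz * t)
  data <- matrix(rep(x, each = n_chan), nrow = n_chan)
  rownames(data) <- labels
  eeg_recording(data, fs)
}

# two delayed unit tones as window matrices; y leads x by lag_ms
delayed_tone_windows <- function(freq_hz = 10, lag_ms = 5, fs = 500,
                                 duration_s = 60, window_ms = 2500,
                                 noise_sd = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  y <- sin(2 * pi * freq_hz * t)
  x <- sin(2 * pi * freq_hz * (t - lag_ms / 1000))
  if (noise_sd > 0) {
    x <- x + rnorm(length(x), 0, noise_sd)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  list(x = window_segments(x, fs, window_ms),
       y = window_segments(y, fs, window_ms))
}

# feature tibble with controllable group separation, built directly
synthetic_feature_table <- function(n_per_group = 24, delta = 0,
                                    right_only = TRUE, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  grp <- rep(c("HSG", "LSG"), each = n_per_group)
  f <- tibble::tibble(subject_id = sprintf("S%02d", seq_len(n)), group = grp)
  for (nm in alpha_feature_names()) {
    x <- rnorm(n)
    shift_all <- !right_only
    is_right <- grepl("_R$", nm)
    if (is_right || shift_all)
      x <- x + ifelse(grp == "HSG", delta / 2, -delta / 2)
    f[[nm]] <- x
  }
  f
}

demo_cohort_features <- function(seed = 101) {
  cached(paste0("demo_features_", seed), {
    coh <- generate_cohort(n_per_group = 24, seed = seed)
    suppressMessages(extract_cohort_features(coh))
  })
}
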