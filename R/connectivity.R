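#' Split a signal into non-overlapping connectivity windows
#'
#' @param x numeric vector.
#' @param fs_hz sampling rate.
#' @param window_ms window length in ms (default 2500); the trailing
#'   remainder is discarded.
#' @return windows x samples matrix.
#' @export
window_segments <- function(x, fs_hz, window_ms = 2500) {
  segment_series(x, fs_hz, window_ms)
}

#' Per-window cross-spectrum at a single frequency
#'
#' Hann-tapered Fourier transforms of each window evaluated at the grid
#' frequency nearest `freq_hz`; the cross-spectral phase is oriented so
#' that a positive argument means the first signal lags the second.
#'
#' @param x_windows,y_windows windows x samples matrices
#'   (see [window_segments()]) with equal dimensions.
#' @param fs_hz sampling rate.
#' @param freq_hz target frequency (evaluated at the nearest FFT bin of
#'   the window length).
#' @return A `cross_spectrum` object: complex per-window values `sxy`,
#'   the evaluated frequency `freq_hz`, and `n_windows`.
#' @export
cross_spectrum_at <- function(x_windows, y_windows, fs_hz, freq_hz) {
  if (!all(dim(x_windows) == dim(y_windows)))
    stop("x and y must have the same number and length of windows")
  n <- ncol(x_windows)
  k <- round(freq_hz * n / fs_hz)  # 0-based bin index
  f_eval <- k * fs_hz / n
  w <- hann_window(n)
  ph <- exp(-2i * pi * k * seq(0, n - 1) / n)
  X <- as.vector((x_windows * rep(w, each = nrow(x_windows))) %*% ph)
  Y <- as.vector((y_windows * rep(w, each = nrow(y_windows))) %*% ph)
  # Conj(X) * Y: positive phase <=> x delayed (lags) relative to y
  structure(list(sxy = Conj(X) * Y, freq_hz = f_eval,
                 n_windows = nrow(x_windows)),
            class = "cross_spectrum")
}

#' Weighted phase lag index
#'
#' `|mean(Im(Sxy))| / mean(|Im(Sxy)|)` over windows: phase coupling in
#' \[0, 1\] that discounts zero-lag (volume-conduction) interactions.
#' Returns 0 when every imaginary part is zero (pure zero-lag coupling).
#'
#' @param cs a `cross_spectrum` (or complex vector of per-window values).
#' @return Value in \[0, 1\].
#' @export
wpli <- function(cs) {
  s <- if (inherits(cs, "cross_spectrum")) cs$sxy else cs
  den <- mean(abs(Im(s)))
  if (den == 0) return(0)
  abs(mean(Im(s))) / den
}

#' Time lag index
#'
#' The circular-mean cross-spectral phase converted to milliseconds at
#' the evaluation frequency: `1000 * Arg(sum(Sxy)) / (2*pi*f)`. Positive
#' values mean the first signal lags the second. Undefined (NA) when the
#' resultant vector vanishes.
#'
#' @param cs a `cross_spectrum`.
#' @param freq_hz evaluation frequency; defaults to the frequency stored
#'   in `cs`.
#' @return Signed lag in milliseconds (within half a period), or `NA`.
#' @export
tli <- function(cs, freq_hz = NULL) {
  s <- if (inherits(cs, "cross_spectrum")) cs$sxy else cs
  if (is.null(freq_hz)) {
    if (!inherits(cs, "cross_spectrum"))
      stop("freq_hz required when cs is a bare vector")
    freq_hz <- cs$freq_hz
  }
  res <- sum(s)
  if (Mod(res) < .Machine$double.eps * length(s)) return(NA_real_)
  1000 * Arg(res) / (2 * pi * freq_hz)
}

#' Cluster-level connectivity: wPLI matrix and the six pipeline features
#'
#' Computes the 14 x 14 electrode-pair wPLI matrix over the cluster
#' electrodes at the subject's alpha frequency, plus the three wPLI
#' features (means over inter-cluster electrode pairs: left
#' intra-hemispheric, right intra-hemispheric, inter-hemispheric
#' posterior) and the three TLI features computed on the cluster-mean
#' time series for the same pairs (frontal first within hemispheres,
#' left posterior first for the inter-hemispheric pair).
#'
#' @param rec an [eeg_recording()] (alpha band-passed) containing the 14
#'   cluster electrodes.
#' @param iaf_hz subject's evaluation frequency; `NA` falls back to
#'   10 Hz (with a message).
#' @param window_ms connectivity window length (default 2500 ms).
#' @return List with `matrix` (14 x 14 symmetric wPLI), `features`
#'   (one-row tibble: `wpli_intra_L`, `wpli_intra_R`, `wpli_inter`,
#'   `tli_intra_L`, `tli_intra_R`, `tli_inter`) and `freq_hz`.
#' @export
cluster_connectivity <- function(rec, iaf_hz, window_ms = 2500) {
  if (is.na(iaf_hz)) {
    message("subject ", rec$subject_id,
            ": no alpha peak; connectivity evaluated at 10 Hz")
    iaf_hz <- 10
  }
  ord <- cluster_electrode_order()
  missing <- setdiff(ord, channel_labels(rec))
  if (length(missing) > 0)
    stop("missing electrode label(s): ", paste(missing, collapse = ", "))
  fs <- rec$fs_hz
  win <- lapply(ord, function(ch) window_segments(rec$data[ch, ], fs,
                                                  window_ms))
  names(win) <- ord
  # single tapered FFT bin per electrode per window
  n <- ncol(win[[1]])
  k <- round(iaf_hz * n / fs)
  f_eval <- k * fs / n
  w <- hann_window(n)
  ph <- exp(-2i * pi * k * seq(0, n - 1) / n)
  coef <- vapply(win, function(m) as.vector((m * rep(w, each = nrow(m))) %*% ph),
                 complex(nrow(win[[1]])))
  M <- matrix(0, 14, 14, dimnames = list(ord, ord))
  for (i in 1:13) for (j in (i + 1):14) {
    v <- wpli(Conj(coef[, i]) * coef[, j])
    M[i, j] <- v; M[j, i] <- v
  }
  cl <- electrode_clusters()
  pair_mean <- function(a, b) mean(M[cl[[a]], cl[[b]]])
  roi_mean_series <- function(roi)
    colMeans(rec$data[cl[[roi]], , drop = FALSE])
  tli_pair <- function(first, second) {
    cs <- cross_spectrum_at(
      window_segments(roi_mean_series(first), fs, window_ms),
      window_segments(roi_mean_series(second), fs, window_ms),
      fs, iaf_hz)
    tli(cs)
  }
  features <- tibble::tibble(
    wpli_intra_L = pair_mean("frontal_L", "posterior_L"),
    wpli_intra_R = pair_mean("frontal_R", "posterior_R"),
    wpli_inter   = pair_mean("posterior_L", "posterior_R"),
    tli_intra_L  = tli_pair("frontal_L", "posterior_L"),
    tli_intra_R  = tli_pair("frontal_R", "posterior_R"),
    tli_inter    = tli_pair("posterior_L", "posterior_R")
  )
  list(matrix = M, features = features, freq_hz = f_eval)
}
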