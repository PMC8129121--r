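#' Welch power spectrum of epoched data
#'
#' Per-epoch Hann-tapered periodograms, zero-padded to a fine frequency
#' grid and averaged across epochs. Power is normalised so that a
#' sinusoid of mean-square power \eqn{P} \eqn{\mu V^2} shows a spectral
#' peak of \eqn{P} \eqn{\mu V^2} (window coherent gain compensated).
#'
#' @param epochs epochs x samples numeric matrix (one ROI), or an
#'   `eeg_epochs` object with a single channel.
#' @param fs_hz sampling rate (taken from the object if available).
#' @param grid_hz frequency grid step after zero padding (default
#'   0.05 Hz).
#' @param fmax_hz highest frequency retained (default 30 Hz).
#' @return A `power_spectrum` object with fields `freq_hz`, `power_uv2`,
#'   `power_db` (`10*log10(power_uv2)`) and `smoothed_db` (filled by
#'   [sgf_smooth()]).
#' @export
compute_power_spectrum <- function(epochs, fs_hz = NULL, grid_hz = 0.05,
                                   fmax_hz = 30) {
  if (inherits(epochs, "eeg_epochs")) {
    if (dim(epochs$data)[2] != 1)
      stop("compute_power_spectrum expects a single-channel epoch set")
    fs_hz <- epochs$fs_hz
    epochs <- epochs$data[, 1, , drop = TRUE]
    if (is.null(dim(epochs))) epochs <- matrix(epochs, nrow = 1)
  }
  stopifnot(is.matrix(epochs), !is.null(fs_hz))
  n <- ncol(epochs)
  nfft <- max(stats::nextn(n, 2), round(fs_hz / grid_hz))
  w <- hann_window(n)
  cg <- sum(w)  # coherent gain
  tapered <- sweep(epochs, 2, w, `*`)
  padded <- cbind(tapered, matrix(0, nrow(epochs), nfft - n))
  X <- stats::mvfft(t(padded))
  keep <- seq_len(floor(fmax_hz * nfft / fs_hz) + 1)
  pgram <- 2 * (Mod(X[keep, , drop = FALSE]) / cg)^2
  pw <- rowMeans(pgram)
  if (all(pw == 0)) warning("all-zero input: zero spectrum")
  structure(list(
    freq_hz = fs_hz * (keep - 1) / nfft,
    power_uv2 = pw,
    power_db = 10 * log10(pmax(pw, .Machine$double.xmin)),
    smoothed_db = NULL,
    n_epochs = nrow(epochs), grid_hz = fs_hz / nfft
  ), class = "power_spectrum")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.3f Hz grid, %d epochs%s\n",
              length(x$freq_hz), x$grid_hz, x$n_epochs,
              if (is.null(x$smoothed_db)) "" else ", smoothed"))
  invisible(x)
}

#' Savitzky-Golay smoothing of the dB spectrum
#'
#' Least-squares local polynomial smoothing of `power_db`, the smoothing
#' step used before alpha peak detection. The window spans
#' `resolution_hz` on each side of every grid point.
#'
#' @param spectrum a `power_spectrum`.
#' @param resolution_hz half-width of the smoothing window in Hz
#'   (default 0.24).
#' @param polyorder polynomial order (default 5); must be smaller than
#'   the window length.
#' @return The spectrum with `smoothed_db` filled in.
#' @export
sgf_smooth <- function(spectrum, resolution_hz = 0.24, polyorder = 5) {
  half <- round(resolution_hz / spectrum$grid_hz)
  n_win <- 2 * half + 1
  if (polyorder >= n_win)
    stop("polyorder (", polyorder, ") must be < window length (", n_win, ")")
  spectrum$smoothed_db <-
    as.numeric(signal::sgolayfilt(spectrum$power_db, p = polyorder, n = n_win))
  spectrum
}

#' Individual alpha frequency
#'
#' The frequency of the maximum of the smoothed dB spectrum within the
#' alpha band, accepted only if it is a strict local maximum of the
#' smoothed curve; otherwise `NA` (no discernible alpha peak).
#'
#' @param spectrum a `power_spectrum` with `smoothed_db`
#'   (see [sgf_smooth()]).
#' @param band alpha search band in Hz (default `c(7, 13)`).
#' @return Peak frequency in Hz, or `NA_real_`.
#' @export
detect_iaf <- function(spectrum, band = c(7, 13)) {
  if (is.null(spectrum$smoothed_db))
    stop("smoothed spectrum missing: run sgf_smooth() first")
  s <- spectrum$smoothed_db
  f <- spectrum$freq_hz
  in_band <- which(f >= band[1] & f <= band[2])
  if (length(in_band) == 0) stop("spectrum does not cover the band")
  j <- in_band[which.max(s[in_band])]
  if (j == 1 || j == length(s)) return(NA_real_)
  if (s[j - 1] < s[j] && s[j] > s[j + 1]) f[j] else NA_real_
}

#' Alpha amplitude
#'
#' Maximum power over the alpha band of the raw dB spectrum
#' (`10*log10` of power in microvolts squared).
#'
#' @inheritParams detect_iaf
#' @return Amplitude in dB.
#' @export
alpha_amplitude <- function(spectrum, band = c(7, 13)) {
  in_band <- spectrum$freq_hz >= band[1] & spectrum$freq_hz <= band[2]
  if (!any(in_band)) stop("spectrum does not cover the band")
  max(spectrum$power_db[in_band])
}

#' Spectrum autoplot
#'
#' Raw and smoothed dB spectrum over the alpha range.
#' @param object a `power_spectrum`.
#' @param band frequency range shown.
#' @param ... unused.
#' @export
autoplot.power_spectrum <- function(object, band = c(6, 14), ...) {
  df <- tibble::tibble(freq_hz = object$freq_hz,
                       raw = object$power_db,
                       smoothed = if (is.null(object$smoothed_db))
                         NA_real_ else object$smoothed_db)
  df <- df[df$freq_hz >= band[1] & df$freq_hz <= band[2], ]
  df <- tidyr::pivot_longer(df, -"freq_hz", names_to = "curve",
                            values_to = "power_db")
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$power_db,
                                   colour = .data$curve)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(10 * log[10](mu * V^2)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
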