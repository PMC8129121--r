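#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed FIR band-pass applied forward and backward (zero
#' group delay). The filter order follows the Hamming design rule
#' `order = 3.3 * fs / transition_hz` for a 2 Hz transition band, the
#' convolution runs in the frequency domain, and the output has the
#' length of the input.
#'
#' @param rec an [eeg_recording()] (or a channels x samples matrix).
#' @param low_hz,high_hz band edges, Hz; default 6-14 Hz around the
#'   alpha band.
#' @param transition_hz transition bandwidth of the design rule.
#' @return Filtered object of the same type.
#' @export
bandpass_filter <- function(rec, low_hz = 6, high_hz = 14,
                            transition_hz = 2) {
  mat <- if (inherits(rec, "eeg_recording")) rec$data else rec
  fs <- if (inherits(rec, "eeg_recording")) rec$fs_hz else
    stop("matrix input needs an eeg_recording wrapper")
  if (fs <= 2 * high_hz) stop("sampling rate too low for requested band")
  ord <- ceiling(3.3 * fs / transition_hz / 2) * 2  # even order
  if (ncol(mat) <= ord)
    stop("recording shorter than the filter order (", ord, " samples)")
  b <- signal::fir1(ord, c(low_hz, high_hz) / (fs / 2), type = "pass",
                    window = signal::hamming(ord + 1))
  out <- fft_filtfilt(mat, b)
  if (inherits(rec, "eeg_recording")) { rec$data <- out; rec } else out
}

# Forward-backward FIR filtering of the rows of a matrix via the
# frequency domain: equivalent to convolving with b twice (squared
# magnitude response, zero phase). Edges are zero-padded by the filter
# length before the circular convolution.
fft_filtfilt <- function(mat, b) {
  single <- is.null(dim(mat))
  if (single) mat <- matrix(mat, 1)
  n <- ncol(mat); L <- length(b)
  nfft <- stats::nextn(n + 2 * L, 2)
  B <- stats::fft(c(b, rep(0, nfft - L)))
  H2 <- Mod(B)^2  # |B|^2: forward + backward pass, zero phase
  X <- stats::mvfft(t(cbind(matrix(0, nrow(mat), L), mat,
                            matrix(0, nrow(mat), nfft - n - L))))
  Y <- Re(stats::mvfft(X * H2, inverse = TRUE)) / nfft
  # group delay of b * reversed b is (L - 1) samples centred at lag 0
  out <- t(Y)[, (L + 1):(L + n), drop = FALSE]
  if (single) drop(out) else out
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean over channels, so every sample's
#' channel mean becomes zero. Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2) stop("average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Resample a recording
#'
#' Anti-aliased polyphase resampling (via [signal::resample()]).
#' Downsampling only unless `allow_upsample = TRUE`.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate, Hz (default 500).
#' @param allow_upsample permit target rates above the original.
#' @export
resample_signal <- function(rec, target_fs = 500, allow_upsample = FALSE) {
  if (target_fs == rec$fs_hz) return(rec)
  if (target_fs > rec$fs_hz && !allow_upsample)
    stop("upsampling requested (", rec$fs_hz, " -> ", target_fs,
         " Hz); set allow_upsample = TRUE to permit")
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  p <- target_fs; q <- rec$fs_hz
  d <- g(p, q); p <- p / d; q <- q / d
  out <- t(apply(rec$data, 1, function(x) signal::resample(x, p, q)))
  rownames(out) <- rownames(rec$data)
  rec$data <- out
  rec$fs_hz <- target_fs
  rec
}

#' Cut a recording into consecutive non-overlapping epochs
#'
#' @param rec an [eeg_recording()].
#' @param epoch_ms epoch length in milliseconds (default 2000).
#' @return An `eeg_epochs` object: `data` is an epochs x channels x
#'   samples array; the trailing remainder is discarded.
#' @export
epoch_signal <- function(rec, epoch_ms = 2000) {
  len <- round(epoch_ms * rec$fs_hz / 1000)
  n_ep <- floor(ncol(rec$data) / len)
  if (n_ep < 1) stop("recording shorter than one epoch (", epoch_ms, " ms)")
  arr <- array(NA_real_, c(n_ep, nrow(rec$data), len))
  for (e in seq_len(n_ep))
    arr[e, , ] <- rec$data[, ((e - 1) * len + 1):(e * len)]
  structure(list(data = arr, epoch_ms = epoch_ms, fs_hz = rec$fs_hz,
                 channel_labels = rownames(rec$data)),
            class = "eeg_epochs")
}

# epochs x samples matrix for a single series
segment_series <- function(x, fs, window_ms) {
  len <- round(window_ms * fs / 1000)
  n_w <- floor(length(x) / len)
  if (n_w < 1) stop("signal shorter than one ", window_ms, " ms window")
  matrix(x[seq_len(n_w * len)], nrow = n_w, ncol = len, byrow = TRUE)
}

#' Match component topographies to ROI templates
#'
#' Correlation-based template matching: a component is a candidate for a
#' template when the absolute Pearson correlation between their
#' topography vectors reaches `threshold`; each component goes to the
#' template it correlates best with, and each template keeps at most
#' `max_per_template` components (highest |r| first). A template left
#' without any component is an error.
#'
#' @param components a component set: list with `topographies`
#'   (channels x components) and `activations` (components x samples).
#' @param templates channels x templates matrix, e.g.
#'   [topography_templates()].
#' @param threshold minimum |Pearson r| (default 0.80).
#' @param max_per_template retain at most this many components per
#'   template (default 3).
#' @param subject_id used in error messages.
#' @return Tibble with columns `template`, `component`, `r`.
#' @export
match_templates <- function(components, templates, threshold = 0.80,
                            max_per_template = 3,
                            subject_id = NA_character_) {
  topo <- components$topographies
  if (nrow(topo) != nrow(templates))
    stop("components and templates must share the channel space")
  r <- stats::cor(topo, templates)  # components x templates
  best_t <- apply(abs(r), 1, which.max)
  rows <- lapply(seq_len(ncol(templates)), function(j) {
    cand <- which(best_t == j & abs(r[, j]) >= threshold)
    if (length(cand) == 0)
      stop(sprintf("template unmatched: subject %s, template %s",
                   subject_id, colnames(templates)[j]))
    cand <- cand[order(-abs(r[cand, j]))]
    cand <- cand[seq_len(min(length(cand), max_per_template))]
    tibble::tibble(template = colnames(templates)[j],
                   component = cand, r = r[cand, j])
  })
  dplyr::bind_rows(rows)
}

#' Extract one time series per region of interest
#'
#' In `cluster-average` mode each ROI series is the mean of its cluster
#' electrodes. In `backprojection` mode the components matched to the
#' ROI's template are projected back to the scalp (summed), then averaged
#' over the cluster electrodes.
#'
#' @param rec an [eeg_recording()].
#' @param clusters named list of electrode sets, default
#'   [electrode_clusters()].
#' @param mode `"cluster-average"` or `"backprojection"`.
#' @param components component set (needed in backprojection mode).
#' @param matches output of [match_templates()]; computed from
#'   [topography_templates()] if missing.
#' @return `roi_series` object: 4 x samples matrix plus sampling rate.
#' @export
roi_time_series <- function(rec, clusters = electrode_clusters(),
                            mode = c("cluster-average", "backprojection"),
                            components = NULL, matches = NULL) {
  mode <- match.arg(mode)
  labs <- channel_labels(rec)
  missing <- setdiff(toupper(unlist(clusters)), labs)
  if (length(missing) > 0)
    stop("unknown cluster electrode(s): ", paste(missing, collapse = ", "))
  base <- rec$data
  if (mode == "backprojection") {
    if (is.null(components))
      stop("backprojection mode needs a component set")
    if (is.null(matches))
      matches <- match_templates(components, topography_templates(labs),
                                 subject_id = rec$subject_id)
  }
  series <- vapply(names(clusters), function(roi) {
    cluster <- toupper(clusters[[roi]])
    if (mode == "cluster-average") {
      colMeans(base[cluster, , drop = FALSE])
    } else {
      sel <- matches$component[matches$template == roi]
      proj <- components$topographies[, sel, drop = FALSE] %*%
        components$activations[sel, , drop = FALSE]
      rownames(proj) <- labs
      colMeans(proj[cluster, , drop = FALSE])
    }
  }, numeric(ncol(base)))
  structure(list(series = t(series), fs_hz = rec$fs_hz,
                 subject_id = rec$subject_id, group = rec$group,
                 mode = mode),
            class = "roi_series")
}
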