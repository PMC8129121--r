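test_that("band-pass filter preserves the passband and kills the stopband", {
  pass <- bandpass_filter(tone_recording(10, amp = 1, duration_s = 20))
  mid <- 2001:8000  # avoid edges
  expect_equal(stats::sd(pass$data[1, mid]), 1 / sqrt(2), tolerance = 0.01)
  stopb <- bandpass_filter(tone_recording(2, amp = 1, duration_s = 20))
  expect_lt(stats::sd(stopb$data[1, mid]), 0.01 / sqrt(2))
  high <- bandpass_filter(tone_recording(25, amp = 1, duration_s = 20))
  expect_lt(stats::sd(high$data[1, mid]), 0.01 / sqrt(2))
})

test_that("forward-backward filtering has zero group delay", {
  set.seed(1)
  rec <- tone_recording(10, duration_s = 20)
  rec$data[1, ] <- rec$data[1, ] + rnorm(ncol(rec$data), 0, 0.2)
  out <- bandpass_filter(rec)
  cc <- stats::ccf(out$data[1, 3000:7000], rec$data[1, 3000:7000],
                   lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("average re-referencing zeroes the channel mean and is idempotent", {
  set.seed(2)
  data <- matrix(rnorm(5 * 100), 5, dimnames = list(paste0("C", 1:5), NULL))
  rec <- rereference_average(eeg_recording(data, 500))
  expect_equal(max(abs(colMeans(rec$data))), 0, tolerance = 1e-12)
  expect_equal(rereference_average(rec)$data, rec$data, tolerance = 1e-12)
  two <- eeg_recording(matrix(c(1, -1), 2, 50,
                              dimnames = list(c("A1", "A2"), NULL)), 500)
  expect_equal(rereference_average(two)$data, two$data)
})

test_that("resampling preserves duration, content and rejects upsampling", {
  rec <- tone_recording(10, fs = 1000, duration_s = 120)
  down <- resample_signal(rec, 500)
  expect_equal(ncol(down$data), 60000)
  ps <- compute_power_spectrum(window_segments(down$data[1, ], 500, 2000),
                               500)
  expect_equal(ps$freq_hz[which.max(ps$power_uv2)], 10, tolerance = 0.1)
  expect_identical(resample_signal(rec, 1000), rec)
  expect_error(resample_signal(rec, 2000), "upsampling")
})

test_that("epoching floors the epoch count and errors on short input", {
  rec <- tone_recording(10, duration_s = 120)
  ep <- epoch_signal(rec, 2000)
  expect_equal(dim(ep$data)[1], 60)
  short <- tone_recording(10, duration_s = 2.999)
  expect_equal(dim(epoch_signal(short, 2000)$data)[1], 1)
  expect_error(epoch_signal(tone_recording(10, duration_s = 1.999), 2000),
               "shorter than one epoch")
})

test_that("template matching implements the threshold / cap / uniqueness rules", {
  tmpl <- topography_templates(montage_cluster14())
  # a component equal to a template is selected with r = 1
  comp <- list(topographies = tmpl[, c("frontal_L", "posterior_R")],
               activations = matrix(0, 2, 10))
  m <- match_templates(comp, tmpl[, c("frontal_L", "posterior_R")])
  expect_equal(sort(m$template), c("frontal_L", "posterior_R"))
  expect_equal(m$r[m$template == "frontal_L"], 1, tolerance = 1e-12)

  # cap at three components per template, ranked by |r|
  base <- tmpl[, "posterior_L"]
  rs <- c(0.95, 0.9, 0.85, 0.82, 0.81)
  set.seed(3)
  mk_with_r <- function(target_r) {
    # mix the standardised template with orthogonalised standardised
    # noise so the sample correlation is exactly target_r
    b <- scale(base)[, 1]
    noise <- scale(rnorm(length(base)))[, 1]
    noise <- noise - b * sum(noise * b) / sum(b^2)
    noise <- noise / stats::sd(noise)
    target_r * b + sqrt(1 - target_r^2) * noise
  }
  topo <- vapply(rs, mk_with_r, numeric(length(base)))
  m <- match_templates(list(topographies = topo, activations = NULL),
                       tmpl[, "posterior_L", drop = FALSE])
  expect_equal(nrow(m), 3)
  expect_equal(m$component, c(1, 2, 3))
  expect_equal(m$r, rs[1:3], tolerance = 1e-6)

  # sign flips and scaling do not matter; orthogonal components never match
  m2 <- match_templates(list(topographies = -5 * topo, activations = NULL),
                        tmpl[, "posterior_L", drop = FALSE])
  expect_equal(m2$component, m$component)
  ortho <- mk_with_r(0)
  expect_error(
    match_templates(list(topographies = cbind(ortho), activations = NULL),
                    tmpl[, "posterior_L", drop = FALSE], subject_id = "S1"),
    "template unmatched.*S1")
})

test_that("both ROI extraction modes recover a single clean source", {
  t <- seq(0, 10 - 1 / 500, by = 1 / 500)
  src <- matrix(sin(2 * pi * 10 * t), 1,
                dimnames = list("posterior_L", NULL))
  rec <- project_to_scalp(src, montage_cluster14(), sensor_noise_uv = 0)
  ca <- roi_time_series(rec, mode = "cluster-average")
  expect_equal(cor(ca$series["posterior_L", ], src[1, ]), 1,
               tolerance = 1e-9)
  w <- source_topography(montage_cluster14(),
                         electrode_clusters()$posterior_L)
  comp <- list(topographies = cbind(w), activations = src)
  matches <- tibble::tibble(template = "posterior_L", component = 1, r = 1)
  bp <- roi_time_series(rec, mode = "backprojection", components = comp,
                        matches = matches)
  expect_equal(cor(bp$series["posterior_L", ], src[1, ]), 1,
               tolerance = 1e-9)
  # identical channels average to any single channel
  expect_equal(ca$series["posterior_L", ],
               rec$data["PO7", ] / w[["PO7"]] * mean(
                 w[electrode_clusters()$posterior_L]), tolerance = 1e-9)
})

test_that("filtering, re-referencing and epoching commute with channel order", {
  set.seed(6)
  data <- matrix(rnorm(6 * 2000), 6,
                 dimnames = list(paste0("C", 1:6), NULL))
  rec <- eeg_recording(data, 500)
  perm <- c(4, 2, 6, 1, 3, 5)
  rec_p <- eeg_recording(data[perm, ], 500)
  chain <- function(r) epoch_signal(rereference_average(bandpass_filter(r)))
  a <- chain(rec); b <- chain(rec_p)
  expect_equal(a$data[, perm, ], b$data[, , ], tolerance = 1e-10)
})

test_that("backprojection and cluster averaging agree on synthetic truth", {
  set.seed(7)
  p <- subject_params(amp_posterior_L = 3, amp_posterior_R = 3,
                      coupling_L = 0.5, coupling_R = 0.5,
                      lag_ms_L = -8, lag_ms_R = 7)
  src <- synthesize_sources(p, 20, 500, background_uv = 1)
  rec <- project_to_scalp(src, montage_cluster14(), sensor_noise_uv = 0.5)
  W <- vapply(electrode_clusters(),
              function(cl) source_topography(montage_cluster14(), cl),
              numeric(14))
  # compare in the analysis band, as the pipeline does
  rec <- bandpass_filter(rec)
  src_f <- bandpass_filter(eeg_recording(src, 500))$data
  comp <- list(topographies = W, activations = src_f,
               provenance = "synthetic-truth")
  ca <- roi_time_series(rec, mode = "cluster-average")
  bp <- roi_time_series(rec, mode = "backprojection", components = comp)
  for (r in rownames(ca$series))
    expect_gt(cor(ca$series[r, ], bp$series[r, ]), 0.9)
})
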