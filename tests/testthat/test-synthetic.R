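test_that("parameter sampling is reproducible and respects degenerate SDs", {
  cfg <- default_group_configs()$HSG
  a <- sample_subject_params(cfg, 5, seed = 42)
  b <- sample_subject_params(cfg, 5, seed = 42)
  expect_identical(a, b)

  zero <- group_gen_config(
    "HSG",
    iaf_mean_hz = c(frontal_L = 10, frontal_R = 10,
                    posterior_L = 10, posterior_R = 10),
    iaf_sd_hz = rep(c(frontal_L = 0, frontal_R = 0,
                      posterior_L = 0, posterior_R = 0), 1),
    amp_mean_uv = c(frontal_L = 1, frontal_R = 1,
                    posterior_L = 3, posterior_R = 3),
    amp_sd_uv = c(frontal_L = 0, frontal_R = 0,
                  posterior_L = 0, posterior_R = 0),
    coupling = c(L = 0.5, R = 0.5),
    lag_ms_mean = c(L = 5, R = 5), lag_ms_sd = c(L = 0, R = 0))
  p <- sample_subject_params(zero, 4, seed = 1)
  expect_true(all(p$iaf_posterior_R == 10))
  expect_true(all(p$amp_posterior_L == 3))
  expect_true(all(p$lag_ms_R == 5))
})

test_that("sampled parameter means obey the law of large numbers", {
  cfg <- default_group_configs()$LSG
  p <- sample_subject_params(cfg, 10000, seed = 7)
  se <- 0.83 / sqrt(10000)
  expect_lt(abs(mean(p$iaf_posterior_R) - 10.70), 3 * se)
})

test_that("invalid generator configs are rejected", {
  base <- default_group_configs()$HSG
  expect_error(group_gen_config("X", base$iaf_mean_hz, -base$iaf_sd_hz - 1,
                                base$amp_mean_uv, base$amp_sd_uv,
                                base$coupling, base$lag_ms_mean,
                                base$lag_ms_sd),
               "standard deviations")
  bad_iaf <- base$iaf_mean_hz; bad_iaf["frontal_L"] <- 5
  expect_error(group_gen_config("X", bad_iaf, base$iaf_sd_hz,
                                base$amp_mean_uv, base$amp_sd_uv,
                                base$coupling, base$lag_ms_mean,
                                base$lag_ms_sd),
               "\\[7, 13\\]")
  bad_cpl <- base$coupling; bad_cpl["L"] <- 1.2
  expect_error(group_gen_config("X", base$iaf_mean_hz, base$iaf_sd_hz,
                                base$amp_mean_uv, base$amp_sd_uv,
                                bad_cpl, base$lag_ms_mean, base$lag_ms_sd),
               "coupling")
})

test_that("sinusoid sources with full coupling carry the exact injected lag", {
  set.seed(3)
  src <- synthesize_sources(
    subject_params(coupling_R = 1, lag_ms_R = 5),
    duration_s = 60, fs_hz = 500, mode = "sinusoid", background_uv = 0)
  cs <- cross_spectrum_at(window_segments(src["frontal_R", ], 500),
                          window_segments(src["posterior_R", ], 500),
                          500, 10)
  expect_equal(wpli(cs), 1, tolerance = 1e-9)
  expect_equal(tli(cs), 5, tolerance = 0.5)
})

test_that("uncoupled sources show only bias-floor wPLI", {
  set.seed(4)
  vals <- replicate(6, {
    src <- synthesize_sources(subject_params(), 60, 500,
                              mode = "narrowband", background_uv = 0)
    cs <- cross_spectrum_at(window_segments(src["frontal_L", ], 500),
                            window_segments(src["posterior_L", ], 500),
                            500, 10)
    wpli(cs)
  })
  # independent-signal floor at W = 24 windows is ~ sqrt(2/(pi*W)) ~ 0.16
  expect_lt(mean(vals), 0.35)
})

test_that("doubling source amplitude raises alpha power by ~6.02 dB", {
  extract_amp <- function(a, seed) {
    set.seed(seed)
    src <- synthesize_sources(subject_params(amp_posterior_R = a), 60, 500,
                              mode = "sinusoid", background_uv = 0)
    ep <- window_segments(src["posterior_R", ], 500, 2000)
    alpha_amplitude(sgf_smooth(compute_power_spectrum(ep, 500)))
  }
  expect_equal(extract_amp(2, 9) - extract_amp(1, 9), 10 * log10(4),
               tolerance = 0.05)
})

test_that("lags beyond half the alpha period are wrap-ambiguous errors", {
  expect_error(
    synthesize_sources(subject_params(lag_ms_R = 49, iaf_posterior_R = 12),
                       60, 500, background_uv = 0),
    "wrap-ambiguous")
})

test_that("scalp projection is the expected linear mixing", {
  src <- matrix(sin(2 * pi * 10 * seq(0, 10, by = 1 / 500)), 1)
  rownames(src) <- "posterior_R"
  rec <- project_to_scalp(src, montage_cluster14(), sensor_noise_uv = 0)
  w <- source_topography(montage_cluster14(),
                         electrode_clusters()$posterior_R)
  expect_equal(rec$data["PO8", ], w[["PO8"]] * src[1, ], tolerance = 1e-12)
  # and the realised topography matches the matching template
  topo <- vapply(seq_len(nrow(rec$data)),
                 function(i) stats::cov(rec$data[i, ], src[1, ]),
                 numeric(1))
  tmpl <- topography_templates(montage_cluster14())[, "posterior_R"]
  expect_gt(cor(topo, tmpl), 0.99)
})

test_that("projection refuses montages without the cluster electrodes", {
  src <- matrix(rnorm(500 * 4), 4)
  rownames(src) <- c("frontal_L", "frontal_R", "posterior_L", "posterior_R")
  expect_error(project_to_scalp(src, c("F1", "F2", "CZ")),
               "missing cluster electrodes")
})

test_that("posterior-dominant config yields posterior-dominant scalp alpha", {
  set.seed(5)
  src <- synthesize_sources(
    subject_params(amp_posterior_L = 4, amp_posterior_R = 4,
                   amp_frontal_L = 0.5, amp_frontal_R = 0.5),
    30, 500, background_uv = 1)
  rec <- project_to_scalp(src, montage_cluster14(), sensor_noise_uv = 0.5)
  rec <- bandpass_filter(rec)
  roi <- roi_time_series(rec)
  amp_of <- function(r) {
    ep <- window_segments(roi$series[r, ], 500, 2000)
    alpha_amplitude(sgf_smooth(compute_power_spectrum(ep, 500)))
  }
  expect_gt(amp_of("posterior_L"), amp_of("frontal_L"))
  expect_gt(amp_of("posterior_R"), amp_of("frontal_R"))
})

test_that("cohorts are balanced, complete, and bit-reproducible", {
  cfgs <- default_group_configs()
  a <- generate_cohort(n_per_group = 2, seed = 10, duration_s = 10)
  b <- generate_cohort(n_per_group = 2, seed = 10, duration_s = 10)
  expect_length(a$recordings, 4)
  expect_equal(nrow(a$ground_truth), 4)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$recordings[[3]]$data, b$recordings[[3]]$data)
  expect_equal(sort(unique(a$ground_truth$group)), c("HSG", "LSG"))
})
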