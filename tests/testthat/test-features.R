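test_that("the smoothed second derivative is exact on low-order polynomials", {
  fs <- 125
  t <- (0:99) / fs
  d2 <- second_derivative(t^2, fs)
  interior <- 10:90
  expect_true(all(abs(d2[interior] - 2) < 1e-6))
  ramp <- second_derivative(5 * t + 1, fs)
  expect_true(all(abs(ramp[interior]) < 1e-6))
  expect_error(second_derivative(rnorm(5), fs), "too short")
})

test_that("the second derivative of a sinusoid matches the closed form", {
  fs <- 125
  t <- (0:(2 * fs)) / fs
  for (f in c(1, 3, 5)) {
    x <- sin(2 * pi * f * t)
    d2 <- second_derivative(x, fs)
    want <- -(2 * pi * f)^2 * x
    interior <- 20:(length(t) - 20)
    expect_lt(max(abs(d2[interior] - want[interior])) / (2 * pi * f)^2, 0.02)
  }
})

test_that("fiducials on a clean rest-morphology beat are direct and ordered", {
  fs <- 125
  t <- (0:109) / fs
  w <- render_beat_for_test(t, a1 = 0.86, ri = 0.45, dt = 0.24)
  fid <- detect_fiducials(w, fs)
  expect_true(fid$ok)
  expect_false(fid$dia_fallback)
  expect_lt(abs(fid$t1 - 0.13), 1.5 / fs)
  expect_lt(abs(fid$dia_t - 0.37), 1.5 / fs)
  expect_true(all(diff(fid$wave_t) > 0))
  expect_gt(fid$wave_amp[["a"]], 0)
  expect_lt(fid$wave_amp[["b"]], 0)
})

test_that("an attenuated exercise beat takes the e-wave fallback", {
  fs <- 125
  t <- (0:68) / fs
  w <- render_beat_for_test(t, a1 = 1.6, ri = 0.15, dt = 0.192)
  fid <- detect_fiducials(w, fs)
  expect_true(fid$ok)
  expect_true(fid$dia_fallback)
})

test_that("a time-reversed beat fails fiducial detection", {
  fs <- 125
  t <- (0:109) / fs
  w <- rev(render_beat_for_test(t, a1 = 0.86, ri = 0.45, dt = 0.24))
  fid <- detect_fiducials(w, fs)
  expect_false(fid$ok)
})

test_that("features satisfy their definitional identities on every beat", {
  syn <- make_clean_synth(durations = c(60, 60, 60), seed = 17)
  beats <- segment_beats(syn$recording) |>
    beat_quality_stats(rec = syn$recording) |>
    classify_beats()
  fe <- suppressMessages(extract_beat_features(syn$recording, beats))
  expect_gt(nrow(fe), 100)
  # augmentation index is the amplitude ratio by construction
  expect_equal(fe$f07_augmentation_index,
               fe$f02_diastolic_peak / fe$f01_systolic_peak, tolerance = 1e-12)
  # inter-wave intervals telescope to t_e - t_a; all intervals positive
  expect_true(all(fe$f14_tb_a > 0 & fe$f15_tb_c > 0 & fe$f16_tc_d > 0 &
                    fe$f17_td_e > 0))
  # dT is the systolic-to-diastolic interval
  expect_equal(fe$f04_delta_t, fe$f05_diastolic_peak_time - fe$f03_t1,
               tolerance = 1e-12)
  expect_true(all(fe$f06_pulse_interval >= 0.3 & fe$f06_pulse_interval <= 2.0))
  expect_true(all(fe$f03_t1 < fe$f06_pulse_interval))
  expect_true(all(fe$f13_ta < fe$f06_pulse_interval))
})

test_that("feature extraction recovers the generator's peak ground truth", {
  syn <- make_clean_synth(durations = c(120, 120, 240), seed = 19)
  rec <- syn$recording
  beats <- segment_beats(rec) |>
    beat_quality_stats(rec = rec) |>
    classify_beats()
  fe <- suppressMessages(extract_beat_features(rec, beats))
  fails <- attr(fe, "failures")
  expect_lt(nrow(fails) / sum(beats$verdict == "accepted"), 0.02)
  bi <- match(fe$beat_id, beats$beat_id)
  gi <- match_beats_to_truth(beats[bi, ], syn$beats)
  ok <- !is.na(gi)
  expect_gt(mean(ok), 0.95)
  gt <- syn$beats[gi[ok], ]; feo <- fe[ok, ]
  foot <- beats$start_sample[bi][ok]
  # systolic peak within 1 sample of ground truth for every beat
  expect_true(all(abs(foot + round(feo$f03_t1 * 125) - gt$systolic_peak_sample) <= 1))
  # diastolic peak within 1 sample where the generator rendered a true local max
  direct <- !feo$dia_fallback & gt$dia_is_local_max
  expect_gt(sum(direct), 200)
  expect_true(all(abs(foot[direct] + round(feo$f05_diastolic_peak_time[direct] * 125) -
                        gt$diastolic_peak_sample[direct]) <= 1))
  # amplitude recovery: f1 matches the latent pulse amplitude within 3%
  expect_lt(max(abs(feo$f01_systolic_peak / gt$a1 - 1)), 0.03)
  # monotone coupling: dT falls as SBP rises across directly measured beats
  rho <- stats::cor(feo$f04_delta_t[direct], gt$sbp[direct], method = "spearman")
  expect_lt(rho, -0.8)
})

test_that("time and ratio features are scale-invariant; amplitudes scale", {
  fs <- 125
  t <- (0:109) / fs
  w <- render_beat_for_test(t, a1 = 0.86, ri = 0.45, dt = 0.24)
  f1 <- extract_features(w, fs, detect_fiducials(w, fs), 120, 70)
  for (c_scale in c(0.5, 3)) {
    f2 <- extract_features(c_scale * w, fs, detect_fiducials(c_scale * w, fs), 120, 70)
    inv <- setdiff(feature_names(),
                   c("f01_systolic_peak", "f02_diastolic_peak", "f08_a_amp"))
    expect_equal(unlist(f2[, inv]), unlist(f1[, inv]), tolerance = 1e-9)
    sc <- c("f01_systolic_peak", "f02_diastolic_peak", "f08_a_amp")
    expect_equal(unlist(f2[, sc]), c_scale * unlist(f1[, sc]), tolerance = 1e-9)
  }
})

test_that("Z-score normalization is exact in-sample and leak-free out-of-sample", {
  set.seed(23)
  d <- tibble::as_tibble(stats::setNames(lapply(1:17, function(i) rnorm(2000, i, i)),
                                         feature_names()))
  st <- zscore_fit(d)
  z <- zscore_apply(d, st)
  expect_true(all(abs(colMeans(as.matrix(z))) < 1e-12))
  expect_true(all(abs(apply(as.matrix(z), 2, sd) - 1) < 1e-12))
  # train/test split: test means stay near 0 at n = 1000 per half
  tr <- d[1:1000, ]; te <- d[1001:2000, ]
  zt <- zscore_apply(te, zscore_fit(tr))
  expect_true(all(abs(colMeans(as.matrix(zt))) < 0.1))
  # constant features are flagged and dropped
  d$f01_systolic_peak <- 1
  expect_warning(st2 <- zscore_fit(d), "constant")
  expect_warning(z2 <- zscore_apply(d, st2), "dropping")
  expect_false("f01_systolic_peak" %in% names(z2))
  expect_error(zscore_fit(d[1, ]), "at least 2")
})
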