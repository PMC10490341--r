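test_that("SSQI equals the hand-derived third standardized moment", {
  expect_equal(compute_ssqi(c(-1, 0, 1)), 0)
  expect_equal(compute_ssqi(c(0, 0, 1)), 1 / sqrt(2), tolerance = 1e-4)
  # mu = 1/3, sigma = sqrt(2/9): third moment = 0.70711
  x <- rnorm(50)
  expect_equal(compute_ssqi(-x), -compute_ssqi(x))
  expect_error(compute_ssqi(c(1, 2)), "at least 3")
  expect_warning(s <- compute_ssqi(rep(2, 10)), "degenerate")
  expect_true(is.na(s))
})

test_that("SSQI matches brute-force and library oracles on random arrays", {
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(10:200, 1), sd = runif(1, 0.1, 10))
    expect_equal(compute_ssqi(x), naive_third_moment(x), tolerance = 1e-12)
    expect_equal(compute_ssqi(x), e1071::skewness(x, type = 1), tolerance = 1e-10)
  }
})

test_that("SSQI is invariant under positive affine maps and flips sign under negative", {
  set.seed(8)
  for (i in 1:20) {
    x <- rexp(100)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 50)
    expect_equal(compute_ssqi(a * x + b), compute_ssqi(x), tolerance = 1e-9)
    expect_equal(compute_ssqi(-a * x + b), -compute_ssqi(x), tolerance = 1e-9)
  }
})

test_that("bandpass keeps the pulse band and suppresses drift", {
  fs <- 125
  t <- (0:(60 * fs - 1)) / fs
  slow <- sin(2 * pi * 0.05 * t)
  out <- bandpass(slow, fs)
  mid <- seq(10 * fs, 50 * fs)  # avoid filter edge transients
  expect_lt(max(abs(out[mid])) / 1, 10^(-20 / 20))  # >= 20 dB attenuation
  inband <- sin(2 * pi * 2 * t)
  out2 <- bandpass(inband, fs)
  expect_lt(abs(max(abs(out2[mid])) - 1), 0.05)
  expect_equal(bandpass(numeric(1000), fs), numeric(1000))
  expect_error(bandpass(rnorm(5), fs), "too short")
})

test_that("segmentation recovers clean beats with exact feet", {
  # 60 bpm, noise-free: one beat per second
  cfg <- protocol_config(phase_durations_s = c(60, 5, 5), resting_hr = 60, seed = 2)
  syn <- synthesize_recording(
    cfg, synth_waveform_params(p_artifact = c(rest = 0, exercise = 0, recovery = 0)),
    hr_noise_sd = 0, bp_noise_sd = 0
  )
  b <- segment_beats(syn$recording)
  rest_b <- b[b$phase == "rest", ]
  expect_true(abs(nrow(rest_b) - 59) <= 1)
  gi <- match_beats_to_truth(rest_b, syn$beats)
  expect_true(all(!is.na(gi)))
  expect_true(all(abs(rest_b$start_sample - syn$beats$foot_sample[gi]) <= 1))
  # determinism
  expect_identical(b, segment_beats(syn$recording))
})

test_that("a constant signal yields an empty segmentation with a warning", {
  d <- tibble::tibble(time_s = (0:9999) / 125, ppg = rep(1, 10000))
  rec <- ppg_recording(d, 125, tibble::tibble(label = "rest", start_sample = 0L,
                                              end_sample = 10000L))
  expect_warning(b <- segment_beats(rec), "empty segmentation")
  expect_equal(nrow(b), 0)
})

test_that("threshold classification follows the acceptance semantics", {
  beats <- tibble::tibble(beat_id = 1:4, start_sample = 0L, end_sample = 10L,
                          phase = "rest",
                          ssqi = c(0.5, -0.2, 0, NA),
                          length_s = 0.8, amplitude = 1)
  out <- classify_beats(beats, quality_model(threshold = 0))
  expect_equal(out$verdict, c("accepted", "rejected", "accepted", "rejected"))
  # -Inf threshold accepts every non-degenerate beat
  out2 <- classify_beats(beats, quality_model(threshold = -Inf))
  expect_equal(out2$verdict, c("accepted", "accepted", "accepted", "rejected"))
  # the verdict partitions the set
  expect_equal(sum(out$verdict == "accepted") + sum(out$verdict == "rejected"),
               nrow(beats))
})

test_that("the linear SVM mode separates a separable toy set and is deterministic", {
  set.seed(31)
  n <- 40
  toy <- tibble::tibble(
    ssqi = c(rnorm(n, 0.6, 0.05), rnorm(n, -0.6, 0.05)),
    length_s = rnorm(2 * n, 0.8, 0.05),
    amplitude = c(rnorm(n, 1, 0.1), rnorm(n, 2.5, 0.1)),
    label = rep(c("clean", "artifact"), each = n)
  )
  m1 <- train_quality_model(toy)
  toy$verdict <- NULL
  pred <- classify_beats(dplyr::mutate(toy, beat_id = dplyr::row_number()), m1)
  expect_equal(pred$verdict, rep(c("accepted", "rejected"), each = n))
  m2 <- train_quality_model(toy)
  expect_identical(m1$svm_fit$coefs, m2$svm_fit$coefs)
  expect_error(train_quality_model(dplyr::filter(toy, label == "clean")),
               "single-class")
  expect_error(train_quality_model(toy[c(1:5, n + (1:5)), ]), "at least 10")
  expect_error(classify_beats(pred, quality_model("svm", svm_fit = NULL)),
               "svm mode requires")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(77)
  n <- 400
  toy <- tibble::tibble(
    ssqi = rnorm(n), length_s = rnorm(n, 0.8, 0.1), amplitude = rnorm(n, 1, 0.2),
    label = sample(rep(c("clean", "artifact"), n / 2))
  )
  half <- seq_len(n / 2)
  m <- train_quality_model(toy[half, ])
  held <- classify_beats(dplyr::mutate(toy[-half, ], beat_id = dplyr::row_number()), m)
  acc <- mean((held$verdict == "accepted") == (toy$label[-half] == "clean"))
  expect_lt(abs(acc - 0.5), 0.10)
})

test_that("rejection-rate arithmetic and its properties hold", {
  expect_equal(rejection_rate(14290, 10878), 23.88)
  expect_equal(rejection_rate(21174, 6566), 68.99)
  expect_equal(rejection_rate(100, 100), 0)
  expect_error(rejection_rate(0, 0), "domain error")
  expect_error(rejection_rate(10, 11), "domain error")
  set.seed(5)
  n_b <- sample(100:10000, 30)
  n_a <- vapply(n_b, function(n) sample(0:n, 1), numeric(1))
  rr <- rejection_rate(n_b, n_a)
  expect_true(all(rr >= 0 & rr <= 100))
  # monotone decreasing in n_after
  expect_true(all(diff(rejection_rate(1000, 0:1000)) <= 0))
})
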