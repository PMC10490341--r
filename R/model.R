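# Sequence dataset construction and the BiLSTM+LSTM blood-pressure
# regressor: sliding windows of consecutive accepted beats feed a
# bidirectional LSTM, a stack of LSTM layers, and a fully connected output
# regressing the BP of each window's final beat.

#' Model configuration
#'
#' Defaults are the full-scale settings: BiLSTM(100) -> LSTM(200, 400, 800)
#' -> FC(1), mini-batch 256, 850 epochs, initial learning rate 0.004,
#' 10-beat windows, 70/15/15 chronological split. `scale` uniformly shrinks
#' hidden sizes and epoch count for desk-scale runs.
#'
#' @param bilstm_units Hidden units of the bidirectional layer (per
#'   direction).
#' @param lstm_units Hidden sizes of the unidirectional stack.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param learning_rate Initial Adam learning rate.
#' @param window_len Beats per window.
#' @param split Train/test/eval fractions, summing to 1.
#' @param seed Integer seed for initialization and shuffling.
#' @param scale Fraction in (0, 1] applied to unit counts and epochs.
#' @return A `bp_model_config` list.
#' @export
bp_model_config <- function(bilstm_units = 100, lstm_units = c(200, 400, 800),
                            batch_size = 256, epochs = 850,
                            learning_rate = 0.004, window_len = 10,
                            split = c(0.70, 0.15, 0.15), seed = 0L,
                            scale = 1) {
  stopifnot(abs(sum(split) - 1) < 1e-9, window_len >= 1,
            all(c(bilstm_units, lstm_units) >= 1),
            scale > 0, scale <= 1, epochs >= 1, learning_rate > 0)
  structure(
    list(bilstm_units = bilstm_units, lstm_units = lstm_units,
         batch_size = batch_size, epochs = epochs,
         learning_rate = learning_rate, window_len = window_len,
         split = split, seed = as.integer(seed), scale = scale),
    class = "bp_model_config"
  )
}

#' Preset model configurations
#'
#' `"paper"` keeps the full-scale settings; `"ci"` shrinks the network to
#' scale 0.25 and caps training at 100 epochs so a desk-scale run finishes
#' in minutes on one CPU.
#'
#' @param preset `"paper"` or `"ci"`.
#' @param seed Integer seed.
#' @return A [bp_model_config()].
#' @export
bp_model_preset <- function(preset = c("paper", "ci"), seed = 0L) {
  preset <- match.arg(preset)
  if (preset == "paper") bp_model_config(seed = seed)
  else bp_model_config(epochs = 400, scale = 0.25, seed = seed)
}

effective_units <- function(cfg) {
  list(
    bilstm = max(1L, as.integer(round(cfg$bilstm_units * cfg$scale))),
    lstm = pmax(1L, as.integer(round(cfg$lstm_units * cfg$scale)))
  )
}

#' Build sliding beat windows
#'
#' Windows of `window_len` consecutive accepted beats, stride 1; a gap in
#' `beat_id` (a rejected or feature-failed beat), a phase change, or a
#' recording change breaks the run. The target is the reference BP of the
#' window's final beat.
#'
#' @param features Feature table (rows = accepted, feature-complete beats,
#'   ordered by `beat_id`), optionally with a `recording_id` column.
#' @param window_len Beats per window.
#' @param feature_cols Feature columns to use (default: all 17 present).
#' @param target `"sbp"` or `"dbp"`.
#' @return A `bp_windows` object: `x` array `[n, window_len, n_features]`,
#'   `y` targets (mmHg), `meta` tibble, `features`, `target`. Empty (with a
#'   warning) when no phase holds `window_len` consecutive beats.
#' @export
build_windows <- function(features, window_len = 10,
                          feature_cols = NULL, target = c("sbp", "dbp")) {
  target <- match.arg(target)
  ycol <- paste0(target, "_ref")
  if (is.null(feature_cols)) feature_cols <- intersect(feature_names(), names(features))
  rid <- if ("recording_id" %in% names(features)) features$recording_id else rep(1L, nrow(features))
  n <- nrow(features)
  if (n == 0) return(empty_windows(feature_cols, window_len, target))
  new_run <- c(TRUE, diff(features$beat_id) != 1 |
                 features$phase[-1] != features$phase[-n] |
                 rid[-1] != rid[-n])
  run_id <- cumsum(new_run)
  xm <- as.matrix(features[, feature_cols])
  xs <- list(); ys <- numeric(0); meta <- list()
  for (r in unique(run_id)) {
    rows <- which(run_id == r)
    if (length(rows) < window_len) next
    for (s in 1:(length(rows) - window_len + 1)) {
      w_rows <- rows[s:(s + window_len - 1)]
      xs[[length(xs) + 1]] <- xm[w_rows, , drop = FALSE]
      last <- w_rows[window_len]
      ys <- c(ys, features[[ycol]][last])
      meta[[length(meta) + 1]] <- tibble::tibble(
        recording_id = rid[last], phase = features$phase[last],
        beat_id_start = features$beat_id[w_rows[1]],
        beat_id_end = features$beat_id[last]
      )
    }
  }
  if (length(xs) == 0) {
    warning("no phase holds window_len consecutive accepted beats", call. = FALSE)
    return(empty_windows(feature_cols, window_len, target))
  }
  X <- array(0, c(length(xs), window_len, length(feature_cols)))
  for (i in seq_along(xs)) X[i, , ] <- xs[[i]]
  meta <- dplyr::bind_rows(meta)
  meta$window_id <- seq_len(nrow(meta))
  structure(list(x = X, y = ys, meta = meta,
                 features = feature_cols, target = target,
                 window_len = window_len),
            class = "bp_windows")
}

empty_windows <- function(feature_cols, window_len, target) {
  structure(list(x = array(0, c(0, window_len, length(feature_cols))),
                 y = numeric(0),
                 meta = tibble::tibble(recording_id = integer(0),
                                       phase = character(0),
                                       beat_id_start = integer(0),
                                       beat_id_end = integer(0),
                                       window_id = integer(0)),
                 features = feature_cols, target = target,
                 window_len = window_len),
            class = "bp_windows")
}

#' @export
print.bp_windows <- function(x, ...) {
  cat(sprintf("<bp_windows> %d windows of %d beats x %d features, target %s\n",
              length(x$y), x$window_len, length(x$features), x$target))
  invisible(x)
}

windows_subset <- function(ds, rows) {
  structure(list(x = ds$x[rows, , , drop = FALSE], y = ds$y[rows],
                 meta = ds$meta[rows, ], features = ds$features,
                 target = ds$target, window_len = ds$window_len),
            class = "bp_windows")
}

#' Split a window dataset into train / test / eval
#'
#' Chronological mode (default) assigns, within each recording-phase group,
#' the first 70% of windows to train, the next 15% to test and the final
#' 15% to eval; a window in a later partition that shares source beats with
#' the preceding partition's boundary window is dropped. Shuffled mode is a
#' seeded random assignment kept as a flagged alternative.
#'
#' @param ds A [build_windows()] dataset.
#' @param split Fractions summing to 1.
#' @param mode `"chronological"` or `"shuffled"`.
#' @param seed Seed for shuffled mode.
#' @return Named list of `bp_windows`: `train`, `test`, `eval`.
#' @export
split_dataset <- function(ds, split = c(0.70, 0.15, 0.15),
                          mode = c("chronological", "shuffled"), seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "bp_windows"), abs(sum(split) - 1) < 1e-9)
  n <- length(ds$y)
  if (n == 0) stop("cannot split an empty dataset", call. = FALSE)
  grp <- paste(ds$meta$recording_id, ds$meta$phase, sep = "::")
  tr <- te <- ev <- integer(0)
  if (mode == "shuffled") {
    idx <- with_local_seed(seed, sample.int(n))
    n_tr <- floor(split[1] * n); n_te <- floor(split[2] * n)
    tr <- idx[seq_len(n_tr)]
    te <- idx[n_tr + seq_len(n_te)]
    ev <- idx[(n_tr + n_te + 1):n]
  } else {
    for (g in unique(grp)) {
      rows <- which(grp == g)
      rows <- rows[order(ds$meta$beat_id_end[rows])]
      m <- length(rows)
      n_tr <- floor(split[1] * m); n_te <- floor(split[2] * m)
      g_tr <- rows[seq_len(n_tr)]
      g_te <- rows[n_tr + seq_len(n_te)]
      g_ev <- if (n_tr + n_te < m) rows[(n_tr + n_te + 1):m] else integer(0)
      if (length(g_tr) > 0 && length(g_te) > 0) {
        bnd <- ds$meta$beat_id_end[g_tr[length(g_tr)]]
        g_te <- g_te[ds$meta$beat_id_start[g_te] > bnd]
      }
      if (length(g_te) > 0 && length(g_ev) > 0) {
        bnd <- ds$meta$beat_id_end[g_te[length(g_te)]]
        g_ev <- g_ev[ds$meta$beat_id_start[g_ev] > bnd]
      }
      tr <- c(tr, g_tr); te <- c(te, g_te); ev <- c(ev, g_ev)
    }
  }
  if (length(tr) == 0 || length(te) == 0 || length(ev) == 0) {
    stop("a partition would be empty; need more windows", call. = FALSE)
  }
  list(train = windows_subset(ds, tr),
       test = windows_subset(ds, te),
       eval = windows_subset(ds, ev))
}

#' Train the BiLSTM+LSTM blood-pressure regressor
#'
#' Trains BiLSTM -> LSTM stack -> FC with mean-squared-error loss and Adam
#' at the configured initial learning rate. Targets are standardized
#' internally (training-set mean/SD) so the regression layer works on unit
#' scale; predictions are mapped back to mmHg. The test split is monitored
#' every epoch and the best-test-loss parameters are retained. All
#' initialization and shuffling derive from `cfg$seed`, so a run is fully
#' reproducible. Loss curves are reported in mmHg^2.
#'
#' @param train,test `bp_windows` datasets sharing a feature schema.
#' @param cfg A [bp_model_config()].
#' @param verbose Print the loss every 10 epochs.
#' @return A `bp_lstm` fit: best parameters, config, training `curves`
#'   tibble, `best_epoch`.
#' @export
train_bp_model <- function(train, test, cfg = bp_model_config(), verbose = FALSE) {
  stopifnot(inherits(train, "bp_windows"), inherits(test, "bp_windows"))
  if (!identical(train$features, test$features)) {
    stop("train/test feature schemas differ", call. = FALSE)
  }
  if (length(train$y) == 0) stop("empty training set", call. = FALSE)
  u <- effective_units(cfg)
  epochs <- max(1L, as.integer(round(cfg$epochs * cfg$scale)))
  n <- length(train$y)
  y_mu <- mean(train$y)
  y_sd <- stats::sd(train$y)
  if (!is.finite(y_sd) || y_sd < 1e-8) y_sd <- 1
  ytr <- (train$y - y_mu) / y_sd
  yte <- (test$y - y_mu) / y_sd
  curves <- tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                           test_loss = numeric(0))
  fit <- with_local_seed(cfg$seed, {
    layers <- net_init(length(train$features), u$bilstm, u$lstm)
    m_state <- tree_zero(layers); v_state <- tree_zero(layers)
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    step <- 0L
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        rows <- idx[b0:min(b0 + cfg$batch_size - 1, n)]
        Xb <- train$x[rows, , , drop = FALSE]
        yb <- ytr[rows]
        fw <- net_forward(layers, Xb)
        loss <- mse_loss(fw$yhat, yb)
        if (!is.finite(loss)) {
          stop(sprintf("divergent loss at epoch %d (loss = %g); try a lower learning rate",
                       ep, loss), call. = FALSE)
        }
        dyhat <- 2 * (fw$yhat - yb) / length(yb)
        grads <- net_backward(layers, fw, dyhat)
        step <- step + 1L
        upd <- adam_update(layers, grads, m_state, v_state,
                           cfg$learning_rate, step)
        layers <- upd$p; m_state <- upd$m; v_state <- upd$v
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      test_loss <- mse_loss(net_forward(layers, test$x)$yhat, yte)
      curves <- dplyr::bind_rows(curves, tibble::tibble(
        epoch = ep, train_loss = ep_loss / nb * y_sd^2,
        test_loss = test_loss * y_sd^2))
      if (test_loss < best$loss) {
        best <- list(loss = test_loss, layers = layers, epoch = ep)
      }
      if (verbose && ep %% 10 == 0) {
        message(sprintf("epoch %d: train %.4f test %.4f", ep, ep_loss / nb, test_loss))
      }
    }
    best
  })
  structure(
    list(layers = fit$layers, config = cfg, features = train$features,
         target = train$target, window_len = train$window_len,
         y_mu = y_mu, y_sd = y_sd,
         curves = curves, best_epoch = fit$epoch,
         best_test_loss = fit$loss * y_sd^2,
         units = u, epochs_run = nrow(curves)),
    class = "bp_lstm"
  )
}

#' @export
print.bp_lstm <- function(x, ...) {
  cat(sprintf(
    "<bp_lstm> %s, BiLSTM(%d)+LSTM(%s)+FC, %d features, best epoch %d/%d (test MSE %.3f)\n",
    x$target, x$units$bilstm, paste(x$units$lstm, collapse = ","),
    length(x$features), x$best_epoch, x$epochs_run, x$best_test_loss))
  invisible(x)
}

#' Predict blood pressure for a window dataset
#'
#' @param object A trained `bp_lstm`.
#' @param newdata A `bp_windows` dataset with the training feature schema.
#' @param ... Unused.
#' @return Numeric vector of BP estimates (mmHg), one per window, in
#'   dataset order.
#' @export
predict.bp_lstm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "bp_windows"))
  if (!identical(object$features, newdata$features)) {
    stop("schema mismatch: newdata features differ from training", call. = FALSE)
  }
  if (length(newdata$y) == 0) return(numeric(0))
  net_forward(object$layers, newdata$x)$yhat * object$y_sd + object$y_mu
}

#' Phase-mean baseline predictor
#'
#' Predicts the mean training target for every window — the reference point
#' a sequence model must beat.
#'
#' @param train Training `bp_windows`.
#' @param newdata `bp_windows` to predict for.
#' @return Numeric vector of constant predictions.
#' @export
baseline_phase_mean <- function(train, newdata) {
  rep(mean(train$y), length(newdata$y))
}
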