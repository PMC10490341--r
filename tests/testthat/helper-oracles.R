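# Independent reference implementations used as oracles, kept deliberately
# naive and separate from the package's code paths.

# third standardized moment with population (1/N) normalization, by loops
naive_third_moment <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- sqrt(sum((x - mu)^2) / n)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + ((x[i] - mu) / sigma)^3
  acc / n
}

# O(n^2) regression-relief reference: plain loops over anchors, neighbors
# and features, mirroring the estimator's update equations literally
naive_rrelieff <- function(x, y, k = 10, sigma = 50) {
  x <- as.matrix(x)
  n <- nrow(x); f <- ncol(x)
  rng_f <- apply(x, 2, function(v) diff(range(v)))
  rng_f[rng_f == 0] <- 1
  xs <- sweep(x, 2, rng_f, "/")
  ys <- y / diff(range(y))
  n_dc <- 0; n_df <- numeric(f); n_dcdf <- numeric(f)
  rank_w <- exp(-(seq_len(k) / sigma)^2)
  rank_w <- rank_w / sum(rank_w)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(abs(xs[j, ] - xs[i, ]))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    for (r in seq_len(k)) {
      j <- nb[r]
      dy <- abs(ys[j] - ys[i])
      n_dc <- n_dc + rank_w[r] * dy
      for (a in seq_len(f)) {
        dfv <- abs(xs[j, a] - xs[i, a])
        n_df[a] <- n_df[a] + rank_w[r] * dfv
        n_dcdf[a] <- n_dcdf[a] + rank_w[r] * dy * dfv
      }
    }
  }
  n_dcdf / n_dc - (n_df - n_dcdf) / (n - n_dc)
}

# one clean beat rendered with the generator's default waveform parameters
render_beat_for_test <- function(t, a1, ri, dt) {
  wf <- synth_waveform_params()
  ppgbp:::render_clean_beat(t, a1, ri * a1, wf$t1_s, dt, wf$s1, wf$s2,
                            wf$notch_amp, wf$notch_frac, wf$notch_width_s)
}

# small clean recording shared across feature/quality tests
make_clean_synth <- function(durations = c(120, 120, 240), seed = 7,
                             ...) {
  cfg <- protocol_config(phase_durations_s = durations, seed = seed)
  synthesize_recording(
    cfg,
    synth_waveform_params(p_artifact = c(rest = 0, exercise = 0, recovery = 0)),
    ...
  )
}

# match segmented beats to ground-truth beats by span (both feet must agree)
match_beats_to_truth <- function(beats, truth, tol = 1L) {
  vapply(seq_len(nrow(beats)), function(i) {
    j <- which.min(abs(truth$foot_sample - beats$start_sample[i]))
    if (abs(truth$foot_sample[j] - beats$start_sample[i]) <= tol &&
        abs(truth$end_sample[j] - beats$end_sample[i]) <= tol) j
    else NA_integer_
  }, integer(1))
}
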