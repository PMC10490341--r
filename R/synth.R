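# Synthetic rest/exercise/recovery PPG + blood-pressure generator.
#
# Emulates a 3 x 20-min ergometer protocol: heart rate driven toward the
# Karvonen target during exercise, SBP rising ~40 mmHg while DBP stays near
# baseline, PPG beats rendered as two log-normal-shaped pulses (systolic +
# attenuated reflected diastolic) with a deterministic, invertible latent map
# from (SBP, DBP) to pulse amplitude and reflection timing, and motion
# artifacts concentrated in the exercise phase.

#' Karvonen target heart rate
#'
#' Target HR = (max HR - resting HR) x intensity + resting HR, with
#' max HR = 220 - age.
#'
#' @param age Age in years (10-100).
#' @param resting_hr Resting heart rate, bpm.
#' @param intensity Training intensity fraction in (0, 1].
#' @return Target heart rate in bpm.
#' @examples
#' karvonen_target_hr(20, 60, 0.7) # 158
#' @export
karvonen_target_hr <- function(age, resting_hr, intensity) {
  if (any(!is.finite(intensity)) || any(intensity <= 0) || any(intensity > 1)) {
    stop("domain error: intensity must lie in (0, 1]", call. = FALSE)
  }
  if (any(age < 10) || any(age > 100)) {
    stop("domain error: age must lie in [10, 100] years", call. = FALSE)
  }
  max_hr <- 220 - age
  (max_hr - resting_hr) * intensity + resting_hr
}

#' Protocol configuration for the synthetic generator
#'
#' Defaults mirror the ergometer protocol the pipeline is designed around:
#' 20 min rest, 20 min exercise at 0.7 Karvonen intensity, 20 min recovery.
#'
#' @param phase_durations_s Durations (s) of rest, exercise, recovery.
#' @param age Subject age, years.
#' @param resting_hr Resting heart rate, bpm.
#' @param intensity Karvonen intensity fraction in (0, 1].
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(phase_durations_s = c(1200, 1200, 1200),
                            age = 22, resting_hr = 65,
                            intensity = 0.7, seed = 1L) {
  if (length(phase_durations_s) != 3 || any(phase_durations_s <= 0)) {
    stop("phase_durations_s must be three positive durations", call. = FALSE)
  }
  if (intensity <= 0 || intensity > 1) {
    stop("domain error: intensity must lie in (0, 1]", call. = FALSE)
  }
  if (age < 10 || age > 100) {
    stop("domain error: age must lie in [10, 100]", call. = FALSE)
  }
  structure(
    list(
      phase_durations_s = as.numeric(phase_durations_s),
      age = age, resting_hr = resting_hr, intensity = intensity,
      seed = as.integer(seed)
    ),
    class = "protocol_config"
  )
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-phase RNG sub-streams keep each phase reproducible when the durations
# of the other phases change. stream 0 = trajectories, 1 = artifacts.
phase_substream <- function(seed, phase_idx, stream = 0L) {
  as.integer((as.double(seed) * 7919 + phase_idx * 104729 + stream * 15485863) %% 2147483647)
}

hr_sbp_deterministic <- function(t, cfg, hr_tau_s, sbp_tau_s,
                                 sbp_baseline, sbp_ex_delta) {
  d <- cumsum(cfg$phase_durations_s)
  hr_target <- karvonen_target_hr(cfg$age, cfg$resting_hr, cfg$intensity)
  # end-of-exercise values, needed as recovery start points
  hr_ex_end <- hr_target - (hr_target - cfg$resting_hr) * exp(-cfg$phase_durations_s[2] / hr_tau_s)
  sbp_ex_end <- sbp_baseline + sbp_ex_delta * (1 - exp(-cfg$phase_durations_s[2] / sbp_tau_s))
  hr <- ifelse(
    t < d[1], cfg$resting_hr,
    ifelse(
      t < d[2],
      hr_target - (hr_target - cfg$resting_hr) * exp(-(t - d[1]) / hr_tau_s),
      cfg$resting_hr + (hr_ex_end - cfg$resting_hr) * exp(-(t - d[2]) / hr_tau_s)
    )
  )
  sbp <- ifelse(
    t < d[1], sbp_baseline,
    ifelse(
      t < d[2],
      sbp_baseline + sbp_ex_delta * (1 - exp(-(t - d[1]) / sbp_tau_s)),
      sbp_baseline + (sbp_ex_end - sbp_baseline) * exp(-(t - d[2]) / sbp_tau_s)
    )
  )
  list(hr = hr, sbp = sbp)
}

#' Simulate per-beat heart-rate and blood-pressure trajectories
#'
#' Heart rate relaxes first-order from the resting value toward the Karvonen
#' target during exercise and back during recovery; SBP relaxes from its
#' baseline toward baseline + `sbp_ex_delta` during exercise; DBP stays at
#' baseline apart from a slow drift. Beat-to-beat Gaussian noise is added to
#' every series, drawn from per-phase sub-streams of `cfg$seed`.
#'
#' @param cfg A [protocol_config()].
#' @param hr_tau_s,sbp_tau_s First-order time constants (s) for HR and SBP.
#' @param sbp_baseline,sbp_ex_delta,dbp_baseline Baseline SBP (mmHg), the
#'   exercise SBP rise (mmHg), and baseline DBP (mmHg).
#' @param dbp_drift_amp Amplitude (mmHg) of the slow sinusoidal DBP drift.
#' @param bp_noise_sd,hr_noise_sd Beat-to-beat noise SDs (mmHg, bpm).
#' @return Tibble with one row per beat: `beat_id`, `t_s` (foot time),
#'   `phase`, `hr`, `sbp`, `dbp`.
#' @export
simulate_trajectories <- function(cfg,
                                  hr_tau_s = 60, sbp_tau_s = 120,
                                  sbp_baseline = 115, sbp_ex_delta = 40,
                                  dbp_baseline = 72, dbp_drift_amp = 3,
                                  bp_noise_sd = 2, hr_noise_sd = 1.5) {
  stopifnot(inherits(cfg, "protocol_config"))
  d <- cumsum(cfg$phase_durations_s)
  rows <- vector("list", 3L)
  t <- 0
  for (p in 1:3) {
    beats_t <- numeric(0)
    hr_n <- numeric(0); sbp_n <- numeric(0); dbp_n <- numeric(0)
    with_local_seed(phase_substream(cfg$seed, p, 0L), {
      while (t < d[p]) {
        det <- hr_sbp_deterministic(t, cfg, hr_tau_s, sbp_tau_s,
                                    sbp_baseline, sbp_ex_delta)
        dbp_det <- dbp_baseline + dbp_drift_amp * sin(2 * pi * t / 600)
        hr_i <- det$hr + stats::rnorm(1, 0, hr_noise_sd)
        hr_i <- min(max(hr_i, 30), 210)
        sbp_i <- det$sbp + stats::rnorm(1, 0, bp_noise_sd)
        dbp_i <- dbp_det + stats::rnorm(1, 0, bp_noise_sd)
        # keep pulse pressure physiological
        sbp_i <- max(sbp_i, dbp_i + 15)
        beats_t <- c(beats_t, t)
        hr_n <- c(hr_n, hr_i); sbp_n <- c(sbp_n, sbp_i); dbp_n <- c(dbp_n, dbp_i)
        t <- t + 60 / hr_i
      }
    })
    rows[[p]] <- tibble::tibble(
      t_s = beats_t, phase = PHASE_LABELS[p],
      hr = hr_n, sbp = sbp_n, dbp = dbp_n
    )
  }
  out <- dplyr::bind_rows(rows)
  out$beat_id <- seq_len(nrow(out))
  out[, c("beat_id", "t_s", "phase", "hr", "sbp", "dbp")]
}

#' Waveform and artifact parameters for the synthetic renderer
#'
#' The latent-to-waveform map is fixed and invertible on clean beats:
#' systolic pulse amplitude `A1 = k_a * (sbp - dbp)`, reflected-pulse delay
#' `dT = dt0_s - k_t * (sbp - sbp_baseline)`, reflected amplitude
#' `A2 = RI * A1` with the reflection index attenuated during exercise.
#'
#' @param fs Sampling rate, Hz.
#' @param k_a Pulse-pressure-to-amplitude gain, a.u./mmHg.
#' @param dt0_s Baseline systolic-to-diastolic peak delay, s.
#' @param k_t Delay shortening per mmHg of SBP above baseline, s/mmHg.
#' @param ri_rest,ri_exercise Reflection index at rest/recovery and during
#'   exercise (diastolic/systolic amplitude ratio).
#' @param t1_s Foot-to-systolic-peak time, s.
#' @param s1,s2 Log-normal shape widths of the systolic and diastolic pulses.
#' @param notch_amp,notch_frac,notch_width_s Dicrotic-notch component: a
#'   narrow Gaussian bump of amplitude `notch_amp * A1` centered at
#'   `t1 + notch_frac * dT`, width `notch_width_s` s. Gives the second
#'   derivative its characteristic c-d-e complex.
#' @param p_artifact Named per-beat artifact probabilities for rest,
#'   exercise, recovery.
#' @param wander_amp_range Baseline-wander amplitude range, in units of A1.
#' @param wander_freq_range Baseline-wander frequency range, Hz.
#' @param spike_amp_range Negative spike amplitude range, in units of A1.
#' @param n_spike_range Range of spike counts per corrupted beat.
#' @return A `synth_waveform_params` list.
#' @export
synth_waveform_params <- function(fs = 125, k_a = 0.02,
                                  dt0_s = 0.24, k_t = 0.0012,
                                  ri_rest = 0.45, ri_exercise = 0.15,
                                  t1_s = 0.13, s1 = 0.35, s2 = 0.25,
                                  notch_amp = 0.05, notch_frac = 0.5,
                                  notch_width_s = 0.02,
                                  p_artifact = c(rest = 0.25, exercise = 0.70, recovery = 0.17),
                                  wander_amp_range = c(1.0, 2.5),
                                  wander_freq_range = c(0.1, 0.5),
                                  spike_amp_range = c(2, 4),
                                  n_spike_range = c(2L, 5L)) {
  stopifnot(fs > 0, k_a > 0, all(PHASE_LABELS %in% names(p_artifact)))
  structure(
    list(fs = fs, k_a = k_a, dt0_s = dt0_s, k_t = k_t,
         ri_rest = ri_rest, ri_exercise = ri_exercise,
         t1_s = t1_s, s1 = s1, s2 = s2,
         notch_amp = notch_amp, notch_frac = notch_frac,
         notch_width_s = notch_width_s,
         p_artifact = p_artifact,
         wander_amp_range = wander_amp_range,
         wander_freq_range = wander_freq_range,
         spike_amp_range = spike_amp_range,
         n_spike_range = n_spike_range),
    class = "synth_waveform_params"
  )
}

# log-normal-shaped pulse, unit peak exactly at tp, zero at t <= 0
lognorm_pulse <- function(t, tp, s) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-(log(t[pos] / tp))^2 / (2 * s^2))
  out
}

render_clean_beat <- function(t_rel, a1, a2, t1, dt, s1, s2,
                              notch_amp = 0, notch_frac = 0.5,
                              notch_width_s = 0.02) {
  w <- a1 * lognorm_pulse(t_rel, t1, s1) + a2 * lognorm_pulse(t_rel, t1 + dt, s2)
  if (notch_amp > 0) {
    w <- w + notch_amp * a1 *
      exp(-((t_rel - (t1 + notch_frac * dt))^2) / (2 * notch_width_s^2))
  }
  w
}

local_maxima_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Synthesize a full recording with ground truth
#'
#' Renders every beat of the simulated trajectories at `wf$fs` as two
#' log-normal pulses on a decaying diastolic tail, corrupts a per-phase
#' Bernoulli fraction of beats with baseline wander plus negative-going
#' spikes, and emits both the recording (with step-function reference BP
#' channels) and a per-beat ground-truth table.
#'
#' @param cfg A [protocol_config()].
#' @param wf A [synth_waveform_params()].
#' @param ... Passed on to [simulate_trajectories()].
#' @return List with `recording` (a [ppg_recording()]) and `beats`, a tibble
#'   with per-beat `sbp`, `dbp`, `hr`, `foot_sample`,
#'   `systolic_peak_sample`, `diastolic_peak_sample` (0-based),
#'   `dia_is_local_max`, `reflection_index`, `artifact_flag`, and the latent
#'   `a1`, `t1_s`, `dt_s`.
#' @export
synthesize_recording <- function(cfg, wf = synth_waveform_params(), ...) {
  stopifnot(inherits(cfg, "protocol_config"), inherits(wf, "synth_waveform_params"))
  traj <- simulate_trajectories(cfg, ...)
  fs <- wf$fs
  total_s <- sum(cfg$phase_durations_s)
  n <- as.integer(round(total_s * fs))
  ppg <- numeric(n)
  sbp_ref <- numeric(n)
  dbp_ref <- numeric(n)

  sbp_baseline <- 115  # must match simulate_trajectories default unless overridden
  dots <- list(...)
  if (!is.null(dots$sbp_baseline)) sbp_baseline <- dots$sbp_baseline

  nb <- nrow(traj)
  foot_sample <- as.integer(round(traj$t_s * fs))
  end_sample <- c(foot_sample[-1], n)
  keep <- end_sample > foot_sample
  traj <- traj[keep, ]; foot_sample <- foot_sample[keep]; end_sample <- end_sample[keep]
  nb <- nrow(traj)

  gt <- tibble::tibble(
    beat_id = seq_len(nb), phase = traj$phase,
    hr = traj$hr, sbp = traj$sbp, dbp = traj$dbp,
    foot_sample = foot_sample, end_sample = end_sample,
    systolic_peak_sample = NA_integer_, diastolic_peak_sample = NA_integer_,
    dia_is_local_max = FALSE,
    reflection_index = ifelse(traj$phase == "exercise", wf$ri_exercise, wf$ri_rest),
    artifact_flag = FALSE,
    a1 = NA_real_, t1_s = wf$t1_s, dt_s = NA_real_
  )

  dt_all <- wf$dt0_s - wf$k_t * (traj$sbp - sbp_baseline)
  if (any(dt_all < 0.05)) {
    stop(sprintf(
      "parameter error: systolic-to-diastolic delay mapped below 0.05 s (min %.4f s); degenerate morphology",
      min(dt_all)), call. = FALSE)
  }
  gt$dt_s <- dt_all
  gt$a1 <- wf$k_a * (traj$sbp - traj$dbp)

  # render clean beats and record waveform-level ground truth
  for (i in seq_len(nb)) {
    idx <- (foot_sample[i] + 1L):end_sample[i]   # 1-based R indices
    t_rel <- (seq_along(idx) - 1) / fs
    a1 <- gt$a1[i]; a2 <- gt$reflection_index[i] * a1
    w <- render_clean_beat(t_rel, a1, a2, wf$t1_s, gt$dt_s[i], wf$s1, wf$s2,
                           wf$notch_amp, wf$notch_frac, wf$notch_width_s)
    ppg[idx] <- w
    sbp_ref[idx] <- traj$sbp[i]
    dbp_ref[idx] <- traj$dbp[i]
    gt$systolic_peak_sample[i] <- foot_sample[i] + which.max(w) - 1L
    # diastolic peak: local max of the rendered beat in the reflection window
    lo <- ceiling((wf$t1_s + 0.4 * gt$dt_s[i]) * fs)
    hi <- floor((wf$t1_s + 1.8 * gt$dt_s[i]) * fs)
    hi <- min(hi, length(w) - 2L)
    cand <- local_maxima_idx(w)
    cand <- cand[cand - 1L >= lo & cand - 1L <= hi & cand - 1L > (gt$systolic_peak_sample[i] - foot_sample[i])]
    if (length(cand) > 0) {
      best <- cand[which.max(w[cand])]
      gt$diastolic_peak_sample[i] <- foot_sample[i] + best - 1L
      gt$dia_is_local_max[i] <- TRUE
    } else {
      gt$diastolic_peak_sample[i] <- foot_sample[i] + as.integer(round((wf$t1_s + gt$dt_s[i]) * fs))
      gt$dia_is_local_max[i] <- FALSE
    }
  }

  # artifact corruption, per-phase sub-streams
  for (p in 1:3) {
    rows_p <- which(gt$phase == PHASE_LABELS[p])
    if (length(rows_p) == 0) next
    p_art <- wf$p_artifact[[PHASE_LABELS[p]]]
    with_local_seed(phase_substream(cfg$seed, p, 1L), {
      flags <- stats::runif(length(rows_p)) < p_art
      for (j in seq_along(rows_p)) {
        if (!flags[j]) next
        i <- rows_p[j]
        idx <- (foot_sample[i] + 1L):end_sample[i]
        t_rel <- (seq_along(idx) - 1) / fs
        a1 <- gt$a1[i]
        amp_w <- a1 * stats::runif(1, wf$wander_amp_range[1], wf$wander_amp_range[2])
        f_w <- stats::runif(1, wf$wander_freq_range[1], wf$wander_freq_range[2])
        phi <- stats::runif(1, 0, 2 * pi)
        art <- amp_w * sin(2 * pi * f_w * t_rel + phi)
        n_sp <- sample(seq(wf$n_spike_range[1], wf$n_spike_range[2]), 1)
        for (s in seq_len(n_sp)) {
          c_sp <- stats::runif(1, 0.05, 0.95) * length(idx)
          a_sp <- a1 * stats::runif(1, wf$spike_amp_range[1], wf$spike_amp_range[2])
          art <- art - a_sp * exp(-((seq_along(idx) - c_sp)^2) / (2 * 1.5^2))
        }
        ppg[idx] <- ppg[idx] + art
        gt$artifact_flag[i] <- TRUE
      }
    })
  }

  phases <- tibble::tibble(
    label = PHASE_LABELS,
    start_sample = as.integer(round(c(0, cumsum(cfg$phase_durations_s)[1:2]) * fs)),
    end_sample = as.integer(round(cumsum(cfg$phase_durations_s) * fs))
  )
  # pad the lead-in of the reference channels
  first_idx <- foot_sample[1] + 1L
  if (first_idx > 1) {
    sbp_ref[1:(first_idx - 1)] <- traj$sbp[1]
    dbp_ref[1:(first_idx - 1)] <- traj$dbp[1]
  }
  rec <- ppg_recording(
    tibble::tibble(
      time_s = (seq_len(n) - 1) / fs,
      ppg = ppg, sbp_ref = sbp_ref, dbp_ref = dbp_ref
    ),
    fs, phases,
    subject_meta = list(age = cfg$age, resting_hr = cfg$resting_hr,
                        intensity = cfg$intensity, seed = cfg$seed,
                        synthetic = TRUE)
  )
  list(recording = rec, beats = gt)
}
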