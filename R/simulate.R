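#' Configuration for the synthetic n-back cohort generator
#'
#' Defaults emulate the structure of a simultaneous EEG-fNIRS n-back
#' study: 26 participants, 3 sessions each, 3 series per session where a
#' series holds one 0-back, one 2-back and one 3-back task in random
#' order (26 x 3 x 9 = 702 tasks). Each task cycle is 2 s instruction,
#' 40 s task, 1 s stop and 20 s rest. EEG is sampled at 200 Hz over a
#' 30-channel montage, fNIRS at 10 Hz over 36 channels.
#'
#' Workload effects are planted generatively:
#' * posterior alpha suppression: the 10 Hz oscillator amplitude at
#'   POz/O1/O2 is scaled by `1 - alpha_suppression * load_rank`
#'   (load_rank 0/1/2 for 0-/2-/3-back);
#' * frontal coupling: the alpha oscillators of Fp1/Fp2/AFz/F1/F2 are
#'   convexly mixed with one shared narrowband source, weight
#'   `w = frontal_coupling_gain * load_rank` (pairwise correlation
#'   `w^2`, alpha power unchanged — the effect is pure coupling);
#' * right-frontal hemodynamics: the task-evoked response amplitude at
#'   AF8 grows by `hbr_effect * load_rank` (visible in HbO and, scaled
#'   by `-kappa`, in HbR).
#'
#' Participant-level response heterogeneity (`subject_sd`) and
#' task-block amplitude jitter (`task_jitter_sd`, shared across channels
#' within a block) are log-normal; they are what keeps single-trial
#' classification away from ceiling, as in real cohorts.
#'
#' @param n_participants,n_sessions,n_sets_per_session cohort layout
#'   (series per session; each series holds one task of each label).
#' @param eeg_rate,fnirs_rate sampling rates in Hz.
#' @param eeg_montage,fnirs_montage data.frames (`label`, `x`, `y`).
#' @param block_layout named durations in seconds:
#'   `instruction`, `task`, `stop`, `rest`.
#' @param alpha_suppression fractional posterior alpha amplitude decrease
#'   per load level.
#' @param frontal_coupling_gain shared-source mixing weight per load level.
#' @param hbr_effect hemodynamic amplitude increment per load level at the
#'   planted fNIRS channel.
#' @param hrf_peak_delay hemodynamic response peak delay in seconds.
#' @param noise_sd EEG 1/f background standard deviation (uV).
#' @param fnirs_noise_sd fNIRS measurement noise standard deviation.
#' @param drift_sd fNIRS slow drift amplitude scale.
#' @param kappa HbR = -kappa * HbO coupling constant.
#' @param osc_amp oscillator amplitudes (uV) at 2, 6, 10 Hz.
#' @param subject_sd,task_jitter_sd log-scale standard deviations of the
#'   participant effect multipliers and per-task amplitude jitter.
#' @param seed integer master seed; per-participant and per-session
#'   streams are derived from it by fixed offsets, so any subset of the
#'   cohort is reproducible in isolation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 26,
                       n_sessions = 3,
                       n_sets_per_session = 3,
                       eeg_rate = 200,
                       fnirs_rate = 10,
                       eeg_montage = default_montage("eeg30"),
                       fnirs_montage = default_montage("fnirs36"),
                       block_layout = c(instruction = 2, task = 40,
                                        stop = 1, rest = 20),
                       alpha_suppression = 0.2,
                       frontal_coupling_gain = 0.25,
                       hbr_effect = 0.5,
                       hrf_peak_delay = 6,
                       noise_sd = 1,
                       fnirs_noise_sd = 0.3,
                       drift_sd = 0.3,
                       kappa = 0.5,
                       osc_amp = c(delta = 1.0, theta = 0.8, alpha = 1.2),
                       subject_sd = 0.3,
                       task_jitter_sd = 0.3,
                       seed = 1) {
  counts <- c(n_participants = n_participants, n_sessions = n_sessions,
              n_sets_per_session = n_sets_per_session)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("cohort counts must be positive integers")
  if (eeg_rate <= 0 || fnirs_rate <= 0)
    stop("sampling rates must be positive")
  if (length(block_layout) != 4L || any(block_layout <= 0))
    stop("block_layout must hold four positive durations")
  if (is.null(names(block_layout)))
    names(block_layout) <- c("instruction", "task", "stop", "rest")
  effects <- c(alpha_suppression, frontal_coupling_gain, hbr_effect,
               noise_sd, fnirs_noise_sd, drift_sd, kappa)
  if (any(effects < 0)) stop("effect and noise parameters must be >= 0")
  if (hrf_peak_delay <= 0) stop("hrf_peak_delay must be positive")
  check_montage(eeg_montage)
  check_montage(fnirs_montage)

  truth <- list(
    posterior_channels = intersect(c("POz", "O1", "O2"), eeg_montage$label),
    frontal_source_channels = intersect(c("Fp1", "Fp2", "AFz", "F1", "F2"),
                                        eeg_montage$label),
    fnirs_channels = intersect("AF8", fnirs_montage$label),
    alpha_suppression = alpha_suppression,
    frontal_coupling_gain = frontal_coupling_gain,
    hbr_effect = hbr_effect
  )
  fr <- truth$frontal_source_channels
  truth$frontal_pairs <- if (length(fr) >= 2)
    t(utils::combn(fr, 2)) else matrix(character(), 0, 2)
  if (!all(truth$posterior_channels %in% eeg_montage$label))
    stop("planted posterior channels missing from montage")

  structure(list(
    n_participants = n_participants, n_sessions = n_sessions,
    n_sets_per_session = n_sets_per_session,
    eeg_rate = eeg_rate, fnirs_rate = fnirs_rate,
    eeg_montage = eeg_montage, fnirs_montage = fnirs_montage,
    block_layout = block_layout,
    alpha_suppression = alpha_suppression,
    frontal_coupling_gain = frontal_coupling_gain,
    hbr_effect = hbr_effect, hrf_peak_delay = hrf_peak_delay,
    noise_sd = noise_sd, fnirs_noise_sd = fnirs_noise_sd,
    drift_sd = drift_sd, kappa = kappa, osc_amp = osc_amp,
    subject_sd = subject_sd, task_jitter_sd = task_jitter_sd,
    seed = as.integer(seed), truth = truth
  ), class = "sim_config")
}

task_labels <- function() c("0-back", "2-back", "3-back")

load_rank <- function(label) {
  match(as.character(label), task_labels()) - 1L
}

cycle_duration <- function(config) sum(config$block_layout)

session_duration <- function(config) {
  3 * config$n_sets_per_session * cycle_duration(config)
}

participant_seed <- function(config, participant) {
  config$seed + 7919L * as.integer(participant)
}

session_seed <- function(config, participant, session) {
  participant_seed(config, participant) + 104729L * as.integer(session)
}

participant_params <- function(config, participant) {
  set.seed(participant_seed(config, participant))
  list(alpha_base = exp(rnorm(1, 0, config$subject_sd)),
       eeg_mult = exp(rnorm(1, 0, config$subject_sd)),
       fnirs_mult = exp(rnorm(1, 0, config$subject_sd)))
}

# Task rows for one session; consumes the current RNG stream (one
# permutation draw per series).
draw_session_events <- function(config, participant, session) {
  bl <- config$block_layout
  cyc <- cycle_duration(config)
  rows <- vector("list", config$n_sets_per_session)
  for (series in seq_len(config$n_sets_per_session)) {
    labs <- sample(task_labels())
    k <- (series - 1L) * 3L + seq_len(3L) - 1L
    rows[[series]] <- data.frame(
      participant = participant, session = session, series = series,
      label = labs,
      onset = k * cyc + unname(bl["instruction"]),
      duration = unname(bl["task"]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Event table for a simulated cohort
#'
#' Generates task onset rows for every participant and session without
#' synthesising any signals; identical to the events embedded in
#' [simulate_session()] output for the same configuration.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `participant`, `session`, `series`,
#'   `label`, `onset` (s, session-relative task onset), `duration` (s).
#' @examples
#' ev <- simulate_events(sim_config())
#' nrow(ev)  # 702 under the default cohort
#' @export
simulate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- list()
  for (p in seq_len(config$n_participants)) {
    for (s in seq_len(config$n_sessions)) {
      set.seed(session_seed(config, p, s))
      out[[length(out) + 1L]] <- draw_session_events(config, p, s)
    }
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

#' Canonical double-gamma hemodynamic response function
#'
#' Response of cortical blood oxygenation to a brief neural event: a
#' positive gamma lobe (shape 6) minus a later undershoot (shape 16,
#' ratio 1/6), time-scaled so the positive peak lands at `peak_delay`
#' seconds, and amplitude-scaled to unit peak.
#'
#' @param t time in seconds (vector, >= 0).
#' @param peak_delay peak latency in seconds (> 0), canonically 6 s.
#' @return dimensionless amplitude, 0 at `t = 0`, peaking at 1.
#' @examples
#' hrf(c(0, 6, 20))
#' @export
hrf <- function(t, peak_delay = 6) {
  if (peak_delay <= 0) stop("peak_delay must be positive")
  if (any(t < 0)) stop("hrf is defined for t >= 0")
  base <- function(u) dgamma(u, shape = 6, rate = 1) -
    dgamma(u, shape = 16, rate = 1) / 6
  mode0 <- stats::optimize(base, c(1, 10), maximum = TRUE)$maximum
  s <- mode0 / peak_delay
  h <- base(t * s)
  h / base(mode0)
}

pink_noise <- function(n, rate, sd_target, floor_hz = 0.5) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * (rate / n)
  shape <- 1 / sqrt(pmax(f, floor_hz))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * (sd_target / stats::sd(x))
}

# Slow stochastic baseline drift (unit sd): 1/f-weighted noise band
# limited to 0.003-0.05 Hz, emulating Mayer waves, respiration and
# instrument drift. Stochastic (coherence time well under the
# inter-task spacing) so it behaves as slow noise rather than a
# session-locked waveform.
slow_drift <- function(n, rate) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * (rate / n)
  shape <- ifelse(f >= 0.003 & f <= 0.05, 1 / sqrt(pmax(f, 0.005)), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Stochastic narrowband oscillation: white noise spectrally shaped by a
# Gaussian bump at f0 (width sigma Hz), unit variance. Unlike a pure
# sinusoid this has a finite coherence time (~1/sigma), so two
# independent draws are not phase-locked — the property that keeps the
# no-coupling PLV/MI baselines honest.
narrowband_noise <- function(n, rate, f0, sigma) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * (rate / n)
  shape <- exp(-((f - f0)^2) / (2 * sigma^2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' Simulate one EEG-fNIRS session
#'
#' Synthesises the EEG (1/f background plus 2/6/10 Hz oscillators with
#' planted load effects), HbO (boxcar convolved with the double-gamma
#' HRF, plus slow drift and noise) and HbR (`-kappa * HbO` plus
#' independent noise) recordings for one participant/session, together
#' with the session event table.
#'
#' @param config a [sim_config()].
#' @param participant,session 1-based indices within the cohort.
#' @return list with elements `eeg`, `hbo`, `hbr` ([recording()]s),
#'   `events` (data.frame) and `truth` (planted-effect bookkeeping).
#' @export
simulate_session <- function(config, participant, session) {
  stopifnot(inherits(config, "sim_config"))
  if (participant < 1 || participant > config$n_participants)
    stop("participant index out of range")
  if (session < 1 || session > config$n_sessions)
    stop("session index out of range")
  pp <- participant_params(config, participant)
  set.seed(session_seed(config, participant, session))
  ev <- draw_session_events(config, participant, session)

  dur <- session_duration(config)
  rate <- config$eeg_rate
  n <- round(dur * rate)
  chans <- config$eeg_montage$label
  C <- length(chans)
  eeg <- matrix(0, C, n, dimnames = list(chans, NULL))

  for (ci in seq_len(C))
    eeg[ci, ] <- pink_noise(n, rate, config$noise_sd)

  posterior <- config$truth$posterior_channels
  frontal <- config$truth$frontal_source_channels
  osc_freq <- c(delta = 2, theta = 6, alpha = 10)
  osc_sigma <- c(delta = 0.75, theta = 0.75, alpha = 1)
  amp0 <- config$osc_amp

  # stochastic narrowband oscillators + planted effects, one amplitude
  # jitter draw per task block (shared across channels: block-level
  # arousal state). Frontal coupling is a *convex* mix of each
  # channel's private alpha process with a shared source (pairwise
  # correlation w^2), so alpha power at the frontal channels is
  # invariant to load and the planted effect is pure coupling.
  for (ti in seq_len(nrow(ev))) {
    load <- load_rank(ev$label[ti])
    i0 <- round(ev$onset[ti] * rate) + 1L
    i1 <- min(n, i0 + round(ev$duration[ti] * rate) - 1L)
    idx <- i0:i1
    jit <- exp(stats::rnorm(1, 0, config$task_jitter_sd))
    w <- min(1, config$frontal_coupling_gain * pp$eeg_mult * load)
    src <- narrowband_noise(length(idx), rate, 10, 1)  # shared alpha source
    for (ci in seq_len(C)) {
      ch <- chans[ci]
      for (oi in seq_len(3)) {
        osc <- narrowband_noise(length(idx), rate, osc_freq[oi],
                                osc_sigma[oi])
        a <- amp0[oi]
        if (names(osc_freq)[oi] == "alpha") {
          a <- a * pp$alpha_base * jit
          if (ch %in% posterior) {
            supp <- config$alpha_suppression * pp$eeg_mult * load
            a <- a * max(0.1, 1 - supp)
          }
          if (w > 0 && ch %in% frontal)
            osc <- sqrt(1 - w^2) * osc + w * src
        }
        # rms a/sqrt(2): band power matches a sinusoid of amplitude a
        eeg[ci, idx] <- eeg[ci, idx] + (a / sqrt(2)) * osc
      }
    }
  }

  # fNIRS: task boxcar convolved with the HRF, per-channel drift + noise
  frate <- config$fnirs_rate
  nf <- round(dur * frate)
  fch <- config$fnirs_montage$label
  Cf <- length(fch)
  planted_f <- config$truth$fnirs_channels
  kern <- hrf(seq(0, 32, by = 1 / frate), config$hrf_peak_delay)
  kern <- kern / sum(kern[kern > 0])

  amps <- matrix(1, Cf, nrow(ev), dimnames = list(fch, NULL))
  for (ti in seq_len(nrow(ev))) {
    load <- load_rank(ev$label[ti])
    jit <- exp(stats::rnorm(1, 0, config$task_jitter_sd))
    amps[, ti] <- jit
    if (length(planted_f))
      amps[planted_f, ti] <- jit *
        (1 + config$hbr_effect * pp$fnirs_mult * load)
  }

  hbo <- matrix(0, Cf, nf, dimnames = list(fch, NULL))
  for (ci in seq_len(Cf)) {
    box <- numeric(nf)
    for (ti in seq_len(nrow(ev))) {
      i0 <- round(ev$onset[ti] * frate) + 1L
      i1 <- min(nf, i0 + round(ev$duration[ti] * frate) - 1L)
      box[i0:i1] <- amps[ci, ti]
    }
    resp <- stats::convolve(box, rev(kern), type = "open")[seq_len(nf)]
    drift <- config$drift_sd * slow_drift(nf, frate)
    hbo[ci, ] <- resp + drift + stats::rnorm(nf, 0, config$fnirs_noise_sd)
  }
  hbr <- -config$kappa * hbo +
    matrix(stats::rnorm(Cf * nf, 0, config$kappa * config$fnirs_noise_sd),
           Cf, nf)
  dimnames(hbr) <- dimnames(hbo)

  list(
    eeg = recording(eeg, rate, "eeg", chans, config$eeg_montage),
    hbo = recording(hbo, frate, "hbo", fch, config$fnirs_montage),
    hbr = recording(hbr, frate, "hbr", fch, config$fnirs_montage),
    events = ev,
    truth = config$truth
  )
}

#' Simulate a (sub)cohort of sessions
#'
#' Materialises the requested participant/session grid in memory. The
#' full default cohort (26 x 3 sessions of ~9.5 min EEG at 200 Hz) is
#' several gigabytes; analyses at that scale should iterate over
#' [simulate_session()] instead.
#'
#' @param config a [sim_config()].
#' @param participants,sessions index vectors (default: the whole grid).
#' @return a `sim_dataset`: list with `sessions` (list of
#'   [simulate_session()] results), combined `events`, `config`, `truth`.
#' @export
simulate_dataset <- function(config, participants = seq_len(config$n_participants),
                             sessions = seq_len(config$n_sessions)) {
  stopifnot(inherits(config, "sim_config"))
  out <- list()
  for (p in participants)
    for (s in sessions)
      out[[sprintf("p%02d_s%d", p, s)]] <- simulate_session(config, p, s)
  ev <- do.call(rbind, lapply(out, `[[`, "events"))
  rownames(ev) <- NULL
  structure(list(sessions = out, events = ev, config = config,
                 truth = config$truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d sessions, %d tasks\n",
              length(x$sessions), nrow(x$events)))
  invisible(x)
}
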