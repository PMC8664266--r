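#' Default 16-channel 10/20 montage
#'
#' Frontal, central, temporal and posterior-temporal sites matching a
#' 16-electrode infant/adult acquisition cap; includes the six channels of
#' the default inter-brain analysis grid (C3, C4, T7, T8, P7, P8).
#' @export
default_layout <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "C3", "Cz", "C4", "T7", "T8", "P3", "P4", "P7", "P8")
}

#' Simulation configuration for synthetic dyads
#'
#' Describes the stated world of the synthetic generator: a two-person
#' recording setup (16-channel 10/20 montage by default), per-condition
#' coupling between named adult and infant channels, theta-band oscillators
#' riding on 1/f background noise, artifact rates, and a behavioral
#' alternating-renewal process.
#'
#' Phase coupling: for a coupled pair with strength `kappa` in \[0, 1\], the
#' infant channel's theta phase tracks the adult channel's phase at a fixed
#' lag (`phase_lag`, default pi/4 — a quarter cycle, where lag-sensitive
#' connectivity metrics are most sensitive) plus a stationary Gaussian
#' jitter with standard deviation `pi * (1 - kappa)`: `kappa = 0` is
#' indistinguishable from independent phases, `kappa = 1` is a perfect
#' constant-lag lock.
#'
#' @param n_dyads number of dyads
#' @param sampling_rate Hz (default 250)
#' @param duration seconds per condition (default 180)
#' @param channel_layout ordered 10/20 labels, shared by both subjects
#' @param conditions condition labels (default `c("blank", "BO")`)
#' @param coupling data.frame with columns `condition`, `adult`, `infant`,
#'   `kappa` — coupling strength per (condition, adult channel, infant
#'   channel); pairs absent from the table are uncoupled
#' @param phase_lag radians, must not be 0 or pi modulo pi (default pi/4)
#' @param theta_freq oscillator frequency in Hz, within \[4, 7\] (default 5)
#' @param noise_exponent 1/f^a spectral slope of the background (default 1)
#' @param snr_db theta-to-noise power ratio in dB (default 0)
#' @param theta_amp oscillator amplitude in microvolts (default 10)
#' @param jump_rate transient square-jump artifacts per minute (default 0)
#' @param ocular_rate ocular events per minute (default 0)
#' @param behavior list of behavioral renewal parameters: `attend_prop` and
#'   `positive_prop` (named per condition or scalar), `negative_prop`,
#'   `mean_bout` seconds
#' @param engagement_sd sd of an optional per-dyad latent engagement scalar
#'   that multiplicatively scales both coupling strength and attention
#'   proportions (default 0 = behavior independent of coupling)
#' @param engagement_conditions conditions the engagement scalar acts on
#'   (default: all but the first, i.e. the non-baseline conditions, so the
#'   latent drives the dyad's condition *contrast* in both modalities)
#' @param seed master integer seed
#' @return a `SimulationConfig`
#' @export
sim_config <- function(n_dyads,
                       sampling_rate = 250,
                       duration = 180,
                       channel_layout = default_layout(),
                       conditions = c("blank", "BO"),
                       coupling = NULL,
                       phase_lag = pi / 4,
                       theta_freq = 5,
                       noise_exponent = 1,
                       snr_db = 0,
                       theta_amp = 10,
                       jump_rate = 0,
                       ocular_rate = 0,
                       behavior = list(attend_prop = 0.55,
                                       positive_prop = 0.2,
                                       negative_prop = 0.05,
                                       mean_bout = 3),
                       engagement_sd = 0,
                       engagement_conditions = conditions[-1],
                       seed = 1L) {
  stopifnot(n_dyads >= 1, duration >= 2, sampling_rate > 0)
  if (theta_freq < 4 || theta_freq > 7)
    stop("theta_freq must lie within [4, 7] Hz")
  if (abs(sin(phase_lag)) < 1e-9)
    stop("phase_lag must not be 0 or pi modulo pi (lag metrics are blind there)")
  if (is.null(coupling))
    coupling <- data.frame(condition = character(), adult = character(),
                           infant = character(), kappa = numeric())
  stopifnot(all(c("condition", "adult", "infant", "kappa") %in%
                  names(coupling)))
  if (nrow(coupling)) {
    if (any(coupling$kappa < 0 | coupling$kappa > 1))
      stop("kappa must lie in [0, 1]")
    if (!all(coupling$condition %in% conditions))
      stop("coupling table references unknown condition")
    if (!all(c(coupling$adult, coupling$infant) %in% channel_layout))
      stop("coupled channels must exist in the layout")
    if (anyDuplicated(coupling[c("condition", "infant")]))
      stop("at most one coupling per infant channel per condition")
  }
  structure(
    list(n_dyads = as.integer(n_dyads), sampling_rate = sampling_rate,
         duration = duration, channel_layout = channel_layout,
         conditions = conditions, coupling = coupling,
         phase_lag = phase_lag, theta_freq = theta_freq,
         noise_exponent = noise_exponent, snr_db = snr_db,
         theta_amp = theta_amp, jump_rate = jump_rate,
         ocular_rate = ocular_rate, behavior = behavior,
         engagement_sd = engagement_sd,
         engagement_conditions = engagement_conditions,
         seed = as.integer(seed)),
    class = "SimulationConfig")
}

# 1/f^a noise via spectral shaping of white Gaussian noise, unit RMS.
pink_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                      # two-sided frequency index
  W <- W * f^(-exponent / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Stationary Gaussian AR(1), marginal sd `sd`, correlation time tau seconds.
ar1_process <- function(n, sd, tau, fs) {
  if (sd <= 0) return(numeric(n))
  rho <- exp(-1 / (tau * fs))
  x1 <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
  c(x1, stats::filter(innov, rho, method = "recursive", init = x1))
}

# Phase trajectory of one free-running theta oscillator: linear ramp plus a
# random initial phase plus slow AR(1) phase wander (sd ~ pi: successive
# epochs carry effectively fresh phases).
free_phase <- function(n, freq, fs) {
  2 * pi * freq * (seq_len(n) - 1) / fs +
    stats::runif(1, 0, 2 * pi) +
    ar1_process(n, sd = pi, tau = 0.75, fs = fs)
}

dyad_engagement <- function(config, dyad_index, condition) {
  if (config$engagement_sd <= 0 ||
      !condition %in% config$engagement_conditions) return(0)
  with_seed(derive_seed(config$seed, "engagement", dyad_index),
            stats::rnorm(1, 0, config$engagement_sd))
}

#' Simulate one dyad's paired recordings for one condition
#'
#' Every channel is `A * cos(phase(t))` plus 1/f background noise at the
#' configured signal-to-noise ratio. Coupled infant channels copy the
#' partner adult channel's phase at the configured lag plus a Gaussian
#' jitter of sd `pi * (1 - kappa)` (see [sim_config()]); all other channels
#' run independent oscillators. Output is deterministic given
#' `(seed, dyad_index, condition)`, with one independent random stream per
#' (dyad, condition, channel, purpose).
#'
#' @param config a [sim_config()]
#' @param dyad_index 1-based dyad index, `<= n_dyads`
#' @param condition condition label from `config$conditions`
#' @return list with elements `infant` and `adult`, both `Recording`s
#' @export
simulate_dyad <- function(config, dyad_index, condition) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!condition %in% config$conditions)
    stop("invalid condition label: ", condition)
  if (dyad_index < 1 || dyad_index > config$n_dyads)
    stop("dyad_index out of range")
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  chans <- config$channel_layout
  A <- config$theta_amp
  noise_rms <- A / sqrt(2) * 10^(-config$snr_db / 20)
  g <- dyad_engagement(config, dyad_index, condition)

  chan_sig <- function(role, ch, phase) {
    noise <- with_seed(derive_seed(config$seed, dyad_index, condition,
                                   role, ch, "noise"),
                       pink_noise(n, config$noise_exponent))
    A * cos(phase) + noise_rms * noise
  }
  adult_phase <- sapply(chans, function(ch)
    with_seed(derive_seed(config$seed, dyad_index, condition, "adult",
                          ch, "phase"),
              free_phase(n, config$theta_freq, fs)))
  tab <- config$coupling[config$coupling$condition == condition, ,
                         drop = FALSE]
  infant_phase <- sapply(chans, function(ch) {
    row <- tab[tab$infant == ch, , drop = FALSE]
    if (nrow(row) == 1 && row$kappa > 0) {
      kappa <- min(1, max(0, row$kappa * (1 + g)))
      sig_eps <- pi * (1 - kappa)
      eps <- with_seed(derive_seed(config$seed, dyad_index, condition,
                                   "infant", ch, "jitter"),
                       ar1_process(n, sd = sig_eps, tau = 0.25, fs = fs))
      adult_phase[, row$adult] + config$phase_lag + eps
    } else {
      with_seed(derive_seed(config$seed, dyad_index, condition, "infant",
                            ch, "phase"),
                free_phase(n, config$theta_freq, fs))
    }
  })
  adult_sig <- t(sapply(chans, function(ch)
    chan_sig("adult", ch, adult_phase[, ch])))
  infant_sig <- t(sapply(chans, function(ch)
    chan_sig("infant", ch, infant_phase[, ch])))
  dyad_id <- sprintf("dyad%03d", dyad_index)
  list(
    infant = new_recording(infant_sig, chans, fs, dyad_id, "infant",
                           condition),
    adult = new_recording(adult_sig, chans, fs, dyad_id, "adult", condition))
}

#' Inject transient-jump and ocular artifacts into a recording
#'
#' Adds (i) 200-ms square jumps on single random channels with amplitude
#' five times the recording's background peak-to-peak, at `jump_rate` events
#' per minute, and (ii) ocular events: sub-4-Hz half-cosine deflections with
#' a fixed frontal-dominated spatial pattern, at `ocular_rate` per minute.
#' Ground truth (event onset times, the true ocular spatial pattern and the
#' pre-artifact signal) is attached as attribute `"artifact_truth"` for test
#' assertions. With both rates zero the recording is returned unchanged.
#'
#' @param recording a `Recording`
#' @param config a [sim_config()] supplying the rates
#' @param seed integer seed for artifact placement
#' @return the contaminated `Recording`
#' @export
inject_artifacts <- function(recording, config, seed = config$seed) {
  stopifnot(config$jump_rate >= 0, config$ocular_rate >= 0)
  if (config$jump_rate == 0 && config$ocular_rate == 0) return(recording)
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  dur_min <- n / fs / 60
  clean <- recording$signal
  sig <- clean
  bg_p2p <- max(apply(clean, 1, function(x) max(x) - min(x)))
  truth <- list(jump_times = numeric(), ocular_times = numeric(),
                ocular_pattern = NULL, clean = clean)

  n_jump <- round(config$jump_rate * dur_min)
  if (n_jump > 0) {
    w <- round(0.2 * fs)
    truth$jump_times <- with_seed(derive_seed(seed, recording$dyad_id,
                                              recording$condition,
                                              recording$role, "jumps"), {
      starts <- sort(sample.int(n - w, n_jump))
      chs <- sample.int(nrow(sig), n_jump, replace = TRUE)
      for (j in seq_len(n_jump))
        sig[chs[j], starts[j] + seq_len(w) - 1] <-
          sig[chs[j], starts[j] + seq_len(w) - 1] + 5 * bg_p2p
      starts / fs
    })
  }

  n_oc <- round(config$ocular_rate * dur_min)
  if (n_oc > 0) {
    chans <- recording$channels
    pat <- ifelse(chans %in% c("Fp1", "Fp2"), 1,
                  ifelse(grepl("^F", chans), 0.6, 0.08))
    pat <- pat / sqrt(sum(pat^2))
    w <- round(0.5 * fs)                        # 0.5-s blink, ~1 Hz content
    wave <- sin(pi * seq_len(w) / w)^2          # smooth unipolar deflection
    truth$ocular_times <- with_seed(derive_seed(seed, recording$dyad_id,
                                                recording$condition,
                                                recording$role, "ocular"), {
      starts <- sort(sample.int(n - w, n_oc))
      amp <- 4 * bg_p2p
      for (j in seq_len(n_oc))
        sig[, starts[j] + seq_len(w) - 1] <-
          sig[, starts[j] + seq_len(w) - 1] + amp * outer(pat, wave)
      starts / fs
    })
    truth$ocular_pattern <- pat
  }
  out <- recording
  out$signal <- sig
  attr(out, "artifact_truth") <- truth
  out
}

# ---- behavior simulation ------------------------------------------------

cond_param <- function(p, condition) {
  if (length(p) > 1 && !is.null(names(p)) && condition %in% names(p))
    unname(p[condition]) else unname(p[1])
}

# Alternating renewal tiling of [0, duration]: "on" bouts labelled from
# on_codes, "off" bouts from off_codes, exponential bout lengths with means
# chosen so the long-run "on" proportion equals p_on.
renewal_log <- function(duration, p_on, mean_bout, on_codes, off_codes,
                        on_weights = NULL, off_weights = NULL) {
  mu_on <- max(2 * mean_bout * p_on, 0.1)
  mu_off <- max(2 * mean_bout * (1 - p_on), 0.1)
  t <- 0
  state_on <- stats::runif(1) < p_on
  code <- character(); onset <- numeric(); offset <- numeric()
  while (t < duration) {
    len <- stats::rexp(1, 1 / if (state_on) mu_on else mu_off)
    len <- max(len, 0.2)
    end <- min(t + len, duration)
    pool <- if (state_on) on_codes else off_codes
    wts <- if (state_on) on_weights else off_weights
    code <- c(code, if (length(pool) == 1) pool
              else sample(pool, 1, prob = wts))
    onset <- c(onset, t); offset <- c(offset, end)
    t <- end
    state_on <- !state_on
  }
  data.frame(code = code, onset = onset, offset = offset)
}

#' Simulate microcoded gaze and affect event logs
#'
#' Gaze and affect channels are alternating-renewal interval processes over
#' the field's standard infant code inventories, tiling the whole session
#' with non-overlapping intervals. Mean bout lengths are chosen so the
#' long-run attention (social gaze + joint attention) and positive-affect
#' proportions match the condition's configured targets, optionally scaled
#' by the dyad's latent engagement (see [sim_config()]).
#'
#' @param config a [sim_config()]
#' @param condition condition label
#' @param seed integer seed
#' @param dyad_index 1-based dyad index (engagement scaling; default 1)
#' @return list with `gaze` and `affect` [event_log()]s
#' @export
simulate_behavior <- function(config, condition, seed = config$seed,
                              dyad_index = 1) {
  stopifnot(config$duration > 0)
  if (!condition %in% config$conditions)
    stop("invalid condition label: ", condition)
  b <- config$behavior
  g <- dyad_engagement(config, dyad_index, condition)
  p_att <- min(0.98, max(0.02, cond_param(b$attend_prop, condition) * (1 + g)))
  p_pos <- min(0.98, max(0.02, cond_param(b$positive_prop, condition)))
  p_neg <- cond_param(if (is.null(b$negative_prop)) 0.05 else b$negative_prop,
                      condition)
  mb <- if (is.null(b$mean_bout)) 3 else b$mean_bout
  gaze_df <- with_seed(derive_seed(seed, dyad_index, condition, "gaze"),
    renewal_log(config$duration, p_att, mb,
                on_codes = c("social gaze", "joint attention"),
                off_codes = c("gaze to object", "gaze aversion",
                              "gaze to environment"),
                on_weights = c(0.8, 0.2), off_weights = c(0.5, 0.25, 0.25)))
  aff_df <- with_seed(derive_seed(seed, dyad_index, condition, "affect"),
    renewal_log(config$duration, p_pos, mb,
                on_codes = "positive",
                off_codes = c("neutral", "negative"),
                off_weights = c(max(1 - p_pos - p_neg, 0.01), p_neg + 1e-12)))
  list(gaze = event_log(gaze_df, "gaze", config$duration),
       affect = event_log(aff_df, "affect", config$duration))
}
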