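# Shared fixture builders. All synthetic; sampling rates are chosen so the
# 1-s / 0.5-s epoch grid falls on whole samples.

# MatchedDyadEpochs built directly from per-epoch signal matrices
# (epochs x samples), single channel per member.
mk_matched <- function(x, y, fs, adult_ch = "C4", infant_ch = "P8") {
  E <- nrow(x)
  structure(list(
    adult_data = array(x, c(E, 1, ncol(x))),
    infant_data = array(y, c(E, 1, ncol(y))),
    onsets = seq(0, by = 0.5, length.out = E), n_matched = E,
    adult_channels = adult_ch, infant_channels = infant_ch,
    sampling_rate = fs, epoch_length = 1, dyad_id = "dyad001",
    condition = "A", excluded = FALSE),
    class = "MatchedDyadEpochs")
}

# Epoch matrices of multi-tone signals covering every theta bin, with a
# fixed per-frequency phase offset `lag` of y behind x and random epoch
# start phases.
tone_epochs <- function(E, fs, freqs = 4:7, lag = pi / 2, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- matrix(0, E, fs); y <- matrix(0, E, fs)
  for (f in freqs) {
    ph <- stats::runif(E, 0, 2 * pi)
    x <- x + t(sapply(ph, function(p) cos(2 * pi * f * t + p)))
    y <- y + t(sapply(ph, function(p) cos(2 * pi * f * t + p - lag)))
  }
  list(x = x, y = y)
}

# Minimal two-channel scenario config: one coupled pair (C4 adult ->
# P8 infant), everything else uncoupled.
tiny_config <- function(kappa, seed = 1, duration = 30, fs = 100,
                        conditions = "A",
                        layout = c("C4", "P8"), ...) {
  coup <- if (kappa > 0)
    data.frame(condition = conditions[length(conditions)], adult = "C4",
               infant = "P8", kappa = kappa)
  else NULL
  sim_config(1, sampling_rate = fs, duration = duration,
             channel_layout = layout, conditions = conditions,
             coupling = coup, seed = seed, ...)
}

# wPLI at the coupled pair for one simulated dyad, no artifacts.
sim_wpli <- function(config, dyad = 1,
                     condition = config$conditions[length(config$conditions)],
                     grid = pair_grid("C4", "P8")) {
  d <- simulate_dyad(config, dyad, condition)
  m <- match_epochs(epoch_recording(d$infant), epoch_recording(d$adult))
  wpli(epoch_cross_spectra(m, grid, band_spec()))$values[1, 1]
}

# Hand-built ConnectivityMap (bypasses the spectral stage) for group tests.
mk_map <- function(dyad_id, condition, values, metric = "wPLI") {
  structure(list(dyad_id = dyad_id, condition = condition, metric = metric,
                 band = band_spec(), values = values, n_epochs_used = 100),
            class = "ConnectivityMap")
}

# dyads x conditions x pairs Gaussian array for permutation tests.
mk_group <- function(n, k = 2, p = 36, seed = 1, effect = 0) {
  set.seed(seed)
  arr <- array(stats::rnorm(n * k * p), c(n, k, p),
               dimnames = list(sprintf("dyad%03d", 1:n), LETTERS[1:k],
                               paste0("p", 1:p)))
  if (effect != 0) arr[, k, 1] <- arr[, k, 1] + effect
  arr
}

grid6x6 <- function() c("C3", "C4", "T7", "T8", "P7", "P8")
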