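#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass applied
#' forward-backward per channel, so the net filter is zero-phase with
#' squared magnitude response: passband ripple well under 1%, stopband
#' attenuation far beyond 40 dB. Edges are handled by odd reflection
#' padding; signal length is preserved. The transition bandwidth adapts to
#' the band (half the low edge, clamped to \[0.5, 2\] Hz), which sets the
#' filter order by the Hamming-window rule ~3.3 fs / transition.
#'
#' @param recording a `Recording`
#' @param low lower passband edge, Hz
#' @param high upper passband edge, Hz
#' @return the filtered `Recording`
#' @export
bandpass <- function(recording, low, high) {
  fs <- recording$sampling_rate
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band must satisfy 0 < low < high < Nyquist")
  h <- fir_bandpass(low, high, fs)
  if (ncol(recording$signal) < 3 * length(h))
    stop("recording shorter than 3x the filter length (",
         sprintf("%.1f", 3 * length(h) / fs), " s needed)")
  out <- recording
  out$signal <- t(apply(recording$signal, 1, filtfilt_fir, h = h))
  rownames(out$signal) <- recording$channels
  out
}

# Hamming-windowed sinc band-pass design, odd length, unit passband gain.
fir_bandpass <- function(low, high, fs) {
  trans <- min(max(low / 2, 0.5), 2)
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  k <- seq(-m, m)
  sinc <- function(f) {
    x <- 2 * f / fs
    ifelse(k == 0, x, sin(pi * x * k) / (pi * k))
  }
  h <- sinc(high) - sinc(low)
  w <- 0.54 + 0.46 * cos(pi * k / m)           # Hamming
  h <- h * w
  f0 <- sqrt(low * high)                       # normalize at band centre
  gain <- abs(sum(h * exp(-2i * pi * f0 / fs * k)))
  h / gain
}

# Forward-backward FIR with odd-reflection padding (filtfilt for FIR).
filtfilt_fir <- function(x, h) {
  np <- length(h)
  pad_l <- 2 * x[1] - rev(x[2:(np + 1)])
  pad_r <- 2 * x[length(x)] - rev(x[(length(x) - np):(length(x) - 1)])
  y <- c(pad_l, x, pad_r)
  y <- fft_conv_same(y, h)
  y <- rev(fft_conv_same(rev(y), h))
  y[np + seq_along(x)]
}

# "Same"-mode linear convolution with a centred odd-length kernel, via FFT.
fft_conv_same <- function(x, h) {
  n <- length(x); m <- length(h)
  L <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                     stats::fft(c(h, numeric(L - m))), inverse = TRUE)) / L
  y[(m - 1) / 2 + seq_len(n)]
}

#' Segment a recording into overlapping fixed-length epochs
#'
#' Epoch k (0-based) covers the half-open window
#' `[k * step, k * step + length)`, anchored at t = 0 of the recording;
#' defaults give 1-s epochs with 500-ms overlap.
#'
#' @param recording a `Recording`
#' @param length epoch length in seconds (default 1.0)
#' @param step epoch step in seconds (default 0.5)
#' @return an `EpochSet`: list with `data` (epochs x channels x samples
#'   array), `onsets` (seconds), `good_mask`, `epoch_length`, `epoch_step`,
#'   `sampling_rate`, `channels`, and source identity fields
#' @export
epoch_recording <- function(recording, length = 1.0, step = 0.5) {
  if (length <= 0 || step <= 0) stop("length and step must be positive")
  fs <- recording$sampling_rate
  nlen <- round(length * fs)
  nstep <- round(step * fs)
  if (abs(nlen - length * fs) > 1e-6 || abs(nstep - step * fs) > 1e-6)
    stop("epoch length and step must be whole numbers of samples at ",
         fs, " Hz")
  total <- ncol(recording$signal)
  if (total < nlen) stop("recording shorter than one epoch")
  n_ep <- (total - nlen) %/% nstep + 1
  data <- array(0, dim = c(n_ep, nrow(recording$signal), nlen))
  for (e in seq_len(n_ep))
    data[e, , ] <- recording$signal[, (e - 1) * nstep + seq_len(nlen)]
  structure(
    list(data = data, onsets = (seq_len(n_ep) - 1) * step,
         good_mask = rep(TRUE, n_ep), epoch_length = length,
         epoch_step = step, sampling_rate = fs,
         channels = recording$channels, dyad_id = recording$dyad_id,
         role = recording$role, condition = recording$condition),
    class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  cat(sprintf("<EpochSet> %s/%s/%s: %d epochs (%d good) x %d ch x %g s\n",
              x$dyad_id, x$role, x$condition, length(x$good_mask),
              sum(x$good_mask), dim(x$data)[2], x$epoch_length))
  invisible(x)
}

#' Automatic peak-to-peak epoch rejection with a subject-wise threshold
#'
#' A transparent stand-in for Bayesian-optimized peak-to-peak rejection:
#' candidate thresholds tau are taken from a 20-point log-spaced grid over
#' 40-400 microvolts; an epoch is bad when its worst channel's
#' peak-to-peak amplitude exceeds tau. tau is chosen to minimize the RMS
#' difference between the mean of the retained epochs and the channel-wise
#' median epoch (median over all epochs at each channel/sample), a robust
#' surrogate of the cross-validated objective. Reject-only: no channel
#' repair or interpolation is attempted.
#'
#' @param epochs an `EpochSet` with at least 10 epochs
#' @param grid optional threshold grid in microvolts
#' @return the `EpochSet` with `good_mask` updated and a `rejection` report
#'   (`threshold`, `fraction`, `p2p` per epoch) attached
#' @export
reject_epochs <- function(epochs, grid = exp(seq(log(40), log(400),
                                                 length.out = 20))) {
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 10) stop("need at least 10 epochs for threshold selection")
  p2p <- apply(epochs$data, 1, function(ep)
    max(apply(ep, 1, function(x) max(x) - min(x))))
  med_ep <- apply(epochs$data, c(2, 3), stats::median)
  score <- sapply(grid, function(tau) {
    keep <- p2p <= tau
    if (!any(keep)) return(Inf)
    mean_ep <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
    sqrt(mean((mean_ep - med_ep)^2))
  })
  if (all(!is.finite(score))) stop("all epochs rejected at every threshold")
  tau <- grid[which.min(score)]
  out <- epochs
  out$good_mask <- epochs$good_mask & (p2p <= tau)
  out$rejection <- list(threshold = tau,
                        fraction = mean(p2p > tau), p2p = p2p)
  out
}

#' Remove decomposition components matching a spatial template
#'
#' Decomposes the recording into as many statistically independent
#' components as channels (symmetric FastICA, deterministic seeded
#' initialization), compares each component's spatial pattern (mixing
#' column) with the supplied template by Pearson correlation, zeroes every
#' component with |r| at or above `r_threshold`, and reconstructs the
#' signal. The analog of template-based (CORRMAP-style) ocular component
#' exclusion. If the decomposition fails to converge the recording is
#' returned unmodified with a warning and `converged = FALSE` in the
#' report.
#'
#' @param recording a filtered `Recording`
#' @param template numeric spatial pattern, one value per channel
#' @param r_threshold absolute-correlation threshold (default 0.8)
#' @param seed seed for the decomposition initialization
#' @return list with `recording` (cleaned) and `report` (`removed` indices,
#'   `r` correlations per component, `converged`)
#' @export
remove_template_components <- function(recording, template,
                                       r_threshold = 0.8, seed = 1L) {
  if (length(template) != nrow(recording$signal))
    stop("template length must equal the number of channels")
  X <- recording$signal
  dec <- tryCatch(fast_ica(X, seed = seed), error = function(e) NULL)
  if (is.null(dec) || !dec$converged) {
    warning("decomposition failed to converge; recording returned unmodified")
    return(list(recording = recording,
                report = list(removed = integer(), r = numeric(),
                              converged = FALSE)))
  }
  r <- apply(dec$A, 2, function(a) stats::cor(a, template))
  removed <- which(abs(r) >= r_threshold)
  S <- dec$S
  if (length(removed)) S[removed, ] <- 0
  out <- recording
  out$signal <- dec$A %*% S + dec$mean
  rownames(out$signal) <- recording$channels
  list(recording = out,
       report = list(removed = removed, r = r, converged = TRUE))
}

# Symmetric FastICA (tanh contrast) on a channels x samples matrix.
# Returns mixing matrix A (channels x components), sources S, channel means.
fast_ica <- function(X, seed = 1L, max_iter = 200, tol = 1e-6) {
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  d <- pmax(eg$values, 1e-12)
  K <- diag(1 / sqrt(d)) %*% t(eg$vectors)     # whitening
  Z <- K %*% Xc
  p <- nrow(X)
  W <- with_seed(seed, matrix(stats::rnorm(p * p), p, p))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- tanh(W %*% Z)
    W1 <- U %*% t(Z) / ncol(Z) - diag(rowMeans(1 - U^2)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  A <- eg$vectors %*% diag(sqrt(d)) %*% t(W)   # mixing in sensor space
  list(A = A, S = W %*% Z, mean = mu, converged = converged)
}

#' Match two recordings' durations by truncation
#'
#' Both recordings are truncated (keeping the start) to the shorter of the
#' two durations — the rule used to equate a dyad's two conditions before
#' epoching.
#'
#' @param rec_a,rec_b `Recording`s
#' @return list of the two truncated `Recording`s, in input order
#' @export
match_durations <- function(rec_a, rec_b) {
  n <- min(ncol(rec_a$signal), ncol(rec_b$signal))
  trunc1 <- function(r) { r$signal <- r$signal[, seq_len(n), drop = FALSE]; r }
  list(trunc1(rec_a), trunc1(rec_b))
}

#' Intersect good epochs across the two members of a dyad
#'
#' Keeps exactly the epochs marked good in both members (same onset grid
#' required), yielding the matched tensors downstream connectivity runs on.
#'
#' @param infant,adult `EpochSet`s on identical onset grids
#' @return a `MatchedDyadEpochs`: list with `infant_data`, `adult_data`
#'   (epochs x channels x samples over the same retained indices),
#'   `onsets`, `n_matched`, channel/sampling metadata
#' @export
match_epochs <- function(infant, adult) {
  if (length(infant$onsets) != length(adult$onsets) ||
      any(abs(infant$onsets - adult$onsets) > 1e-9) ||
      infant$epoch_length != adult$epoch_length)
    stop("epoch onset grids differ between dyad members")
  keep <- which(infant$good_mask & adult$good_mask)
  structure(
    list(infant_data = infant$data[keep, , , drop = FALSE],
         adult_data = adult$data[keep, , , drop = FALSE],
         onsets = infant$onsets[keep], n_matched = length(keep),
         infant_channels = infant$channels, adult_channels = adult$channels,
         sampling_rate = infant$sampling_rate,
         epoch_length = infant$epoch_length,
         dyad_id = infant$dyad_id, condition = infant$condition,
         excluded = FALSE),
    class = "MatchedDyadEpochs")
}

#' @export
print.MatchedDyadEpochs <- function(x, ...) {
  cat(sprintf("<MatchedDyadEpochs> %s/%s: %d matched epochs%s\n",
              x$dyad_id, x$condition, x$n_matched,
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

#' Enforce a minimum matched span and an optional analysis cap
#'
#' Dyads whose matched epochs span less than `min_seconds` are flagged
#' `excluded`; when `cap_seconds` is set only epochs with onset strictly
#' below the cap are retained (analysis restricted to the first
#' `cap_seconds` of the session).
#'
#' @param matched a `MatchedDyadEpochs`
#' @param min_seconds minimum matched span in seconds (default 60)
#' @param cap_seconds optional onset cap in seconds (e.g. 90)
#' @return the updated `MatchedDyadEpochs`
#' @export
enforce_minimum <- function(matched, min_seconds = 60, cap_seconds = NULL) {
  out <- matched
  if (!is.null(cap_seconds)) {
    keep <- which(out$onsets < cap_seconds)
    out$infant_data <- out$infant_data[keep, , , drop = FALSE]
    out$adult_data <- out$adult_data[keep, , , drop = FALSE]
    out$onsets <- out$onsets[keep]
    out$n_matched <- length(keep)
  }
  span <- if (out$n_matched == 0) 0
          else max(out$onsets) + out$epoch_length - min(out$onsets)
  if (span < min_seconds) out$excluded <- TRUE
  out
}
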