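make_rec <- function(sig, fs = 120, chans = paste0("ch", seq_len(nrow(sig)))) {
  new_recording(sig, chans, fs, "dyad001", "adult", "A")
}

test_that("band-pass keeps in-band tones, kills stopband and DC", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rec <- make_rec(rbind(10 * sin(2 * pi * 5 * t),
                        10 * sin(2 * pi * 60 * t),
                        rep(100, length(t))), fs = fs)
  out <- bandpass(rec, 1, 50)
  mid <- seq(5 * fs, 15 * fs)                  # away from edges
  amp <- function(x) (max(x[mid]) - min(x[mid])) / 2
  expect_equal(amp(out$signal[1, ]), 10, tolerance = 0.01)
  expect_lt(amp(out$signal[2, ]), 0.1)
  expect_lt(max(abs(out$signal[3, mid])), 1)
  expect_error(bandpass(rec, 1, 200), "Nyquist")
  short <- make_rec(matrix(rnorm(fs), 1), fs = fs)
  expect_error(bandpass(short, 1, 50), "filter length")
})

test_that("filtering is idempotent for in-band content", {
  fs <- 250
  set.seed(1)
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  rec <- make_rec(matrix(10 * sin(2 * pi * 6 * t) + rnorm(length(t)), 1),
                  fs = fs)
  f1 <- bandpass(rec, 1, 50)
  f2 <- bandpass(f1, 1, 50)
  mid <- seq(5 * fs, 25 * fs)
  rel <- sqrt(mean((f2$signal[1, mid] - f1$signal[1, mid])^2)) /
    sqrt(mean(f1$signal[1, mid]^2))
  expect_lt(rel, 0.02)
})

test_that("epoch grid matches the overlapping-window arithmetic", {
  fs <- 250
  rec <- make_rec(matrix(rnorm(180 * fs), 1), fs = fs)
  ep <- epoch_recording(rec)
  expect_equal(length(ep$onsets), 359)
  expect_equal(ep$onsets[1:3], c(0, 0.5, 1))
  one <- epoch_recording(make_rec(matrix(rnorm(fs), 1), fs = fs))
  expect_equal(length(one$onsets), 1)
  expect_error(epoch_recording(make_rec(matrix(rnorm(2 * fs), 1), fs = fs),
                               length = 1.2003), "whole numbers")
  # a 0.9-s recording is rejected at construction (minimum 1 s)
  expect_error(new_recording(matrix(rnorm(0.9 * fs), 1, 0.9 * fs), "c1",
                             fs, "d", "adult", "A"), "1 s")
  expect_error(epoch_recording(rec, length = -1), "positive")
})

test_that("concatenating non-overlapping epoch halves reconstructs the signal", {
  fs <- 100
  sig <- matrix(rnorm(10 * fs), 1)
  ep <- epoch_recording(make_rec(sig, fs = fs))
  half <- fs / 2
  pieces <- lapply(seq_along(ep$onsets), function(e) ep$data[e, 1, 1:half])
  recon <- c(unlist(pieces), ep$data[length(ep$onsets), 1, (half + 1):fs])
  expect_identical(recon, as.vector(sig[1, seq_along(recon)]))
})

test_that("rejection: clean fixtures keep epochs, contaminated lose exactly the bad ones", {
  cfg <- tiny_config(0.5, seed = 4, duration = 60, fs = 120)
  clean <- simulate_dyad(cfg, 1, "A")$infant
  rej <- reject_epochs(epoch_recording(clean))
  expect_lt(rej$rejection$fraction, 0.05)
  cfg_j <- tiny_config(0.5, seed = 4, duration = 60, fs = 120,
                       jump_rate = 10)
  dirty <- inject_artifacts(clean, cfg_j)
  truth <- attr(dirty, "artifact_truth")
  rj <- reject_epochs(epoch_recording(dirty))
  overl <- sapply(rj$onsets, function(o)
    any(truth$jump_times < o + 1 & truth$jump_times + 0.2 > o))
  expect_true(all(!rj$good_mask[overl]))
  expect_lt(mean(!rj$good_mask[!overl]), 0.05)
  # identical epochs: nothing rejected once tau clears their p2p
  flat <- epoch_recording(make_rec(matrix(rep(sin(seq_len(120) / 5), 20),
                                          1), fs = 120))
  rf <- reject_epochs(flat)
  expect_true(all(rf$good_mask))
  expect_error(reject_epochs(epoch_recording(make_rec(matrix(rnorm(240),
                                                             1), fs = 120))),
               "at least 10")
})

test_that("template component removal cleans ocular events and is identity otherwise", {
  cfg <- sim_config(1, sampling_rate = 120, duration = 60,
                    channel_layout = default_layout(), conditions = "A",
                    ocular_rate = 8, seed = 5)
  d <- simulate_dyad(cfg, 1, "A")
  dirty <- inject_artifacts(d$infant, cfg, seed = 11)
  truth <- attr(dirty, "artifact_truth")
  filt <- bandpass(dirty, 1, 50)
  ref <- bandpass(d$infant, 1, 50)              # ground-truth neural
  res <- remove_template_components(filt, truth$ocular_pattern, seed = 2)
  expect_true(res$report$converged)
  expect_gte(length(res$report$removed), 1)
  expect_gt(max(abs(res$report$r[res$report$removed])), 0.9)
  c4 <- which(dirty$channels == "C4")
  expect_gt(stats::cor(res$recording$signal[c4, ], ref$signal[c4, ]),
            stats::cor(filt$signal[c4, ], ref$signal[c4, ]))
  # orthogonal template: nothing removed, reconstruction is exact
  tmpl <- res$report$r                          # arbitrary non-matching vec
  tmpl <- rep(c(1, -1), 8)
  res2 <- remove_template_components(ref, tmpl, seed = 2)
  expect_length(res2$report$removed, 0)
  expect_lt(max(abs(res2$recording$signal - ref$signal)) /
              max(abs(ref$signal)), 1e-6)
  expect_error(remove_template_components(ref, 1:3), "template length")
})

test_that("duration matching truncates from the start to the shorter recording", {
  fs <- 100
  a <- make_rec(matrix(rnorm(180 * fs), 1), fs = fs)
  b <- make_rec(matrix(rnorm(150 * fs), 1), fs = fs)
  m <- match_durations(a, b)
  expect_equal(recording_duration(m[[1]]), 150)
  expect_equal(recording_duration(m[[2]]), 150)
  expect_identical(m[[1]]$signal[1, ], a$signal[1, 1:(150 * fs)])
  m2 <- match_durations(a, a)
  expect_identical(m2[[1]]$signal, a$signal)
  c1 <- make_rec(matrix(rnorm(90.3 * fs), 1), fs = fs)
  c2 <- make_rec(matrix(rnorm(90.0 * fs), 1), fs = fs)
  expect_equal(recording_duration(match_durations(c1, c2)[[1]]), 90)
})

test_that("epoch matching is an intersection, commutative and monotone", {
  fs <- 100
  mk_ep <- function(mask, role) {
    r <- new_recording(matrix(rnorm(fs * (length(mask) + 1) / 2, ), 1,
                              fs * (length(mask) + 1) / 2),
                       "C4", fs, "dyad001", role, "A")
    ep <- epoch_recording(r)
    ep$good_mask <- mask
    ep
  }
  inf <- mk_ep(c(TRUE, TRUE, FALSE, FALSE), "infant")
  adu <- mk_ep(c(TRUE, FALSE, TRUE, FALSE), "adult")
  m <- match_epochs(inf, adu)
  expect_equal(m$n_matched, 1)
  expect_equal(m$onsets, 0)
  m_swap <- match_epochs(adu, inf)
  expect_equal(m_swap$n_matched, m$n_matched)
  expect_equal(m_swap$onsets, m$onsets)
  # all good -> identity; adding a good epoch never removes a retained one
  all_good <- match_epochs(mk_ep(rep(TRUE, 4), "infant"),
                           mk_ep(rep(TRUE, 4), "adult"))
  expect_equal(all_good$n_matched, 4)
  more <- match_epochs(mk_ep(c(TRUE, TRUE, TRUE, FALSE), "infant"), adu)
  expect_true(all(m$onsets %in% more$onsets))
  # disjoint masks
  none <- match_epochs(mk_ep(c(TRUE, FALSE, TRUE, FALSE), "infant"),
                       mk_ep(c(FALSE, TRUE, FALSE, TRUE), "adult"))
  expect_equal(none$n_matched, 0)
  expect_error(epoch_cross_spectra(none, pair_grid("C4", "C4")),
               "insufficient epochs")
  # matched count never exceeds either member's good count
  expect_lte(more$n_matched, sum(adu$good_mask))
  # differing grids error
  short <- mk_ep(c(TRUE, TRUE, TRUE), "adult")
  expect_error(match_epochs(inf, short), "grids differ")
})

test_that("minimum-span enforcement flags short dyads and caps onsets", {
  fs <- 100
  rec <- function(secs, role) new_recording(matrix(rnorm(secs * fs), 1,
                                                   secs * fs),
                                            "C4", fs, "d", role, "A")
  m45 <- match_epochs(epoch_recording(rec(45, "infant")),
                      epoch_recording(rec(45, "adult")))
  expect_true(enforce_minimum(m45, min_seconds = 60)$excluded)
  m180 <- match_epochs(epoch_recording(rec(180, "infant")),
                       epoch_recording(rec(180, "adult")))
  capped <- enforce_minimum(m180, min_seconds = 60, cap_seconds = 90)
  expect_true(all(capped$onsets < 90))
  expect_equal(capped$n_matched, 180)          # onsets 0, 0.5, ..., 89.5
  expect_false(capped$excluded)
  ident <- enforce_minimum(m45, min_seconds = 0)
  expect_equal(ident$n_matched, m45$n_matched)
  expect_false(ident$excluded)
})
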