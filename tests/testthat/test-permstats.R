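test_that("two-condition RM-ANOVA F equals the squared paired t", {
  for (seed in 1:25) {
    arr <- mk_group(n = sample(5:30, 1), k = 2, p = 4, seed = seed)
    res <- rm_anova_map(arr)
    for (j in 1:4) {
      tt <- stats::t.test(arr[, 2, j], arr[, 1, j], paired = TRUE)
      expect_equal(res$F[[j]], unname(tt$statistic)^2, tolerance = 1e-10)
    }
    expect_true(all(res$eta_sq_p >= 0 & res$eta_sq_p <= 1))
  }
  # identical condition columns
  arr <- mk_group(10, 2, 3, seed = 1)
  arr[, 2, ] <- arr[, 1, ]
  res0 <- rm_anova_map(arr)
  expect_equal(unname(res0$F), rep(0, 3))
  expect_equal(unname(res0$eta_sq_p), rep(0, 3))
  # zero error variance with an effect: Inf sentinel + warning
  arr[, 2, ] <- arr[, 1, ] + 1
  expect_warning(resI <- rm_anova_map(arr), "zero error variance")
  expect_true(all(is.infinite(resI$F)))
})

test_that("mean F under a known additive effect matches the noncentral expectation", {
  n <- 30; d <- 0.8; sigma <- 1
  set.seed(10)
  Fs <- replicate(500, {
    base <- rnorm(n, 0, 1)
    a <- base + rnorm(n, 0, sigma)
    b <- base + d + rnorm(n, 0, sigma)
    arr <- array(c(a, b), c(n, 2, 1))
    rm_anova_map(arr)$F[[1]]
  })
  lambda <- n * d^2 / (2 * sigma^2)
  expected <- (n - 1) / (n - 3) * (1 + lambda)
  expect_lt(abs(mean(Fs) - expected) / expected, 0.1)
})

test_that("eta_sq_p and F are invariant to affine rescaling of both conditions", {
  arr <- mk_group(12, 2, 5, seed = 3, effect = 0.5)
  res <- rm_anova_map(arr)
  res2 <- rm_anova_map(arr * 7.3 + 2.1)
  expect_equal(res$F, res2$F, tolerance = 1e-10)
  expect_equal(res$eta_sq_p, res2$eta_sq_p, tolerance = 1e-10)
})

test_that("exhaustive sign-flip p equals the brute-force enumeration oracle", {
  n <- 5
  arr <- mk_group(n, 2, 3, seed = 7, effect = 1.2)
  res <- max_f_permutation(arr, n_perm = 50, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 2^n)
  # independent oracle: enumerate sign vectors, F via t.test each time
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  max_null <- apply(signs, 1, function(s) {
    max(sapply(1:3, function(j) {
      dd <- s * (arr[, 2, j] - arr[, 1, j])
      unname(stats::t.test(dd)$statistic)^2
    }))
  })
  p_oracle <- sapply(res$F, function(f) mean(max_null >= f - 1e-12))
  expect_equal(unname(res$p_perm), unname(p_oracle), tolerance = 1e-12)
  # exchangeability: permuting dyad order leaves F and p unchanged
  perm <- sample(n)
  res_p <- max_f_permutation(arr[perm, , ], n_perm = 50, seed = 1)
  expect_equal(unname(res_p$F), unname(res$F), tolerance = 1e-12)
  expect_equal(unname(res_p$p_perm), unname(res$p_perm), tolerance = 1e-12)
})

test_that("Monte-Carlo p agrees with the exhaustive p within binomial error", {
  arr <- mk_group(8, 2, 6, seed = 2, effect = 1)
  ex <- max_f_permutation(arr, seed = 1)
  mc <- max_f_permutation(arr, n_perm = 1000, seed = 5,
                          exhaustive_limit = 1)
  expect_true(ex$exhaustive); expect_false(mc$exhaustive)
  for (j in seq_along(ex$p_perm)) {
    p <- ex$p_perm[[j]]
    tol <- 2 * sqrt(p * (1 - p) / 1000) + 2 / 1001
    expect_lt(abs(mc$p_perm[[j]] - p), max(tol, 0.005))
  }
  expect_warning(max_f_permutation(arr, n_perm = 50, seed = 1,
                                   exhaustive_limit = 1), "coarse")
  expect_error(max_f_permutation(mk_group(1, 2, 3)), "at least 2 dyads")
})

test_that("k > 2 conditions use within-dyad label shuffles", {
  arr <- mk_group(10, 3, 4, seed = 6, effect = 2.5)
  res <- max_f_permutation(arr, n_perm = 300, seed = 2)
  expect_false(res$exhaustive)
  expect_equal(res$df, c(2, 18))
  expect_length(res$null_max_F, 300)
  expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
  expect_lt(res$p_perm[[1]], 0.05)             # injected effect found
})

test_that("pseudo-dyad null detects real coupling and stays uniform under none", {
  mk_list <- function(kappa, seed, n_dyads = 8) {
    cfg <- sim_config(n_dyads, sampling_rate = 100, duration = 20,
                      channel_layout = c("C4", "P8"), conditions = "A",
                      coupling = if (kappa > 0)
                        data.frame(condition = "A", adult = "C4",
                                   infant = "P8", kappa = kappa) else NULL,
                      seed = seed)
    lapply(seq_len(n_dyads), function(d) {
      pair <- simulate_dyad(cfg, d, "A")
      match_epochs(epoch_recording(pair$infant),
                   epoch_recording(pair$adult))
    })
  }
  res <- pseudo_dyad_null(mk_list(0.7, seed = 1), "C4", "P8", M = 200,
                          seed = 1)
  expect_lte(res$p, 0.05)
  expect_gt(res$real_mean, mean(res$null))
  # null uniformity: KS test over repeated studies
  ps <- sapply(1:60, function(s)
    pseudo_dyad_null(mk_list(0, seed = 100 + s), "C4", "P8", M = 100,
                     seed = s)$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(pseudo_dyad_null(mk_list(0, seed = 1, n_dyads = 2), "C4",
                                "P8"), "at least 5")
})

test_that("change score matches its arithmetic and symmetries", {
  expect_equal(change_score(0.11, 0.08), 0.03 / 0.11, tolerance = 1e-12)
  expect_equal(change_score(0.5, 0.5), 0)
  expect_equal(change_score(0, 0), 0)
  expect_error(change_score(-0.1, 0.2), "non-negative")
  set.seed(1)
  a <- runif(50); b <- runif(50); c <- runif(50, 0.1, 10)
  expect_equal(change_score(a, b), -change_score(b, a), tolerance = 1e-12)
  expect_equal(change_score(c * a, c * b), change_score(a, b),
               tolerance = 1e-12)
  expect_true(all(abs(change_score(a, b)) <= 1))
})

test_that("single-pass 3-SD exclusion follows the full-vector rule", {
  # |10 - 2| = 8 < 3 * 4.47: nothing excluded, despite appearances
  expect_equal(exclude_3sd(c(0, 0, 0, 0, 10)), rep(FALSE, 5))
  expect_equal(exclude_3sd(rep(2, 6)), rep(FALSE, 6))
  set.seed(3)
  x <- c(rnorm(49), 100)
  expect_equal(which(exclude_3sd(x)), 50L)
  expect_error(exclude_3sd(c(1, 2)), "at least 3")
})

test_that("paired t and Pearson match hand-computed closed forms", {
  a <- c(2, 4, 5, 4, 5); b <- c(1, 2, 4, 3, 5)
  d <- a - b
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  res <- paired_t(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-10)
  x <- c(1, 2, 3, 5, 8); y <- c(2, 3, 4, 8, 12)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cr <- pearson(x, y)
  expect_equal(cr$r, r_hand, tolerance = 1e-10)
  expect_equal(cr$df, 3)
  # trivial identities
  expect_equal(paired_t(a, a), list(t = 0, df = 4, p = 1))
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_error(paired_t(a, b[1:4]), "equal length")
  expect_error(pearson(rep(1, 5), y), "zero variance")
})

test_that("stats JSON round-trips the per-pair report", {
  arr <- mk_group(8, 2, 4, seed = 9, effect = 1.5)
  res <- max_f_permutation(arr, seed = 3)
  path <- tempfile(fileext = ".json")
  write_stats_json(res, path)
  j <- jsonlite::read_json(path)
  expect_equal(length(j$pairs), 4)
  expect_equal(j$pairs[[1]]$F, res$F[[1]], tolerance = 1e-12)
  expect_equal(j$alpha, 0.05)
  null <- as.numeric(readLines(paste0(path, ".null.txt")))
  expect_equal(null, unname(res$null_max_F), tolerance = 1e-12)
  unlink(c(path, paste0(path, ".null.txt")))
})
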