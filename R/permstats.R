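#' Mass-univariate one-way repeated-measures ANOVA across electrode pairs
#'
#' For each inter-subject electrode pair, a one-way within-dyad ANOVA
#' comparing conditions: `F = MS_cond / MS_error` with
#' `df = (k - 1, (k - 1)(n - 1))`, and partial eta squared
#' `SS_cond / (SS_cond + SS_error)`. With two conditions F is exactly the
#' squared paired-t statistic. Zero error variance yields an `Inf` sentinel
#' with a warning.
#'
#' @param group a [group_connectivity()] array (or plain dyads x conditions
#'   x pairs array)
#' @param conditions conditions to contrast (default: all in the group)
#' @return list with `F` and `eta_sq_p` vectors (one per pair), `df`
#' @export
rm_anova_map <- function(group, conditions = NULL) {
  X <- if (inherits(group, "GroupConnectivity")) group$values else group
  if (!is.null(conditions)) X <- X[, conditions, , drop = FALSE]
  n <- dim(X)[1]; k <- dim(X)[2]; p <- dim(X)[3]
  if (n < 3) stop("need at least 3 dyads complete in all conditions")
  if (k < 2) stop("need at least 2 conditions")
  Fv <- numeric(p); eta <- numeric(p)
  for (j in seq_len(p)) {
    x <- X[, , j]
    grand <- mean(x)
    ss_cond <- n * sum((colMeans(x) - grand)^2)
    resid <- x - outer(rowMeans(x), rep(1, k)) -
      outer(rep(1, n), colMeans(x)) + grand
    ss_err <- sum(resid^2)
    if (ss_err <= .Machine$double.eps * max(1, ss_cond)) {
      if (ss_cond > 0) {
        warning("zero error variance; F set to Inf")
        Fv[j] <- Inf; eta[j] <- 1
      } else {
        Fv[j] <- 0; eta[j] <- 0
      }
    } else {
      Fv[j] <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
      eta[j] <- ss_cond / (ss_cond + ss_err)
    }
  }
  names(Fv) <- names(eta) <- dimnames(X)[[3]]
  list(F = Fv, eta_sq_p = eta, df = c(k - 1, (k - 1) * (n - 1)))
}

# >= comparison with relative tie tolerance: statistics regenerated by a
# different (vectorized) code path must count as exceedances of themselves.
ge_tol <- function(a, b) a >= b - 1e-9 * abs(b) - 1e-12

# Vectorized two-condition F for all sign assignments S (m x n) applied to
# the dyad x pair difference matrix D: F = n * mean^2 / var per pair.
flip_F <- function(S, D) {
  n <- nrow(D)
  M <- (S %*% D) / n                           # m x pairs means
  q <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  V <- (q - n * M^2) / (n - 1)
  Fm <- n * M^2 / V
  Fm[V <= 0] <- ifelse(abs(M[V <= 0]) > 0, Inf, 0)
  Fm
}

#' Max-F permutation test with family-wise error control
#'
#' Per-pair repeated-measures F values are referred to the permutation
#' distribution of the maximum F over all pairs, obtained by shuffling
#' condition labels independently within each dyad. With two conditions the
#' within-dyad shuffle is a sign flip of the paired difference; when
#' `2^n_dyads <= exhaustive_limit` all sign assignments are enumerated
#' exactly, otherwise `n_perm` random assignments are drawn. Monte-Carlo
#' p-values use the add-one convention `(1 + #(max F >= F_obs)) /
#' (1 + n_perm)`; exhaustive p-values are the exact proportion over all
#' `2^n` assignments (the identity assignment included).
#'
#' @param group a [group_connectivity()] (or dyads x conditions x pairs
#'   array)
#' @param conditions conditions to contrast
#' @param n_perm number of random permutations (default 1000; below 100
#'   warns)
#' @param seed integer seed
#' @param alpha significance level (default 0.05)
#' @param exhaustive_limit enumerate exactly when `2^n` is at most this
#'   (default 4096)
#' @return a `MassUnivariateResult`: `F`, `eta_sq_p`, `p_perm`, `p_naive`
#'   (uncorrected parametric F-distribution p), `null_max_F`,
#'   `significant_pairs`, `alpha`, `n_perm`, `seed`, `exhaustive`
#' @export
max_f_permutation <- function(group, conditions = NULL, n_perm = 1000,
                              seed = 1L, alpha = 0.05,
                              exhaustive_limit = 4096) {
  X <- if (inherits(group, "GroupConnectivity")) group$values else group
  if (!is.null(conditions)) X <- X[, conditions, , drop = FALSE]
  n <- dim(X)[1]; k <- dim(X)[2]
  if (n < 2) stop("need at least 2 dyads")
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  obs <- rm_anova_map(X)
  exhaustive <- (k == 2) && (2^n <= exhaustive_limit)
  if (k == 2) {
    D <- X[, 2, ] - X[, 1, ]
    if (is.null(dim(D))) D <- matrix(D, ncol = 1)
    if (exhaustive) {
      m <- 2^n
      S <- (-1)^((matrix(0:(m - 1), m, n) %/%
                    matrix(2^(0:(n - 1)), m, n, byrow = TRUE)) %% 2)
      Fm <- flip_F(S, D)
      null_max <- apply(Fm, 1, max)
      p <- vapply(obs$F, function(f) mean(ge_tol(null_max, f)), 0)
      n_used <- m
    } else {
      S <- with_seed(derive_seed(seed, "maxF"),
                     matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            n_perm, n))
      Fm <- flip_F(S, D)
      null_max <- apply(Fm, 1, max)
      p <- vapply(obs$F, function(f)
        (1 + sum(ge_tol(null_max, f))) / (1 + n_perm), 0)
      n_used <- n_perm
    }
  } else {
    null_max <- with_seed(derive_seed(seed, "maxF"), vapply(
      seq_len(n_perm), function(b) {
        Xp <- X
        for (d in seq_len(n)) Xp[d, , ] <- X[d, sample.int(k), ]
        max(rm_anova_map(Xp)$F)
      }, 0))
    p <- vapply(obs$F, function(f)
      (1 + sum(ge_tol(null_max, f))) / (1 + n_perm), 0)
    exhaustive <- FALSE
    n_used <- n_perm
  }
  p_naive <- stats::pf(obs$F, obs$df[1], obs$df[2], lower.tail = FALSE)
  sig <- names(p)[p <= alpha]
  structure(
    list(F = obs$F, eta_sq_p = obs$eta_sq_p, df = obs$df, p_perm = p,
         p_naive = p_naive, null_max_F = null_max, alpha = alpha,
         significant_pairs = sig, n_perm = n_used, seed = seed,
         exhaustive = exhaustive),
    class = "MassUnivariateResult")
}

#' @export
print.MassUnivariateResult <- function(x, ...) {
  cat(sprintf(
    "<MassUnivariateResult> %d pairs, df = (%d, %d), %s %d assignments\n",
    length(x$F), x$df[1], x$df[2],
    if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm))
  if (length(x$significant_pairs))
    cat("significant at alpha =", x$alpha, ":",
        paste(x$significant_pairs, collapse = ", "), "\n")
  else cat("no pair significant at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Pseudo-dyad surrogate null for inter-brain connectivity
#'
#' Builds `M` surrogate datasets by re-pairing each adult with a uniformly
#' drawn non-partner infant from the same condition (a derangement of the
#' dyad labels), recomputes the target pair's wPLI from the raw matched
#' epochs of each surrogate pair (truncating to the shorter member's epoch
#' count), and compares the real dyads' mean connectivity with the
#' surrogate distribution: `p = (1 + #(null mean >= real mean)) / (1 + M)`.
#'
#' @param matched_list list of `MatchedDyadEpochs`, one per dyad, same
#'   condition
#' @param adult_channel,infant_channel the target electrode pair
#' @param band a [band_spec()]
#' @param M number of surrogate datasets (default 1000; below 100 warns)
#' @param seed integer seed
#' @param min_epochs per-pair epoch floor passed to the spectral stage
#' @return list with `real_mean`, `null` (length-M vector of surrogate mean
#'   wPLI), `p`, `M`
#' @export
pseudo_dyad_null <- function(matched_list, adult_channel, infant_channel,
                             band = band_spec(), M = 1000, seed = 1L,
                             min_epochs = 20) {
  n <- length(matched_list)
  if (n < 5) stop("need at least 5 dyads for a pseudo-dyad null")
  if (M < 100) warning("M < 100: surrogate p-values are coarse")
  # keep per-member epoch FFTs so surrogate cross-spectra can be formed
  # between arbitrary adult/infant re-pairings
  one_sided <- lapply(matched_list, function(m) {
    fs <- m$sampling_rate
    ns <- dim(m$infant_data)[3]
    hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, ns - 1) / ns)
    bins <- seq(ceiling(band$fmin), floor(band$fmax)) + 1
    one <- function(data, ch, chans) {
      seg <- data[, match(ch, chans), , drop = FALSE]
      dim(seg) <- c(dim(data)[1], ns)
      seg <- seg - rowMeans(seg)
      t(stats::mvfft(t(seg * rep(hann, each = nrow(seg))))[bins, ,
                                                           drop = FALSE])
    }
    list(a = one(m$adult_data, adult_channel, m$adult_channels),
         i = one(m$infant_data, infant_channel, m$infant_channels))
  })
  wpli_xy <- function(Xa, Xi) {
    E <- min(nrow(Xa), nrow(Xi))
    if (E < min_epochs) stop("insufficient epochs in surrogate pair")
    im <- Im(Xa[seq_len(E), , drop = FALSE] *
               Conj(Xi[seq_len(E), , drop = FALSE]))
    num <- abs(colSums(im)); den <- colSums(abs(im))
    mean(ifelse(den == 0, 0, num / den))
  }
  real <- vapply(one_sided, function(s) wpli_xy(s$a, s$i), 0)
  real_mean <- mean(real)
  null <- with_seed(derive_seed(seed, "pseudo"), vapply(seq_len(M),
    function(b) {
      repeat {
        perm <- sample.int(n)
        if (all(perm != seq_len(n))) break
      }
      mean(vapply(seq_len(n), function(d)
        wpli_xy(one_sided[[d]]$a, one_sided[[perm[d]]]$i), 0))
    }, 0))
  list(real_mean = real_mean, null = null,
       p = (1 + sum(ge_tol(null, real_mean))) / (1 + M), M = M)
}

#' Normalized paired change score
#'
#' `(a - b) / max(a, b)` for non-negative paired measures, bounded in
#' \[-1, 1\]; `0/0` is defined as 0. Antisymmetric and scale-invariant.
#'
#' @param a,b non-negative scalars or equal-length vectors
#' @return the change score(s)
#' @export
change_score <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("change_score requires non-negative inputs")
  m <- pmax(a, b)
  ifelse(m == 0, 0, (a - b) / m)
}

#' Single-pass 3-SD outlier flag
#'
#' Mean and sample SD are computed once on the full vector; element i is
#' flagged iff `|x_i - mean| > 3 * SD`. Zero variance flags nothing.
#'
#' @param values numeric vector, length at least 3
#' @return logical mask, `TRUE` = excluded
#' @export
exclude_3sd <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > 3 * s
}

#' Two-sided paired t test
#'
#' @param a,b equal-length paired vectors, n >= 3
#' @return list with `t`, `df = n - 1`, `p`
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a - b) == 0) {
    if (all(a == b))                           # a = b: t = 0, p = 1
      return(list(t = 0, df = length(a) - 1, p = 1))
    stop("zero variance of paired differences")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Two-sided Pearson correlation test
#'
#' @param x,y equal-length vectors, n >= 3
#' @return list with `r`, `df = n - 2`, `p`
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ht <- stats::cor.test(x, y)
  list(r = unname(ht$estimate), df = unname(ht$parameter), p = ht$p.value)
}

#' Write a mass-univariate result as JSON
#'
#' Per-pair `{F, eta_sq_p, p_perm, p_naive, significant}` plus alpha, df,
#' seed and permutation scheme; the null max-F sample goes to a sidecar
#' `<path>.null.txt`, one value per line.
#'
#' @param result a `MassUnivariateResult`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_stats_json <- function(result, path) {
  per_pair <- lapply(names(result$F), function(pr) list(
    F = result$F[[pr]], eta_sq_p = result$eta_sq_p[[pr]],
    p_perm = result$p_perm[[pr]], p_naive = result$p_naive[[pr]],
    significant = pr %in% result$significant_pairs))
  names(per_pair) <- names(result$F)
  jsonlite::write_json(
    list(pairs = per_pair, alpha = result$alpha, df = result$df,
         n_perm = result$n_perm, seed = result$seed,
         exhaustive = result$exhaustive),
    path, auto_unbox = TRUE, digits = NA)
  writeLines(format(result$null_max_F, digits = 17),
             paste0(path, ".null.txt"))
  invisible(path)
}
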