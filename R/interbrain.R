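#' Frequency band specification
#'
#' @param name band name
#' @param fmin,fmax band edges in Hz; theta defaults to 4-7 Hz
#' @return a `BandSpec`
#' @export
band_spec <- function(name = "theta", fmin = 4, fmax = 7) {
  if (!(fmin > 0 && fmin <= fmax)) stop("need 0 < fmin <= fmax")
  structure(list(name = name, fmin = fmin, fmax = fmax), class = "BandSpec")
}

#' Inter-subject electrode pair grid
#'
#' The default grid crosses the six central/temporal/posterior-temporal
#' sites of each subject (C3, C4, T7, T8, P7, P8), yielding the canonical
#' 36 adult-by-infant combinations per dyad per condition.
#'
#' @param adult_channels,infant_channels ordered channel label vectors
#' @return a `PairGrid` with `n_pairs = length(adult) * length(infant)`
#' @export
pair_grid <- function(adult_channels = c("C3", "C4", "T7", "T8", "P7", "P8"),
                      infant_channels = adult_channels) {
  structure(list(adult_channels = adult_channels,
                 infant_channels = infant_channels,
                 n_pairs = length(adult_channels) * length(infant_channels)),
            class = "PairGrid")
}

#' Per-epoch cross-spectra between adult and infant channels
#'
#' Each 1-s matched epoch is demeaned per channel, Hann-tapered, and
#' Fourier-transformed; the cross-spectrum for pair (a, i) at bin f is
#' `X_a(f) * Conj(X_i(f))`. One-second epochs put the DFT bins at integer
#' Hz, so the band's bins are the integers from `ceiling(fmin)` to
#' `floor(fmax)` (theta: 4, 5, 6, 7 Hz).
#'
#' @param matched a `MatchedDyadEpochs` with 1.0-s epochs
#' @param grid a [pair_grid()]
#' @param band a [band_spec()]
#' @param min_epochs minimum matched epochs required (default 20)
#' @return a `cross_spectra` object: complex array epochs x pairs x bins
#'   with grid/band metadata; pairs ordered adult-major
#'   (adult 1 x all infants, adult 2 x all infants, ...)
#' @export
epoch_cross_spectra <- function(matched, grid = pair_grid(),
                                band = band_spec(), min_epochs = 20) {
  if (abs(matched$epoch_length - 1) > 1e-9)
    stop("cross-spectra require 1.0-s epochs (integer-Hz bins)")
  if (ceiling(band$fmin) > floor(band$fmax))
    stop("band contains no integer-Hz bin")
  bins <- seq(ceiling(band$fmin), floor(band$fmax))
  if (max(bins) >= matched$sampling_rate / 2)
    stop("band exceeds Nyquist")
  if (matched$n_matched < min_epochs)
    stop(sprintf("insufficient epochs: %d matched, %d required",
                 matched$n_matched, min_epochs))
  ai <- match(grid$adult_channels, matched$adult_channels)
  ii <- match(grid$infant_channels, matched$infant_channels)
  if (anyNA(ai) || anyNA(ii)) stop("grid channel missing from recording")
  n <- dim(matched$infant_data)[3]
  E <- matched$n_matched
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  bin_idx <- bins + 1
  spec1 <- function(data, chans) {
    # epochs x channels x bins spectra of demeaned, tapered epochs
    out <- array(0i, dim = c(E, length(chans), length(bins)))
    for (ci in seq_along(chans)) {
      seg <- data[, chans[ci], , drop = FALSE]
      dim(seg) <- c(E, n)
      seg <- seg - rowMeans(seg)
      F <- stats::mvfft(t(seg * rep(hann, each = E)))
      out[, ci, ] <- t(F[bin_idx, , drop = FALSE])
    }
    out
  }
  Xa <- spec1(matched$adult_data, ai)
  Xi <- spec1(matched$infant_data, ii)
  na <- length(ai); ni <- length(ii)
  cross <- array(0i, dim = c(E, na * ni, length(bins)))
  pairs <- character(na * ni)
  k <- 0
  for (a in seq_len(na)) for (i in seq_len(ni)) {
    k <- k + 1
    cross[, k, ] <- Xa[, a, ] * Conj(Xi[, i, ])
    pairs[k] <- paste0(grid$adult_channels[a], ":", grid$infant_channels[i])
  }
  structure(list(cross = cross, pairs = pairs, bins = bins, grid = grid,
                 band = band, dyad_id = matched$dyad_id,
                 condition = matched$condition, n_epochs = E),
            class = "cross_spectra")
}

connectivity_map <- function(values_by_pair, cs, metric) {
  g <- cs$grid
  m <- matrix(values_by_pair, nrow = length(g$adult_channels),
              ncol = length(g$infant_channels), byrow = TRUE,
              dimnames = list(g$adult_channels, g$infant_channels))
  structure(list(dyad_id = cs$dyad_id, condition = cs$condition,
                 metric = metric, band = cs$band, values = m,
                 n_epochs_used = cs$n_epochs),
            class = "ConnectivityMap")
}

#' @export
print.ConnectivityMap <- function(x, ...) {
  cat(sprintf("<ConnectivityMap> %s/%s %s [%s %g-%g Hz], %d epochs\n",
              x$dyad_id, x$condition, x$metric, x$band$name, x$band$fmin,
              x$band$fmax, x$n_epochs_used))
  print(round(x$values, 3))
  invisible(x)
}

#' Weighted phase lag index
#'
#' Per pair and frequency bin, `wPLI(f) = |sum_e Im S_e(f)| /
#' sum_e |Im S_e(f)|`, with 0/0 defined as 0; the map value is the
#' unweighted mean over the band's bins. Phase differences are weighted by
#' the magnitude of their imaginary (lagged) part, so near-zero-lag
#' coupling — e.g. two people receiving the same stimulus — contributes
#' only marginally, while a genuine nonzero-lag lock drives the index to 1.
#'
#' @param cs a [epoch_cross_spectra()] result
#' @return a `ConnectivityMap` with values in \[0, 1\]
#' @export
wpli <- function(cs) {
  im <- Im(cs$cross)                            # epochs x pairs x bins
  num <- abs(apply(im, c(2, 3), sum))
  den <- apply(abs(im), c(2, 3), sum)
  v <- ifelse(den == 0, 0, num / den)
  connectivity_map(rowMeans(v), cs, "wPLI")
}

#' Phase locking value
#'
#' Per pair and bin, the magnitude of the mean unit phasor of the
#' cross-spectral phase differences, `|mean_e exp(i arg S_e(f))|`, averaged
#' over band bins. Unlike [wpli()], PLV counts zero-lag coupling in full.
#' Epochs whose cross-spectrum is exactly zero contribute a zero phasor.
#'
#' @param cs a [epoch_cross_spectra()] result
#' @return a `ConnectivityMap` with values in \[0, 1\]
#' @export
plv <- function(cs) {
  z <- cs$cross
  mag <- abs(z)
  ph <- ifelse(mag == 0, 0i, z / ifelse(mag == 0, 1, mag))
  v <- abs(apply(ph, c(2, 3), mean))
  connectivity_map(rowMeans(v), cs, "PLV")
}

#' Stack per-dyad connectivity maps into a dense group array
#'
#' @param maps list of `ConnectivityMap`s; every dyad must be present in
#'   every condition (missing cells are an error, not NA)
#' @param conditions condition labels to include (default: all observed,
#'   in order of first appearance)
#' @return a `GroupConnectivity`: array dyads x conditions x pairs with
#'   dimnames, plus `pairs` label vector and the shared grid/band
#' @export
group_connectivity <- function(maps, conditions = NULL) {
  stopifnot(length(maps) > 0)
  dyads <- unique(vapply(maps, `[[`, "", "dyad_id"))
  conds <- if (is.null(conditions))
    unique(vapply(maps, `[[`, "", "condition")) else conditions
  proto <- maps[[1]]
  pairs <- as.vector(t(outer(rownames(proto$values),
                             colnames(proto$values), paste, sep = ":")))
  arr <- array(NA_real_,
               dim = c(length(dyads), length(conds), length(pairs)),
               dimnames = list(dyads, conds, pairs))
  for (m in maps) {
    if (!identical(dim(m$values), dim(proto$values)))
      stop("ragged connectivity maps")
    if (m$condition %in% conds)
      arr[m$dyad_id, m$condition, ] <- as.vector(t(m$values))
  }
  if (anyNA(arr)) {
    miss <- which(is.na(arr[, , 1, drop = FALSE]), arr.ind = TRUE)
    stop("missing dyad-condition cells: ",
         paste(dyads[miss[, 1]], conds[miss[, 2]], sep = "/",
               collapse = ", "))
  }
  structure(list(values = arr, dyads = dyads, conditions = conds,
                 pairs = pairs, metric = proto$metric, band = proto$band),
            class = "GroupConnectivity")
}

#' Write connectivity maps as long-format TSV
#'
#' Columns: `dyad_id, condition, metric, band, adult_ch, infant_ch, value,
#' n_epochs`.
#'
#' @param maps list of `ConnectivityMap`s
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_connectivity_tsv <- function(maps, path) {
  rows <- do.call(rbind, lapply(maps, function(m) {
    g <- expand.grid(infant_ch = colnames(m$values),
                     adult_ch = rownames(m$values),
                     stringsAsFactors = FALSE)
    data.frame(dyad_id = m$dyad_id, condition = m$condition,
               metric = m$metric, band = m$band$name,
               adult_ch = g$adult_ch, infant_ch = g$infant_ch,
               value = as.vector(t(m$values)), n_epochs = m$n_epochs_used)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
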