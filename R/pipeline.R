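#' Declarative run configuration
#'
#' Either a synthetic scenario (a [sim_config()] plus contrast definition)
#' or a manifest of recording files. Consumed by [run_contrast()] and
#' [run_brain_behavior()], and readable from JSON via [read_run_config()].
#'
#' @param sim a [sim_config()] for synthetic runs, or `NULL`
#' @param manifest data.frame with columns `dyad_id, role, condition, path,
#'   format` (`"tsv"` or `"edf"`) for file-based runs, or `NULL`
#' @param contrast character vector of the two condition labels to compare
#' @param band a [band_spec()]
#' @param grid a [pair_grid()]
#' @param filter_low,filter_high broadband filter edges in Hz (default
#'   1-50)
#' @param epoch_length,epoch_step epoching grid in seconds (default 1, 0.5)
#' @param min_seconds,cap_seconds matched-span floor and analysis cap
#' @param min_epochs per-dyad epoch floor for connectivity (default 20)
#' @param n_perm permutations for the max-F test (default 1000)
#' @param alpha significance level (default 0.05)
#' @param target_pair `c(adult_channel, infant_channel)` for change-score
#'   analyses
#' @param reject logical: run peak-to-peak epoch rejection (default TRUE)
#' @param seed master seed
#' @param out_dir output directory, or `NULL` for no file output
#' @return a `RunConfig`
#' @export
run_config <- function(sim = NULL, manifest = NULL,
                       contrast = NULL, band = band_spec(),
                       grid = pair_grid(), filter_low = 1,
                       filter_high = 50, epoch_length = 1,
                       epoch_step = 0.5, min_seconds = 0,
                       cap_seconds = NULL, min_epochs = 20,
                       n_perm = 1000, alpha = 0.05,
                       target_pair = c("C4", "P8"), reject = TRUE,
                       seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(manifest))
    stop("config needs either a synthetic scenario or a file manifest")
  if (!is.null(manifest)) {
    stopifnot(all(c("dyad_id", "role", "condition", "path") %in%
                    names(manifest)))
    missing <- !file.exists(manifest$path)
    if (any(missing))
      stop("manifest file(s) not found: ",
           paste(manifest$path[missing], collapse = ", "))
  }
  conds <- if (!is.null(sim)) sim$conditions else unique(manifest$condition)
  if (is.null(contrast)) contrast <- conds[1:2]
  if (anyNA(contrast) || !all(contrast %in% conds))
    stop("contrast condition missing from manifest/scenario: ",
         paste(setdiff(contrast, conds), collapse = ", "))
  structure(
    list(sim = sim, manifest = manifest, contrast = contrast, band = band,
         grid = grid, filter_low = filter_low, filter_high = filter_high,
         epoch_length = epoch_length, epoch_step = epoch_step,
         min_seconds = min_seconds, cap_seconds = cap_seconds,
         min_epochs = min_epochs, n_perm = n_perm, alpha = alpha,
         target_pair = target_pair, reject = reject, seed = as.integer(seed),
         out_dir = out_dir),
    class = "RunConfig")
}

#' Read a run configuration from a JSON file
#'
#' The JSON mirrors [run_config()]'s arguments; the `sim` block mirrors
#' [sim_config()] (its `coupling` table as an array of row objects).
#'
#' @param path JSON path
#' @return a `RunConfig`
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(j$sim)) {
    s <- j$sim
    args <- s[intersect(names(s), names(formals(sim_config)))]
    if (!is.null(args$coupling))
      args$coupling <- as.data.frame(args$coupling)
    sim <- do.call(sim_config, args)
  }
  band <- if (is.null(j$band)) band_spec()
          else band_spec(j$band$name, j$band$fmin, j$band$fmax)
  grid <- if (is.null(j$grid)) pair_grid()
          else pair_grid(j$grid$adult_channels, j$grid$infant_channels)
  rest <- j[intersect(names(j), setdiff(names(formals(run_config)),
                                        c("sim", "band", "grid",
                                          "manifest")))]
  manifest <- if (!is.null(j$manifest)) as.data.frame(j$manifest) else NULL
  do.call(run_config, c(list(sim = sim, manifest = manifest, band = band,
                             grid = grid), rest))
}

# Stage-tagged error propagation
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

load_recordings <- function(config, dyad_id, condition) {
  if (!is.null(config$sim)) {
    idx <- as.integer(sub("^dyad0*", "", dyad_id))
    return(simulate_dyad(config$sim, idx, condition))
  }
  m <- config$manifest
  sel <- m[m$dyad_id == dyad_id & m$condition == condition, , drop = FALSE]
  if (nrow(sel) != 2) stop("manifest must have exactly one infant and one ",
                           "adult file for ", dyad_id, "/", condition)
  read1 <- function(row) {
    fmt <- if ("format" %in% names(row) && nzchar(row$format)) row$format
           else if (grepl("\\.edf$", row$path, ignore.case = TRUE)) "edf"
           else "tsv"
    if (fmt == "edf") read_recording_edf(row$path)
    else read_recording_tsv(row$path)
  }
  list(infant = read1(sel[sel$role == "infant", ]),
       adult = read1(sel[sel$role == "adult", ]))
}

config_dyads <- function(config) {
  if (!is.null(config$sim)) sprintf("dyad%03d", seq_len(config$sim$n_dyads))
  else unique(config$manifest$dyad_id)
}

# Preprocess one dyad in both contrast conditions: duration matching across
# conditions, band-pass, epoching, rejection, within-dyad epoch matching,
# minimum-span enforcement.
preprocess_dyad <- function(config, dyad_id) {
  recs <- lapply(config$contrast, function(cond)
    load_recordings(config, dyad_id, cond))
  names(recs) <- config$contrast
  nmin <- min(vapply(recs, function(r) ncol(r$infant$signal), 0))
  lapply(recs, function(r) {
    r <- lapply(r, function(x) {
      x$signal <- x$signal[, seq_len(nmin), drop = FALSE]
      x
    })
    r <- lapply(r, bandpass, low = config$filter_low,
                high = config$filter_high)
    ep <- lapply(r, epoch_recording, length = config$epoch_length,
                 step = config$epoch_step)
    if (config$reject) ep <- lapply(ep, reject_epochs)
    matched <- match_epochs(ep$infant, ep$adult)
    enforce_minimum(matched, config$min_seconds, config$cap_seconds)
  })
}

#' Run the full two-condition contrast pipeline
#'
#' preprocess -> connectivity -> permutation inference: every dyad is
#' loaded (or simulated) in both contrast conditions, duration-matched,
#' filtered, epoched, rejection-screened, epoch-matched across the two
#' heads, reduced to band-averaged wPLI over the pair grid, stacked, and
#' passed to the max-F permutation test. When `out_dir` is set, writes
#' `connectivity.tsv`, `stats.json` (+ null sidecar) and `run_log.json`
#' with all seeds, parameters and a config hash.
#'
#' @param config a [run_config()] (or path to a JSON config)
#' @return list with `group` (GroupConnectivity), `result`
#'   (MassUnivariateResult), `maps`, `excluded` dyads, `log`
#' @export
run_contrast <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  dyads <- config_dyads(config)
  maps <- list(); excluded <- character()
  for (d in dyads) {
    matched <- stage("preprocess", preprocess_dyad(config, d))
    if (any(vapply(matched, `[[`, TRUE, "excluded"))) {
      excluded <- c(excluded, d)
      next
    }
    for (cond in config$contrast) {
      cs <- stage("interbrain",
                  epoch_cross_spectra(matched[[cond]], config$grid,
                                      config$band, config$min_epochs))
      maps[[length(maps) + 1]] <- wpli(cs)
    }
  }
  if (!length(maps)) stop("[interbrain] no dyad survived preprocessing")
  group <- stage("interbrain", group_connectivity(maps, config$contrast))
  result <- stage("permstats",
                  max_f_permutation(group, config$contrast,
                                    n_perm = config$n_perm,
                                    seed = config$seed,
                                    alpha = config$alpha))
  log <- run_log(config, list(n_dyads_analyzed = length(dyads) -
                                length(excluded),
                              excluded_dyads = excluded))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_connectivity_tsv(maps, file.path(config$out_dir,
                                           "connectivity.tsv"))
    write_stats_json(result, file.path(config$out_dir, "stats.json"))
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(group = group, result = result, maps = maps, excluded = excluded,
       log = log)
}

run_log <- function(config, extra = list()) {
  ser <- config
  ser$sim$coupling <- if (!is.null(ser$sim)) ser$sim$coupling else NULL
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  hash <- unname(tools::md5sum(tmp))
  input_hashes <- if (!is.null(config$manifest))
    as.list(tools::md5sum(config$manifest$path)) else NULL
  unlink(tmp)
  c(list(package_version = as.character(utils::packageVersion("dyadsync")),
         config_hash = hash, seed = config$seed, n_perm = config$n_perm,
         alpha = config$alpha, contrast = config$contrast,
         band = unclass(config$band), input_hashes = input_hashes,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    extra)
}

#' Correlate connectivity and behavior change scores
#'
#' For each dyad, computes the target pair's wPLI in both contrast
#' conditions and the behavioral measures (visual attention, positive
#' arousal) from the dyad's event logs, turns each into a normalized
#' change score, applies the single-pass 3-SD exclusion to every variable
#' (a dyad flagged on either member of a correlated pair is dropped from
#' that correlation), and reports the Pearson correlation of the neural
#' change score with each behavioral change score, with n before and after
#' exclusion.
#'
#' @param config a [run_config()] with a synthetic scenario (behavior logs
#'   are simulated per dyad/condition) or a manifest accompanied by
#'   `behavior_paths`: data.frame `dyad_id, condition, gaze_path,
#'   affect_path`
#' @param behavior_paths optional data.frame for file-based behavior logs
#' @return list with `neural` change scores, `behavior` change-score
#'   data.frame, `correlations` (per measure: r, df, p, n_total, n_used),
#'   `excluded`
#' @export
run_brain_behavior <- function(config, behavior_paths = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dyads <- config_dyads(config)
  neural <- numeric(); att <- numeric(); pos <- numeric()
  kept <- character()
  tgrid <- pair_grid(config$target_pair[1], config$target_pair[2])
  for (d in dyads) {
    matched <- stage("preprocess", preprocess_dyad(config, d))
    if (any(vapply(matched, `[[`, TRUE, "excluded"))) next
    w <- vapply(config$contrast, function(cond)
      wpli(epoch_cross_spectra(matched[[cond]], tgrid, config$band,
                               config$min_epochs))$values[1, 1], 0)
    beh <- lapply(config$contrast, function(cond) {
      if (!is.null(config$sim)) {
        idx <- as.integer(sub("^dyad0*", "", d))
        simulate_behavior(config$sim, cond, dyad_index = idx)
      } else {
        row <- behavior_paths[behavior_paths$dyad_id == d &
                                behavior_paths$condition == cond, ]
        if (nrow(row) != 1) stop("behavior logs missing for ", d, "/", cond)
        list(gaze = read_event_log(row$gaze_path, "gaze"),
             affect = read_event_log(row$affect_path, "affect"))
      }
    })
    a <- vapply(beh, function(b)
      visual_attention(b$gaze, b$affect), 0)
    p <- vapply(beh, function(b) positive_arousal(b$affect), 0)
    neural <- c(neural, change_score(w[2], w[1]))
    att <- c(att, change_score(a[2], a[1]))
    pos <- c(pos, change_score(p[2], p[1]))
    kept <- c(kept, d)
  }
  n_total <- length(kept)
  if (n_total < 3) stop("[permstats] fewer than 3 dyads with complete data")
  correlate <- function(b) {
    drop <- exclude_3sd(neural) | exclude_3sd(b)
    if (sum(!drop) < 3)
      stop("[permstats] fewer than 3 dyads after 3-SD exclusion")
    ct <- pearson(neural[!drop], b[!drop])
    c(ct, list(n_total = n_total, n_used = sum(!drop),
               excluded = kept[drop]))
  }
  list(neural = stats::setNames(neural, kept),
       behavior = data.frame(dyad_id = kept, visual_attention = att,
                             positive_arousal = pos),
       correlations = list(visual_attention = correlate(att),
                           positive_arousal = correlate(pos)))
}
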