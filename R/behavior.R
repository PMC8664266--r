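GAZE_CODES <- c("social gaze", "gaze to object", "joint attention",
                "gaze aversion", "gaze to environment", "drowsy/tired",
                "uncodable gaze")
AFFECT_CODES <- c("positive", "neutral", "negative", "uncodable")

#' Behavioral event log
#'
#' A validated set of coded, non-overlapping intervals on one coding
#' channel (`gaze` or `affect`), covering a session of known duration.
#' Codes must come from the channel's inventory; time not covered by any
#' interval is treated as uncodable downstream (with a warning at
#' computation time).
#'
#' @param intervals data.frame with columns `code`, `onset`, `offset`
#'   (seconds)
#' @param channel `"gaze"` or `"affect"`
#' @param session_duration session length in seconds (default: max offset)
#' @return an `EventLog`
#' @export
event_log <- function(intervals, channel, session_duration = NULL) {
  channel <- match.arg(channel, c("gaze", "affect"))
  stopifnot(all(c("code", "onset", "offset") %in% names(intervals)))
  inv <- if (channel == "gaze") GAZE_CODES else AFFECT_CODES
  if (nrow(intervals)) {
    bad <- setdiff(unique(intervals$code), inv)
    if (length(bad)) stop("unknown ", channel, " code(s): ",
                          paste(bad, collapse = ", "))
    if (any(intervals$onset < 0)) stop("negative onset time")
    if (any(intervals$onset >= intervals$offset))
      stop("each interval must have onset < offset")
    o <- order(intervals$onset)
    intervals <- intervals[o, , drop = FALSE]
    if (nrow(intervals) > 1 &&
        any(intervals$onset[-1] < intervals$offset[-nrow(intervals)] - 1e-9))
      stop("overlapping intervals within one channel")
  }
  if (is.null(session_duration))
    session_duration <- if (nrow(intervals)) max(intervals$offset) else 0
  structure(list(channel = channel, intervals = intervals,
                 session_duration = session_duration),
            class = "EventLog")
}

#' Read an event log from CSV
#'
#' Expects a header row `code,onset_s,offset_s`. Unknown codes,
#' within-channel overlaps and negative times are rejected.
#'
#' @param path CSV path
#' @param channel `"gaze"` or `"affect"`
#' @param session_duration optional known session length
#' @return an `EventLog`
#' @export
read_event_log <- function(path, channel, session_duration = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "onset_s", "offset_s") %in% names(df)))
    stop("event log must have columns code,onset_s,offset_s")
  event_log(data.frame(code = df$code, onset = df$onset_s,
                       offset = df$offset_s), channel, session_duration)
}

#' Write an event log to CSV
#' @param log an `EventLog`
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_event_log <- function(log, path) {
  utils::write.csv(data.frame(code = log$intervals$code,
                              onset_s = log$intervals$onset,
                              offset_s = log$intervals$offset),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- interval algebra ---------------------------------------------------

# Merge a two-column matrix/data.frame of [onset, offset) intervals into a
# disjoint sorted set.
iv_merge <- function(iv) {
  if (!nrow(iv)) return(matrix(numeric(), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + 1e-12)
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    else out <- rbind(out, iv[i, ])
  }
  out
}

iv_length <- function(iv) if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0

iv_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(), ncol = 2))
  out <- matrix(numeric(), ncol = 2)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) out <- rbind(out, c(lo, hi))
  }
  iv_merge(out)
}

iv_union <- function(a, b) iv_merge(rbind(a, b))

# Disjoint merged intervals carrying the given codes in a log.
log_intervals <- function(log, codes) {
  iv <- log$intervals[log$intervals$code %in% codes, c("onset", "offset"),
                      drop = FALSE]
  iv_merge(as.matrix(iv))
}

# Time in [0, duration] not covered by any interval (treated as uncodable).
log_gaps <- function(log) {
  cov <- iv_merge(as.matrix(log$intervals[c("onset", "offset")]))
  gaps <- matrix(numeric(), ncol = 2)
  t <- 0
  for (i in seq_len(nrow(cov))) {
    if (cov[i, 1] > t + 1e-12) gaps <- rbind(gaps, c(t, cov[i, 1]))
    t <- max(t, cov[i, 2])
  }
  if (t < log$session_duration - 1e-12)
    gaps <- rbind(gaps, c(t, log$session_duration))
  gaps
}

warn_coverage <- function(log) {
  gap <- iv_length(log_gaps(log))
  codable <- log$session_duration - gap -
    iv_length(log_intervals(log, c("uncodable gaze", "uncodable")))
  if (codable < 0.5 * log$session_duration)
    warning(sprintf("%s channel: codable time below 50%% of the session",
                    log$channel))
  if (gap > 1e-9)
    warning(sprintf("%s channel: %.1f s uncovered, treated as uncodable",
                    log$channel, gap))
  invisible(gap)
}

#' Infant visual attention proportion
#'
#' Proportion of codable session time the infant gazed at the adult's face:
#' numerator is the time in social gaze or joint attention, minus its
#' overlap with negative affect (crying/fussing); denominator is the
#' session minus uncodable gaze time (including uncovered gaps) minus
#' negative-affect time, the two subtracted as a union so overlap is
#' counted once.
#'
#' @param gaze,affect `EventLog`s covering the same session
#' @return proportion in \[0, 1\]
#' @export
visual_attention <- function(gaze, affect) {
  stopifnot(inherits(gaze, "EventLog"), inherits(affect, "EventLog"))
  if (abs(gaze$session_duration - affect$session_duration) > 1e-9)
    stop("gaze and affect logs cover different sessions")
  warn_coverage(gaze)
  attend <- log_intervals(gaze, c("social gaze", "joint attention"))
  neg <- log_intervals(affect, "negative")
  unc <- iv_union(log_intervals(gaze, "uncodable gaze"), log_gaps(gaze))
  num <- iv_length(attend) - iv_length(iv_intersect(attend, neg))
  den <- gaze$session_duration - iv_length(iv_union(unc, neg))
  if (den <= 1e-12) stop("no codable time: denominator is not positive")
  num / den
}

#' Infant positive arousal proportion
#'
#' Time in positive affect divided by the session's codable affect time
#' (session minus uncodable affect, including uncovered gaps).
#'
#' @param affect an `EventLog` on the affect channel
#' @return proportion in \[0, 1\]
#' @export
positive_arousal <- function(affect) {
  stopifnot(inherits(affect, "EventLog"))
  warn_coverage(affect)
  pos <- iv_length(log_intervals(affect, "positive"))
  unc <- iv_union(log_intervals(affect, "uncodable"), log_gaps(affect))
  den <- affect$session_duration - iv_length(unc)
  if (den <= 1e-12) stop("no codable time: denominator is not positive")
  pos / den
}

CIB_SAFETY_ITEMS <- c("supportive_presence", "positive_affect",
                      "initiation", "lead_interaction", "reciprocity",
                      "adaptation_regulation", "tension")

#' Infant safety composite from global interaction codes
#'
#' Seven 5-point Likert items — adult supportive presence, infant positive
#' affect, infant initiation, infant lead of the interaction, dyadic
#' reciprocity, dyadic adaptation/regulation, and dyadic tension — are
#' averaged after reversing tension (`6 - x`) so all items point in the
#' same (safer) direction.
#'
#' @param items named numeric vector or list with exactly the seven items
#'   (`supportive_presence`, `positive_affect`, `initiation`,
#'   `lead_interaction`, `reciprocity`, `adaptation_regulation`,
#'   `tension`), each in \[1, 5\]
#' @return composite mean in \[1, 5\]
#' @export
cib_safety <- function(items) {
  items <- unlist(items)
  miss <- setdiff(CIB_SAFETY_ITEMS, names(items))
  if (length(miss)) stop("missing CIB item(s): ", paste(miss, collapse = ", "))
  v <- items[CIB_SAFETY_ITEMS]
  if (any(v < 1 | v > 5)) stop("CIB items must lie in [1, 5]")
  v["tension"] <- 6 - v["tension"]
  mean(v)
}
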