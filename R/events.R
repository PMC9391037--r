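#' Movement event tables
#'
#' A movement event is one scored interval during which the fetal mouth was
#' open (orofacial) or the head was away from baseline (head). Events live
#' on an integer frame timeline at 30 Hz, closed on both ends: the onset is
#' the first frame where the jaws separated, the offset the frame where
#' they fully came back together. Events truncated because the face left
#' view carry `partial = TRUE`.
#'
#' @param session_id,pregnancy_id identifiers (recycled to length).
#' @param gestational_day integer gestational day (embryonic day E).
#' @param kind `"orofacial"` or `"head"`.
#' @param onset,offset frame indices (non-negative integers, offset >= onset).
#' @param partial logical, movement truncated by loss of view.
#' @return A `data.frame` with one row per event.
#' @export
movement_events <- function(session_id, pregnancy_id, gestational_day,
                            kind, onset, offset, partial = FALSE) {
  n <- length(onset)
  kind <- match.arg(kind, c("orofacial", "head"), several.ok = TRUE)
  ev <- data.frame(
    session_id = rep_len(as.character(session_id), n),
    pregnancy_id = rep_len(as.character(pregnancy_id), n),
    gestational_day = rep_len(as.integer(gestational_day), n),
    kind = rep_len(kind, n),
    onset = as.integer(onset),
    offset = as.integer(offset),
    partial = rep_len(as.logical(partial), n),
    stringsAsFactors = FALSE
  )
  validate_events(ev)
  ev
}

validate_events <- function(ev) {
  stopifnot(is.data.frame(ev))
  need <- c("onset", "offset", "kind", "partial")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event table lacks columns: ", paste(miss, collapse = ", "))
  if (any(ev$onset < 0)) stop("negative onset frame")
  bad <- which(ev$offset < ev$onset)
  if (length(bad)) {
    stop("offset precedes onset for event row(s) ", paste(bad, collapse = ", "))
  }
  invisible(ev)
}

#' Merge same-kind events into movement units (bouts)
#'
#' Individual movements separated by gaps of at most `gap_threshold_frames`
#' frames (default 15 frames = 500 ms at 30 Hz, the criterion that splits
#' the bimodal inter-syllable interval distribution of neonatal marmoset
#' calls) belong to the same movement unit. The gap between consecutive
#' events is `next onset - previous offset` in frames; a gap exactly equal
#' to the threshold merges. Each constituent movement is one "syllable" of
#' the unit, and a unit is partial if any constituent is.
#'
#' @param events data.frame of events of a single kind, sorted by onset and
#'   non-overlapping (a negative gap is an error naming the offending pair).
#' @param gap_threshold_frames non-negative integer merge threshold.
#' @return A unit table: `onset`, `offset` (frames), `duration_s`,
#'   `syllable_count`, `partial`, plus any `session_id`/`pregnancy_id`/
#'   `gestational_day`/`kind` columns carried over.
#' @examples
#' ev <- movement_events("s1", "p1", 100, "orofacial",
#'                       onset = c(0, 25), offset = c(10, 40))
#' merge_events(ev)  # gap of 15 frames: one unit, two syllables
#' @export
merge_events <- function(events, gap_threshold_frames = 15L) {
  validate_events(events)
  stopifnot(gap_threshold_frames >= 0)
  if (length(unique(events$kind)) > 1) {
    stop("merge_events expects events of a single kind")
  }
  n <- nrow(events)
  if (n == 0) return(empty_units(events))
  if (is.unsorted(events$onset)) {
    i <- which(diff(events$onset) < 0)[1]
    stop("events not sorted by onset: rows ", i, " and ", i + 1)
  }
  if (n > 1) {
    gaps <- events$onset[-1] - events$offset[-n]
    if (any(gaps < 0)) {
      i <- which(gaps < 0)[1]
      stop("overlapping same-kind events: rows ", i, " and ", i + 1,
           " (onset ", events$onset[i + 1], " < offset ", events$offset[i], ")")
    }
    unit_id <- cumsum(c(1L, as.integer(gaps > gap_threshold_frames)))
  } else {
    unit_id <- 1L
  }
  onset <- as.integer(tapply(events$onset, unit_id, min))
  offset <- as.integer(tapply(events$offset, unit_id, max))
  units <- data.frame(
    onset = onset,
    offset = offset,
    duration_s = frames_to_seconds(offset - onset),
    syllable_count = as.integer(tapply(events$partial, unit_id, length)),
    partial = as.logical(tapply(events$partial, unit_id, any)),
    stringsAsFactors = FALSE
  )
  for (col in c("session_id", "pregnancy_id", "gestational_day", "kind")) {
    if (col %in% names(events)) units[[col]] <- events[[col]][1]
  }
  units
}

empty_units <- function(events = NULL) {
  u <- data.frame(
    onset = integer(0), offset = integer(0), duration_s = numeric(0),
    syllable_count = integer(0), partial = logical(0),
    stringsAsFactors = FALSE
  )
  if (!is.null(events)) {
    for (col in c("session_id", "pregnancy_id", "gestational_day", "kind")) {
      if (col %in% names(events)) u[[col]] <- events[[col]][0]
    }
  }
  u
}

#' Construct a recording session
#'
#' A session bundles the merged orofacial and head movement units observed
#' during the face-visible footage of one ultrasound visit.
#'
#' @param session_id,pregnancy_id identifiers.
#' @param gestational_day integer embryonic day.
#' @param visible_time_s seconds of usable face-visible footage (> 0).
#' @param orofacial_units,head_units unit tables from [merge_events()].
#' @return An object of class `fv_session`.
#' @export
fv_session <- function(session_id, pregnancy_id, gestational_day,
                       visible_time_s, orofacial_units = empty_units(),
                       head_units = empty_units()) {
  if (!is.numeric(visible_time_s) || visible_time_s <= 0) {
    stop("visible_time_s must be positive")
  }
  span <- visible_time_s * FRAME_RATE
  for (u in list(orofacial_units, head_units)) {
    if (nrow(u) && (any(u$onset < 0) || any(u$offset > span))) {
      stop("unit interval outside [0, visible_time_s * 30]")
    }
  }
  structure(
    list(
      session_id = as.character(session_id),
      pregnancy_id = as.character(pregnancy_id),
      gestational_day = as.integer(gestational_day),
      visible_time_s = as.numeric(visible_time_s),
      orofacial_units = orofacial_units,
      head_units = head_units
    ),
    class = "fv_session"
  )
}

#' @export
print.fv_session <- function(x, ...) {
  cat(sprintf(
    "<fv_session %s | pregnancy %s | E%d | %.0f s visible | %d orofacial, %d head units>\n",
    x$session_id, x$pregnancy_id, x$gestational_day, x$visible_time_s,
    nrow(x$orofacial_units), nrow(x$head_units)
  ))
  invisible(x)
}

#' Movement rate of a session
#'
#' Number of movement units per hour of face-visible footage. Partially
#' captured units count: truncation removes duration information, not the
#' fact that a movement occurred.
#'
#' @param session an `fv_session`.
#' @param kind `"orofacial"` or `"head"`.
#' @return movements per hour.
#' @export
movement_rate <- function(session, kind = c("orofacial", "head")) {
  kind <- match.arg(kind)
  if (session$visible_time_s <= 0) stop("zero visible time")
  units <- if (kind == "orofacial") session$orofacial_units else session$head_units
  nrow(units) / (session$visible_time_s / 3600)
}

#' Durations of movement units
#'
#' Partially captured units are excluded by default: the fetus moved out of
#' focus while the mouth was still open, so their durations are censored.
#'
#' @param units a unit table.
#' @param exclude_partial drop partial units first (default `TRUE`).
#' @return numeric vector of durations in seconds.
#' @export
unit_durations <- function(units, exclude_partial = TRUE) {
  if (exclude_partial) units <- units[!units$partial, , drop = FALSE]
  units$duration_s
}
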