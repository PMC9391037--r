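#' Duration-by-syllable criteria boxes
#'
#' A criteria box is a closed duration range (seconds) crossed with a
#' closed integer syllable-number range; a criterion may be a union of
#' boxes (the lick signature is bimodal: short few-syllable licks and very
#' long many-syllable licks).
#'
#' @param name criterion name.
#' @param duration_range numeric `c(lo, hi)` in seconds, or a list of such
#'   ranges (one per union member).
#' @param syllable_range integer `c(lo, hi)`, or a list parallel to
#'   `duration_range`.
#' @return An `fv_criteria` object.
#' @export
criteria_box <- function(name, duration_range, syllable_range) {
  if (!is.list(duration_range)) duration_range <- list(duration_range)
  if (!is.list(syllable_range)) syllable_range <- list(syllable_range)
  stopifnot(length(duration_range) == length(syllable_range))
  boxes <- Map(function(d, s) {
    stopifnot(length(d) == 2, length(s) == 2, d[1] <= d[2], s[1] <= s[2])
    list(duration = as.numeric(d), syllables = as.numeric(s))
  }, duration_range, syllable_range)
  structure(list(name = name, boxes = boxes), class = "fv_criteria")
}

#' @export
print.fv_criteria <- function(x, ...) {
  cat("<fv_criteria ", x$name, ">\n", sep = "")
  for (b in x$boxes) {
    cat(sprintf("  duration [%.3g, %.3g] s x syllables [%d, %d]\n",
                b$duration[1], b$duration[2], b$syllables[1], b$syllables[2]))
  }
  invisible(x)
}

#' Infant call signature criteria
#'
#' The duration/syllable signatures derived from P1(-7) infant recordings:
#' contact calls 3.69-6.5 s and 5-9 syllables; twitters 0.96-1.5 s and 2-3
#' syllables; licks the union of a short box (0.33-3.77 s, 1-6 syllables)
#' and a long box (6.67-14.29 s, 10-16 syllables). All bounds are closed.
#'
#' @return named list of `fv_criteria`: `contact`, `twitter`, `lick`.
#' @export
default_criteria <- function() {
  list(
    contact = criteria_box("contact", c(3.69, 6.5), c(5, 9)),
    twitter = criteria_box("twitter", c(0.96, 1.5), c(2, 3)),
    lick = criteria_box("lick",
                        list(c(0.33, 3.77), c(6.67, 14.29)),
                        list(c(1, 6), c(10, 16)))
  )
}

#' Membership of (duration, syllable) points in a criteria box
#'
#' @param duration_s,syllables numeric vectors (recycled to equal length).
#' @param criteria an `fv_criteria`.
#' @return logical vector: inside any union member (closed bounds).
#' @export
in_criteria <- function(duration_s, syllables, criteria) {
  n <- max(length(duration_s), length(syllables))
  duration_s <- rep_len(duration_s, n)
  syllables <- rep_len(syllables, n)
  inside <- rep(FALSE, n)
  for (b in criteria$boxes) {
    inside <- inside |
      (duration_s >= b$duration[1] & duration_s <= b$duration[2] &
         syllables >= b$syllables[1] & syllables <= b$syllables[2])
  }
  inside
}

#' Geometric overlap of two criteria
#'
#' Reports every pairwise intersection of the union members of two
#' criteria (closed boxes intersect iff both their duration and syllable
#' ranges intersect).
#'
#' @param a,b `fv_criteria` objects.
#' @return list: `disjoint` (logical) and `regions`, a list of intersecting
#'   duration/syllable rectangles (empty when disjoint).
#' @export
criteria_overlap <- function(a, b) {
  regions <- list()
  for (ba in a$boxes) {
    for (bb in b$boxes) {
      dlo <- max(ba$duration[1], bb$duration[1])
      dhi <- min(ba$duration[2], bb$duration[2])
      slo <- max(ba$syllables[1], bb$syllables[1])
      shi <- min(ba$syllables[2], bb$syllables[2])
      if (dlo <= dhi && slo <= shi) {
        regions[[length(regions) + 1]] <-
          list(duration = c(dlo, dhi), syllables = c(slo, shi))
      }
    }
  }
  list(disjoint = length(regions) == 0, regions = regions)
}

#' Syllable count of a complete movement unit
#'
#' Number of constituent mouth movements. Partially captured units are
#' rejected for this statistic (their trailing syllables were lost with
#' the view).
#'
#' @param unit one row of a unit table.
#' @return integer.
#' @export
count_syllables <- function(unit) {
  if (isTRUE(unit$partial)) stop("partial unit: syllable count is censored")
  as.integer(unit$syllable_count)
}

#' Likelihood that an in-box call is of a given type
#'
#' Among all labeled infant calls whose duration and syllable number fall
#' inside the criteria box, the fraction carrying the target type label
#' (e.g. the 97% contact-call likelihood of the contact box).
#'
#' @param calls data.frame with columns `type`, `duration_s`,
#'   `syllable_count`.
#' @param criteria an `fv_criteria`.
#' @param target_type type label.
#' @return fraction in \[0, 1\]; `NA` (with a warning) when no call falls
#'   inside the box.
#' @export
type_likelihood <- function(calls, criteria, target_type) {
  inside <- in_criteria(calls$duration_s, calls$syllable_count, criteria)
  if (!any(inside)) {
    warning("no call falls inside the criteria box; likelihood undefined")
    return(NA_real_)
  }
  mean(calls$type[inside] == target_type)
}

#' Percentage of a session's movements matching a call signature
#'
#' Fraction (x 100) of the session's complete (non-partial) orofacial
#' movement units whose duration and syllable number fall inside the
#' criteria box.
#'
#' @param session an `fv_session`.
#' @param criteria an `fv_criteria`.
#' @return percentage in \[0, 100\]; `NA` when the session has no complete
#'   unit.
#' @export
percent_match <- function(session, criteria) {
  units <- session$orofacial_units
  units <- units[!units$partial, , drop = FALSE]
  if (!nrow(units)) return(NA_real_)
  100 * mean(in_criteria(units$duration_s, units$syllable_count, criteria))
}

#' Cohort percent-match table
#'
#' @param sessions list of `fv_session`.
#' @param criteria an `fv_criteria` or named list of them.
#' @return data.frame with `session_id`, `pregnancy_id`, `gestational_day`
#'   and one percent-match column per criterion.
#' @export
percent_match_table <- function(sessions, criteria = default_criteria()) {
  if (inherits(criteria, "fv_criteria")) {
    criteria <- stats::setNames(list(criteria), criteria$name)
  }
  out <- data.frame(
    session_id = vapply(sessions, `[[`, character(1), "session_id"),
    pregnancy_id = vapply(sessions, `[[`, character(1), "pregnancy_id"),
    gestational_day = vapply(sessions, `[[`, integer(1), "gestational_day"),
    stringsAsFactors = FALSE
  )
  for (nm in names(criteria)) {
    out[[paste0("pct_", nm)]] <-
      vapply(sessions, percent_match, numeric(1), criteria[[nm]])
  }
  out
}

#' Reconcile audio call durations with video durations
#'
#' Audio and video measure call duration slightly differently (voicing
#' onset vs jaw separation). From calls measured in both modalities the
#' median duration discrepancy (video minus audio) is computed and added
#' to every audio-only duration.
#'
#' @param audio_duration,video_duration paired durations (seconds) of the
#'   calls captured in both modalities.
#' @param audio_only durations measured in audio alone.
#' @return list: `delta` (median discrepancy) and `adjusted` durations.
#' @export
adjust_audio_durations <- function(audio_duration, video_duration, audio_only) {
  stopifnot(length(audio_duration) == length(video_duration))
  if (!length(audio_duration)) stop("no paired audio/video durations")
  delta <- median(video_duration - audio_duration)
  list(delta = delta, adjusted = audio_only + delta)
}

#' Derive a criteria box from labeled infant calls
#'
#' Grid search over candidate closed duration and syllable bounds
#' maximizing the target-type likelihood of the box — i.e. the maximum
#' possible separation from the other call types — subject to the box
#' capturing at least `min_capture` of the target-type calls. Duration
#' candidates are quantiles of the target calls' observed durations;
#' syllable candidates the observed integer range.
#'
#' @param calls data.frame with `type`, `duration_s`, `syllable_count`.
#' @param target_type type to isolate.
#' @param min_capture minimum fraction of target calls the box must retain
#'   (default 0.5).
#' @param n_quantiles duration grid resolution per side (default 21).
#' @return list: `criteria` (an `fv_criteria`), `likelihood`, `capture`.
#' @export
derive_criteria <- function(calls, target_type, min_capture = 0.5,
                            n_quantiles = 21) {
  tgt <- calls[calls$type == target_type, , drop = FALSE]
  if (!nrow(tgt)) stop("no calls of the target type")
  lo_grid <- unique(quantile(tgt$duration_s, seq(0, 0.5, length.out = n_quantiles)))
  hi_grid <- unique(quantile(tgt$duration_s, seq(0.5, 1, length.out = n_quantiles)))
  s_rng <- range(tgt$syllable_count)
  best <- NULL
  for (dlo in lo_grid) for (dhi in hi_grid) {
    for (slo in s_rng[1]:s_rng[2]) for (shi in slo:s_rng[2]) {
      box <- criteria_box(target_type, c(dlo, dhi), c(slo, shi))
      cap <- mean(in_criteria(tgt$duration_s, tgt$syllable_count, box))
      if (cap < min_capture) next
      inside <- in_criteria(calls$duration_s, calls$syllable_count, box)
      lik <- mean(calls$type[inside] == target_type)
      if (is.null(best) || lik > best$likelihood ||
          (lik == best$likelihood && cap > best$capture)) {
        best <- list(criteria = box, likelihood = lik, capture = cap)
      }
    }
  }
  best
}
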