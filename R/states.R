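STATE_LEVELS <- c("S1", "S2", "S3", "S4", "S5")

#' Classify movement occurrences into the five co-occurrence states
#'
#' Each movement occurrence is one of: S1 isolated orofacial movement, S2
#' isolated head movement, S3 orofacial movement joined by an overlapping
#' head movement (orofacial onset strictly first, head onset strictly
#' inside the orofacial interval), S4 the converse (head leads), S5
#' synchronous onsets (same frame). An overlapping orofacial-head pair is a
#' single occurrence; a unit overlapping several units of the other kind is
#' paired with the first unused overlapper and its remaining overlaps are
#' ignored, so every unit contributes to exactly one occurrence.
#' Occurrences are anchored at the earlier onset of the pair.
#'
#' @param orofacial_units,head_units unit tables sorted by onset
#'   (non-overlapping within kind), e.g. from [merge_events()]. Partial
#'   units are included: state coding needs only onsets/offsets.
#' @return A data.frame with columns `state` (factor over S1..S5) and
#'   `anchor` (frame), ordered by anchor.
#' @examples
#' oro <- data.frame(onset = 0L, offset = 100L)
#' head <- data.frame(onset = 50L, offset = 160L)
#' classify_states(oro, head)  # one occurrence, S3
#' @export
classify_states <- function(orofacial_units, head_units) {
  res <- cpp_pair_states(
    as.integer(orofacial_units$onset), as.integer(orofacial_units$offset),
    as.integer(head_units$onset), as.integer(head_units$offset)
  )
  data.frame(
    state = factor(STATE_LEVELS[res$state], levels = STATE_LEVELS),
    anchor = as.integer(res$anchor),
    stringsAsFactors = FALSE
  )
}

#' State occurrences of a session
#'
#' @param session an `fv_session`.
#' @return as [classify_states()], with `session_id` and `gestational_day`
#'   columns added.
#' @export
session_states <- function(session) {
  st <- classify_states(session$orofacial_units, session$head_units)
  if (nrow(st)) {
    st$session_id <- session$session_id
    st$gestational_day <- session$gestational_day
  }
  st
}

#' Empirical state distribution
#'
#' Frequency of occurrence of each of the five states. An empty sequence
#' yields an all-`NA` vector flagged with `attr(, "n") = 0`; consumers
#' (entropy, divergence, baselines) skip such sessions.
#'
#' @param states data.frame from [classify_states()], or a factor/character
#'   vector of state labels.
#' @return named numeric vector of length 5 summing to 1, with attribute
#'   `n` = number of occurrences.
#' @export
state_distribution <- function(states) {
  labels <- if (is.data.frame(states)) states$state else states
  labels <- factor(labels, levels = STATE_LEVELS)
  n <- length(labels)
  if (n == 0) {
    p <- rep(NA_real_, 5)
    names(p) <- STATE_LEVELS
  } else {
    p <- as.vector(table(labels)) / n
    names(p) <- STATE_LEVELS
  }
  attr(p, "n") <- n
  p
}

#' First-order Markov transition matrix of a state sequence
#'
#' `m[i, j]` is the frequency of transitions from state i to state j among
#' all transitions leaving i. Rows never observed as a source are all zero.
#'
#' @inheritParams state_distribution
#' @return 5 x 5 matrix with rows/columns named S1..S5; rows with any mass
#'   sum to 1.
#' @export
transition_matrix <- function(states) {
  labels <- if (is.data.frame(states)) states$state else states
  labels <- factor(labels, levels = STATE_LEVELS)
  m <- matrix(0, 5, 5, dimnames = list(STATE_LEVELS, STATE_LEVELS))
  n <- length(labels)
  if (n >= 2) {
    from <- as.integer(labels[-n])
    to <- as.integer(labels[-1])
    for (k in seq_along(from)) m[from[k], to[k]] <- m[from[k], to[k]] + 1
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  m
}
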