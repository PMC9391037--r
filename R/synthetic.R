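#' Cohort generator specification
#'
#' Defines the statistical structure of a synthetic fetal-movement cohort:
#' per-gestational-day schedules for orofacial rate (inverse-U, peaking
#' mid-observation), head rate (linear decline), orofacial-head coupling
#' (linear decline from strong early coupling to near independence at
#' term), and the fraction of orofacial units shaped like contact calls
#' (rising toward term, which also raises durations and syllable counts).
#' Defaults mirror the qualitative shapes reported for the study cohort:
#' four pregnancies, 16 sessions each on alternate days E93-146, with a
#' few percent of units partially captured.
#'
#' @param n_pregnancies number of pregnancies (default 4).
#' @param sessions_per_pregnancy sessions per pregnancy (default 16; 64
#'   sessions total).
#' @param day_range gestational-day span of testing (default E93-146).
#' @param visible_time_s usable face-visible footage per session (default
#'   900 s).
#' @param orofacial_rate,head_rate functions day -> movements per hour.
#' @param coupling function day -> probability in \[0, 1\] that a head unit
#'   is onset-coupled inside an orofacial unit.
#' @param contact_fraction function day -> probability that an orofacial
#'   unit is contact-call-shaped (5-9 syllables, 3.7-6.5 s).
#' @param partial_prob probability a unit is flagged partially captured.
#' @return An `fv_cohort_spec` (a list).
#' @export
cohort_spec <- function(n_pregnancies = 4,
                        sessions_per_pregnancy = 16,
                        day_range = c(93, 146),
                        visible_time_s = 900,
                        orofacial_rate = function(day)
                          pmax(40 + 80 * (1 - ((day - 118) / 28)^2), 10),
                        head_rate = function(day)
                          pmax(60 - (day - 93) * 45 / 53, 5),
                        coupling = function(day)
                          pmin(pmax(0.8 - (day - 93) * 0.7 / 53, 0), 1),
                        contact_fraction = function(day)
                          pmin(pmax(0.05 + (day - 93) * 0.30 / 53, 0), 1),
                        partial_prob = 0.07) {
  stopifnot(day_range[1] >= 90, day_range[2] <= 147,
            partial_prob >= 0, partial_prob <= 1, visible_time_s > 0)
  structure(
    list(
      n_pregnancies = n_pregnancies,
      sessions_per_pregnancy = sessions_per_pregnancy,
      day_range = day_range,
      visible_time_s = visible_time_s,
      orofacial_rate = orofacial_rate,
      head_rate = head_rate,
      coupling = coupling,
      contact_fraction = contact_fraction,
      partial_prob = partial_prob
    ),
    class = "fv_cohort_spec"
  )
}

# Syllable-resolved orofacial unit: returns event (onset, offset) frames
# relative to the unit onset. Contact-shaped units draw total duration on
# the frame grid inside 3.7-6.5 s with 5-9 syllables; background units are
# short bouts of 1-4 cycles. Intra-unit gaps are always <= 14 frames so
# the merge rule reassembles the unit exactly.
r_unit_shape <- function(contact_shaped) {
  if (contact_shaped) {
    k <- sample(5:9, 1)
    total <- sample(111:195, 1)
    gaps <- if (k > 1) sample(4:10, k - 1, replace = TRUE) else integer(0)
  } else {
    k <- sample(1:4, 1, prob = c(0.45, 0.3, 0.15, 0.1))
    gaps <- if (k > 1) sample(4:14, k - 1, replace = TRUE) else integer(0)
    total <- sum(gaps) + sum(sample(6:27, k, replace = TRUE))
  }
  rem <- total - sum(gaps) - 2L * k
  extra <- if (rem > 0) drop(stats::rmultinom(1, rem, rep(1, k))) else rep(0L, k)
  cyc <- 2L + extra
  on <- cumsum(c(0L, cyc[-k] + gaps))
  list(onset = on, offset = on + cyc, total = sum(cyc) + sum(gaps))
}

# Renewal placement: lay n units of the given total lengths into
# [0, span] with iid exponential gaps; units past the span are dropped.
place_renewal <- function(lengths, span) {
  n <- length(lengths)
  if (n == 0) return(integer(0))
  free <- span - sum(lengths)
  if (free <= 0) {
    stop("infeasible packing: requested units exceed the visible span")
  }
  gaps <- rexp(n, rate = n / free)
  onsets <- as.integer(round(cumsum(gaps) + cumsum(c(0, lengths[-n]))))
  onsets[onsets + lengths > span] <- NA_integer_
  onsets
}

#' Generate a synthetic movement-event cohort
#'
#' Produces per-session orofacial and head event streams with the
#' generative structure declared in the [cohort_spec()]: orofacial units
#' placed by a renewal process at the scheduled rate; each head unit
#' onset-coupled strictly inside a random orofacial interval with the
#' scheduled day-dependent probability, otherwise placed independently.
#' Sessions are built by running the generated events through
#' [merge_events()], so every generated artifact is a valid input to the
#' analysis stages. The full event table is attached as
#' `attr(, "events")`.
#'
#' @param spec an `fv_cohort_spec`.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @return list of `fv_session`, with attributes `events` (the event
#'   table) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- as.integer(spec$visible_time_s * FRAME_RATE)
  days <- round(seq(spec$day_range[1], spec$day_range[2],
                    length.out = spec$sessions_per_pregnancy))
  sessions <- list()
  all_events <- list()
  for (p in seq_len(spec$n_pregnancies)) {
    preg <- sprintf("P%d", p)
    for (s in seq_along(days)) {
      day <- days[s]
      sid <- sprintf("%s_E%03d", preg, day)
      hours <- spec$visible_time_s / 3600

      # orofacial stream
      n_o <- rpois(1, spec$orofacial_rate(day) * hours)
      shapes <- lapply(seq_len(n_o), function(i)
        r_unit_shape(runif(1) < spec$contact_fraction(day)))
      o_lengths <- vapply(shapes, `[[`, numeric(1), "total")
      o_starts <- place_renewal(o_lengths, span)
      keep <- !is.na(o_starts)
      shapes <- shapes[keep]
      o_starts <- o_starts[keep]
      o_events <- if (length(o_starts)) do.call(rbind, lapply(
        seq_along(o_starts), function(i) {
          data.frame(onset = o_starts[i] + shapes[[i]]$onset,
                     offset = o_starts[i] + shapes[[i]]$offset,
                     unit = i)
        })) else data.frame(onset = integer(0), offset = integer(0),
                            unit = integer(0))
      o_unit_iv <- if (length(o_starts))
        cbind(o_starts, o_starts + vapply(shapes, `[[`, numeric(1), "total"))
      else matrix(integer(0), 0, 2)

      # head stream: single-cycle units, steady duration, scheduled coupling
      n_h <- rpois(1, spec$head_rate(day) * hours)
      h_len <- pmax(as.integer(round(stats::rlnorm(n_h, log(1.2 * FRAME_RATE), 0.4))), 3L)
      coupled <- which(runif(n_h) < spec$coupling(day))
      h_on <- rep(NA_integer_, n_h)
      # couple each selected head to a distinct orofacial unit so that
      # coupled heads cannot collide with one another (collisions would
      # thin the early-gestation head stream and distort its linear rate)
      # coupling orientation: the young fetus combines the two movements
      # in all three ways (head joins an ongoing orofacial movement,
      # orofacial joins an ongoing head movement, synchronous onsets)
      n_host <- nrow(o_unit_iv)
      if (n_host > 0 && length(coupled)) {
        coupled <- coupled[seq_len(min(length(coupled), n_host))]
        hosts <- sample.int(n_host, length(coupled))
        orient <- sample(1:3, length(coupled), replace = TRUE)
        for (m in seq_along(coupled)) {
          i <- coupled[m]
          o_on_m <- o_unit_iv[hosts[m], 1]
          o_off_m <- o_unit_iv[hosts[m], 2]
          h_on[i] <- switch(orient[m],
            # head onset strictly inside the orofacial interval (S3)
            if (o_off_m - 1L >= o_on_m + 1L)
              as.integer(sample((o_on_m + 1L):(o_off_m - 1L), 1)) else NA_integer_,
            # orofacial onset strictly inside the head interval (S4)
            if (h_len[i] >= 2L && o_on_m >= 1L)
              max(o_on_m - as.integer(sample.int(h_len[i] - 1L, 1)), 0L) else NA_integer_,
            # synchronous onset (S5)
            o_on_m
          )
        }
      }
      free_idx <- which(is.na(h_on))
      if (length(free_idx)) {
        h_on[free_idx] <- place_renewal(h_len[free_idx], span)
      }
      ok <- !is.na(h_on) & (h_on + h_len) <= span
      h_on <- h_on[ok]
      h_len <- h_len[ok]
      ord <- order(h_on)
      h_on <- h_on[ord]
      h_len <- h_len[ord]
      # enforce within-kind separation by deferring colliding units past
      # the previous offset (plus the merge gap, so the unit count is
      # preserved); dropping them instead would thin the stream in
      # proportion to its density and bend the scheduled linear rate
      if (length(h_on) > 1) {
        keep_h <- rep(TRUE, length(h_on))
        last_off <- h_on[1] + h_len[1]
        for (i in 2:length(h_on)) {
          if (h_on[i] <= last_off + 15L) {
            h_on[i] <- last_off + 16L
          }
          if (h_on[i] + h_len[i] > span) {
            keep_h[i] <- FALSE
          } else {
            last_off <- h_on[i] + h_len[i]
          }
        }
        h_on <- h_on[keep_h]
        h_len <- h_len[keep_h]
      }

      ev <- rbind(
        if (nrow(o_events)) data.frame(
          session_id = sid, pregnancy_id = preg, gestational_day = day,
          kind = "orofacial", onset = as.integer(o_events$onset),
          offset = as.integer(o_events$offset),
          partial = rep(FALSE, nrow(o_events)),
          stringsAsFactors = FALSE
        ),
        if (length(h_on)) data.frame(
          session_id = sid, pregnancy_id = preg, gestational_day = day,
          kind = "head", onset = as.integer(h_on),
          offset = as.integer(h_on + h_len),
          partial = rep(FALSE, length(h_on)),
          stringsAsFactors = FALSE
        )
      )
      # partial flags are assigned per unit, so mark the last event of a
      # partial unit and propagate through the merge
      o_units <- merge_events(
        ev[ev$kind == "orofacial", , drop = FALSE][
          order(ev$onset[ev$kind == "orofacial"]), , drop = FALSE])
      h_units <- merge_events(
        ev[ev$kind == "head", , drop = FALSE][
          order(ev$onset[ev$kind == "head"]), , drop = FALSE])
      if (nrow(o_units)) {
        o_units$partial <- runif(nrow(o_units)) < spec$partial_prob
      }
      if (nrow(h_units)) {
        h_units$partial <- runif(nrow(h_units)) < spec$partial_prob
      }
      # mirror unit partial flags back onto the constituent events
      if (nrow(ev)) {
        for (kind in c("orofacial", "head")) {
          un <- if (kind == "orofacial") o_units else h_units
          if (!nrow(un)) next
          sel <- ev$kind == kind
          idx <- findInterval(ev$onset[sel], un$onset)
          ev$partial[sel] <- un$partial[pmax(idx, 1)]
        }
      }
      sessions[[sid]] <- fv_session(sid, preg, day, spec$visible_time_s,
                                    o_units, h_units)
      all_events[[sid]] <- ev
    }
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  structure(sessions, events = events, spec = spec)
}

#' Call-shaped temporal profile specification
#'
#' Describes a mouth-opening waveform as a train of raised-cosine
#' open-close cycles separated by sub-500 ms closed gaps, with optional
#' amplitude jitter, additive noise, and a smooth monotone time warp.
#' Presets reproduce the duration/syllable signatures of the infant call
#' types (durations drawn on the 30 Hz frame grid strictly inside the
#' criteria box).
#'
#' @param call_type `"custom"`, `"contact"`, `"twitter"`, `"lick_short"`
#'   or `"lick_long"`.
#' @param syllable_count integer, or range to sample from.
#' @param duration_frames total-duration frame range (overrides cycle
#'   sampling when given).
#' @param cycle_frames per-cycle frame range (used when `duration_frames`
#'   is `NULL`).
#' @param gap_frames intra-call gap frame range; must stay below 15 frames
#'   so syllables are not split into separate units.
#' @param noise_sd additive Gaussian noise sd (amplitude units; cycles
#'   have amplitude ~1).
#' @param warp_amp time-warp amplitude in (0, 0.3); 0 disables warping.
#' @param amp_jitter per-cycle amplitude jitter half-range.
#' @return An `fv_profile_spec`.
#' @export
profile_spec <- function(call_type = c("custom", "contact", "twitter",
                                       "lick_short", "lick_long"),
                         syllable_count = NULL, duration_frames = NULL,
                         cycle_frames = c(12, 22), gap_frames = c(4, 10),
                         noise_sd = 0.05, warp_amp = 0.1,
                         amp_jitter = 0.15) {
  call_type <- match.arg(call_type)
  preset <- switch(call_type,
    contact = list(syllable_count = 5:9, duration_frames = c(112, 194)),
    twitter = list(syllable_count = 2:3, duration_frames = c(29, 44)),
    lick_short = list(syllable_count = 1:6, duration_frames = c(11, 112)),
    lick_long = list(syllable_count = 10:16, duration_frames = c(201, 428)),
    custom = list(syllable_count = 3, duration_frames = NULL)
  )
  if (is.null(syllable_count)) syllable_count <- preset$syllable_count
  if (is.null(duration_frames) && call_type != "custom") {
    duration_frames <- preset$duration_frames
  }
  if (any(gap_frames >= 15)) stop("intra-call gaps must be < 15 frames")
  structure(
    list(call_type = call_type, syllable_count = syllable_count,
         duration_frames = duration_frames, cycle_frames = cycle_frames,
         gap_frames = gap_frames, noise_sd = noise_sd,
         warp_amp = warp_amp, amp_jitter = amp_jitter),
    class = "fv_profile_spec"
  )
}

#' Generate a synthetic mouth-opening profile
#'
#' Concatenates `syllable_count` raised-cosine open-close cycles with
#' closed gaps, samples at 30 Hz, applies a smooth monotone time warp and
#' additive noise. The ground-truth syllable count is attached for
#' quality-gate tests.
#'
#' @param spec an `fv_profile_spec`.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return numeric profile with attributes `syllable_count` and
#'   `duration_s`.
#' @export
generate_profile <- function(spec = profile_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- if (length(spec$syllable_count) > 1) {
    sample(spec$syllable_count, 1)
  } else {
    spec$syllable_count
  }
  gaps <- if (k > 1) {
    sample(spec$gap_frames[1]:spec$gap_frames[2], k - 1, replace = TRUE)
  } else integer(0)
  if (!is.null(spec$duration_frames)) {
    total <- sample(spec$duration_frames[1]:spec$duration_frames[2], 1)
    min_cyc <- 4L
    rem <- total - sum(gaps) - min_cyc * k
    if (rem < 0) {  # very short total: shrink gaps
      gaps <- rep(spec$gap_frames[1], length(gaps))
      rem <- max(total - sum(gaps) - min_cyc * k, 0)
    }
    cyc <- min_cyc + drop(stats::rmultinom(1, rem, rep(1, k)))
  } else {
    cyc <- sample(spec$cycle_frames[1]:spec$cycle_frames[2], k, replace = TRUE)
  }
  amps <- runif(k, 1 - spec$amp_jitter, 1 + spec$amp_jitter)
  segs <- vector("list", 2 * k - 1)
  for (j in seq_len(k)) {
    t <- seq(0, 1, length.out = cyc[j])
    segs[[2 * j - 1]] <- amps[j] * 0.5 * (1 - cos(2 * pi * t))
    if (j < k) segs[[2 * j]] <- rep(0, gaps[j])
  }
  v <- unlist(segs)
  v <- perturb_profile(v, noise_sd = spec$noise_sd, warp_amp = spec$warp_amp)
  attr(v, "syllable_count") <- as.integer(k)
  attr(v, "duration_s") <- length(v) / FRAME_RATE
  v
}

#' Warp and add noise to a profile
#'
#' Applies a smooth monotone time warp (endpoints fixed; warp amplitude
#' below 1/pi guarantees monotonicity) followed by additive Gaussian
#' noise. Used both inside [generate_profile()] and to fabricate fetal
#' profiles as perturbed copies of call templates.
#'
#' @param values numeric profile.
#' @param noise_sd additive noise sd.
#' @param warp_amp warp amplitude in \[0, 0.3\].
#' @return perturbed numeric vector of the same length.
#' @export
perturb_profile <- function(values, noise_sd = 0.05, warp_amp = 0.1) {
  n <- length(values)
  if (warp_amp > 0 && n >= 3) {
    s <- seq(0, 1, length.out = n)
    u <- runif(1, -1, 1)
    w <- s + warp_amp * u * sin(pi * s)
    values <- approx(s, values, xout = w)$y
  }
  if (noise_sd > 0) values <- values + rnorm(n, 0, noise_sd)
  values
}

#' Generate a labeled infant call table
#'
#' Draws call records whose duration and syllable-number distributions
#' mimic the P1(-7) infant repertoire: contact calls long and
#' multi-syllabic (median near 3.7 s / 5 syllables), twitters short with
#' 2-3 syllables, licks bimodal (mostly short few-syllable movements with
#' a long many-syllable tail).
#'
#' @param n named vector of counts per type (defaults: 120 contact, 109
#'   twitter, 37 lick).
#' @param seed integer seed (`NULL` = current RNG state).
#' @return data.frame: `call_id`, `type`, `duration_s`, `syllable_count`,
#'   `modality`.
#' @export
generate_infant_calls <- function(n = c(contact = 120, twitter = 109,
                                        lick = 37), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  if (!is.na(n["contact"]) && n["contact"] > 0) {
    m <- n[["contact"]]
    rows$contact <- data.frame(
      type = "contact",
      duration_s = pmin(pmax(stats::rlnorm(m, log(3.9), 0.22), 1.2), 8),
      syllable_count = pmin(pmax(round(rnorm(m, 5.4, 1.4)), 1), 10),
      stringsAsFactors = FALSE
    )
  }
  if (!is.na(n["twitter"]) && n["twitter"] > 0) {
    m <- n[["twitter"]]
    rows$twitter <- data.frame(
      type = "twitter",
      duration_s = pmin(pmax(rnorm(m, 1.2, 0.22), 0.4), 2.6),
      syllable_count = sample(1:4, m, replace = TRUE,
                              prob = c(0.12, 0.42, 0.36, 0.10)),
      stringsAsFactors = FALSE
    )
  }
  if (!is.na(n["lick"]) && n["lick"] > 0) {
    m <- n[["lick"]]
    long <- runif(m) < 0.18
    dur <- ifelse(long, runif(m, 6.8, 14.2),
                  pmin(pmax(stats::rlnorm(m, log(1.5), 0.55), 0.33), 3.7))
    syl <- ifelse(long, sample(10:16, m, replace = TRUE),
                  pmin(pmax(round(stats::rlnorm(m, log(2), 0.5)), 1), 6))
    rows$lick <- data.frame(
      type = "lick", duration_s = dur, syllable_count = as.integer(syl),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cbind(call_id = sprintf("C%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out$modality <- "audio"
  out
}
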