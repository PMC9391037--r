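#' Percent overlap of orofacial and head movements
#'
#' Total instances of overlap (states S3, S4, S5: one per overlapping
#' orofacial-head pair, synchronous onsets included) divided by the total
#' number of movement units of both kinds.
#'
#' @param session an `fv_session`.
#' @return fraction in \[0, 1\]; `NA` for a session without any unit.
#' @export
percent_overlap <- function(session) {
  n_o <- nrow(session$orofacial_units)
  n_h <- nrow(session$head_units)
  if (n_o + n_h == 0) return(NA_real_)
  n_ov <- cpp_overlap_count(
    as.integer(session$orofacial_units$onset),
    as.integer(session$orofacial_units$offset),
    as.integer(session$head_units$onset),
    as.integer(session$head_units$offset)
  )
  n_ov / (n_o + n_h)
}

#' Per-session overlap table for a cohort
#'
#' @param sessions list of `fv_session` objects.
#' @return data.frame: `session_id`, `pregnancy_id`, `gestational_day`,
#'   `pct_overlap`.
#' @export
overlap_table <- function(sessions) {
  data.frame(
    session_id = vapply(sessions, `[[`, character(1), "session_id"),
    pregnancy_id = vapply(sessions, `[[`, character(1), "pregnancy_id"),
    gestational_day = vapply(sessions, `[[`, integer(1), "gestational_day"),
    pct_overlap = vapply(sessions, percent_overlap, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Duration and latency pools of one unit stream (frames). The latency pool
# holds the n inter-unit gaps including the initial offset from time 0 to
# the first onset, so a stream of n units contributes n durations and n
# latencies.
stream_pools <- function(units) {
  n <- nrow(units)
  if (n == 0) return(list(dur = integer(0), lat = integer(0)))
  dur <- units$offset - units$onset
  lat <- c(units$onset[1], units$onset[-1] - units$offset[-n])
  list(dur = dur, lat = lat)
}

# Resample a stream from its pools: draw n durations and n latencies with
# replacement and lay alternating latency-duration segments end to end
# from time 0. Units extending past the visible span are dropped.
resample_stream <- function(pools, span_frames) {
  n <- length(pools$dur)
  if (n == 0) return(list(onset = integer(0), offset = integer(0)))
  dur <- pools$dur[sample.int(n, n, replace = TRUE)]
  lat <- pools$lat[sample.int(n, n, replace = TRUE)]
  offset <- cumsum(lat + dur)
  onset <- offset - dur
  keep <- offset <= span_frames
  list(onset = onset[keep], offset = offset[keep])
}

#' Shuffle a session for the permutation null
#'
#' Independently rebuilds each movement stream by resampling, with
#' replacement, as many unit durations and inter-unit latencies as the
#' original stream had, laying alternating latency-duration segments end to
#' end from time 0. Duration and latency marginals are preserved (up to
#' resampling); any orofacial-head coupling is destroyed. Units extending
#' past the visible span are dropped. A session lacking units of either
#' kind is returned unchanged.
#'
#' @param session an `fv_session`.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (the envelope drives its own substreams).
#' @return an `fv_session` with shuffled single-interval units.
#' @export
shuffle_session <- function(session, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(session$orofacial_units) == 0 || nrow(session$head_units) == 0) {
    return(session)
  }
  span <- session$visible_time_s * FRAME_RATE
  s <- session
  for (field in c("orofacial_units", "head_units")) {
    str <- resample_stream(stream_pools(session[[field]]), span)
    s[[field]] <- data.frame(
      onset = as.integer(str$onset),
      offset = as.integer(str$offset),
      duration_s = frames_to_seconds(str$offset - str$onset),
      syllable_count = rep(1L, length(str$onset)),
      partial = rep(FALSE, length(str$onset)),
      stringsAsFactors = FALSE
    )
  }
  s
}

#' Permutation envelope for the overlap trajectory
#'
#' The null model for the claim that orofacial-head overlap declines beyond
#' what falling movement rates alone produce. Every replicate shuffles all
#' sessions with [shuffle_session()], computes per-session percent overlap,
#' averages per gestational day (the same aggregation used on the observed
#' data), and fits a linear slope across days. The envelope is the
#' pointwise 2.5/97.5 percentile band of the per-day averages over
#' replicates; the significance of the mean regression line is the nullity
#' p-value of the slope fitted to the replicate-mean curve.
#'
#' @param sessions list of `fv_session` objects.
#' @param n_reps number of shuffles (default 1000).
#' @param seed integer master seed; replicate r runs on a seed derived from
#'   it, so results are reproducible.
#' @param envelope_probs lower/upper percentile probabilities.
#' @return An object of class `fv_envelope`: `day` (grid), `mean`, `lower`,
#'   `upper`, `rep_slopes`, `slope_ci`, `mean_line_slope`, `mean_line_p`,
#'   `degree` (AIC-selected on the observed per-session data), `observed`
#'   (per-day observed means), `n_reps`, `seed`.
#' @export
permutation_envelope <- function(sessions, n_reps = 1000, seed = NULL,
                                 envelope_probs = c(0.025, 0.975)) {
  stopifnot(n_reps >= 1)
  obs <- overlap_table(sessions)
  ok <- !is.na(obs$pct_overlap)
  degree <- tryCatch(
    select_poly_degree_aic(obs$gestational_day[ok], obs$pct_overlap[ok]),
    error = function(e) 1L
  )
  days <- sort(unique(obs$gestational_day))
  obs_mean <- tapply(obs$pct_overlap, factor(obs$gestational_day, levels = days),
                     mean, na.rm = TRUE)

  span_frames <- vapply(sessions, function(s) s$visible_time_s * FRAME_RATE,
                        numeric(1))
  pool_o <- lapply(sessions, function(s) stream_pools(s$orofacial_units))
  pool_h <- lapply(sessions, function(s) stream_pools(s$head_units))
  day_f <- factor(obs$gestational_day, levels = days)
  nd <- length(days)
  dbar <- mean(days)
  dctr <- days - dbar
  dss <- sum(dctr^2)

  rep_means <- matrix(NA_real_, n_reps, nd)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed %% 2147483647L)
  for (r in seq_len(n_reps)) {
    if (!is.null(base_seed)) set.seed((base_seed + 7919L * r) %% 2147483647L)
    pct <- vapply(seq_along(sessions), function(i) {
      po <- pool_o[[i]]; ph <- pool_h[[i]]
      if (length(po$dur) == 0 || length(ph$dur) == 0) {
        return(obs$pct_overlap[i])
      }
      so <- resample_stream(po, span_frames[i])
      sh <- resample_stream(ph, span_frames[i])
      tot <- length(so$onset) + length(sh$onset)
      if (tot == 0) return(NA_real_)
      cpp_overlap_count(so$onset, so$offset, sh$onset, sh$offset) / tot
    }, numeric(1))
    rep_means[r, ] <- tapply(pct, day_f, mean, na.rm = TRUE)
  }

  rep_slopes <- apply(rep_means, 1, function(m) {
    ok <- !is.na(m)
    sum(dctr[ok] * (m[ok] - mean(m[ok]))) / sum(dctr[ok]^2)
  })
  mean_curve <- colMeans(rep_means, na.rm = TRUE)
  lims <- apply(rep_means, 2, quantile, probs = envelope_probs, na.rm = TRUE)
  mean_fit <- lm(mean_curve ~ days)
  mean_sum <- summary(mean_fit)$coefficients
  structure(
    list(
      day = days,
      mean = as.numeric(mean_curve),
      lower = as.numeric(lims[1, ]),
      upper = as.numeric(lims[2, ]),
      rep_slopes = as.numeric(rep_slopes),
      slope_ci = quantile(rep_slopes, envelope_probs, na.rm = TRUE),
      mean_line_slope = mean_sum["days", "Estimate"],
      mean_line_p = mean_sum["days", "Pr(>|t|)"],
      degree = degree,
      observed = as.numeric(obs_mean),
      n_reps = n_reps,
      seed = seed
    ),
    class = "fv_envelope"
  )
}

#' @export
print.fv_envelope <- function(x, ...) {
  cat(sprintf(
    "<fv_envelope | %d days x %d reps | slope CI [%.2g, %.2g] | mean-line p = %.3g>\n",
    length(x$day), x$n_reps, x$slope_ci[1], x$slope_ci[2], x$mean_line_p
  ))
  invisible(x)
}
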