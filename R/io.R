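#' Read a movement-event table
#'
#' Delimited text (comma, header row) with columns `session_id`,
#' `pregnancy_id`, `gestational_day`, `kind`, `onset_s`, `offset_s`,
#' `partial` (0/1). Times are given in seconds and snapped to the 30 Hz
#' frame grid by rounding; all internal computation is in frames.
#' Malformed rows are reported with their line numbers (header = line 1).
#'
#' @param path file path.
#' @return event data.frame (frames).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "pregnancy_id", "gestational_day", "kind",
            "onset_s", "offset_s", "partial")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("event table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(empty_events())
  }
  problems <- character(0)
  line <- seq_len(nrow(raw)) + 1L
  for (col in c("gestational_day", "onset_s", "offset_s", "partial")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      problems <- c(problems, sprintf("line %d: non-numeric %s '%s'",
                                      line[bad], col, raw[[col]][bad]))
    }
    raw[[col]] <- v
  }
  bad_kind <- which(!raw$kind %in% c("orofacial", "head"))
  if (length(bad_kind)) {
    problems <- c(problems, sprintf("line %d: unknown kind '%s'",
                                    line[bad_kind], raw$kind[bad_kind]))
  }
  bad_iv <- which(raw$offset_s < raw$onset_s)
  if (length(bad_iv)) {
    problems <- c(problems, sprintf("line %d: offset %.3f s precedes onset %.3f s",
                                    line[bad_iv], raw$offset_s[bad_iv],
                                    raw$onset_s[bad_iv]))
  }
  if (length(problems)) {
    stop("malformed event table:\n  ", paste(problems, collapse = "\n  "))
  }
  data.frame(
    session_id = as.character(raw$session_id),
    pregnancy_id = as.character(raw$pregnancy_id),
    gestational_day = as.integer(raw$gestational_day),
    kind = raw$kind,
    onset = seconds_to_frames(raw$onset_s),
    offset = seconds_to_frames(raw$offset_s),
    partial = raw$partial != 0,
    stringsAsFactors = FALSE
  )
}

empty_events <- function() {
  data.frame(session_id = character(0), pregnancy_id = character(0),
             gestational_day = integer(0), kind = character(0),
             onset = integer(0), offset = integer(0), partial = logical(0),
             stringsAsFactors = FALSE)
}

#' Write a movement-event table
#'
#' Inverse of [read_events()]: frames are written as exact seconds
#' (frame / 30).
#'
#' @param events event data.frame (frames).
#' @param path file path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    session_id = events$session_id,
    pregnancy_id = events$pregnancy_id,
    gestational_day = events$gestational_day,
    kind = events$kind,
    onset_s = frames_to_seconds(events$onset),
    offset_s = frames_to_seconds(events$offset),
    partial = as.integer(events$partial),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a movement-unit table
#'
#' Same dialect as the event table plus `syllable_count` and `duration_s`.
#'
#' @param units unit data.frame.
#' @param path file path.
#' @export
write_units <- function(units, path) {
  out <- units
  out$onset_s <- frames_to_seconds(out$onset)
  out$offset_s <- frames_to_seconds(out$offset)
  out$onset <- NULL
  out$offset <- NULL
  out$partial <- as.integer(out$partial)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble sessions from an event table
#'
#' Splits an event table by session, merges each kind into movement units
#' with the 500 ms rule, and wraps the result into `fv_session` objects.
#'
#' @param events event data.frame (frames), e.g. from [read_events()].
#' @param visible_time_s named numeric vector of per-session visible time
#'   in seconds; sessions absent from it default to the last offset.
#' @param gap_threshold_frames merge threshold (default 15).
#' @return list of `fv_session`.
#' @export
build_sessions <- function(events, visible_time_s = NULL,
                           gap_threshold_frames = 15L) {
  ids <- unique(events$session_id)
  out <- lapply(ids, function(sid) {
    ev <- events[events$session_id == sid, , drop = FALSE]
    vt <- if (!is.null(visible_time_s) && sid %in% names(visible_time_s)) {
      visible_time_s[[sid]]
    } else {
      frames_to_seconds(max(ev$offset))
    }
    mk <- function(kind) {
      sub <- ev[ev$kind == kind, , drop = FALSE]
      sub <- sub[order(sub$onset), , drop = FALSE]
      merge_events(sub, gap_threshold_frames)
    }
    fv_session(sid, ev$pregnancy_id[1], ev$gestational_day[1], vt,
               mk("orofacial"), mk("head"))
  })
  names(out) <- ids
  out
}

#' Write call templates as JSON
#'
#' Templates are serialized as arrays keyed by syllable count, the plain
#' interchange format for the DTW stage.
#'
#' @param templates list of `fv_call_template`.
#' @param path file path.
#' @export
write_templates <- function(templates, path) {
  obj <- lapply(templates, function(t) {
    list(syllable_count = t$syllable_count, values = t$values,
         n_profiles = t$n_profiles)
  })
  names(obj) <- vapply(templates, function(t) as.character(t$syllable_count),
                       character(1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  templates <- lapply(obj, function(t) {
    structure(
      list(syllable_count = as.integer(t$syllable_count),
           values = as.numeric(t$values), raw_values = NULL,
           cost_trace = NULL, n_profiles = as.integer(t$n_profiles)),
      class = "fv_call_template"
    )
  })
  templates[order(vapply(templates, `[[`, integer(1), "syllable_count"))]
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter with the study defaults: 30 Hz frame
#' rate, 15-frame (500 ms) merge gap, E93-99 divergence baseline, 1000
#' permutation replicates, Savitzky-Golay degree 3 / window 9, spline
#' smoothing 0.999 for exemplars and 0.1 for templates, and the infant
#' call criteria boxes.
#'
#' @param merge_gap_frames unit-merge threshold in frames.
#' @param baseline_day_range gestational-day range of the KL baseline.
#' @param n_reps permutation replicates.
#' @param seed master seed for every stochastic stage.
#' @param envelope_probs permutation envelope percentiles.
#' @param criteria named list of `fv_criteria`.
#' @param savgol_degree,savgol_window profile smoothing parameters.
#' @param spline_exemplar,spline_template csaps smoothing parameters.
#' @param max_degree AIC search bound for trend fitting.
#' @param kl_smoothing additive smoothing for [kl_divergence()] (0 = off).
#' @return named list of class `fv_config`.
#' @export
pipeline_config <- function(merge_gap_frames = 15L,
                            baseline_day_range = c(93, 99),
                            n_reps = 1000L,
                            seed = 1L,
                            envelope_probs = c(0.025, 0.975),
                            criteria = default_criteria(),
                            savgol_degree = 3L,
                            savgol_window = 9L,
                            spline_exemplar = 0.999,
                            spline_template = 0.1,
                            max_degree = 10L,
                            kl_smoothing = 0) {
  structure(
    list(frame_rate = 30L, merge_gap_frames = merge_gap_frames,
         baseline_day_range = baseline_day_range, n_reps = n_reps,
         seed = seed, envelope_probs = envelope_probs, criteria = criteria,
         savgol_degree = savgol_degree, savgol_window = savgol_window,
         spline_exemplar = spline_exemplar,
         spline_template = spline_template, max_degree = max_degree,
         kl_smoothing = kl_smoothing),
    class = "fv_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a list of sessions: state coding, entropy
#' and KL trajectories with AIC-selected polynomial fits, orofacial/head
#' movement rates, overlap with the permutation envelope, percent-match
#' tables against the call criteria with pregnancy-controlled regressions,
#' and (when profiles and templates are supplied) DTW matching with
#' per-session medians and their regression. Fully deterministic given
#' `config$seed`.
#'
#' @param sessions list of `fv_session`.
#' @param config an `fv_config`.
#' @param profiles optional data.frame of fetal profiles: columns
#'   `session_id`, `pregnancy_id`, `gestational_day`, `manual_syllables`,
#'   plus a list-column `values` of raw traces.
#' @param templates optional list of `fv_call_template`.
#' @return A result bundle (list) with a `manifest` of parameters and
#'   per-stage sample sizes.
#' @export
run_pipeline <- function(sessions, config = pipeline_config(),
                         profiles = NULL, templates = NULL) {
  days <- vapply(sessions, `[[`, integer(1), "gestational_day")
  pregs <- vapply(sessions, `[[`, character(1), "pregnancy_id")

  info <- entropy_divergence_table(sessions, config$baseline_day_range,
                                   config$kl_smoothing)
  # trajectories with too few finite points (e.g. KL mostly infinite
  # against a sparse baseline) get a shrunken degree search or no fit
  fit_trend <- function(x, y) {
    ok <- is.finite(y) & is.finite(x)
    n <- sum(ok)
    if (n < 4) {
      return(list(degree = NA_integer_, fit = NULL, n = n))
    }
    deg <- select_poly_degree_aic(x[ok], y[ok],
                                  min(config$max_degree, n - 2))
    list(degree = deg, fit = fit_polynomial(x[ok], y[ok], deg), n = n)
  }
  entropy_tr <- fit_trend(info$gestational_day, info$H_bits)
  kl_tr <- fit_trend(info$gestational_day, info$KL_bits)
  entropy_degree <- entropy_tr$degree
  entropy_fit <- entropy_tr$fit
  kl_degree <- kl_tr$degree
  kl_fit <- kl_tr$fit

  rates <- data.frame(
    session_id = vapply(sessions, `[[`, character(1), "session_id"),
    pregnancy_id = pregs,
    gestational_day = days,
    orofacial_rate = vapply(sessions, movement_rate, numeric(1), "orofacial"),
    head_rate = vapply(sessions, movement_rate, numeric(1), "head"),
    stringsAsFactors = FALSE
  )
  oro_degree <- fit_trend(rates$gestational_day, rates$orofacial_rate)$degree
  head_degree <- fit_trend(rates$gestational_day, rates$head_rate)$degree

  ov <- overlap_table(sessions)
  ov_ok <- !is.na(ov$pct_overlap)
  overlap_reg <- regress_with_pregnancy(ov$pct_overlap[ov_ok],
                                        ov$gestational_day[ov_ok],
                                        ov$pregnancy_id[ov_ok])
  envelope <- permutation_envelope(sessions, config$n_reps, config$seed,
                                   config$envelope_probs)

  pm <- percent_match_table(sessions, config$criteria)
  match_reg <- lapply(names(config$criteria), function(nm) {
    col <- pm[[paste0("pct_", nm)]]
    ok <- !is.na(col)
    regress_with_pregnancy(col[ok], pm$gestational_day[ok],
                           pm$pregnancy_id[ok])
  })
  names(match_reg) <- names(config$criteria)

  dtw <- NULL
  if (!is.null(profiles) && !is.null(templates)) {
    gate <- gate_profiles(profiles$values, profiles$manual_syllables,
                          config$savgol_window)
    kept <- which(gate$keep)
    matches <- data.frame(
      session_id = profiles$session_id[kept],
      pregnancy_id = profiles$pregnancy_id[kept],
      gestational_day = profiles$gestational_day[kept],
      stringsAsFactors = FALSE
    )
    res <- lapply(kept, function(i) {
      v <- smooth_savgol(profiles$values[[i]], config$savgol_degree,
                         config$savgol_window)
      match_to_templates(zscore_profile(v), templates)
    })
    matches$cost <- vapply(res, `[[`, numeric(1), "cost")
    matches$best_syllables <- vapply(res, `[[`, integer(1), "best_syllables")
    medians <- session_median_dtw(matches)
    dtw_reg <- regress_with_pregnancy(medians$median_cost,
                                      medians$gestational_day,
                                      medians$pregnancy_id)
    dtw <- list(gate = gate, matches = matches, medians = medians,
                regression = dtw_reg)
  }

  list(
    info = info,
    fits = list(entropy = entropy_fit, kl = kl_fit),
    degrees = list(entropy = entropy_degree, kl = kl_degree,
                   orofacial_rate = oro_degree, head_rate = head_degree),
    rates = rates,
    overlap = ov,
    overlap_regression = overlap_reg,
    envelope = envelope,
    percent_match = pm,
    match_regressions = match_reg,
    dtw = dtw,
    manifest = list(
      package_version = as.character(utils::packageVersion("fetalvoc")),
      config = config[setdiff(names(config), "criteria")],
      n_sessions = length(sessions),
      n_orofacial_units = sum(vapply(sessions, function(s)
        nrow(s$orofacial_units), numeric(1))),
      n_head_units = sum(vapply(sessions, function(s)
        nrow(s$head_units), numeric(1))),
      n_profiles_kept = if (is.null(dtw)) NA_integer_ else sum(dtw$gate$keep),
      n_sessions_with_dtw = if (is.null(dtw)) NA_integer_ else
        nrow(dtw$medians)
    )
  )
}
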