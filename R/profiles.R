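#' Z-score a temporal profile
#'
#' Mouth-opening magnitude traces are z-scored before any comparison so
#' that only the temporal shape, not the opening amplitude (which depends
#' on probe position), carries information.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return numeric vector with mean 0 and sd 1.
#' @export
zscore_profile <- function(values) {
  if (length(values) < 2) stop("profile too short to z-score")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("constant profile cannot be z-scored")
  (values - mean(values)) / s
}

#' Savitzky-Golay smoothing of a temporal profile
#'
#' Local least-squares polynomial smoothing with the window/degree used
#' for fetal mouth-opening traces (cubic, 9-frame window). A degree-3
#' filter reproduces any cubic exactly.
#'
#' @param values numeric vector, `length(values) >= window`.
#' @param poly_degree polynomial degree (default 3).
#' @param window odd sliding window size, `window > poly_degree` (default 9).
#' @return smoothed vector of the same length.
#' @export
smooth_savgol <- function(values, poly_degree = 3, window = 9) {
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= poly_degree) stop("window must exceed the polynomial degree")
  if (length(values) < window) {
    stop("profile shorter than the smoothing window (", window, " frames)")
  }
  as.numeric(signal::sgolayfilt(values, p = poly_degree, n = window))
}

#' Cubic smoothing spline on the frame grid
#'
#' Penalized natural cubic smoothing spline in the csaps parameterization:
#' minimizes \eqn{p \sum_i (y_i - f(i))^2 + (1 - p) \int f''(t)^2 dt} over
#' natural cubic splines with knots at every frame, solved in Reinsch form
#' \eqn{(p I + (1 - p) K) f = p y} where \eqn{K = D^T W^{-1} D} is the
#' roughness matrix of the unit-spaced grid. `smoothing = 1` interpolates
#' (returns the data); `smoothing = 0` is the least-squares line limit.
#'
#' @param values numeric vector, length >= 4.
#' @param smoothing p in \[0, 1\].
#' @return smoothed vector evaluated at the input grid.
#' @export
smooth_profile_spline <- function(values, smoothing) {
  n <- length(values)
  if (n < 4) stop("need at least 4 samples for a cubic smoothing spline")
  if (!is.numeric(smoothing) || smoothing < 0 || smoothing > 1) {
    stop("smoothing must lie in [0, 1]")
  }
  if (smoothing == 1) return(values)
  x <- seq_len(n)
  if (smoothing == 0) {
    return(as.numeric(fitted(lm(values ~ x))))
  }
  # second-difference matrix D ((n-2) x n) and W (tridiagonal, h = 1)
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  W <- diag(2 / 3, n - 2)
  if (n > 3) {
    idx <- seq_len(n - 3)
    W[cbind(idx, idx + 1)] <- 1 / 6
    W[cbind(idx + 1, idx)] <- 1 / 6
  }
  K <- crossprod(D, solve(W, D))
  A <- smoothing * diag(n) + (1 - smoothing) * K
  as.numeric(solve(A, smoothing * values))
}

#' Dynamic time warping cost between two profiles
#'
#' Minimal cumulative absolute difference over monotone warping paths with
#' steps (1,0), (0,1), (1,1) and matched endpoints; no path-length
#' normalization, so the cost is a raw dissimilarity (0 = identical,
#' symmetric). Optionally both sequences are first refined by uniform
#' linear interpolation (`refine` sub-samples per original step), a
#' continuous-DTW approximation.
#'
#' @param a,b numeric vectors (z-scored profiles), length >= 2.
#' @param refine integer >= 1 linear-interpolation refinement factor
#'   (default 1 = plain discrete DTW).
#' @return non-negative cost.
#' @export
dtw_cost <- function(a, b, refine = 1L) {
  if (length(a) < 1 || length(b) < 1) stop("empty profile")
  if (refine > 1) {
    a <- refine_linear(a, refine)
    b <- refine_linear(b, refine)
  }
  cpp_dtw_cost(as.numeric(a), as.numeric(b))
}

refine_linear <- function(v, factor) {
  n <- length(v)
  if (n < 2) return(v)
  approx(seq_len(n), v, n = (n - 1) * factor + 1)$y
}

#' DTW barycenter average (DBA) call template
#'
#' Iterative barycenter of a set of equal-syllable-count call profiles:
#' every profile is aligned to the current average by DTW, each average
#' sample is updated to the mean of the samples aligned to it, and the
#' total DTW cost from the average to all profiles is monitored. Iteration
#' stops after `n_iter` rounds or as soon as the total cost stops
#' decreasing (the best iterate is kept, so the recorded cost trace is
#' non-increasing). The converged average is finally smoothed with the
#' template smoothing spline (`smoothing = 0.1`); pass `smoothing = NULL`
#' to skip.
#'
#' @param profiles non-empty list of numeric vectors (z-scored profiles of
#'   one syllable count).
#' @param syllable_count integer label attached to the template.
#' @param n_iter maximum barycenter iterations (default 10).
#' @param smoothing csaps smoothing parameter for the final template
#'   (default 0.1), or `NULL` for the raw barycenter.
#' @return An `fv_call_template`: `syllable_count`, `values`, `raw_values`,
#'   `cost_trace`, `n_profiles`.
#' @export
dba_template <- function(profiles, syllable_count = NA_integer_,
                         n_iter = 10, smoothing = 0.1) {
  if (!length(profiles)) stop("no profiles to average")
  profiles <- lapply(profiles, as.numeric)
  lens <- lengths(profiles)
  init <- which.min(abs(lens - median(lens)))[1]
  avg <- profiles[[init]]
  total_cost <- function(a) sum(vapply(profiles, function(p)
    cpp_dtw_cost(a, p), numeric(1)))
  best_cost <- total_cost(avg)
  trace <- best_cost
  for (it in seq_len(n_iter)) {
    sums <- numeric(length(avg))
    cnts <- numeric(length(avg))
    for (p in profiles) {
      path <- cpp_dtw_path(avg, p)
      sums[path[, 1]] <- sums[path[, 1]] + p[path[, 2]]
      cnts[path[, 1]] <- cnts[path[, 1]] + 1
    }
    cand <- sums / cnts
    cand_cost <- total_cost(cand)
    if (cand_cost < best_cost) {
      avg <- cand
      best_cost <- cand_cost
      trace <- c(trace, cand_cost)
    } else {
      break
    }
  }
  values <- if (is.null(smoothing)) avg else smooth_profile_spline(avg, smoothing)
  structure(
    list(
      syllable_count = as.integer(syllable_count),
      values = values,
      raw_values = avg,
      cost_trace = trace,
      n_profiles = length(profiles)
    ),
    class = "fv_call_template"
  )
}

#' @export
print.fv_call_template <- function(x, ...) {
  cat(sprintf("<fv_call_template | %d syllables | %d profiles | %d frames>\n",
              x$syllable_count, x$n_profiles, length(x$values)))
  invisible(x)
}

#' Build the per-syllable-count template set
#'
#' Groups infant call profiles by syllable count and runs [dba_template()]
#' on every group, mirroring the 1-7 syllable contact-call template set.
#'
#' @param profiles list of numeric vectors.
#' @param syllable_counts integer vector, one per profile.
#' @inheritParams dba_template
#' @return list of `fv_call_template`, ordered by syllable count.
#' @export
build_call_templates <- function(profiles, syllable_counts, n_iter = 10,
                                 smoothing = 0.1) {
  stopifnot(length(profiles) == length(syllable_counts))
  counts <- sort(unique(syllable_counts))
  templates <- lapply(counts, function(k) {
    dba_template(profiles[syllable_counts == k], syllable_count = k,
                 n_iter = n_iter, smoothing = smoothing)
  })
  names(templates) <- as.character(counts)
  templates
}

#' Match a profile against all call templates
#'
#' DTW cost against every template; the lowest cost is retained together
#' with the syllable count of the winning template. Ties go to the lower
#' syllable count.
#'
#' @param values numeric vector (z-scored fetal movement profile).
#' @param templates list of `fv_call_template` (any order).
#' @param refine passed to [dtw_cost()].
#' @return list: `cost` (the minimum), `best_syllables`, `costs` (named by
#'   template syllable count).
#' @export
match_to_templates <- function(values, templates, refine = 1L) {
  if (!length(templates)) stop("no templates")
  counts <- vapply(templates, function(t) t$syllable_count, integer(1))
  ord <- order(counts)
  templates <- templates[ord]
  counts <- counts[ord]
  costs <- vapply(templates, function(t) dtw_cost(values, t$values, refine),
                  numeric(1))
  names(costs) <- as.character(counts)
  best <- which.min(costs)  # first minimum = lowest syllable count on ties
  list(cost = unname(costs[best]), best_syllables = counts[best], costs = costs)
}

#' Per-session median DTW cost
#'
#' The retained (lowest) DTW costs of all profiles of a session are
#' compiled and their median taken; sessions contributing no usable profile
#' are omitted.
#'
#' @param matches data.frame with columns `session_id` and `cost` (and
#'   optionally `pregnancy_id`, `gestational_day`, carried through).
#' @return data.frame with one row per session and `median_cost`.
#' @export
session_median_dtw <- function(matches) {
  matches <- matches[!is.na(matches$cost), , drop = FALSE]
  if (!nrow(matches)) {
    return(data.frame(session_id = character(0), median_cost = numeric(0)))
  }
  ids <- unique(matches$session_id)
  out <- data.frame(
    session_id = ids,
    median_cost = vapply(ids, function(i)
      median(matches$cost[matches$session_id == i]), numeric(1)),
    stringsAsFactors = FALSE
  )
  for (col in c("pregnancy_id", "gestational_day")) {
    if (col %in% names(matches)) {
      out[[col]] <- matches[[col]][match(ids, matches$session_id)]
    }
  }
  rownames(out) <- NULL
  out
}

#' Automated syllable count of a raw mouth-opening profile
#'
#' Counts maximal runs of the trace above a fraction of its amplitude
#' (baseline = minimum). Runs shorter than `min_frames` are ignored as
#' noise spikes. Used as the quality gate: a profile whose automated count
#' disagrees with the manually scored syllable number is excluded from DTW
#' analysis.
#'
#' @param values raw (not z-scored) profile, baseline near 0.
#' @param threshold amplitude fraction separating open from closed
#'   (default 0.2).
#' @param min_frames minimum run length in frames (default 2).
#' @return integer syllable count.
#' @export
count_profile_syllables <- function(values, threshold = 0.2, min_frames = 2) {
  rng <- range(values)
  if (diff(rng) == 0) return(0L)
  thr <- rng[1] + threshold * diff(rng)
  r <- rle(values > thr)
  sum(r$values & r$lengths >= min_frames)
}

#' Quality-gate fetal movement profiles
#'
#' A profile is usable for template matching when (a) it is at least as
#' long as the Savitzky-Golay window, and (b) its automated syllable count
#' agrees with the manually scored count.
#'
#' @param profiles list of raw numeric profiles.
#' @param manual_counts integer vector of manually scored syllable numbers.
#' @param window Savitzky-Golay window length (default 9).
#' @param ... passed to [count_profile_syllables()].
#' @return data.frame: `auto_count`, `long_enough`, `count_match`, `keep`.
#' @export
gate_profiles <- function(profiles, manual_counts, window = 9, ...) {
  stopifnot(length(profiles) == length(manual_counts))
  auto <- vapply(profiles, count_profile_syllables, integer(1), ...)
  long_enough <- lengths(profiles) >= window
  count_match <- auto == manual_counts
  data.frame(
    auto_count = auto,
    long_enough = long_enough,
    count_match = count_match,
    keep = long_enough & count_match
  )
}
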