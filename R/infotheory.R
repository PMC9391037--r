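#' Shannon entropy of a state distribution
#'
#' \deqn{H(X) = -\sum_i P(X=i)\,\log_2 P(X=i)} with the convention
#' \eqn{0 \log 0 = 0}. For five states the maximum is
#' \eqn{\log_2 5 \approx 2.32} bits (uniform distribution); 0 bits means a
#' single state accounts for every occurrence.
#'
#' @param p probability vector (non-negative, summing to 1 within `tol`).
#' @param tol tolerance on the sum-to-one check.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(rep(0.2, 5))  # log2(5) = 2.3219 bits
#' @export
shannon_entropy <- function(p, tol = 1e-8) {
  check_distribution(p, tol)
  pos <- p > 0
  -sum(p[pos] * log2(p[pos]))
}

#' Kullback-Leibler divergence between state distributions
#'
#' \deqn{KL(P\,\|\,Q) = \sum_i P_i \log_2 (P_i / Q_i)} with
#' \eqn{0\log(0/q) = 0}. When some \eqn{P_i > 0} has \eqn{Q_i = 0} the
#' divergence is infinite and `Inf` is returned explicitly; no silent
#' regularization is applied. For baselines with empty cells an optional
#' additive smoothing (add `smoothing` to every cell of Q, renormalize) can
#' be switched on.
#'
#' @param p,q probability vectors of equal length.
#' @param smoothing non-negative additive smoothing applied to `q`
#'   (default 0 = off).
#' @inheritParams shannon_entropy
#' @return divergence in bits (non-negative, possibly `Inf`).
#' @export
kl_divergence <- function(p, q, smoothing = 0, tol = 1e-8) {
  check_distribution(p, tol)
  check_distribution(q, tol)
  if (length(p) != length(q)) stop("distributions differ in length")
  if (smoothing > 0) q <- (q + smoothing) / sum(q + smoothing)
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log2(p[pos] / q[pos]))
}

check_distribution <- function(p, tol = 1e-8) {
  if (anyNA(p)) stop("distribution contains NA (empty state sequence?)")
  if (any(p < 0)) stop("negative probability component")
  if (abs(sum(p) - 1) > tol) stop("probabilities do not sum to 1")
  invisible(p)
}

#' Early-gestation baseline state distribution
#'
#' Arithmetic mean of the per-session state distributions of all sessions
#' whose gestational day falls in `day_range` (default E93-99, the first
#' six testing sessions across pregnancies), renormalized. Sessions without
#' any movement occurrence are skipped.
#'
#' @param sessions list of `fv_session` objects.
#' @param day_range closed gestational-day interval.
#' @return named probability vector of length 5.
#' @export
baseline_distribution <- function(sessions, day_range = c(93, 99)) {
  days <- vapply(sessions, function(s) s$gestational_day, numeric(1))
  keep <- days >= day_range[1] & days <= day_range[2]
  if (!any(keep)) stop("no session in the baseline day range")
  dists <- lapply(sessions[keep], function(s) state_distribution(session_states(s)))
  dists <- Filter(function(p) attr(p, "n") > 0, dists)
  if (!length(dists)) stop("baseline sessions have no movement occurrences")
  p <- Reduce(`+`, dists) / length(dists)
  p <- p / sum(p)
  attr(p, "n") <- length(dists)
  p
}

#' Per-session entropy and divergence trajectories
#'
#' Computes, for every session, the Shannon entropy of its state
#' distribution and its KL divergence from the early-gestation baseline.
#' Sessions without occurrences get `NA`.
#'
#' @inheritParams baseline_distribution
#' @param smoothing passed to [kl_divergence()].
#' @return data.frame: `session_id`, `pregnancy_id`, `gestational_day`,
#'   `n_occurrences`, `H_bits`, `KL_bits`.
#' @export
entropy_divergence_table <- function(sessions, day_range = c(93, 99),
                                     smoothing = 0) {
  baseline <- baseline_distribution(sessions, day_range)
  rows <- lapply(sessions, function(s) {
    p <- state_distribution(session_states(s))
    n <- attr(p, "n")
    data.frame(
      session_id = s$session_id,
      pregnancy_id = s$pregnancy_id,
      gestational_day = s$gestational_day,
      n_occurrences = n,
      H_bits = if (n > 0) shannon_entropy(p) else NA_real_,
      KL_bits = if (n > 0) kl_divergence(p, baseline, smoothing) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
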