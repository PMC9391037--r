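#' Least-squares polynomial fit
#'
#' Ordinary least-squares polynomial of the given degree. The predictor is
#' centred and scaled internally for conditioning; coefficients are
#' reported both in the scaled basis and back-transformed to the original
#' x basis (ascending powers).
#'
#' @param x,y numeric vectors of equal length, `length(x) > degree`.
#' @param degree non-negative integer.
#' @return An `fv_polyfit`: `degree`, `coefficients` (ascending powers of
#'   x), `coefficients_scaled`, `center`, `scale`, `rss`, `n`, `x_domain`.
#' @examples
#' f <- fit_polynomial(1:10, 2 * (1:10) + 1, 1)
#' f$coefficients  # (1, 2): intercept 1, slope 2
#' @export
fit_polynomial <- function(x, y, degree) {
  stopifnot(length(x) == length(y), degree >= 0)
  n <- length(x)
  if (n <= degree) stop("need more points than the polynomial degree")
  ctr <- mean(x)
  scl <- stats::sd(x)
  if (!is.finite(scl) || scl == 0) scl <- 1
  z <- (x - ctr) / scl
  Z <- outer(z, 0:degree, `^`)
  qz <- qr(Z)
  if (qz$rank < degree + 1) {
    stop("rank-deficient polynomial design (degree ", degree,
         " with ", length(unique(x)), " distinct x values)")
  }
  b <- qr.coef(qz, y)
  fitted <- drop(Z %*% b)
  # back-transform: sum_k b_k ((x - ctr)/scl)^k expanded in powers of x
  q <- c(-ctr / scl, 1 / scl)
  coefs <- numeric(degree + 1)
  pw <- 1
  for (k in 0:degree) {
    coefs[seq_along(pw)] <- coefs[seq_along(pw)] + b[k + 1] * pw
    if (k < degree) pw <- poly_mult(pw, q)
  }
  structure(
    list(
      degree = as.integer(degree),
      coefficients = coefs,
      coefficients_scaled = as.numeric(b),
      center = ctr,
      scale = scl,
      rss = sum((y - fitted)^2),
      n = n,
      x_domain = range(x)
    ),
    class = "fv_polyfit"
  )
}

# product of two polynomials given as ascending coefficient vectors
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' @export
predict.fv_polyfit <- function(object, newdata, ...) {
  z <- (newdata - object$center) / object$scale
  drop(outer(z, 0:object$degree, `^`) %*% object$coefficients_scaled)
}

#' @export
print.fv_polyfit <- function(x, ...) {
  cat(sprintf("<fv_polyfit degree %d | n = %d | RSS = %.4g>\n",
              x$degree, x$n, x$rss))
  invisible(x)
}

#' AIC-guided polynomial degree selection
#'
#' Selects the polynomial order of a developmental trajectory with a
#' Gaussian-likelihood AIC, \eqn{AIC(d) = n\,\ln(RSS_d/n) + 2k +
#' 2k(k+1)/(n-k-1)} with \eqn{k = d + 2} parameters (d + 1 coefficients
#' plus the residual variance; the last term is the usual small-sample
#' correction). Degrees are searched incrementally from 0 and the search
#' stops after two consecutive degrees fail to improve the criterion,
#' returning the best degree visited. The stop-after-two-increases rule
#' keeps a single flat step (e.g. the vanishing linear term of a symmetric
#' inverse-U) from ending the search, while denying the many higher-degree
#' competitors of a plain full-range argmin their ~16%-per-step chance of
#' overfitting.
#'
#' @param x,y numeric vectors; at least `max_degree + 2` points.
#' @param max_degree highest degree considered (default 10).
#' @return the selected degree (integer).
#' @export
select_poly_degree_aic <- function(x, y, max_degree = 10) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (n < max_degree + 2) {
    stop("need at least max_degree + 2 points (", max_degree + 2,
         "), got ", n)
  }
  max_degree <- min(max_degree, length(unique(x)) - 1)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 == 0) return(0L)
  floor_rss <- rss0 * 1e-12  # numerical tie floor for (near-)exact fits
  aic_of <- function(d) {
    rss <- if (d == 0) rss0 else fit_polynomial(x, y, d)$rss
    rss <- max(rss, floor_rss)
    k <- d + 2
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  best_aic <- Inf
  best_d <- 0L
  misses <- 0L
  d <- 0L
  while (misses < 2L && d <= max_degree) {
    a <- aic_of(d)
    if (a < best_aic) {
      best_aic <- a
      best_d <- d
      misses <- 0L
    } else {
      misses <- misses + 1L
    }
    d <- d + 1L
  }
  best_d
}

#' Linear regression on gestational day controlling for pregnancy
#'
#' Fits `y ~ gestational_day + pregnancy` with pregnancy as reference-coded
#' fixed-effect indicators, and tests the nullity of the gestational-day
#' effect (single-term ANOVA F test; for this one-degree-of-freedom effect
#' F equals the squared t statistic). With fewer than two pregnancies the
#' covariate is dropped with a warning.
#'
#' @param y response (one value per session).
#' @param gestational_day numeric covariate of interest.
#' @param pregnancy_id factor-coercible pregnancy labels.
#' @return An `fv_regression`: `beta`, `se`, `t`, `F`, `df1`, `df2`, `p`,
#'   `n`, `covariates`.
#' @export
regress_with_pregnancy <- function(y, gestational_day, pregnancy_id) {
  ok <- !is.na(y) & !is.na(gestational_day)
  y <- y[ok]
  gestational_day <- gestational_day[ok]
  pregnancy_id <- factor(pregnancy_id[ok])
  covariates <- "pregnancy"
  if (nlevels(pregnancy_id) < 2) {
    warning("fewer than two pregnancies; dropping the pregnancy covariate")
    fit <- lm(y ~ gestational_day)
    covariates <- character(0)
  } else {
    fit <- lm(y ~ gestational_day + pregnancy_id)
  }
  if (anyNA(coef(fit))) stop("collinear design: ",
                             paste(names(coef(fit))[is.na(coef(fit))],
                                   collapse = ", "))
  cf <- summary(fit)$coefficients["gestational_day", ]
  structure(
    list(
      beta = unname(cf["Estimate"]),
      se = unname(cf["Std. Error"]),
      t = unname(cf["t value"]),
      F = unname(cf["t value"]^2),
      df1 = 1L,
      df2 = fit$df.residual,
      p = unname(cf["Pr(>|t|)"]),
      n = length(y),
      covariates = covariates,
      fit = fit
    ),
    class = "fv_regression"
  )
}

#' @export
print.fv_regression <- function(x, ...) {
  cat(sprintf(
    "<fv_regression | beta +/- SE = %.4g +/- %.4g, t = %.3g; F[%d,%d] = %.3g; p = %.3g>\n",
    x$beta, x$se, x$t, x$df1, x$df2, x$F, x$p
  ))
  invisible(x)
}

#' Percentile trajectories of unit duration or syllable number
#'
#' Per-session median, 25th and 75th percentile of the complete orofacial
#' units' durations (seconds) or syllable counts, with polynomial fits
#' across gestational day. The AIC-selected degree of the median curve is
#' reused for the quartile curves so the three trajectories stay
#' comparable.
#'
#' @param sessions list of `fv_session`.
#' @param what `"duration"` or `"syllables"`.
#' @param max_degree AIC search bound for the median curve.
#' @return list: `stats` (per-session data.frame with `p50`, `p25`,
#'   `p75`), `degree`, and `fits` (one `fv_polyfit` per percentile).
#' @export
percentile_trends <- function(sessions, what = c("duration", "syllables"),
                              max_degree = 10) {
  what <- match.arg(what)
  rows <- lapply(sessions, function(s) {
    u <- s$orofacial_units
    u <- u[!u$partial, , drop = FALSE]
    v <- if (what == "duration") u$duration_s else u$syllable_count
    if (!length(v)) v <- NA_real_
    q <- quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(session_id = s$session_id, pregnancy_id = s$pregnancy_id,
               gestational_day = s$gestational_day,
               n_units = sum(!is.na(v)) * (length(v) > 0),
               p50 = q[1], p25 = q[2], p75 = q[3],
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  ok <- is.finite(stats$p50)
  degree <- select_poly_degree_aic(stats$gestational_day[ok], stats$p50[ok],
                                   min(max_degree, sum(ok) - 2))
  fits <- lapply(c(p50 = "p50", p25 = "p25", p75 = "p75"), function(col) {
    keep <- is.finite(stats[[col]])
    fit_polynomial(stats$gestational_day[keep], stats[[col]][keep], degree)
  })
  list(stats = stats, degree = degree, fits = fits)
}
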