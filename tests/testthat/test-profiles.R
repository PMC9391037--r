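# independent roughness functional: fit the natural cubic interpolating
# spline through (1..n, f) and integrate its squared second derivative
# (piecewise linear between knots, so the integral is exact)
roughness_natural <- function(f) {
  n <- length(f)
  fn <- splinefun(seq_len(n), f, method = "natural")
  d2 <- fn(seq_len(n), deriv = 2)
  a <- d2[-n]; b <- d2[-1]
  sum((a^2 + a * b + b^2) / 3)
}

csaps_objective <- function(f, y, p) {
  p * sum((y - f)^2) + (1 - p) * roughness_natural(f)
}

test_that("z-scoring removes amplitude and rejects degenerate traces", {
  set.seed(61)
  v <- rnorm(50, mean = 3, sd = 4)
  z <- zscore_profile(v)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(zscore_profile(10 * v + 2), z)
  expect_error(zscore_profile(rep(1, 10)), "constant")
  expect_error(zscore_profile(3), "too short")
})

test_that("Savitzky-Golay smoothing preserves cubics and matches local fits", {
  x <- 1:40
  cubic <- 0.01 * x^3 - 0.4 * x^2 + 2 * x - 5
  expect_equal(smooth_savgol(cubic), cubic, tolerance = 1e-8)
  expect_equal(smooth_savgol(rep(2.5, 20)), rep(2.5, 20), tolerance = 1e-9)

  # oracle: direct sliding least-squares cubic at interior points
  set.seed(62)
  v <- sin(seq(0, 4 * pi, length.out = 60)) + rnorm(60, sd = 0.2)
  sm <- smooth_savgol(v, 3, 9)
  for (i in seq(5, 56, by = 7)) {
    idx <- (i - 4):(i + 4)
    fit <- lm(v[idx] ~ poly(idx, 3, raw = TRUE))
    expect_equal(sm[i], unname(fitted(fit)[5]), tolerance = 1e-8)
  }
  expect_error(smooth_savgol(v, 3, 8), "odd")
  expect_error(smooth_savgol(v[1:5], 3, 9), "shorter")
})

test_that("the smoothing spline hits its limits and minimizes the objective", {
  set.seed(63)
  v <- cumsum(rnorm(25))
  expect_equal(smooth_profile_spline(v, 1), v)

  x <- 1:30
  lin <- 0.7 * x - 2
  for (p in c(0, 1e-4, 0.5, 0.999)) {
    expect_equal(smooth_profile_spline(lin, p), lin, tolerance = 1e-7)
  }
  ls_line <- as.numeric(fitted(lm(v ~ seq_along(v))))
  expect_equal(smooth_profile_spline(v, 0), ls_line, tolerance = 1e-9)

  # solution minimizes the penalized objective (checked with an
  # independently constructed roughness functional)
  y <- sin(seq(0, 2 * pi, length.out = 20)) + rnorm(20, sd = 0.3)
  for (p in c(0.1, 0.999)) {
    f <- smooth_profile_spline(y, p)
    j0 <- csaps_objective(f, y, p)
    for (rep in 1:15) {
      expect_lte(j0, csaps_objective(f + rnorm(20, sd = 0.05), y, p) + 1e-10)
    }
    expect_lte(j0, csaps_objective(y, y, p) + 1e-10)
  }
  expect_error(smooth_profile_spline(v, 1.2), "0, 1")
})

test_that("DTW cost matches exhaustive path enumeration on tiny inputs", {
  expect_equal(dtw_cost(c(0, 1, 2), c(0, 2)), dtw_bruteforce(c(0, 1, 2), c(0, 2)))
  set.seed(64)
  for (rep in 1:30) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    expect_equal(dtw_cost(a, b), dtw_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("DTW is a symmetric non-negative dissimilarity, zero on identity", {
  set.seed(65)
  for (rep in 1:15) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1))
    expect_equal(dtw_cost(a, a), 0)
    expect_gte(dtw_cost(a, b), 0)
    expect_equal(dtw_cost(a, b), dtw_cost(b, a))
    # joint time reversal leaves the cost unchanged
    expect_equal(dtw_cost(rev(a), rev(b)), dtw_cost(a, b), tolerance = 1e-12)
  }
  expect_error(dtw_cost(numeric(0), 1:3), "empty")
})

test_that("interpolation refinement keeps DTW semantics", {
  set.seed(66)
  a <- rnorm(12); b <- rnorm(15)
  c1 <- dtw_cost(a, b, refine = 1)
  c3 <- dtw_cost(a, b, refine = 3)
  expect_gte(c3, 0)
  # identical inputs still cost zero after refinement
  expect_equal(dtw_cost(a, a, refine = 4), 0)
  expect_false(isTRUE(all.equal(c1, 0)))
})

test_that("DBA fixed points and descent hold", {
  set.seed(67)
  v <- sin(seq(0, 2 * pi, length.out = 30))
  t1 <- dba_template(list(v, v, v), 3, smoothing = NULL)
  expect_equal(t1$values, v)
  t2 <- dba_template(list(v), 3, smoothing = NULL)
  expect_equal(t2$values, v)
  for (rep in 1:5) {
    profs <- lapply(1:6, function(i) rnorm(sample(15:25, 1)))
    t <- dba_template(profs, 1, n_iter = 8, smoothing = NULL)
    expect_true(all(diff(t$cost_trace) <= 1e-12))
  }
  expect_error(dba_template(list()), "no profiles")
})

test_that("template matching retains the minimum-cost template", {
  set.seed(68)
  templates <- lapply(1:5, function(k) {
    structure(list(syllable_count = k,
                   values = sin(seq(0, k * pi, length.out = 20 + 5 * k))),
              class = "fv_call_template")
  })
  m <- match_to_templates(templates[[3]]$values, templates)
  expect_equal(m$cost, 0)
  expect_equal(m$best_syllables, 3L)
  # oracle: explicit loop over templates
  for (rep in 1:10) {
    v <- rnorm(25)
    m <- match_to_templates(v, templates)
    costs <- sapply(templates, function(t) dtw_cost(v, t$values))
    expect_equal(m$cost, min(costs))
    expect_equal(m$best_syllables, which.min(costs))
  }
  m1 <- match_to_templates(rnorm(20), templates[2])
  expect_equal(m1$best_syllables, 2L)
})

test_that("ties in template matching go to the lower syllable count", {
  v <- c(0, 1, 0)
  same <- structure(list(syllable_count = 4L, values = v),
                    class = "fv_call_template")
  same2 <- structure(list(syllable_count = 2L, values = v),
                     class = "fv_call_template")
  m <- match_to_templates(v, list(same, same2))
  expect_equal(m$best_syllables, 2L)
})

test_that("session medians match a sort-based oracle", {
  m <- data.frame(session_id = c("a", "a", "a"), cost = c(3, 1, 2))
  expect_equal(session_median_dtw(m)$median_cost, 2)
  m2 <- data.frame(session_id = "b", cost = 7)
  expect_equal(session_median_dtw(m2)$median_cost, 7)
  set.seed(69)
  costs <- rnorm(10)
  m3 <- data.frame(session_id = "c", cost = costs)
  srt <- sort(costs)
  expect_equal(session_median_dtw(m3)$median_cost, (srt[5] + srt[6]) / 2)
  # sessions without usable profiles are omitted
  m4 <- data.frame(session_id = c("a", "b"), cost = c(1, NA))
  expect_equal(session_median_dtw(m4)$session_id, "a")
})

test_that("automated syllable counting and the quality gate work on clean traces", {
  set.seed(70)
  for (k in c(1, 3, 7)) {
    v <- generate_profile(profile_spec("custom", syllable_count = k,
                                       noise_sd = 0, warp_amp = 0))
    expect_equal(count_profile_syllables(v), k)
    expect_equal(attr(v, "syllable_count"), k)
  }
  profs <- lapply(c(2, 4, 5), function(k)
    as.numeric(generate_profile(profile_spec("custom", syllable_count = k,
                                             noise_sd = 0, warp_amp = 0))))
  g <- gate_profiles(profs, c(2, 9, 5))
  expect_equal(g$keep, c(TRUE, FALSE, TRUE))
  short <- list(c(0, 1, 0))
  g2 <- gate_profiles(short, 1)
  expect_false(g2$keep)
  expect_false(g2$long_enough)
})
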