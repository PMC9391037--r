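test_that("syllable counts come from complete units only", {
  u5 <- make_units(0, 300, syllables = 5)
  expect_equal(count_syllables(u5[1, ]), 5L)
  u1 <- make_units(0, 30, syllables = 1)
  expect_equal(count_syllables(u1[1, ]), 1L)
  up <- make_units(0, 300, partial = TRUE, syllables = 4)
  expect_error(count_syllables(up[1, ]), "partial")
  # cross-module consistency: merged 7-event unit carries count 7
  on <- seq(0, by = 15, length.out = 7)
  u7 <- merge_events(make_events(on, on + 10), 15)
  expect_equal(count_syllables(u7[1, ]), 7L)
})

test_that("criteria membership uses closed bounds and unions", {
  crit <- default_criteria()
  expect_true(in_criteria(4.0, 6, crit$contact))
  expect_false(in_criteria(1.0, 2, crit$contact))
  # boundary values count (closed intervals)
  expect_true(in_criteria(3.69, 5, crit$contact))
  expect_true(in_criteria(6.5, 9, crit$contact))
  # lick union: both lobes
  expect_true(in_criteria(1.0, 2, crit$lick))
  expect_true(in_criteria(10.0, 12, crit$lick))
  expect_false(in_criteria(5.0, 8, crit$lick))
})

test_that("type likelihood equals direct counting on labeled populations", {
  crit <- default_criteria()
  calls <- data.frame(
    type = c("contact", "contact", "twitter", "lick"),
    duration_s = c(4, 5, 4.2, 1),
    syllable_count = c(6, 7, 6, 2)
  )
  expect_equal(type_likelihood(calls, crit$contact, "contact"), 2 / 3)
  calls2 <- data.frame(type = rep("contact", 4),
                       duration_s = rep(4, 4), syllable_count = rep(6, 4))
  expect_equal(type_likelihood(calls2, crit$contact, "contact"), 1)
  expect_equal(type_likelihood(calls2, crit$contact, "twitter"), 0)
  out <- data.frame(type = "contact", duration_s = 1, syllable_count = 1)
  expect_warning(lik <- type_likelihood(out, crit$contact, "contact"),
                 "undefined")
  expect_true(is.na(lik))

  set.seed(81)
  big <- generate_infant_calls(seed = 81)
  lik <- type_likelihood(big, crit$contact, "contact")
  inside <- in_criteria(big$duration_s, big$syllable_count, crit$contact)
  expect_equal(lik, sum(big$type[inside] == "contact") / sum(inside))
})

test_that("likelihood is monotone under target-only refinement", {
  set.seed(82)
  calls <- generate_infant_calls(seed = 82)
  crit <- default_criteria()$contact
  lik0 <- type_likelihood(calls, crit, "contact")
  # refine to a sub-box containing only contact calls
  sub <- criteria_box("sub", c(4.5, 5.5), c(6, 7))
  inside <- in_criteria(calls$duration_s, calls$syllable_count, sub)
  if (any(inside) && all(calls$type[inside] == "contact")) {
    expect_gte(type_likelihood(calls, sub, "contact"), lik0)
  }
})

test_that("percent match applies boxes to complete units with closed bounds", {
  crit <- default_criteria()$contact
  s <- make_session(oro_on = 0, oro_off = 120, visible_time_s = 600)
  s$orofacial_units$syllable_count <- 6L
  s$orofacial_units$duration_s <- 4.0
  expect_equal(percent_match(s, crit), 100)
  s$orofacial_units$duration_s <- 1.0
  s$orofacial_units$syllable_count <- 2L
  expect_equal(percent_match(s, crit), 0)
  # exact boundary: 3.69 s and 5 syllables is in-box
  s$orofacial_units$duration_s <- 3.69
  s$orofacial_units$syllable_count <- 5L
  expect_equal(percent_match(s, crit), 100)
  # partial-only session is flagged
  s$orofacial_units$partial <- TRUE
  expect_true(is.na(percent_match(s, crit)))
})

test_that("audio durations are adjusted by the median discrepancy", {
  r <- adjust_audio_durations(c(1, 2, 3), c(1.2, 2.2, 3.2), c(5, 6))
  expect_equal(r$delta, 0.2)
  expect_equal(r$adjusted, c(5.2, 6.2))
  r0 <- adjust_audio_durations(c(1, 2), c(1, 2), c(4, 5))
  expect_equal(r0$adjusted, c(4, 5))
  set.seed(83)
  a <- runif(9); d <- rnorm(9)
  r2 <- adjust_audio_durations(a, a + d, 0)
  expect_equal(r2$delta, sort(d)[5])  # sort-based median oracle
  expect_error(adjust_audio_durations(numeric(0), numeric(0), 1), "no paired")
})

test_that("criteria geometry: twitter and the long lick lobe avoid the contact box", {
  crit <- default_criteria()
  expect_true(criteria_overlap(crit$contact, crit$twitter)$disjoint)
  long_lick <- criteria_box("long", c(6.67, 14.29), c(10, 16))
  expect_true(criteria_overlap(crit$contact, long_lick)$disjoint)
  # the short lick lobe shares the sliver [3.69, 3.77] s x {5, 6} with the
  # contact box; the printed 0% likelihoods are empirical, not geometric
  ov <- criteria_overlap(crit$contact, crit$lick)
  expect_false(ov$disjoint)
  expect_equal(ov$regions[[1]]$duration, c(3.69, 3.77))
  expect_equal(ov$regions[[1]]$syllables, c(5, 6))
})

test_that("derived criteria isolate a well-separated type", {
  set.seed(84)
  calls <- rbind(
    data.frame(type = "contact", duration_s = runif(60, 4, 6),
               syllable_count = sample(5:9, 60, TRUE)),
    data.frame(type = "twitter", duration_s = runif(60, 0.5, 1.5),
               syllable_count = sample(1:3, 60, TRUE))
  )
  best <- derive_criteria(calls, "contact", min_capture = 0.8)
  expect_equal(best$likelihood, 1)
  expect_gte(best$capture, 0.8)
})
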