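test_that("generation is reproducible from the seed", {
  c1 <- generate_cohort(cohort_spec(n_pregnancies = 1,
                                    sessions_per_pregnancy = 4), seed = 7)
  c2 <- generate_cohort(cohort_spec(n_pregnancies = 1,
                                    sessions_per_pregnancy = 4), seed = 7)
  expect_identical(attr(c1, "events"), attr(c2, "events"))
  p1 <- generate_profile(profile_spec("contact"), seed = 3)
  p2 <- generate_profile(profile_spec("contact"), seed = 3)
  expect_identical(as.numeric(p1), as.numeric(p2))
  t1 <- generate_infant_calls(seed = 5)
  t2 <- generate_infant_calls(seed = 5)
  expect_identical(t1, t2)
})

test_that("generated sessions are valid inputs to every consuming stage", {
  coh <- generate_cohort(cohort_spec(n_pregnancies = 2,
                                     sessions_per_pregnancy = 6), seed = 8)
  expect_length(coh, 12)
  for (s in coh) {
    expect_s3_class(s, "fv_session")
    # within-kind sorted and non-overlapping
    for (u in list(s$orofacial_units, s$head_units)) {
      if (nrow(u) > 1) {
        expect_false(is.unsorted(u$onset))
        expect_true(all(u$onset[-1] >= u$offset[-nrow(u)]))
      }
      expect_true(all(u$offset <= s$visible_time_s * 30))
    }
    st <- session_states(s)
    expect_true(all(st$state %in% paste0("S", 1:5)))
  }
  # the attached event table reproduces the unit structure via the merge
  ev <- attr(coh, "events")
  rebuilt <- build_sessions(
    ev, stats::setNames(rep(900, length(coh)), names(coh)))
  for (sid in names(coh)) {
    expect_equal(rebuilt[[sid]]$orofacial_units$onset,
                 coh[[sid]]$orofacial_units$onset)
    expect_equal(rebuilt[[sid]]$orofacial_units$syllable_count,
                 coh[[sid]]$orofacial_units$syllable_count)
  }
})

test_that("full programmed coupling yields the constructed overlap fraction", {
  spec <- cohort_spec(n_pregnancies = 1, sessions_per_pregnancy = 4,
                      coupling = function(day) 1)
  coh <- generate_cohort(spec, seed = 9)
  for (s in coh) {
    n_o <- nrow(s$orofacial_units); n_h <- nrow(s$head_units)
    st <- session_states(s)
    n_pairs <- sum(st$state %in% c("S3", "S4", "S5"))
    expect_equal(percent_overlap(s), n_pairs / (n_o + n_h))
    # with c = 1 nearly every head is placed on an orofacial unit
    expect_gt(n_pairs / min(n_o, n_h), 0.6)
  }
})

test_that("zero coupling produces only chance-level overlap", {
  spec <- cohort_spec(n_pregnancies = 2, sessions_per_pregnancy = 8,
                      coupling = function(day) 0)
  coh <- generate_cohort(spec, seed = 10)
  obs <- 0; exp <- 0
  for (s in coh) {
    st <- session_states(s)
    obs <- obs + sum(st$state %in% c("S3", "S4", "S5"))
    span <- s$visible_time_s * 30
    busy_o <- sum(s$orofacial_units$offset - s$orofacial_units$onset) / span
    busy_h <- sum(s$head_units$offset - s$head_units$onset) / span
    exp <- exp + nrow(s$head_units) * busy_o + nrow(s$orofacial_units) * busy_h
  }
  expect_lt(abs(obs - exp) / exp, 0.35)
  expect_lt(obs / sum(sapply(coh, function(s)
    nrow(s$orofacial_units) + nrow(s$head_units))), 0.12)
})

test_that("profile generation respects syllable count and criteria boxes", {
  set.seed(12)
  for (k in c(1, 4, 16)) {
    v <- generate_profile(profile_spec("custom", syllable_count = k,
                                       noise_sd = 0, warp_amp = 0))
    expect_equal(count_profile_syllables(v), k)
  }
  # contact preset durations land inside the contact box by construction
  durs <- replicate(60, attr(generate_profile(profile_spec("contact")),
                             "duration_s"))
  expect_true(all(durs >= 3.69 & durs <= 6.5))
  # intra-call gaps must stay below the merge threshold
  expect_error(profile_spec("custom", gap_frames = c(5, 20)), "15 frames")
})

test_that("infant call tables carry the signature medians", {
  calls <- generate_infant_calls(n = c(contact = 400, twitter = 300,
                                       lick = 200), seed = 13)
  con <- calls[calls$type == "contact", ]
  twi <- calls[calls$type == "twitter", ]
  lic <- calls[calls$type == "lick", ]
  expect_equal(median(con$duration_s), 3.9, tolerance = 0.15)
  expect_equal(median(con$syllable_count), 5, tolerance = 0.5)
  expect_true(median(twi$duration_s) >= 0.96 && median(twi$duration_s) <= 1.5)
  expect_true(median(twi$syllable_count) %in% 2:3)
  # licks are bimodal: both lobes populated
  expect_gt(sum(lic$duration_s > 6.5), 10)
  expect_gt(sum(lic$duration_s < 3.77), 100)
  none <- generate_infant_calls(n = c(contact = 0, twitter = 10, lick = 0),
                                seed = 14)
  expect_true(all(none$type == "twitter"))
})

test_that("infeasible packing is rejected", {
  spec <- cohort_spec(n_pregnancies = 1, sessions_per_pregnancy = 2,
                      visible_time_s = 20,
                      orofacial_rate = function(day) 4000)
  expect_error(generate_cohort(spec, seed = 15), "infeasible packing")
})
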