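test_that("isolated and overlapping movements map to the documented states", {
  # no overlap: isolated orofacial then isolated head
  st <- classify_states(make_units(0, 100), make_units(200, 300))
  expect_equal(as.character(st$state), c("S1", "S2"))

  # head starts strictly inside the orofacial interval: orofacial leads
  st2 <- classify_states(make_units(0, 100), make_units(50, 160))
  expect_equal(as.character(st2$state), "S3")
  expect_equal(st2$anchor, 0L)

  # same onset frame: synchronous
  st3 <- classify_states(make_units(50, 160), make_units(50, 300))
  expect_equal(as.character(st3$state), "S5")

  # head leads, orofacial starts strictly inside
  st4 <- classify_states(make_units(80, 200), make_units(50, 160))
  expect_equal(as.character(st4$state), "S4")

  # onset exactly at the other unit's offset frame is no overlap
  st5 <- classify_states(make_units(0, 100), make_units(100, 160))
  expect_equal(as.character(st5$state), c("S1", "S2"))
})

test_that("each overlapping pair yields exactly one occurrence", {
  set.seed(21)
  for (rep in 1:25) {
    s <- random_session(n_oro = sample(3:15, 1), n_head = sample(3:15, 1))
    st <- classify_states(s$orofacial_units, s$head_units)
    n_pairs <- sum(st$state %in% c("S3", "S4", "S5"))
    expect_equal(nrow(st),
                 nrow(s$orofacial_units) + nrow(s$head_units) - n_pairs)
    expect_false(is.unsorted(st$anchor))
  }
})

test_that("classification is symmetric under kind exchange", {
  set.seed(22)
  swap <- c(S1 = "S2", S2 = "S1", S3 = "S4", S4 = "S3", S5 = "S5")
  for (rep in 1:20) {
    s <- random_session()
    a <- classify_states(s$orofacial_units, s$head_units)
    b <- classify_states(s$head_units, s$orofacial_units)
    expect_equal(as.character(b$state), unname(swap[as.character(a$state)]))
  }
})

test_that("state distribution gives empirical frequencies and flags empties", {
  p <- state_distribution(c("S1", "S1", "S2", "S5"))
  expect_equal(as.numeric(p), c(0.5, 0.25, 0, 0, 0.25))
  expect_equal(attr(p, "n"), 4)
  p2 <- state_distribution("S3")
  expect_equal(as.numeric(p2), c(0, 0, 1, 0, 0))
  p3 <- state_distribution(character(0))
  expect_true(all(is.na(p3)))
  expect_equal(attr(p3, "n"), 0)
})

test_that("transition matrix matches brute-force pair counting", {
  m <- transition_matrix(c("S1", "S2", "S1", "S2"))
  expect_equal(m["S1", "S2"], 1)
  expect_equal(m["S2", "S1"], 1)
  expect_equal(sum(m), 2)
  m2 <- transition_matrix(c("S1", "S1", "S1"))
  expect_equal(m2["S1", "S1"], 1)
  expect_equal(sum(m2), 1)

  set.seed(23)
  labs <- paste0("S", sample(1:5, 1000, replace = TRUE))
  m3 <- transition_matrix(labs)
  # oracle: count every consecutive pair directly
  counts <- matrix(0, 5, 5)
  for (k in 1:999) {
    i <- as.integer(substring(labs[k], 2))
    j <- as.integer(substring(labs[k + 1], 2))
    counts[i, j] <- counts[i, j] + 1
  }
  expect_equal(unname(m3), counts / rowSums(counts))
  expect_equal(unname(rowSums(m3)), rep(1, 5))
})

test_that("uncoupled streams overlap at about the random-coincidence rate", {
  # With independent renewal streams the chance that a given pair of units
  # coincides is governed by the busy fraction of each stream; estimate the
  # expected number of overlap occurrences from the generated intervals
  # themselves and compare against the classifier's count over many
  # sessions.
  set.seed(24)
  n_obs <- 0; n_exp <- 0
  for (rep in 1:200) {
    s <- random_session(n_oro = 10, n_head = 8, span_s = 400)
    st <- classify_states(s$orofacial_units, s$head_units)
    n_obs <- n_obs + sum(st$state %in% c("S3", "S4", "S5"))
    span <- s$visible_time_s * 30
    busy_o <- sum(s$orofacial_units$offset - s$orofacial_units$onset) / span
    busy_h <- sum(s$head_units$offset - s$head_units$onset) / span
    n_exp <- n_exp + nrow(s$head_units) * busy_o + nrow(s$orofacial_units) * busy_h
  }
  # pairing truncation makes the observed count slightly lower than the
  # naive expectation; agreement within 20% over 200 sessions
  expect_lt(abs(n_obs - n_exp) / n_exp, 0.2)
})
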