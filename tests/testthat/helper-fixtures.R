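# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

make_units <- function(onset, offset, partial = FALSE, syllables = 1L) {
  n <- length(onset)
  data.frame(
    onset = as.integer(onset),
    offset = as.integer(offset),
    duration_s = (offset - onset) / 30,
    syllable_count = rep_len(as.integer(syllables), n),
    partial = rep_len(partial, n),
    stringsAsFactors = FALSE
  )
}

make_session <- function(oro_on = integer(0), oro_off = integer(0),
                         head_on = integer(0), head_off = integer(0),
                         visible_time_s = 600, day = 100,
                         pregnancy = "P1", id = "S1",
                         oro_partial = FALSE, head_partial = FALSE) {
  fv_session(id, pregnancy, day, visible_time_s,
             make_units(oro_on, oro_off, oro_partial),
             make_units(head_on, head_off, head_partial))
}

make_events <- function(onset, offset, kind = "orofacial", partial = FALSE,
                        id = "S1") {
  movement_events(id, "P1", 100, kind, onset, offset, partial)
}

# Brute-force DTW by explicit enumeration of every monotone warping path
# (steps (1,0), (0,1), (1,1), endpoints matched). Exponential; tiny inputs
# only. Independent of the package's dynamic program.
dtw_bruteforce <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# All monotone warping paths for a given shape (n, m), as a list of
# two-column index matrices. Used by the vectorized exhaustive oracle in
# the acceptance suite.
all_warp_paths <- function(n, m) {
  paths <- list()
  walk <- function(i, j, acc) {
    acc[[length(acc) + 1]] <- c(i, j)
    if (i == n && j == m) {
      paths[[length(paths) + 1]] <<- do.call(rbind, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, list())
  paths
}

# Random renewal-style session used by property tests: two independent
# streams of non-overlapping units.
random_session <- function(n_oro = 10, n_head = 8, span_s = 600,
                           id = "S1", day = 100) {
  draw <- function(n) {
    dur <- sample(5:90, n, replace = TRUE)
    # gaps scaled so the stream spreads over the whole span
    gap_max <- max(2 * round(span_s * 30 / n) - 60, 10)
    gap <- sample(1:gap_max, n, replace = TRUE)
    off <- cumsum(gap + dur)
    on <- off - dur
    keep <- off <= span_s * 30
    list(on = on[keep], off = off[keep])
  }
  o <- draw(n_oro); h <- draw(n_head)
  make_session(o$on, o$off, h$on, h$off, visible_time_s = span_s,
               id = id, day = day)
}
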