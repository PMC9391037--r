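---
title: "Quantifying the prenatal emergence of vocal-motor behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the prenatal emergence of vocal-motor behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalvoc)
```

## The scientific question

Marmoset infants vocalize from the first day of life, and their dominant
vocalization — the contact call ("phee") — is a long, rhythmically
multi-syllabic signal. `fetalvoc` implements an analysis pipeline for
asking whether the motor program behind that call is assembled *before*
birth: serial ultrasound sessions across the last trimester (roughly
embryonic day E93 to birth at ~E146) are scored frame-by-frame for
orofacial movements (jaw separation) and head movements, and the package
quantifies (a) how the joint orofacial–head movement repertoire becomes
more ordered and decoupled with gestational age, and (b) how the temporal
shape, duration, and syllable structure of fetal mouth movements converge
on the signature of the infant contact call rather than on other orofacial
behaviors (twitter calls, licking).

All timelines are integer frames at exactly 30 Hz — the capture rate of
both the ultrasound and infant video — and seconds appear only at the I/O
boundary. This avoids floating-point drift in interval arithmetic and
mirrors how the source data were scored.

## Movement units

A scored *movement event* is a closed frame interval (onset = first frame
of jaw separation, offset = frame of full closure). Events of one kind
separated by gaps of at most 500 ms (15 frames) form one *movement unit*
(`merge_events()`); the constituent events are the unit's "syllables",
matching the criterion used to segment syllables of neonatal calls, where
500 ms splits the bimodal inter-syllable interval distribution. The
boundary case — a gap of exactly 15 frames — merges. Units truncated by
loss of the fetal face (`partial`) count toward movement *rates* (the
movement happened) but are excluded from *duration* and *syllable-number*
statistics (their tails are censored).

## Five-state co-occurrence coding and order statistics

Each movement occurrence is coded into one of five states: isolated
orofacial (S1), isolated head (S2), orofacial joined by an overlapping
head movement (S3), head joined by an overlapping orofacial movement (S4),
or synchronous onsets (S5). Overlap requires the later onset to fall at
least one frame after, and strictly before the offset of, the earlier
movement; each overlapping pair is a single occurrence, and a unit
overlapping several opposite-kind units is paired greedily with the first.
The per-session state distribution feeds two information measures:

- Shannon entropy $H(X) = -\sum_{i=1}^{5} P(X{=}i)\log_2 P(X{=}i)$
  (with $0\log 0 = 0$), bounded by $\log_2 5 \approx 2.32$ bits — the
  session-level behavioral variability;
- Kullback–Leibler divergence $KL(P\|Q)=\sum_i P_i \log_2 (P_i/Q_i)$ of
  each session's distribution from the early-gestation baseline $P$, the
  mean distribution of the E93–99 sessions. A session sharing no support
  with the baseline returns an explicit `Inf` rather than a silently
  smoothed value; an optional additive-smoothing argument exists for
  baselines with empty cells but defaults to off.

Both measures are invariant to relabeling the states, so the coding
direction of S3 versus S4 (which of the two orderings carries which
label) cannot affect any downstream trajectory.

## The overlap permutation null

Percent overlap — overlapping pairs over total movements — declines with
gestation, but so do movement rates; a decline in overlap could be pure
coincidence-rate arithmetic. The null model (`permutation_envelope()`)
therefore rebuilds every session with both streams independently
resampled: as many durations and as many inter-unit latencies as the
original stream had are drawn with replacement and laid end to end from
time zero, preserving the duration and latency marginals while destroying
any coupling. The initial offset from zero to the first onset is pooled
with the latencies, and shuffled units extending past the session span
are dropped (rescaling was rejected because it distorts the marginals).
Per replicate, overlap is averaged per gestational day — the same
aggregation applied to the observed data — and 1000 replicates give the
2.5/97.5 percentile envelope, the replicate slope distribution, and the
nullity p-value of the line fitted to the replicate-mean curve.
Replicate $r$ runs on a seed derived deterministically from the master
seed, so envelopes are exactly reproducible.

## Trend fitting

Developmental trajectories are fitted with ordinary least-squares
polynomials whose degree is chosen by a Gaussian-likelihood AIC,
$AIC(d) = n\ln(RSS_d/n) + 2k + 2k(k+1)/(n-k-1)$, $k = d+2$. The search is
incremental from degree 0 and stops after two consecutive degrees fail to
improve the criterion, keeping the best degree visited. This was a
genuinely open design point: a plain argmin over degrees 0–10 lets eight
spare degrees each take a ~16% chance at overfitting, which drops
exact-degree recovery to roughly two-thirds; a stop-at-first-increase
rule, conversely, terminates at degree 0 for near-symmetric inverse-U
shapes whose linear term vanishes. The two-miss patience rule with the
small-sample correction recovers the true degree in well over 80% of
simulated cohorts on both shape classes, and the selected degree is
invariant to rescaling the day axis because fitting is done on a
standardized predictor (coefficients are back-transformed for reporting).

Duration and syllable-number trajectories are summarized per session by
their median and quartiles (`percentile_trends()`); the degree is
selected on the median curve and reused for the 25th/75th percentile
curves so the three trajectories remain directly comparable.

Hypothesis tests on trajectories use `regress_with_pregnancy()`: OLS of
the response on gestational day plus reference-coded pregnancy
indicators, reporting the day slope, SE, t, and the single-term ANOVA F
and p (for this one-degree-of-freedom effect $F = t^2$ exactly). Fixed
effects were chosen over random intercepts because four pregnancies are
too few to estimate a variance component stably.

## Temporal profiles, DTW, and call templates

Mouth-opening traces are z-scored (shape, not amplitude, is the signal —
amplitude depends on probe position), smoothed with a Savitzky–Golay
filter (degree 3, window 9 frames; a degree-3 filter passes cubics
untouched), and compared by dynamic time warping. The DTW here is the
plain dynamic program with local cost $|a_i - b_j|$, steps
$\{(1,0),(0,1),(1,1)\}$, matched endpoints, and no path-length
normalization; an optional uniform linear-interpolation refinement of
both sequences approximates continuous-time DTW and defaults to off.
These semantics are pinned by an exhaustive path-enumeration oracle in
the test suite rather than assumed from any external implementation.

Infant contact-call templates (one per syllable count, 1–7) are built by
DTW barycenter averaging: profiles of one syllable count are aligned to
the current average, each average sample is updated to the mean of its
aligned samples, and iteration stops when the total DTW cost stops
decreasing (the best iterate is kept, so the recorded cost trace is
non-increasing by construction). The converged barycenter is smoothed
with a cubic smoothing spline at parameter 0.1; exemplar traces use
0.999. The spline is the csaps parameterization — minimize
$p\sum_i (y_i - f_i)^2 + (1-p)\int f''^2$ on the unit-spaced frame grid,
solved in Reinsch form — so $p = 1$ interpolates and $p \to 0$ tends to
the least-squares line.

Every fetal profile is matched against all templates and the lowest cost
retained (ties to the lower syllable count, an arbitrary but fixed rule);
session medians of the retained costs feed the pregnancy-controlled
regression. Profiles enter this stage only if they pass a quality gate:
at least as long as the smoothing window, and with an automated syllable
count (runs of the trace above 20% of its amplitude, minimum two frames)
agreeing with the manually scored count. The length requirement is our
reading of the smoothing-compatibility exclusion; it is stated as such
rather than claimed as the original criterion.

## Call criteria

Signature boxes are closed duration × syllable rectangles: contact
3.69–6.5 s × 5–9 syllables; twitter 0.96–1.5 s × 2–3; lick the union of
0.33–3.77 s × 1–6 and 6.67–14.29 s × 10–16. `percent_match()` scores a
session's complete units against a box; `type_likelihood()` computes the
fraction of in-box labeled infant calls carrying the target type. One
geometric fact deserves honesty: the contact box and the short-lick box
*intersect* in the sliver 3.69–3.77 s × {5, 6} syllables — a movement of
3.70 s and 5 syllables satisfies both. Empirical statements that no lick
falls in the contact box are claims about observed calls, not about the
rectangles; `criteria_overlap()` reports the shared region explicitly,
and the test suite records the geometric overlap as a known property.
Audio-measured durations can be reconciled with video-measured ones by
adding the median paired discrepancy (`adjust_audio_durations()`).

## The synthetic cohort

`generate_cohort()` emulates the study's structure so the whole pipeline
runs with no data download: four pregnancies with 16 sessions each on
alternate days E93–146 and 900 s of usable footage per session (about
15–45 min of recording of which a fraction shows the face). Orofacial
units arrive by a renewal process under an inverse-U rate schedule
peaking mid-window (~E118, between 40 and 120 movements/h); head units
decline linearly (60 to ~15/h, ~1.2 s mean duration, fewer than
orofacial units throughout as in the study counts); each head unit is
coupled to a *distinct* orofacial unit with probability declining
linearly 0.8 to 0.1, its orientation drawn uniformly among
orofacial-leading, head-leading, and synchronous — the young fetus mixes
all three, which is what makes early entropy high. The fraction of
contact-shaped orofacial units (5–9 syllables, duration drawn on the
frame grid inside 3.69–6.5 s) rises from 5% to 35%, driving the duration,
syllable-number, and percent-match trends; 7% of units are flagged
partial. Sessions are assembled by pushing the generated *events* through
`merge_events()`, so generator outputs are valid inputs to every
consuming stage by construction.

Call-shaped waveforms (`generate_profile()`) are trains of raised-cosine
open–close cycles with sub-500 ms gaps, amplitude jitter, additive
Gaussian noise, and a smooth monotone time warp (amplitude < 1/π
guarantees monotonicity). The infant call table (`generate_infant_calls()`)
draws 120 contact calls (median ≈ 3.9 s, 5 syllables), 109 twitters, and
37 bimodal licks.

What the generator does *not* emulate: physiological rhythms
(respiratory or autonomic periodicity), scorer disagreement, ultrasound
image-quality artifacts, and any dependence between consecutive sessions
of one fetus. Passing tests therefore demonstrate that the pipeline
recovers known structure from data of this form, not that the biological
effect sizes are as simulated.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty sessions yield flagged
`NA` distributions that consumers skip; near-exact polynomial fits are
floored at a relative RSS of 1e-12 so ties resolve toward the smaller
degree; constant profiles cannot be z-scored and are rejected; DTW ties
in backtracking prefer the diagonal. The test suite exercises the
permutation machinery at 1000 replicates over 20 seeded cohorts, degree
recovery over 100 cohorts, template matching over 200 profiles against
templates built from 25 synthetic infant calls, and the regression's
type-I error over 1000 null replicates — sizes chosen to keep Monte
Carlo error well below the tested margins while the full suite completes
in minutes.

## Known limitations

Only first-order transition structure is computed (no entropy rates of
higher-order chains); overlap is count-based (the duration-weighted
variant is out of scope); profiles are consumed, never extracted from
video; and the criteria-derivation grid search explores quantile bounds
of the target type rather than the full 0.01 s lattice, which is ample
for well-separated synthetic types but coarser than an exhaustive search.
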