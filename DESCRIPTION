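Package: fetalvoc
Title: Prenatal Development of Vocalization-Related Orofacial Movements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the prenatal emergence of vocal-motor
    behavior from ultrasound-scored movement records. Merges frame-scored
    orofacial and head movement events into movement units (bouts), codes
    each occurrence into a five-state orofacial/head co-occurrence scheme,
    and tracks developmental order through per-session Shannon entropy and
    Kullback-Leibler divergence from an early-gestation baseline. Tests
    orofacial-head decoupling with a duration- and latency-preserving
    permutation null, fits AIC-selected polynomial trends and
    pregnancy-controlled regressions, and matches mouth-opening temporal
    profiles to infant contact-call templates built by dynamic time warping
    (DTW) barycenter averaging. Duration-by-syllable criteria boxes classify
    movements as contact-call-like, twitter-like, or lick-like. A synthetic
    cohort generator emulates the event-stream and waveform structure of
    the study data so the full pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
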