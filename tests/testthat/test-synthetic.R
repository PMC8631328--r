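# Synthetic cohort generator: determinism, substream decoupling, band
# fidelity against a periodogram oracle, oddball log structure, cohort
# table structure and closed-loop marker recovery.

test_that("recordings are bit-identical for identical (seed, cell)", {
  spec <- cohort_spec(duration_s = 8, n_channels = 2, seed = 7)
  r1 <- generate_eeg(spec, 2, "Day3")
  r2 <- generate_eeg(spec, 2, "Day3")
  expect_identical(r1$samples, r2$samples)
  # a different channel count changes nothing for shared channels
  spec1 <- cohort_spec(duration_s = 8, n_channels = 1, seed = 7)
  r3 <- generate_eeg(spec1, 2, "Day3")
  expect_identical(r3$samples[, 1], r1$samples[, 1])
})

test_that("substreams decouple subjects, sessions and channels", {
  spec <- cohort_spec(duration_s = 8, n_channels = 2, seed = 7)
  r1 <- generate_eeg(spec, 1, "Day1")
  r2 <- generate_eeg(spec, 2, "Day1")
  r3 <- generate_eeg(spec, 1, "Day2")
  expect_false(identical(r1$samples, r2$samples))
  expect_false(identical(r1$samples, r3$samples))
  expect_false(identical(r1$samples[, 1], r1$samples[, 2]))
  # a cohort with more subjects reproduces subject 1 exactly
  spec_b <- cohort_spec(duration_s = 8, n_channels = 2, n_subjects = 5L,
                        seed = 7)
  expect_identical(generate_eeg(spec_b, 1, "Day1")$samples, r1$samples)
})

test_that("generator validates its inputs", {
  spec <- cohort_spec(duration_s = 8)
  expect_error(generate_eeg(spec, 10, "Day1"), "subject")
  expect_error(generate_eeg(spec, 1, "Day9"), "unknown session")
  expect_error(cohort_spec(duration_s = -4), "positive")
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(entropy_trajectory = c(0.5, 0.6)), "length")
  expect_error(cohort_spec(band_trajectory = matrix(1, 6, 4)), "sum to 1")
})

test_that("band specs carry the dyadic edges and valid profiles", {
  bs <- band_specs(c(delta = 0.25, theta = 0.25, alpha = 0.25,
                     beta = 0.25))
  expect_equal(bs$band_name, c("delta", "theta", "alpha", "beta"))
  # disjoint and ordered half-open ranges
  expect_true(all(diff(as.vector(rbind(bs$low_hz, bs$high_hz))) >= 0))
  expect_equal(bs$high_hz[1], bs$low_hz[2])
  expect_error(band_specs(c(delta = 0.5, theta = 0.5, alpha = 0.2,
                            beta = -0.2)), "non-negative")
  expect_error(band_specs(c(delta = 0.3, theta = 0.3, alpha = 0.3,
                            beta = 0.3)), "sum to 1")
})

test_that("profile solver hits the requested entropy exactly", {
  for (h in c(0.4, 0.65, 0.8, 0.95, 1)) {
    p <- profile_for_entropy(h)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(-log(sum(p^2)) / log(4), h, tolerance = 1e-6)
  }
  # out-of-range targets clamp to the attainable range
  p_lo <- profile_for_entropy(0.01)
  expect_true(all(p_lo >= 0))
  expect_equal(sum(p_lo), 1, tolerance = 1e-9)
})

test_that("generated band powers match the programmed profile (periodogram)", {
  # pure oscillatory mixture: measure after the analysis band-pass in the
  # dyadic detail-band windows (which tile the spectrum, so filter skirts
  # stay accounted for); 15% relative tolerance on each band share
  dy <- list(c(2, 3.90625), c(3.90625, 7.8125), c(7.8125, 15.625),
             c(15.625, 31.25))
  for (h in c(0.65, 0.9)) {
    spec <- cohort_spec(duration_s = 120, n_channels = 1, bg_fraction = 0,
                        between_subject_sd = 0, within_subject_sd = 0,
                        entropy_trajectory = rep(h, 6), seed = 31)
    prog <- profile_for_entropy(h)
    rec <- bandpass(generate_eeg(spec, 1, "Day1"))
    meas <- oracle_rel_band_power(rec$samples[, 1], spec$fs, dy)
    for (b in 1:4)
      expect_lt(abs(meas[b] - prog[b]) / prog[b], 0.15)
  }
})

test_that("background noise share is accounted for by the oracle", {
  # with 1/f background at its default 30% share, the expected band share
  # is (1-bg)*p_b + bg*w_b with w_b computed from the background's own
  # shaped spectrum (numeric integral, independent arithmetic)
  spec <- cohort_spec(duration_s = 120, n_channels = 1,
                      between_subject_sd = 0, within_subject_sd = 0,
                      entropy_trajectory = rep(0.8, 6), seed = 32)
  prog <- profile_for_entropy(0.8)
  dy <- list(c(2, 3.90625), c(3.90625, 7.8125), c(7.8125, 15.625),
             c(15.625, 31.25))
  f <- seq(0.01, 125, by = 0.01)
  mag2 <- function(f, lo, hi, ord = 4)
    (1 / (1 + (lo / f)^(2 * ord))) * (1 / (1 + (f / hi)^(2 * ord)))
  # background power density after generation shaping and the pipeline's
  # own band-pass: f^-1 * |band(3,30)|^2 (generation) * |band(3,30)|^2
  dens <- f^-1 * mag2(f, 3, 30)^2 * mag2(f, 3, 30)
  wb <- vapply(dy, function(b) sum(dens[f >= b[1] & f < b[2]]), numeric(1))
  bgshare <- wb / sum(wb)
  rec <- bandpass(generate_eeg(spec, 1, "Day1"))
  meas <- oracle_rel_band_power(rec$samples[, 1], spec$fs, dy)
  expected <- 0.7 * prog + 0.3 * bgshare
  expected <- expected / sum(expected)
  for (b in 1:4)
    expect_lt(abs(meas[b] - expected[b]) / expected[b], 0.15)
})

test_that("oddball logs have fixed-period onsets and seeded determinism", {
  sp <- oddball_spec("audio", total_duration_s = 240, isi_ms = 1000,
                     stim_dur_ms = 50, seed = 5)
  log <- generate_oddball_log(sp)
  stim <- log[log$kind != "press", ]
  expect_equal(nrow(stim), 228L) # floor(240 / 1.05)
  expect_equal(diff(sort(stim$time_s)), rep(1.05, 227), tolerance = 1e-12)
  expect_identical(generate_oddball_log(sp), log)
  expect_true(all(log$modality == "audio"))
  expect_false(is.unsorted(log$time_s))
})

test_that("deviant probability and responses behave as programmed", {
  # p_deviant = 0: no deviants, no presses
  log0 <- generate_oddball_log(oddball_spec(p_deviant = 0, rt_mean_s = 0.35,
                                            seed = 1))
  expect_equal(sum(log0$kind == "deviant"), 0L)
  expect_equal(sum(log0$kind == "press"), 0L)
  # long run: deviant fraction concentrates near 0.2 (10500 s -> 10000)
  spL <- oddball_spec(p_deviant = 0.2, total_duration_s = 10500,
                      miss_rate = 0, seed = 9)
  logL <- generate_oddball_log(spL)
  stim <- logL[logL$kind != "press", ]
  expect_equal(nrow(stim), 10000L)
  expect_lt(abs(mean(stim$kind == "deviant") - 0.2), 0.01)
  # every response falls inside the valid window of some deviant
  dv <- logL$time_s[logL$kind == "deviant"]
  pr <- logL$time_s[logL$kind == "press"]
  expect_equal(length(pr), length(dv))
  expect_true(all(pr - dv > 0.1 & pr - dv <= 1.0))
})

test_that("oddball spec validates probabilities and geometry", {
  expect_error(oddball_spec(p_deviant = 1.2), "probabilities")
  expect_error(oddball_spec(miss_rate = -0.1), "probabilities")
  expect_error(oddball_spec(total_duration_s = 0.5), "period")
  expect_error(oddball_spec(rt_mean_s = 2), "window")
})

test_that("cohort has one row per subject x session with valid values", {
  spec <- cohort_spec(n_subjects = 9L, duration_s = 8, seed = 3)
  ch <- generate_cohort(spec, keep_recordings = FALSE,
                        oddball_audio = oddball_spec("audio",
                                                     total_duration_s = 60),
                        oddball_visual = oddball_spec("visual",
                                                      total_duration_s = 60))
  expect_equal(nrow(ch$sessions), 54L) # 9 x 6
  expect_true(all(ch$sessions$sss %in% 1:7))
  expect_true(all(ch$sessions$sleep_min >= 0))
  expect_true(all(ch$sessions$rt_audio_s > 0.1 &
                    ch$sessions$rt_audio_s < 1.0))
  expect_equal(validate_session_table(ch$sessions)$issues,
               validate_session_table(ch$sessions)$issues[0, ],
               ignore_attr = TRUE)
  # deterministic regeneration
  ch2 <- generate_cohort(spec, keep_recordings = FALSE,
                         oddball_audio = oddball_spec("audio",
                                                      total_duration_s = 60),
                         oddball_visual = oddball_spec("visual",
                                                       total_duration_s = 60))
  expect_identical(ch$sessions, ch2$sessions)
})

test_that("zero trends and zero noise give identical SSS across sessions", {
  spec <- cohort_spec(n_subjects = 2L, duration_s = 8, seed = 3)
  tr <- cohort_trends(sss_mean = rep(3, 6), sss_between_sd = 0,
                      sss_within_sd = 0, sleep_mean = rep(300, 6),
                      sleep_sd = rep(0, 6))
  ch <- generate_cohort(spec, trends = tr, keep_recordings = FALSE,
                        oddball_audio = oddball_spec("audio",
                                                     total_duration_s = 30),
                        oddball_visual = oddball_spec("visual",
                                                      total_duration_s = 30))
  expect_true(all(ch$sessions$sss == 3L))
  expect_true(all(ch$sessions$sleep_min == 300))
})

test_that("latent SSS outside 1..7 is clamped and reported", {
  spec <- cohort_spec(n_subjects = 2L, duration_s = 8, seed = 3)
  tr <- cohort_trends(sss_mean = c(0, 1, 2, 6, 8, 9), sss_between_sd = 0,
                      sss_within_sd = 0)
  expect_message(
    ch <- generate_cohort(spec, trends = tr, keep_recordings = FALSE,
                          oddball_audio = oddball_spec("audio",
                                                       total_duration_s = 30),
                          oddball_visual = oddball_spec("visual",
                                                        total_duration_s = 30)),
    "clamped")
  expect_true(all(ch$sessions$sss >= 1 & ch$sessions$sss <= 7))
})

test_that("programmed band flattening is recovered as rising entropy", {
  # concentrated profile -> lower downstream entropy than uniform profile
  specC <- cohort_spec(duration_s = 32, n_channels = 1,
                       entropy_trajectory = rep(0.30, 6),
                       between_subject_sd = 0, within_subject_sd = 0,
                       seed = 3)
  specU <- cohort_spec(duration_s = 32, n_channels = 1,
                       entropy_trajectory = rep(1, 6),
                       between_subject_sd = 0, within_subject_sd = 0,
                       seed = 3)
  hC <- cell_entropy(specC, 1, "Day1")
  hU <- cell_entropy(specU, 1, "Day1")
  expect_lt(hC, hU)
  # uniform programmed profile lands within 0.1 of the maximum
  expect_lt(abs(hU - 1), 0.1)
})

test_that("programmed negative sleep-entropy coupling appears in pooled r", {
  spec <- cohort_spec(n_subjects = 4L, duration_s = 32, n_channels = 1,
                      seed = 11)
  ch <- generate_cohort(spec, keep_recordings = FALSE,
                        oddball_audio = oddball_spec("audio",
                                                     total_duration_s = 30),
                        oddball_visual = oddball_spec("visual",
                                                      total_duration_s = 30))
  ent <- unlist(lapply(seq_len(spec$n_subjects), function(subj)
    sapply(spec$session_labels, function(s) cell_entropy(spec, subj, s))))
  # sessions table is subject-major in the same order
  r <- pearson(ent, ch$sessions$sleep_min)
  expect_lt(r$r, 0)
})
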