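# Generators: determinism, ground-truth bookkeeping, and signal properties
# recoverable by independent oracles.

test_that("speech generator is seed-deterministic and rejects bad schedules", {
  sp <- audio_spec(1.2, f0_contour = data.frame(start_s = 0, end_s = 1.2,
                                                f0_hz = 140),
                   pause_schedule = data.frame(onset_s = 0.5, offset_s = 0.7),
                   seed = 21)
  a1 <- make_speech_audio(sp)
  a2 <- make_speech_audio(sp)
  expect_identical(a1$audio$samples, a2$audio$samples)

  expect_error(audio_spec(2, pause_schedule = data.frame(
    onset_s = c(0.2, 0.4), offset_s = c(0.5, 0.8))), "overlap")
  expect_error(audio_spec(1, theta_am_depth = 1.5), "theta_am_depth")
})

test_that("scheduled pauses appear verbatim in the ground-truth segmentation", {
  ps <- data.frame(onset_s = c(0.6, 1.4, 2.2), offset_s = c(0.9, 1.7, 2.5))
  sp <- audio_spec(3, pause_schedule = ps, seed = 4)
  seg <- make_speech_audio(sp)$segmentation
  pauses <- seg$events[seg$events$kind == "pause", ]
  expect_equal(nrow(pauses), 3)
  expect_equal(pauses$onset_s, ps$onset_s)
  expect_equal(pauses$offset_s, ps$offset_s)
  # events tile the sample
  expect_equal(seg$events$onset_s[-1], head(seg$events$offset_s, -1))
  expect_equal(max(seg$events$offset_s), 3)
})

test_that("voiced audio carries the scheduled f0 (autocorrelation oracle)", {
  sp <- audio_spec(1.0, f0_contour = data.frame(start_s = 0, end_s = 1,
                                                f0_hz = 150), seed = 5)
  x <- make_speech_audio(sp)$audio
  # independent oracle: raw autocorrelation peak on one voiced frame
  frame <- x$samples[2001:4000]
  lags <- 40:300
  ac <- vapply(lags, function(L)
    sum(frame[1:(2000 - L)] * frame[(L + 1):2000]), numeric(1))
  f0_hat <- x$fs / lags[which.max(ac)]
  expect_lt(abs(f0_hat - 150), 2)
})

test_that("sEMG triplet is deterministic, validated, and coupling-faithful", {
  es <- semg_spec(3, coupling = 0.5, seed = 9)
  c1 <- make_semg_triplet(es)
  c2 <- make_semg_triplet(es)
  expect_identical(c1$RTEMP$samples, c2$RTEMP$samples)
  expect_named(c1, c("RTEMP", "RMAS", "RABD"))
  expect_error(semg_spec(3, coupling = 1.2), "coupling")
  expect_error(semg_spec(3, drive_bands = list(c(100, 1100))), "drive bands")

  # coupling = 1 with one drive band: raw coherence approaches 1 in band
  es1 <- semg_spec(30, burst_schedule = data.frame(onset_s = 0.2,
                                                   offset_s = 29.8),
                   drive_bands = list(c(15, 25)), coupling = 1,
                   noise_sd = 0.01, seed = 10)
  tri <- make_semg_triplet(es1)
  sp <- coherence_spectrum(tri$RTEMP, tri$RMAS)
  inband <- sp$freqs >= 16 & sp$freqs < 24
  expect_gt(mean(sp$coh[inband]), 0.95)
})

test_that("uncoupled channels carry no significant band coherence (Monte Carlo)", {
  hits <- vapply(1:20, function(s) {
    es <- semg_spec(60, burst_schedule = data.frame(onset_s = 0.2,
                                                    offset_s = 59.8),
                    coupling = 0, seed = 100 + s)
    tri <- make_semg_triplet(es)
    sp <- coherence_spectrum(tri$RTEMP, tri$RMAS)
    feats <- band_coherence_features(
      list(RTEMP_RMAS = sp, RTEMP_RABD = sp, RABD_RMAS = sp))
    all(feats[c("IMC_RTEMP_RMAS_theta_alpha", "IMC_RTEMP_RMAS_beta",
                "IMC_RTEMP_RMAS_gamma")] == 0)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cohort generator yields the expected table shape and null effects", {
  recs <- make_cohort(c(2, 3), n_sentences = 2, seed = 1)
  expect_length(recs, 10)
  expect_equal(sum(vapply(recs, function(r) r$group == "ALS", logical(1))), 6)
  # determinism
  recs2 <- make_cohort(c(2, 3), n_sentences = 2, seed = 1)
  expect_identical(recs[[1]]$audio$samples, recs2[[1]]$audio$samples)
  expect_error(make_cohort(1), "at least 2")
  expect_error(make_cohort(2, effect_map = c(bogus = 1)), "unknown")
})

test_that("pause lengthening injected at the signal level shifts pause features", {
  # recompute Cohen's d on generated cohorts (feature-level oracle)
  eff <- c(pause_dur = 3)
  recs <- make_cohort(4, effect_map = eff, n_sentences = 2, seed = 3)
  gt_mean_pause <- vapply(recs, function(r) {
    seg <- attr(r, "ground_truth")$segmentation
    d <- seg$events$offset_s - seg$events$onset_s
    mean(d[seg$events$kind == "pause"])
  }, numeric(1))
  grp <- vapply(recs, function(r) r$group, character(1))
  d <- cohens_d_screen(data.frame(p = gt_mean_pause), grp)$d
  expect_gt(abs(d), 0.5)
  expect_lt(mean(gt_mean_pause[grp == "control"]),
            mean(gt_mean_pause[grp == "ALS"]))
})

test_that("factor-table generator recovers its own covariance structure", {
  L <- matrix(0, 5, 1); L[, 1] <- 0.8
  rownames(L) <- paste0("x", 1:5)
  ft <- make_factor_table(2000, L, seed = 2)
  expect_identical(ft$table, make_factor_table(2000, L, seed = 2)$table)
  # implied inter-item correlation = 0.64
  cm <- cor(ft$table)
  expect_equal(mean(cm[upper.tri(cm)]), 0.64, tolerance = 0.05)
  # null structure
  ft0 <- make_factor_table(500, matrix(0, 4, 1), uniqueness = 1, seed = 3)
  cm0 <- cor(ft0$table)
  expect_lt(max(abs(cm0[upper.tri(cm0)])), 0.15)
  expect_error(make_factor_table(10, L, uniqueness = -1), "uniqueness")
})
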