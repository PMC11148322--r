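# Envelope extraction, theta modulation depth, n:m phase synchronization,
# and the cochlear critical-band filterbank.

test_that("the Hilbert envelope of an AM tone tracks the modulator", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  x <- time_series((1 + 0.5 * cos(2 * pi * 5 * t)) * cos(2 * pi * 100 * t), fs)
  env <- envelope_100hz(x)
  expect_equal(env$fs, 100)
  tt <- seq(0, by = 1 / 100, length.out = length(env$samples))
  expected <- 1 + 0.5 * cos(2 * pi * 5 * tt)
  core <- round(0.1 * length(tt)):round(0.9 * length(tt))
  expect_lt(max(abs(env$samples[core] - expected[core])) / max(expected), 0.05)

  # constant tone: constant envelope
  xc <- time_series(cos(2 * pi * 100 * t), fs)
  ec <- envelope_100hz(xc)
  expect_lt(diff(range(ec$samples[core])) / mean(ec$samples), 0.02)
})

test_that("pause excision shortens the envelope by the pause duration", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- time_series(cos(2 * pi * 50 * t), fs)
  ev <- data.frame(kind = c("speech", "pause", "speech"),
                   onset_s = c(0, 1.5, 2.5), offset_s = c(1.5, 2.5, 4))
  seg <- mmbulbar:::new_segmentation(ev, 4)
  env <- envelope_100hz(x, seg)
  expect_equal(length(env$samples), 3 * 100 + 1, tolerance = 2)
  expect_error(envelope_100hz(time_series(cos(2 * pi * 50 * t[1:500]), fs),
                              mmbulbar:::new_segmentation(
                                data.frame(kind = "speech", onset_s = 0,
                                           offset_s = 0.5), 0.5)),
               "less than 1 s")
})

test_that("theta modulation depth isolates the theta band", {
  t <- seq(0, 20, by = 0.01)
  env_theta <- time_series(1 + cos(2 * pi * 5 * t), 100)
  expect_gt(theta_mod_depth(env_theta), 0.95)
  env_delta <- time_series(1 + cos(2 * pi * 1.5 * t), 100)
  expect_lt(theta_mod_depth(env_delta), 0.1)
  env_two <- time_series(1 + cos(2 * pi * 5 * t) + cos(2 * pi * 20 * t), 100)
  expect_equal(theta_mod_depth(env_two), 0.5, tolerance = 0.05)
  expect_error(theta_mod_depth(time_series(rep(1, 50), 100)), "2 s")
})

test_that("n:m PSI detects exact locking, rejects the null, ignores amplitude", {
  t <- seq(0, 100, by = 0.01)
  locked <- time_series(1 + 0.3 * cos(2 * pi * 1.75 * t) +
                          0.3 * cos(2 * pi * 3.5 * t), 100)
  psi <- nm_psi(locked, c(0.9, 2.5), c(2.5, 12), n = 2, m = 1)
  expect_gt(psi, 0.95)
  # PSI(x, x) with n = m = 1 is exactly 1
  single <- time_series(1 + 0.3 * cos(2 * pi * 5 * t), 100)
  expect_equal(nm_psi(single, c(2.5, 12), c(2.5, 12), 1, 1), 1,
               tolerance = 1e-9)
  # amplitude scaling leaves the phase statistic unchanged
  scaled <- time_series(7 * locked$samples, 100)
  expect_equal(nm_psi(scaled, c(0.9, 2.5), c(2.5, 12), 2, 1), psi)
  # independent narrowband components: PSI small (Monte Carlo)
  null_psi <- vapply(1:5, function(s) {
    e <- time_series(1 + band_noise(10001, 100, 0.9, 2.5, seed = s) +
                       band_noise(10001, 100, 2.5, 12, seed = 100 + s), 100)
    nm_psi(e, c(0.9, 2.5), c(2.5, 12), 2, 1)
  }, numeric(1))
  expect_lt(max(null_psi), 0.1)
  expect_error(nm_psi(time_series(rep(1, 5000), 100), c(0.9, 2.5),
                      c(2.5, 12), 2, 1), "degenerate")
})

test_that("null PSI decays roughly as 1/sqrt(N) with envelope length", {
  psi_at <- function(n_s, seeds) median(vapply(seeds, function(s) {
    e <- time_series(1 + band_noise(n_s * 100 + 1, 100, 0.9, 2.5, seed = s) +
                       band_noise(n_s * 100 + 1, 100, 2.5, 12, seed = 200 + s),
                     100)
    nm_psi(e, c(0.9, 2.5), c(2.5, 12), 2, 1)
  }, numeric(1)))
  short <- psi_at(25, 1:7)
  long <- psi_at(400, 1:7)
  # 16x the length: expect roughly 4x decay; accept >= 2x
  expect_gt(short / long, 2)
})

test_that("the critical-band filterbank is selective and partitions correctly", {
  fs <- 22050
  t <- seq(0, 2, by = 1 / fs)
  tone <- time_series(sin(2 * pi * 200 * t), fs)
  envs <- cochlear_critical_envelopes(tone)
  expect_named(envs, c("100_300", "300_800", "1000_3000", "3000_8000"))
  means <- vapply(envs, function(e) mean(e$samples), numeric(1))
  expect_gt(means["100_300"], 5 * max(means[-1]))

  # every narrowband centre maps to at most one critical band; centres in
  # the 800-1,000 and 8,000-10,000 Hz gaps map to none
  centers <- attr(envs, "centers_hz")
  cb <- critical_bands()
  n_members <- vapply(centers, function(fc)
    sum(vapply(cb, function(b) fc >= b[1] && fc < b[2], logical(1))),
    numeric(1))
  expect_true(all(n_members <= 1))
  in_gap <- (centers >= 800 & centers < 1000) |
    (centers >= 8000 & centers <= 10000)
  expect_true(all(n_members[in_gap] == 0))
  expect_true(any(in_gap))

  # white noise excites all four critical bands
  set.seed(3)
  wn <- time_series(rnorm(2 * fs), fs)
  en <- cochlear_critical_envelopes(wn)
  expect_true(all(vapply(en, function(e) mean(e$samples) > 0, logical(1))))
})

test_that("the rhythm block emits 21 correctly named bounded features", {
  rec <- fixture_recording(seed = 41)
  seg <- segment_speech_pauses(rec$audio, speaking_rate_wpm = 170)
  semg_envs <- lapply(lapply(rec$semg, preprocess_semg), envelope_100hz,
                      segmentation = seg)
  crit_envs <- cochlear_critical_envelopes(rec$audio, seg)
  fb <- rhythm_feature_block(semg_envs, crit_envs)
  expect_length(fb, 21)
  expect_true(all(fb >= 0 & fb <= 1))
  man <- feature_manifest(as_table = TRUE)
  expect_setequal(names(fb), man$name[man$construct == "rhythm"])
  # strong scheduled theta AM shows up in all acoustic depths
  expect_true(all(fb[paste0("hbenvlp_mod_depth_theta_",
                            names(critical_bands()))] > 0.5))
})
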