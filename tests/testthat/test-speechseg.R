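# Pause/speech segmentation with rate-scaled thresholds, pause features,
# f0 tracking, and semitone prosody features.

test_that("segmentation recovers the scheduled pauses and tiles the sample", {
  ps <- data.frame(onset_s = c(0.8, 1.6, 2.3), offset_s = c(1.1, 1.9, 2.6))
  sp <- audio_spec(3.2, pause_schedule = ps,
                   f0_contour = data.frame(start_s = 0, end_s = 3.2,
                                           f0_hz = 120), seed = 5)
  audio <- make_speech_audio(sp)$audio
  seg <- segment_speech_pauses(audio, seg_params(), 160)
  ev <- seg$events
  expect_equal(sum(ev$kind == "pause"), 3)
  expect_equal(ev$onset_s[-1], head(ev$offset_s, -1))   # exact tiling
  expect_equal(max(ev$offset_s), duration(audio))
  # detected pause onsets within the 10-ms gate ramps of the schedule
  det <- ev[ev$kind == "pause", ]
  expect_lt(max(abs(det$onset_s - ps$onset_s)), 0.05)
})

test_that("sub-threshold runs shorter than the scaled minimum are not pauses", {
  sp <- audio_spec(2, pause_schedule = data.frame(onset_s = 1.0,
                                                  offset_s = 1.1),
                   f0_contour = data.frame(start_s = 0, end_s = 2,
                                           f0_hz = 120), seed = 6)
  audio <- make_speech_audio(sp)$audio
  # 100-ms silence < 150-ms minimum at the baseline rate: no pause
  seg <- segment_speech_pauses(audio, seg_params(), 160)
  expect_equal(sum(seg$events$kind == "pause"), 0)
  # halving the speaking rate doubles the duration thresholds, so the same
  # 100-ms silence is still below the 300-ms scaled minimum
  seg2 <- segment_speech_pauses(audio, seg_params(), 80)
  expect_equal(sum(seg2$events$kind == "pause"), 0)
  # doubling the rate halves the minimum to 75 ms: now it is a pause
  seg3 <- segment_speech_pauses(audio, seg_params(), 320)
  expect_equal(sum(seg3$events$kind == "pause"), 1)
})

test_that("continuous tone gives one speech event; silence warns with one pause", {
  tone <- time_series(sin(2 * pi * 200 * seq(0, 1, by = 1 / 22050)), 22050)
  seg <- segment_speech_pauses(tone, seg_params(), 160)
  expect_equal(nrow(seg$events), 1)
  expect_equal(seg$events$kind, "speech")

  quiet <- time_series(1e-7 * sin(1:22050), 22050)
  expect_warning(seg0 <- segment_speech_pauses(quiet, seg_params(), 160),
                 "all-silent")
  expect_equal(seg0$events$kind, "pause")
})

test_that("pause features match hand arithmetic and conventions", {
  ev <- data.frame(kind = c("speech", "pause", "speech", "pause", "speech"),
                   onset_s = c(0, 1.0, 1.2, 2.0, 2.4),
                   offset_s = c(1.0, 1.2, 2.0, 2.4, 3.0))
  seg <- mmbulbar:::new_segmentation(ev, 3)
  pf <- pause_features(seg)
  expect_equal(unname(pf["MeanDur_intrapause"]), 0.3)
  expect_equal(unname(pf["SdevDur_intrapause"]), sd(c(0.2, 0.4)))
  expect_equal(unname(pf["pct_intrapause"]), 20)

  # single pause: SD 0 by convention
  ev1 <- data.frame(kind = c("pause", "speech"), onset_s = c(0, 0.5),
                    offset_s = c(0.5, 2))
  pf1 <- pause_features(mmbulbar:::new_segmentation(ev1, 2))
  expect_equal(unname(pf1), c(0.5, 0, 25))

  # no pauses
  ev2 <- data.frame(kind = "speech", onset_s = 0, offset_s = 2)
  expect_equal(unname(pause_features(mmbulbar:::new_segmentation(ev2, 2))),
               c(0, 0, 0))
})

test_that("f0 tracking recovers a sawtooth fundamental and flags noise unvoiced", {
  sp <- audio_spec(1.0, f0_contour = data.frame(start_s = 0, end_s = 1,
                                                f0_hz = 150), seed = 5)
  audio <- make_speech_audio(sp)$audio
  tr <- extract_f0(audio, "M")
  expect_lt(abs(median(tr$f0_hz[tr$voiced]) - 150), 2)

  # a 220-Hz tone gives the same answer under both window lengths
  tone <- time_series(sin(2 * pi * 220 * seq(0, 1, by = 1 / 22050)), 22050)
  fM <- median(extract_f0(tone, "M")$f0_hz[extract_f0(tone, "M")$voiced])
  fF <- median(extract_f0(tone, "F")$f0_hz[extract_f0(tone, "F")$voiced])
  expect_lt(abs(fM - fF), 1)

  # white noise: no (or almost no) voiced frames
  set.seed(4)
  noise <- time_series(rnorm(22050), 22050)
  res <- tryCatch(extract_f0(noise, "M"), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "unvoiced")
  } else {
    expect_gte(mean(!res$voiced), 0.9)
  }
})

test_that("prosody features follow the semitone closed forms", {
  mk_trace <- function(f0) structure(
    list(times_s = seq_along(f0) / 100, f0_hz = f0,
         voiced = rep(TRUE, length(f0)), window_s = 0.02),
    class = "mmb_f0trace")
  # constant pitch: zero spread
  pf <- prosody_features(mk_trace(rep(220, 50)))
  expect_equal(unname(pf["sdevF0.st"]), 0)
  expect_equal(unname(pf["iqrF0.st"]), 0)
  expect_equal(unname(pf["meanF0.st"]), 12 * log2(220))

  # one-octave equal alternation: SD ~ 6 st, IQR = 12 st
  f0 <- rep(c(220, 440), 200)
  pf2 <- prosody_features(mk_trace(f0))
  expect_equal(unname(pf2["sdevF0.st"]), 6, tolerance = 0.01)
  expect_equal(unname(pf2["iqrF0.st"]), 12, tolerance = 1e-6)

  # doubling every f0 shifts the mean by +12 st, leaves spread unchanged
  pf3 <- prosody_features(mk_trace(2 * f0))
  expect_equal(unname(pf3["meanF0.st"] - pf2["meanF0.st"]), 12)
  expect_equal(unname(pf3["sdevF0.st"]), unname(pf2["sdevF0.st"]))
  expect_equal(unname(pf3["iqrF0.st"]), unname(pf2["iqrF0.st"]))

  expect_error(prosody_features(mk_trace(220)), "2 voiced")
})

test_that("segmentation export writes one labelled event per line", {
  ev <- data.frame(kind = c("speech", "pause"), onset_s = c(0, 1.25),
                   offset_s = c(1.25, 1.5))
  seg <- mmbulbar:::new_segmentation(ev, 1.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_segmentation(seg, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_match(lines[2], "^1\\.250000\t1\\.500000\tpause$")
})
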