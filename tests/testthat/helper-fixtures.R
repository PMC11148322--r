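# Shared fixtures: small, seeded synthetic inputs built in code.

# one short multimodal recording with known ground truth; two interior
# 200-ms pauses scaled to the requested duration
fixture_recording <- function(seed = 7, duration = 4.4) {
  p1 <- 0.32 * duration; p2 <- 0.64 * duration
  asp <- audio_spec(
    duration,
    f0_contour = data.frame(
      start_s = c(0, p1 + 0.2, p2 + 0.2),
      end_s = c(p1, p2, duration),
      f0_hz = c(118, 126, 121)),
    pause_schedule = data.frame(onset_s = c(p1, p2),
                                offset_s = c(p1 + 0.2, p2 + 0.2)),
    theta_am_rate = 4.5, theta_am_depth = 0.5, seed = seed)
  make_recording(asp, participant_id = "P01", group = "control", sex = "M",
                 speaking_rate_wpm = 170)
}

# band-limited noise via a zero-phase Butterworth band-pass
band_noise <- function(n, fs, lo, hi, seed = 1) {
  set.seed(seed)
  flt <- signal::butter(2, c(lo, hi) / (fs / 2), "pass")
  as.numeric(signal::filtfilt(flt, rnorm(n)))
}

reduced_config <- function() extract_config(rqa_max_segments = 1)
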