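# Pause/speech segmentation of the acoustic waveform with rate-scaled
# duration thresholds, and the pause features derived from it.

#' Segmentation threshold settings
#'
#' Baseline values follow established speech-pause-analysis practice:
#' minimum pause duration 150 ms, minimum speech-event duration 35 ms, and an
#' amplitude threshold of 0.04, here interpreted as a fraction of the
#' sample's peak absolute amplitude applied to a 10-ms RMS envelope so the
#' segmentation is invariant to recording gain. The duration thresholds are
#' scaled by `baseline_rate_wpm / speaking_rate_wpm`: slower speakers get
#' proportionally longer minimum durations.
#'
#' @param min_pause_s baseline minimum pause duration (s)
#' @param min_speech_s baseline minimum speech-event duration (s)
#' @param amp_threshold amplitude threshold as a fraction of peak |waveform|
#' @param baseline_rate_wpm reference speaking rate (words per minute)
#' @param env_win_s RMS envelope window (s)
#' @param silence_floor absolute amplitude below which the whole sample is
#'   treated as silent (the main threshold is relative to the sample's own
#'   peak, so silence needs an absolute floor)
#' @param scale_direction `"inverse"` (default) scales thresholds by
#'   baseline/actual rate; `"direct"` scales by actual/baseline
#' @return list of settings
#' @export
seg_params <- function(min_pause_s = 0.150, min_speech_s = 0.035,
                       amp_threshold = 0.04, baseline_rate_wpm = 160,
                       env_win_s = 0.010, silence_floor = 1e-5,
                       scale_direction = c("inverse", "direct")) {
  scale_direction <- match.arg(scale_direction)
  stopifnot(min_pause_s > 0, min_speech_s > 0, amp_threshold > 0,
            baseline_rate_wpm > 0)
  as.list(environment())
}

new_segmentation <- function(events, duration_s) {
  structure(list(events = events, duration_s = duration_s),
            class = "mmb_segmentation")
}

#' @export
print.mmb_segmentation <- function(x, ...) {
  np <- sum(x$events$kind == "pause")
  cat(sprintf("<mmb_segmentation> %.3f s, %d events (%d pauses)\n",
              x$duration_s, nrow(x$events), np))
  invisible(x)
}

#' Segment an audio waveform into pause and speech events
#'
#' A short-window RMS envelope is thresholded at
#' `amp_threshold x max(|waveform|)`. Sub-threshold runs at least as long as
#' the (rate-scaled) minimum pause duration become pauses; supra-threshold
#' runs shorter than the (rate-scaled) minimum speech duration are absorbed
#' into adjacent pauses. Events exactly tile the sample.
#'
#' @param audio an [time_series()]
#' @param params a [seg_params()]
#' @param speaking_rate_wpm the speaker's rate, used to scale the duration
#'   thresholds
#' @return an `mmb_segmentation` (events data.frame: kind, onset_s, offset_s)
#' @export
segment_speech_pauses <- function(audio, params = seg_params(),
                                  speaking_rate_wpm = params$baseline_rate_wpm) {
  stopifnot(inherits(audio, "mmb_ts"), speaking_rate_wpm > 0)
  fs <- audio$fs
  n <- length(audio$samples)
  scale <- if (params$scale_direction == "inverse")
    params$baseline_rate_wpm / speaking_rate_wpm
  else speaking_rate_wpm / params$baseline_rate_wpm
  min_pause_n <- round(params$min_pause_s * scale * fs)
  min_speech_n <- round(params$min_speech_s * scale * fs)
  env <- moving_rms(audio$samples, round(params$env_win_s * fs))
  thr <- params$amp_threshold * max(abs(audio$samples))
  speech <- env >= thr
  if (max(abs(audio$samples)) < params$silence_floor) speech[] <- FALSE
  if (!any(speech)) {
    warning("all-silent audio: returning a single pause event")
    ev <- data.frame(kind = "pause", onset_s = 0, offset_s = n / fs)
    return(new_segmentation(ev, n / fs))
  }
  # sub-threshold runs >= min pause become pauses; shorter ones are speech
  pause <- logical(n)
  low <- true_runs(!speech)
  for (i in seq_len(nrow(low)))
    if (low$len[i] >= min_pause_n) pause[low$start[i]:low$end[i]] <- TRUE
  # supra-threshold runs < min speech adjacent to a pause are absorbed
  sp <- true_runs(!pause)
  for (i in seq_len(nrow(sp))) {
    if (sp$len[i] >= min_speech_n) next
    left_pause <- sp$start[i] > 1 && pause[sp$start[i] - 1]
    right_pause <- sp$end[i] < n && pause[sp$end[i] + 1]
    if (left_pause || right_pause) pause[sp$start[i]:sp$end[i]] <- TRUE
  }
  r <- rle(pause)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  ev <- data.frame(kind = ifelse(r$values, "pause", "speech"),
                   onset_s = (starts - 1) / fs, offset_s = ends / fs)
  new_segmentation(ev, n / fs)
}

#' Pause features from a segmentation
#'
#' Mean and sample standard deviation of pause durations (seconds) and the
#' percentage of total time spent in pauses. With no pauses all three are 0;
#' with a single pause the SD is 0 by convention.
#'
#' @param seg an `mmb_segmentation`
#' @return named numeric: `MeanDur_intrapause`, `SdevDur_intrapause`,
#'   `pct_intrapause`
#' @export
pause_features <- function(seg) {
  stopifnot(inherits(seg, "mmb_segmentation"))
  ev <- seg$events
  d <- ev$offset_s[ev$kind == "pause"] - ev$onset_s[ev$kind == "pause"]
  if (length(d) == 0)
    return(c(MeanDur_intrapause = 0, SdevDur_intrapause = 0,
             pct_intrapause = 0))
  c(MeanDur_intrapause = mean(d),
    SdevDur_intrapause = if (length(d) > 1) stats::sd(d) else 0,
    pct_intrapause = 100 * sum(d) / seg$duration_s)
}

#' Export a segmentation as a plain-text label file
#'
#' One event per line: onset, offset (seconds, 6 decimals), kind.
#' @param seg an `mmb_segmentation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_segmentation <- function(seg, path) {
  ev <- seg$events
  writeLines(sprintf("%.6f\t%.6f\t%s", ev$onset_s, ev$offset_s, ev$kind),
             path)
  invisible(path)
}

# indices (logical mask) of samples belonging to speech events
speech_mask <- function(seg, fs, n) {
  keep <- logical(n)
  ev <- seg$events[seg$events$kind == "speech", , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    a <- max(1L, floor(ev$onset_s[i] * fs) + 1L)
    b <- min(n, ceiling(ev$offset_s[i] * fs))
    if (b >= a) keep[a:b] <- TRUE
  }
  keep
}

#' Excise pauses from a time series given a segmentation
#'
#' Speech events are concatenated in order; used before the rhythm analysis.
#' @param ts an [time_series()]
#' @param seg an `mmb_segmentation` on the same timeline
#' @return an [time_series()] containing only the speech samples
#' @export
excise_pauses <- function(ts, seg) {
  stopifnot(inherits(ts, "mmb_ts"), inherits(seg, "mmb_segmentation"))
  keep <- speech_mask(seg, ts$fs, length(ts$samples))
  if (!any(keep)) stop("no speech samples left after pause excision")
  time_series(ts$samples[keep], ts$fs, ts$label)
}
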