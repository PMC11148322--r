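# Recording I/O and the sEMG preprocessing chain: zero-phase 60 Hz notch +
# 20 Hz high-pass, DC removal, full-wave rectification, and burst-centred
# 1-s epoching.

#' Write a multimodal recording to disk
#'
#' Audio goes to a mono PCM-16 WAV file; the three sEMG channels go to a
#' tab-delimited text file with a header row naming the channels.
#'
#' @param rec an [multimodal_recording()]
#' @param audio_path WAV output path
#' @param semg_path delimited-text output path
#' @param digits significant digits for the sEMG text (17 round-trips
#'   doubles exactly)
#' @return invisibly, a list of the two paths
#' @export
write_recording <- function(rec, audio_path, semg_path, digits = 17) {
  stopifnot(inherits(rec, "mmb_recording"))
  write_wav(rec$audio, audio_path)
  m <- sapply(rec$semg, function(ch) ch$samples)
  df <- as.data.frame(format(m, digits = digits, scientific = TRUE,
                             trim = TRUE))
  utils::write.table(df, semg_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(audio = audio_path, semg = semg_path))
}

#' Read a multimodal recording from disk
#'
#' @param audio_path mono WAV path
#' @param semg_path delimited sEMG text path; must have a header row naming
#'   at least the channels `RTEMP`, `RMAS`, `RABD`
#' @param metadata list of metadata fields passed to
#'   [multimodal_recording()] (`participant_id`, `group`, `sex`,
#'   `speaking_rate_wpm`, `sentence_id`)
#' @param semg_fs sampling rate of the sEMG file in Hz
#' @param expected_fs named numeric `c(audio = ..., semg = ...)` of expected
#'   rates, or `NULL` to skip the check
#' @param fs_tol relative tolerance of the rate check
#' @return an `mmb_recording`
#' @export
read_recording <- function(audio_path, semg_path, metadata = list(),
                           semg_fs = 2000,
                           expected_fs = c(audio = 22050, semg = 2000),
                           fs_tol = 0.001) {
  audio <- read_wav(audio_path)
  tab <- utils::read.table(semg_path, header = TRUE, sep = "")
  if (ncol(tab) < 3)
    stop("sEMG file must have at least 3 numeric columns, found ", ncol(tab))
  wanted <- c("RTEMP", "RMAS", "RABD")
  missing_ch <- setdiff(wanted, names(tab))
  if (length(missing_ch))
    stop("missing sEMG channel label(s): ", paste(missing_ch, collapse = ", "))
  if (!is.null(expected_fs)) {
    if (abs(audio$fs - expected_fs[["audio"]]) > fs_tol * expected_fs[["audio"]])
      stop(sprintf("audio sampling rate mismatch: got %g Hz, expected %g Hz",
                   audio$fs, expected_fs[["audio"]]))
    if (abs(semg_fs - expected_fs[["semg"]]) > fs_tol * expected_fs[["semg"]])
      stop(sprintf("sEMG sampling rate mismatch: got %g Hz, expected %g Hz",
                   semg_fs, expected_fs[["semg"]]))
  }
  semg <- lapply(wanted, function(ch) time_series(tab[[ch]], semg_fs, ch))
  names(semg) <- wanted
  do.call(multimodal_recording, c(list(audio = audio, semg = semg), metadata))
}

#' sEMG preprocessing: 60 Hz notch, 20 Hz high-pass, DC removal
#'
#' A second-order IIR notch (Q = 30) and a 4th-order Butterworth high-pass,
#' both applied forward-backward (zero phase); the mean is removed last.
#'
#' @param ts an [time_series()] (or numeric vector with `fs`)
#' @param fs sampling rate when `ts` is a bare vector
#' @param notch_hz notch centre frequency (power-line)
#' @param notch_q notch quality factor (centre / bandwidth)
#' @param highpass_hz high-pass corner frequency
#' @return preprocessed [time_series()]
#' @export
preprocess_semg <- function(ts, fs = NULL, notch_hz = 60, notch_q = 30,
                            highpass_hz = 20) {
  ts <- as_ts(ts, fs)
  x <- ts$samples
  if (length(x) < 0.1 * ts$fs)
    stop("series shorter than filter warm-up (need >= 0.1 s)")
  # RBJ biquad notch at notch_hz with quality notch_q
  w0 <- 2 * pi * notch_hz / ts$fs
  alpha <- sin(w0) / (2 * notch_q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  x <- zp_filtfilt(b, a, x)
  x <- zp_butter(x, 4, highpass_hz / (ts$fs / 2), "high")
  x <- x - mean(x)
  time_series(x, ts$fs, ts$label)
}

#' Full-wave rectification
#'
#' @param ts an [time_series()] (or numeric vector)
#' @return the element-wise absolute value, same container as the input
#' @export
rectify <- function(ts) {
  if (inherits(ts, "mmb_ts")) {
    ts$samples <- abs(ts$samples)
    ts
  } else abs(ts)
}

#' Burst-detector and epoching settings
#'
#' The burst detector is the package's own (the reference procedure does not
#' define one): the smoothed rectified envelope is thresholded at
#' `q_low + rel_height * (q_high - q_low)` of its own distribution, which
#' adapts to the recording's quiet floor and activity level without
#' calibration. Envelopes whose quantile spread is below
#' `min_contrast x median` are treated as containing no activity (flat or
#' noise-only recordings). All constants are exposed here.
#'
#' @param epoch_s epoch length in seconds
#' @param rms_win_s moving-RMS smoothing window
#' @param min_burst_s minimum supra-threshold duration to count as a burst
#' @param max_gap_s sub-threshold gaps shorter than this are bridged before
#'   the minimum-duration rule (the drive-modulated envelope dips briefly
#'   within one burst)
#' @param q_low,q_high envelope quantiles anchoring the quiet floor and the
#'   activity level
#' @param rel_height threshold position between the two anchors
#' @param min_contrast minimum `(q_high - q_low) / median` spread for the
#'   envelope to count as containing activity at all
#' @param stationarity_max_ratio epochs whose first/second-half RMS ratio
#'   exceeds this are discarded as non-stationary
#' @return list of settings
#' @export
burst_config <- function(epoch_s = 1, rms_win_s = 0.1, min_burst_s = 0.2,
                         max_gap_s = 0.2, q_low = 0.10, q_high = 0.90,
                         rel_height = 0.25, min_contrast = 0.5,
                         stationarity_max_ratio = 3) {
  as.list(environment())
}

# detect burst centres (seconds) on a rectified series
detect_burst_centers <- function(ts, cfg = burst_config()) {
  env <- moving_rms(ts$samples, round(cfg$rms_win_s * ts$fs))
  qs <- stats::quantile(env, c(cfg$q_low, cfg$q_high))
  if ((qs[2] - qs[1]) < cfg$min_contrast * stats::median(env))
    return(numeric(0))   # flat envelope: no discernible activity
  thr <- qs[1] + cfg$rel_height * (qs[2] - qs[1])
  above <- env > thr
  # bridge brief sub-threshold dips inside a burst
  gaps <- true_runs(!above)
  n <- length(above)
  for (i in seq_len(nrow(gaps)))
    if (gaps$len[i] < cfg$max_gap_s * ts$fs &&
        gaps$start[i] > 1 && gaps$end[i] < n)
      above[gaps$start[i]:gaps$end[i]] <- TRUE
  runs <- true_runs(above)
  if (nrow(runs) > 0)
    runs <- runs[runs$len >= cfg$min_burst_s * ts$fs, , drop = FALSE]
  if (nrow(runs) == 0) return(numeric(0))
  centers <- numeric(0)
  ep_n <- cfg$epoch_s * ts$fs
  for (i in seq_len(nrow(runs))) {
    len <- runs$len[i]
    # candidate centres tile the run; the greedy placer enforces non-overlap
    k <- max(1L, ceiling(len / ep_n))
    centers <- c(centers, runs$start[i] + (seq_len(k) - 0.5) * len / k)
  }
  centers / ts$fs
}

#' Extract and concatenate stationary 1-s epochs centred on activity bursts
#'
#' Bursts are detected on the smoothed rectified envelope; non-overlapping
#' epochs of `epoch_s` seconds are placed greedily at the burst centres
#' (shifted to tile when they would overlap), and epochs failing a simple
#' stationarity proxy (first/second-half RMS ratio) are discarded.
#'
#' @param ts rectified, preprocessed [time_series()]
#' @param cfg a [burst_config()]
#' @param centers optional externally supplied burst centres in seconds
#'   (e.g. shared across channels); when `NULL` they are detected from `ts`
#' @return a [time_series()] of the concatenated epochs with attribute
#'   `epoch_log` (data.frame of epoch centres and bounds, in seconds)
#' @export
burst_epoch_concat <- function(ts, cfg = burst_config(), centers = NULL) {
  stopifnot(inherits(ts, "mmb_ts"))
  if (duration(ts) < cfg$epoch_s)
    stop("series shorter than one epoch")
  if (is.null(centers)) centers <- detect_burst_centers(ts, cfg)
  if (length(centers) == 0) stop("no supra-threshold activity")
  n <- length(ts$samples)
  ep_n <- round(cfg$epoch_s * ts$fs)
  starts <- integer(0)
  prev_end <- 0L
  for (c_s in sort(centers)) {
    st <- round(c_s * ts$fs) - ep_n %/% 2
    st <- max(st, prev_end)           # shift right to tile
    if (st + ep_n > n) st <- n - ep_n # clamp to the series end
    if (st < prev_end) next           # cannot fit without overlap
    starts <- c(starts, st)
    prev_end <- st + ep_n
  }
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    ep <- ts$samples[(starts[i] + 1):(starts[i] + ep_n)]
    h <- ep_n %/% 2
    r1 <- sqrt(mean(ep[1:h]^2)); r2 <- sqrt(mean(ep[(h + 1):ep_n]^2))
    ratio <- max(r1, r2) / max(min(r1, r2), 1e-12)
    keep[i] <- ratio <= cfg$stationarity_max_ratio
  }
  starts <- starts[keep]
  if (length(starts) == 0) stop("no supra-threshold activity")
  out <- unlist(lapply(starts, function(st)
    ts$samples[(st + 1):(st + ep_n)]))
  log <- data.frame(center_s = (starts + ep_n / 2) / ts$fs,
                    onset_s = starts / ts$fs,
                    offset_s = (starts + ep_n) / ts$fs)
  res <- time_series(out, ts$fs, ts$label)
  attr(res, "epoch_log") <- log
  res
}
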