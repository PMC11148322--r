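#' Uniformly sampled time series
#'
#' Light-weight container used for all signals in the package: a numeric
#' sample vector, its sampling rate in Hz, and a channel label.
#'
#' @param samples numeric vector of finite samples
#' @param fs sampling rate in Hz (> 0)
#' @param label channel name (e.g. `"RTEMP"`, `"audio"`)
#' @return an object of class `mmb_ts`
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 1/100)), fs = 100)
#' duration(ts)
#' @export
time_series <- function(samples, fs, label = "signal") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (length(samples) == 0) stop("empty sample vector")
  if (any(!is.finite(samples))) stop("non-finite samples in '", label, "'")
  structure(list(samples = samples, fs = fs, label = as.character(label)),
            class = "mmb_ts")
}

#' @export
print.mmb_ts <- function(x, ...) {
  cat(sprintf("<mmb_ts> '%s': %d samples @ %g Hz (%.3f s)\n",
              x$label, length(x$samples), x$fs, duration(x)))
  invisible(x)
}

#' Duration of a time series in seconds
#' @param ts an `mmb_ts`
#' @return length in seconds
#' @export
duration <- function(ts) length(ts$samples) / ts$fs

# coerce vector-or-ts to mmb_ts
as_ts <- function(x, fs = NULL, label = "signal") {
  if (inherits(x, "mmb_ts")) return(x)
  if (is.null(fs)) stop("fs required when passing a bare numeric vector")
  time_series(x, fs, label)
}

#' One multimodal speech sample
#'
#' Bundles the synchronized audio waveform, the three surface-EMG channels
#' (right anterior temporalis RTEMP, right masseter RMAS, right anterior belly
#' of digastric RABD) and the participant metadata for one sentence.
#'
#' @param audio an [time_series()] at (nominally) 22,050 Hz
#' @param semg named list of exactly three [time_series()] at (nominally)
#'   2,000 Hz, names `RTEMP`, `RMAS`, `RABD`
#' @param participant_id identifier string
#' @param group one of `"control"`, `"ALS"`, `"ALS+B"`, `"ALS-B"`
#' @param sex `"M"` or `"F"`
#' @param speaking_rate_wpm speaking rate in words per minute (used to scale
#'   the pause/speech duration thresholds)
#' @param sentence_id sentence index within the reading passage (1..19)
#' @return an object of class `mmb_recording`
#' @export
multimodal_recording <- function(audio, semg, participant_id = "P01",
                                 group = c("control", "ALS", "ALS+B", "ALS-B"),
                                 sex = c("M", "F"),
                                 speaking_rate_wpm = 160, sentence_id = 1L) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  stopifnot(inherits(audio, "mmb_ts"))
  if (!is.list(semg) || length(semg) != 3)
    stop("exactly 3 sEMG channels are required")
  wanted <- c("RTEMP", "RMAS", "RABD")
  if (is.null(names(semg)) || !setequal(names(semg), wanted))
    stop("sEMG channels must be named RTEMP, RMAS, RABD")
  semg <- semg[wanted]
  for (ch in wanted) {
    stopifnot(inherits(semg[[ch]], "mmb_ts"))
    semg[[ch]]$label <- ch
  }
  if (!is.numeric(speaking_rate_wpm) || speaking_rate_wpm <= 0)
    stop("speaking_rate_wpm must be positive")
  structure(list(audio = audio, semg = semg,
                 participant_id = as.character(participant_id),
                 group = group, sex = sex,
                 speaking_rate_wpm = speaking_rate_wpm,
                 sentence_id = as.integer(sentence_id)),
            class = "mmb_recording")
}

#' @export
print.mmb_recording <- function(x, ...) {
  cat(sprintf("<mmb_recording> %s sentence %d [%s, %s, %.0f WPM]\n",
              x$participant_id, x$sentence_id, x$group, x$sex,
              x$speaking_rate_wpm))
  cat(sprintf("  audio: %.2f s @ %g Hz; sEMG: %.2f s @ %g Hz x 3\n",
              duration(x$audio), x$audio$fs,
              duration(x$semg[[1]]), x$semg[[1]]$fs))
  invisible(x)
}
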