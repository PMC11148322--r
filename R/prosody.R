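# Fundamental-frequency tracking (normalized cross-correlation) and the
# semitone-scale prosody features.

#' Track the vocal fundamental frequency
#'
#' Frame-wise normalized cross-correlation: each analysis frame is
#' cross-correlated with the immediately following samples over the lag range
#' implied by the f0 search range; the lag of the highest normalized
#' correlation gives the period, refined by parabolic interpolation. Frames
#' whose peak correlation falls below the voicing threshold are marked
#' unvoiced. The window is 20 ms for male and 10 ms for female voices; the
#' search range is 60-300 Hz (male) / 100-500 Hz (female).
#'
#' @param audio an [time_series()]
#' @param sex `"M"` or `"F"`
#' @param hop_s frame hop in seconds
#' @param f0_range override of the search range `c(lo, hi)` in Hz
#' @param voicing_threshold minimum normalized correlation for a voiced frame
#' @return an object of class `mmb_f0trace`: data.frame-backed list with
#'   `times_s`, `f0_hz`, `voiced`, plus the window length used
#' @export
extract_f0 <- function(audio, sex = c("M", "F"), hop_s = 0.010,
                       f0_range = NULL, voicing_threshold = 0.5) {
  sex <- match.arg(sex)
  stopifnot(inherits(audio, "mmb_ts"))
  fs <- audio$fs
  win_s <- if (sex == "M") 0.020 else 0.010
  if (is.null(f0_range)) f0_range <- if (sex == "M") c(60, 300) else c(100, 500)
  w <- round(win_s * fs)
  lag_min <- max(2L, floor(fs / f0_range[2]))
  lag_max <- ceiling(fs / f0_range[1])
  x <- audio$samples
  n <- length(x)
  if (n < w + lag_max + 1) stop("audio shorter than one analysis window")
  starts <- seq(1, n - w - lag_max, by = max(1L, round(hop_s * fs)))
  times <- f0 <- rr <- numeric(length(starts))
  c2 <- cumsum(c(0, x^2))
  for (i in seq_along(starts)) {
    s <- starts[i]
    x1 <- x[s:(s + w - 1)]
    e1 <- sum(x1^2)
    times[i] <- (s - 1 + w / 2) / fs
    if (e1 < 1e-12) { rr[i] <- 0; next }
    seg <- x[s:(s + w + lag_max - 1)]
    # numerator for all lags via FFT cross-correlation
    L <- stats::nextn(length(seg) + w)
    X1 <- stats::fft(c(rev(x1), numeric(L - w)))
    XS <- stats::fft(c(seg, numeric(L - length(seg))))
    cc <- Re(stats::fft(X1 * XS, inverse = TRUE)) / L
    num <- cc[w:(w + lag_max)]          # lag 0..lag_max
    e2 <- c2[s + (0:lag_max) + w] - c2[s + (0:lag_max)]
    r <- num / sqrt(e1 * pmax(e2, 1e-24))
    lags <- lag_min:lag_max
    rl <- r[lags + 1]
    k <- which.max(rl)
    rr[i] <- rl[k]
    lag <- lags[k]
    # parabolic refinement around the peak
    if (k > 1 && k < length(rl)) {
      y1 <- rl[k - 1]; y2 <- rl[k]; y3 <- rl[k + 1]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / den
    }
    f0[i] <- fs / lag
  }
  voiced <- rr >= voicing_threshold & f0 >= f0_range[1] & f0 <= f0_range[2]
  if (!any(voiced)) stop("unvoiced sample: no voiced frame found")
  structure(list(times_s = times, f0_hz = f0, voiced = voiced,
                 window_s = win_s, corr = rr),
            class = "mmb_f0trace")
}

#' @export
print.mmb_f0trace <- function(x, ...) {
  cat(sprintf("<mmb_f0trace> %d frames (%.0f%% voiced), window %g ms\n",
              length(x$times_s), 100 * mean(x$voiced), 1000 * x$window_s))
  invisible(x)
}

#' Semitone-scale prosody features from an f0 trace
#'
#' f0 values of voiced frames are converted to semitones
#' (`12 * log2(f0 / ref)`, reference 1 Hz by convention - only the mean
#' depends on the reference); the features are their sample SD, interquartile
#' range, and mean.
#'
#' @param trace an `mmb_f0trace`
#' @param ref_hz semitone reference frequency
#' @return named numeric: `sdevF0.st`, `iqrF0.st`, `meanF0.st`
#' @export
prosody_features <- function(trace, ref_hz = 1) {
  stopifnot(inherits(trace, "mmb_f0trace"))
  f0 <- trace$f0_hz[trace$voiced]
  if (length(f0) < 2) stop("fewer than 2 voiced frames")
  st <- 12 * log2(f0 / ref_hz)
  c(sdevF0.st = stats::sd(st), iqrF0.st = stats::IQR(st),
    meanF0.st = mean(st))
}
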