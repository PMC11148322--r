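# Intermuscular coherence: Welch auto/cross spectra (Hamming 1024, 75%
# overlap, 4096-point FFT), magnitude-squared coherence, an
# independent-segments significance level, and the band-gated features.

#' Welch settings for the coherence analysis
#'
#' @param nfft FFT length (zero-padded)
#' @param win_len sliding window length in samples (Hamming)
#' @param overlap fractional window overlap
#' @param lhat_factor variance-equivalent independent-segment factor: the
#'   adjusted segment count is `L_hat = K * lhat_factor` where `K` is the
#'   number of overlapped windows (0.52 is the standard correction for a
#'   Hamming window at 75% overlap)
#' @return list of settings
#' @export
coherence_params <- function(nfft = 4096, win_len = 1024, overlap = 0.75,
                             lhat_factor = 0.52) {
  stopifnot(win_len <= nfft, overlap >= 0, overlap < 1)
  as.list(environment())
}

#' Frequency bands of the oscillatory drives
#'
#' theta/alpha 4-12 Hz (slow subcortical/cortical drive), beta 12-30 Hz
#' (fast motor-cortical drive for submaximal tonic contraction), low gamma
#' 30-60 Hz (stronger tonic and phasic contraction). Band membership is
#' half-open `[lo, hi)`.
#' @return named list of `c(lo, hi)` Hz
#' @export
imc_bands <- function() {
  list(theta_alpha = c(4, 12), beta = c(12, 30), gamma = c(30, 60))
}

#' Magnitude-squared coherence spectrum of two signals
#'
#' Welch-averaged auto- and cross-spectra with the stated window and overlap;
#' coherence is `|Sxy|^2 / (Sxx * Syy)` per frequency bin. Also returns the
#' adjusted independent-segment count `L_hat` and the corresponding
#' significance level.
#'
#' @param x,y equal-length [time_series()] (or numeric vectors with `fs`);
#'   in the pipeline these are the rectified, burst-epoched sEMG channels
#' @param params a [coherence_params()]
#' @param fs sampling rate when `x`, `y` are bare vectors
#' @return object of class `mmb_coherence`: list with `freqs`, `coh`,
#'   `sxx`, `syy`, `sxy`, `L_hat`, `sig_level`
#' @export
coherence_spectrum <- function(x, y, params = coherence_params(), fs = NULL) {
  x <- as_ts(x, fs); y <- as_ts(y, fs)
  if (length(x$samples) != length(y$samples))
    stop("x and y must have equal length")
  if (x$fs != y$fs) stop("x and y must share a sampling rate")
  n <- length(x$samples)
  win <- params$win_len
  if (n < 2 * win) stop("series shorter than two windows")
  hop <- round(win * (1 - params$overlap))
  starts <- seq(1, n - win + 1, by = hop)
  K <- length(starts)
  w <- signal::hamming(win)
  segmat <- function(z) {
    m <- vapply(starts, function(s) z[s:(s + win - 1)] * w, numeric(win))
    rbind(m, matrix(0, params$nfft - win, K))
  }
  X <- stats::mvfft(segmat(x$samples))
  Y <- stats::mvfft(segmat(y$samples))
  nb <- params$nfft / 2 + 1
  X <- X[1:nb, , drop = FALSE]; Y <- Y[1:nb, , drop = FALSE]
  sxx <- rowMeans(Mod(X)^2)
  syy <- rowMeans(Mod(Y)^2)
  sxy <- rowMeans(X * Conj(Y))
  coh <- Mod(sxy)^2 / pmax(sxx * syy, 1e-300)
  coh <- pmin(coh, 1)
  L_hat <- K * params$lhat_factor
  sig <- if (L_hat > 1) significance_threshold(L_hat) else NA_real_
  structure(list(freqs = (0:(nb - 1)) * x$fs / params$nfft, coh = coh,
                 sxx = sxx, syy = syy, sxy = sxy, K = K, L_hat = L_hat,
                 sig_level = sig, fs = x$fs),
            class = "mmb_coherence")
}

#' @export
print.mmb_coherence <- function(x, ...) {
  cat(sprintf(
    "<mmb_coherence> %d bins to %.1f Hz, K = %d windows, L_hat = %.1f, S = %.3f\n",
    length(x$freqs), max(x$freqs), x$K, x$L_hat, x$sig_level))
  invisible(x)
}

#' @export
plot.mmb_coherence <- function(x, xlim = c(0, 100), ...) {
  graphics::plot(x$freqs, x$coh, type = "l", xlim = xlim, ylim = c(0, 1),
                 xlab = "Frequency (Hz)", ylab = "Coherence", ...)
  graphics::abline(h = x$sig_level, lty = 2)
  invisible(x)
}

#' Significance level of coherence under independence
#'
#' The upper 95% confidence limit of coherence between independent signals,
#' `S = 1 - 0.05^(1/(L_hat - 1))`, where `L_hat` is the adjusted number of
#' overlapped segments. Strictly decreasing in `L_hat`.
#'
#' @param L_hat adjusted segment count (> 1)
#' @return the significance level in (0, 1)
#' @examples
#' significance_threshold(2)   # 0.95
#' @export
significance_threshold <- function(L_hat) {
  if (any(L_hat <= 1)) stop("L_hat must exceed 1")
  1 - 0.05^(1 / (L_hat - 1))
}

#' Band-averaged, significance-gated coherence features
#'
#' Mean coherence over the in-band bins for each muscle pair and band; band
#' means below the pair's significance level are set to zero, since only
#' supra-significance coherence carries information about functional
#' connectivity.
#'
#' @param specs named list of three `mmb_coherence` objects, names
#'   `RTEMP_RMAS`, `RTEMP_RABD`, `RABD_RMAS`
#' @param bands named list of `c(lo, hi)` bands, see [imc_bands()]
#' @return named numeric of 9 features `IMC_<pair>_<band>`
#' @export
band_coherence_features <- function(specs, bands = imc_bands()) {
  pairs <- c("RTEMP_RMAS", "RTEMP_RABD", "RABD_RMAS")
  if (is.null(names(specs)) || !setequal(names(specs), pairs))
    stop("specs must be named ", paste(pairs, collapse = ", "))
  out <- numeric(0)
  for (bn in names(bands)) {
    b <- bands[[bn]]
    for (pr in pairs) {
      sp <- specs[[pr]]
      sel <- sp$freqs >= b[1] & sp$freqs < b[2]
      if (!any(sel)) stop("band ", bn, " outside the frequency grid")
      v <- mean(sp$coh[sel])
      if (is.na(sp$sig_level) || v < sp$sig_level) v <- 0
      out[paste0("IMC_", pr, "_", bn)] <- v
    }
  }
  out
}

#' Dump a coherence spectrum to CSV for inspection
#' @param spec an `mmb_coherence`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_coherence <- function(spec, path) {
  utils::write.csv(data.frame(freq = spec$freqs, coh = spec$coh,
                              sig_level = spec$sig_level),
                   path, row.names = FALSE)
  invisible(path)
}
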