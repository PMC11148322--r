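# Multiscale envelope rhythm metrics: Hilbert envelopes at 100 Hz, theta
# modulation depth, n:m phase-synchronization indices, and the ERB-spaced
# cochlear filterbank combined into four critical-band envelopes.

#' Rhythm timescale bands (Hz, at the 100-Hz envelope rate)
#'
#' delta 0.9-2.5 Hz (prosodic stress), theta 2.5-12 Hz (syllables),
#' beta/gamma 12-40 Hz (sub-syllabic segments).
#' @return named list of `c(lo, hi)`
#' @export
timescale_bands <- function() {
  list(delta = c(0.9, 2.5), theta = c(2.5, 12), beta_gamma = c(12, 40))
}

#' Critical bands of the acoustic analysis (Hz)
#'
#' 100-300 (vocal pitch), 300-800 (first formant), 1,000-3,000 (second
#' formant), 3,000-8,000 (consonant noise energy). The gaps 800-1,000 and
#' 8,000-10,000 Hz are intentionally excluded.
#' @return named list of `c(lo, hi)`
#' @export
critical_bands <- function() {
  list(`100_300` = c(100, 300), `300_800` = c(300, 800),
       `1000_3000` = c(1000, 3000), `3000_8000` = c(3000, 8000))
}

#' Hilbert envelope resampled to 100 Hz
#'
#' Pauses are excised first when a segmentation is supplied; the magnitude of
#' the analytic signal is anti-alias filtered and resampled to `fs_out`.
#'
#' @param ts an [time_series()]
#' @param segmentation optional `mmb_segmentation` for pause excision
#' @param fs_out output envelope rate in Hz
#' @return an [time_series()] envelope at `fs_out`
#' @export
envelope_100hz <- function(ts, segmentation = NULL, fs_out = 100) {
  stopifnot(inherits(ts, "mmb_ts"))
  if (!is.null(segmentation)) ts <- excise_pauses(ts, segmentation)
  if (duration(ts) < 1) stop("less than 1 s of signal after pause excision")
  # zero-pad to a 2-3-5-smooth length for the FFT, then trim the envelope
  n <- length(ts$samples)
  np <- stats::nextn(n, c(2, 3, 5))
  env <- Mod(analytic_signal(c(ts$samples, numeric(np - n))))[seq_len(n)]
  time_series(resample_to(env, ts$fs, fs_out), fs_out,
              paste0(ts$label, "_env"))
}

#' Theta modulation depth of an envelope
#'
#' The demeaned envelope's power spectrum (2048-point FFT, Hamming window,
#' Welch-averaged when the envelope exceeds one window) is integrated over
#' the theta band and normalized by the total spectral power above DC. The
#' DC bin is excluded (the envelope is demeaned) so the metric is not
#' saturated by the envelope mean.
#'
#' @param env an [time_series()] envelope (>= 2 s)
#' @param band `c(lo, hi)` Hz, default theta
#' @param nfft FFT length
#' @return modulation depth in `[0, 1]`
#' @export
theta_mod_depth <- function(env, band = timescale_bands()$theta, nfft = 2048) {
  stopifnot(inherits(env, "mmb_ts"))
  if (duration(env) < 2) stop("envelope shorter than 2 s")
  x <- env$samples - mean(env$samples)
  n <- length(x)
  win_len <- min(n, nfft)
  w <- signal::hamming(win_len)
  hop <- max(1L, win_len %/% 2)
  starts <- seq(1, n - win_len + 1, by = hop)
  P <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- c(x[s:(s + win_len - 1)] * w, numeric(nfft - win_len))
    P <- P + Mod(stats::fft(seg)[1:(nfft %/% 2 + 1)])^2
  }
  freqs <- (0:(nfft %/% 2)) * env$fs / nfft
  tot <- sum(P[freqs > 0])
  if (tot <= 0) stop("zero total spectral power")
  sum(P[freqs >= band[1] & freqs < band[2]]) / tot
}

# band-pass a demeaned envelope into one timescale component (4th-order
# zero-lag Butterworth; prototype order 4, so 4th-order roll-off per edge)
timescale_component <- function(env, band) {
  x <- env$samples - mean(env$samples)
  zp_butter(x, 4, c(band[1], band[2]) / (env$fs / 2), "pass")
}

#' n:m phase synchronization index between two timescale components
#'
#' Both bands are extracted with a 4th-order zero-lag Butterworth band-pass;
#' instantaneous phases come from the analytic signal, and the index is the
#' modulus of the time-averaged phasor of the generalized phase difference
#' `n * phi1 - m * phi2`. 0 = no synchrony, 1 = perfect n:m locking. A 10%
#' margin at each end is discarded before averaging to avoid filter edge
#' effects. Amplitude-invariant (phase-only statistic).
#'
#' @param env an [time_series()] envelope
#' @param band1 slower band `c(lo, hi)` in Hz (phase multiplied by `n`)
#' @param band2 faster band `c(lo, hi)` in Hz (phase multiplied by `m`)
#' @param n,m integer frequency ratio (delta-theta uses 2:1, theta-beta/gamma
#'   3:1)
#' @return PSI in `[0, 1]`
#' @export
nm_psi <- function(env, band1, band2, n = 2, m = 1) {
  stopifnot(inherits(env, "mmb_ts"))
  if (duration(env) < 3 / band1[1])
    stop("envelope shorter than 3 cycles of the slower band")
  b1 <- timescale_component(env, band1)
  b2 <- timescale_component(env, band2)
  if (stats::sd(b1) < 1e-12 || stats::sd(b2) < 1e-12)
    stop("degenerate (constant) band component")
  p1 <- Arg(analytic_signal(b1))
  p2 <- Arg(analytic_signal(b2))
  len <- length(p1)
  trim <- max(1L, round(0.1 * len))
  keep <- trim:(len - trim)
  Mod(mean(exp(1i * (n * p1[keep] - m * p2[keep]))))
}

# ERB-rate scale (Glasberg & Moore)
erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Critical-band Hilbert envelopes of pause-excised speech
#'
#' The waveform is band-pass filtered in the spectral domain into 28 narrow
#' bands whose edges are equally spaced on the ERB-rate (cochlear) scale
#' from 100 to 10,000 Hz; each band's analytic signal is obtained in the same
#' FFT pass (negative frequencies zeroed), its envelope resampled to 100 Hz,
#' and the narrow-band envelopes whose centre frequency (geometric mean of
#' the band edges) falls inside a critical band are averaged into that
#' critical-band envelope. Centres in the 800-1,000 and 8,000-10,000 Hz gaps
#' map to no critical band.
#'
#' @param audio an [time_series()]
#' @param segmentation optional `mmb_segmentation` for pause excision
#' @param n_bands number of narrow bands
#' @param f_range `c(lo, hi)` Hz span of the filterbank
#' @param combine `"mean"` (default) or `"sum"` of member envelopes
#' @param fs_out envelope rate
#' @return named list of four [time_series()] envelopes (names as in
#'   [critical_bands()]); narrow-band centre frequencies in attribute
#'   `centers_hz`
#' @export
cochlear_critical_envelopes <- function(audio, segmentation = NULL,
                                        n_bands = 28,
                                        f_range = c(100, 10000),
                                        combine = c("mean", "sum"),
                                        fs_out = 100) {
  combine <- match.arg(combine)
  stopifnot(inherits(audio, "mmb_ts"))
  if (!is.null(segmentation)) audio <- excise_pauses(audio, segmentation)
  if (duration(audio) < 1) stop("less than 1 s of signal after pause excision")
  x <- audio$samples
  n_orig <- length(x)
  # zero-pad to a 2-3-5-smooth length so the big FFT stays fast; the padded
  # tail of each envelope is trimmed again below
  nn <- stats::nextn(n_orig, c(2, 3, 5))
  if (nn > n_orig) x <- c(x, numeric(nn - n_orig))
  X <- stats::fft(x)
  freqs <- (0:(nn - 1)) * audio$fs / nn   # 0 .. fs (wrapping)
  edges <- erb_rate_inv(seq(erb_rate(f_range[1]), erb_rate(f_range[2]),
                            length.out = n_bands + 1))
  centers <- sqrt(edges[-1] * edges[-(n_bands + 1)])
  cb <- critical_bands()
  member <- vapply(centers, function(fc) {
    hit <- which(vapply(cb, function(b) fc >= b[1] & fc < b[2], logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  # Each band's analytic signal is reconstructed at baseband from its own
  # FFT bins (common inverse-FFT length across bands), which is an exact
  # downsampling of the full-rate analytic narrowband signal: the band
  # occupies fewer bins than the baseband grid, so no aliasing occurs.
  bins <- lapply(seq_len(n_bands), function(k) {
    which(freqs >= edges[k] & freqs < edges[k + 1] & freqs <= audio$fs / 2)
  })
  Lb <- stats::nextn(max(lengths(bins)) + 8, 2)
  fs_b <- Lb * audio$fs / nn
  envs <- vector("list", length(cb))
  counts <- integer(length(cb))
  for (k in seq_len(n_bands)) {
    if (is.na(member[k])) next
    Z <- complex(real = numeric(Lb))
    Z[seq_along(bins[[k]])] <- X[bins[[k]]]
    z <- stats::fft(Z, inverse = TRUE) * (2 / nn)      # analytic, baseband
    e <- Mod(z)[seq_len(max(2, floor(Lb * n_orig / nn)))]  # drop padded tail
    e <- resample_to(e, fs_b, fs_out)
    j <- member[k]
    envs[[j]] <- if (is.null(envs[[j]])) e else envs[[j]] + e
    counts[j] <- counts[j] + 1L
  }
  out <- lapply(seq_along(cb), function(j) {
    if (counts[j] == 0) stop("no narrowband centre in band ", names(cb)[j])
    e <- envs[[j]]
    if (combine == "mean") e <- e / counts[j]
    time_series(e, fs_out, paste0("hbenvlp_", names(cb)[j]))
  })
  names(out) <- names(cb)
  attr(out, "centers_hz") <- centers
  out
}

#' The 21 rhythm features
#'
#' Per sEMG channel (3) and per critical-band acoustic envelope (4): theta
#' modulation depth, delta-theta PSI (2:1) and theta-beta/gamma PSI (3:1).
#'
#' @param semg_envs named list of three sEMG envelopes (`RTEMP`, `RMAS`,
#'   `RABD`) at 100 Hz
#' @param crit_envs named list of four critical-band envelopes at 100 Hz
#' @param bands timescale bands, see [timescale_bands()]
#' @return named numeric of 9 + 12 features
#' @export
rhythm_feature_block <- function(semg_envs, crit_envs,
                                 bands = timescale_bands()) {
  stopifnot(setequal(names(semg_envs), c("RTEMP", "RMAS", "RABD")),
            setequal(names(crit_envs), names(critical_bands())))
  out <- numeric(0)
  for (ch in c("RTEMP", "RMAS", "RABD"))
    out[paste0("mod_depth_theta_", ch)] <-
      theta_mod_depth(semg_envs[[ch]], bands$theta)
  for (ch in c("RTEMP", "RMAS", "RABD"))
    out[paste0("PSI_delta_theta_", ch)] <-
      nm_psi(semg_envs[[ch]], bands$delta, bands$theta, n = 2, m = 1)
  for (ch in c("RTEMP", "RMAS", "RABD"))
    out[paste0("PSI_theta_beta.gamma_", ch)] <-
      nm_psi(semg_envs[[ch]], bands$theta, bands$beta_gamma, n = 3, m = 1)
  cbn <- names(critical_bands())
  for (b in cbn)
    out[paste0("hbenvlp_mod_depth_theta_", b)] <-
      theta_mod_depth(crit_envs[[b]], bands$theta)
  for (b in cbn)
    out[paste0("hbenvlp_PSI_delta_theta_", b)] <-
      nm_psi(crit_envs[[b]], bands$delta, bands$theta, n = 2, m = 1)
  for (b in cbn)
    out[paste0("hbenvlp_PSI_theta_beta.gamma_", b)] <-
      nm_psi(crit_envs[[b]], bands$theta, bands$beta_gamma, n = 3, m = 1)
  out
}
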