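# Complexity via recurrence quantification analysis: delay embedding,
# recurrence plot, determinism (DET), applied to 1-s sEMG segments
# (m = 30, tau = 5, eps = 0.1) and to the 13 MFCC series (m = 3, tau = 15,
# eps = 0.2).

#' RQA parameter set
#'
#' @param m embedding dimension
#' @param tau delay in samples/frames
#' @param eps recurrence threshold as a fraction of the maximal pairwise
#'   phase-space distance of the z-scored embedded series
#' @param lmin minimal diagonal line length counted as deterministic
#' @param theiler exclusion half-width around the line of identity
#'   (1 excludes only the LOI itself)
#' @return list of parameters
#' @export
rqa_params <- function(m, tau, eps, lmin = 2, theiler = 1) {
  stopifnot(m >= 1, tau >= 1, eps > 0, lmin >= 2, theiler >= 1)
  list(m = m, tau = tau, eps = eps, lmin = lmin, theiler = theiler)
}

#' Recurrence plot of a series
#'
#' The z-scored series is delay-embedded with `(m, tau)`; two embedded
#' points are recurrent when their Euclidean distance is at most
#' `eps x max pairwise distance`. The plot is symmetric and the line of
#' identity is excluded by the Theiler window.
#'
#' @param series numeric vector
#' @param params an [rqa_params()]
#' @return object of class `mmb_rp`: list with the logical matrix `R` and
#'   the parameters used
#' @export
recurrence_plot <- function(series, params) {
  x <- as.numeric(series)
  n <- length(x)
  span <- (params$m - 1) * params$tau
  if (n <= span + params$lmin) stop("series too short for this embedding")
  s <- stats::sd(x)
  if (s < 1e-12) stop("constant series: z-score undefined")
  x <- (x - mean(x)) / s
  ne <- n - span
  E <- vapply(0:(params$m - 1), function(k) x[(1 + k * params$tau):
                                                (ne + k * params$tau)],
              numeric(ne))
  E <- matrix(E, nrow = ne)
  sq <- rowSums(E^2)
  D2 <- -2 * tcrossprod(E)
  D2 <- D2 + sq          # adds by column (i index)
  D2 <- t(D2) + sq
  D2[D2 < 0] <- 0
  thr2 <- (params$eps^2) * max(D2)
  R <- D2 <= thr2
  # Theiler window: drop |i - j| < theiler (theiler = 1 removes the LOI)
  for (k in 0:(params$theiler - 1)) {
    idx <- seq_len(ne - k)
    R[cbind(idx + k, idx)] <- FALSE
    if (k > 0) R[cbind(idx, idx + k)] <- FALSE
  }
  structure(list(R = R, n_points = ne, params = params), class = "mmb_rp")
}

#' @export
print.mmb_rp <- function(x, ...) {
  cat(sprintf("<mmb_rp> %d x %d, %d recurrence points (RR = %.3f)\n",
              x$n_points, x$n_points, sum(x$R),
              sum(x$R) / (x$n_points^2 - x$n_points)))
  invisible(x)
}

#' Determinism of a recurrence plot
#'
#' The fraction of recurrence points lying on diagonal line segments of
#' length at least `lmin`; high for periodic signals, low for complex ones.
#' With zero recurrence points the feature is defined as 0 (with a warning).
#'
#' @param rp an `mmb_rp`
#' @return DET in `[0, 1]`
#' @export
determinism <- function(rp) {
  stopifnot(inherits(rp, "mmb_rp"))
  R <- rp$R
  npts <- sum(R)
  if (npts == 0) {
    warning("no recurrence points; DET defined as 0")
    return(0)
  }
  n <- nrow(R)
  lmin <- rp$params$lmin
  if (lmin == 2) {
    # fast path: a point sits on a diagonal line of length >= 2 iff it has a
    # diagonal neighbour
    nb <- matrix(FALSE, n, n)
    nb[-1, -1] <- R[-n, -n]                   # up-left neighbour
    nb[-n, -n] <- nb[-n, -n] | R[-1, -1]      # down-right neighbour
    return(sum(R & nb) / npts)
  }
  # general case: diagonal run lengths by dynamic programming over rows
  Lp <- numeric(n)
  in_lines <- 0
  for (i in seq_len(n)) {
    ri <- R[i, ]
    Lc <- numeric(n)
    Lc[1] <- as.numeric(ri[1])
    if (n > 1) Lc[2:n] <- ri[2:n] * (Lp[1:(n - 1)] + 1)
    if (i < n) {
      nxt <- c(R[i + 1, 2:n], FALSE)     # R[i+1, j+1]
      ended <- Lc >= 1 & !nxt
    } else ended <- Lc >= 1
    lens <- Lc[ended]
    in_lines <- in_lines + sum(lens[lens >= lmin])
    Lp <- Lc
  }
  in_lines / npts
}

#' Mean determinism of 1-s sEMG segments
#'
#' DET with `(m = 30, tau = 5, eps = 0.1)` is computed on non-overlapping
#' 1-s segments of each preprocessed channel (during which the signal is
#' treated as stable) and averaged across segments. When `max_segments` is
#' finite, an evenly spaced subset of segments is used.
#'
#' @param semg named list of three preprocessed [time_series()]
#' @param params an [rqa_params()]
#' @param segment_s segment length in seconds
#' @param max_segments cap on the number of segments per channel
#' @return named numeric `DET_RTEMP`, `DET_RMAS`, `DET_RABD`
#' @export
semg_determinism_features <- function(semg, params = rqa_params(30, 5, 0.1),
                                      segment_s = 1, max_segments = Inf) {
  stopifnot(setequal(names(semg), c("RTEMP", "RMAS", "RABD")))
  out <- numeric(0)
  for (ch in c("RTEMP", "RMAS", "RABD")) {
    ts <- semg[[ch]]
    seg_n <- round(segment_s * ts$fs)
    k <- floor(length(ts$samples) / seg_n)
    if (k < 1) stop("less than one full segment in channel ", ch)
    use <- if (is.finite(max_segments) && k > max_segments)
      unique(round(seq(1, k, length.out = max_segments))) else seq_len(k)
    dets <- vapply(use, function(j) {
      seg <- ts$samples[((j - 1) * seg_n + 1):(j * seg_n)]
      determinism(recurrence_plot(seg, params))
    }, numeric(1))
    out[paste0("DET_", ch)] <- mean(dets)
  }
  out
}

# --- MFCC front end -------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel-frequency cepstral coefficients
#'
#' Standard front end: 25-ms Hamming frames with 10-ms hop, power spectrum,
#' 26 triangular mel filters spanning 0 to fs/2, log filter energies, and a
#' DCT-II. Coefficients 1..`n_coef` are returned (the 0th, overall-energy
#' coefficient is excluded).
#'
#' @param audio an [time_series()]
#' @param n_coef number of coefficients
#' @param n_filters mel filterbank size
#' @param frame_s,hop_s frame length and hop in seconds
#' @return matrix `n_coef x n_frames`
#' @export
mfcc_matrix <- function(audio, n_coef = 13, n_filters = 26,
                        frame_s = 0.025, hop_s = 0.010) {
  stopifnot(inherits(audio, "mmb_ts"))
  x <- audio$samples
  fs <- audio$fs
  flen <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  nfft <- stats::nextn(flen, 2)
  if (length(x) < flen) stop("audio shorter than one frame")
  starts <- seq(1, length(x) - flen + 1, by = hop)
  w <- signal::hamming(flen)
  frames <- vapply(starts, function(s) c(x[s:(s + flen - 1)] * w,
                                         numeric(nfft - flen)),
                   numeric(nfft))
  P <- Mod(stats::mvfft(frames))^2
  nb <- nfft / 2 + 1
  P <- P[1:nb, , drop = FALSE]
  freqs <- (0:(nb - 1)) * fs / nfft
  mel_pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2),
                           length.out = n_filters + 2))
  fb <- matrix(0, n_filters, nb)
  for (j in seq_len(n_filters)) {
    lo <- mel_pts[j]; ce <- mel_pts[j + 1]; hi <- mel_pts[j + 2]
    up <- freqs >= lo & freqs <= ce
    dn <- freqs > ce & freqs <= hi
    fb[j, up] <- (freqs[up] - lo) / (ce - lo)
    fb[j, dn] <- (hi - freqs[dn]) / (hi - ce)
  }
  logE <- log(fb %*% P + 1e-12)
  dct <- outer(seq_len(n_coef), seq_len(n_filters) - 0.5,
               function(k, j) cos(pi * k * j / n_filters))
  C <- dct %*% logE
  rownames(C) <- paste0("mfcc", seq_len(n_coef))
  C
}

#' Determinism of the MFCC trajectories
#'
#' The first 13 MFCCs are computed from the audio; each coefficient series
#' is fed into RQA with `(m = 3, tau = 15, eps = 0.2)` and its determinism
#' reported.
#'
#' @param audio an [time_series()]
#' @param params an [rqa_params()]
#' @param ... passed to [mfcc_matrix()]
#' @return named numeric `DET_mfcc1` .. `DET_mfcc13`
#' @export
mfcc_determinism_features <- function(audio, params = rqa_params(3, 15, 0.2),
                                      ...) {
  C <- mfcc_matrix(audio, ...)
  span <- (params$m - 1) * params$tau
  if (ncol(C) <= span + params$lmin)
    stop("too few MFCC frames for this embedding")
  out <- apply(C, 1, function(s) determinism(recurrence_plot(s, params)))
  names(out) <- paste0("DET_", rownames(C))
  out
}
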