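# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving RMS via cumulative sums; win in samples. Edges hold the
# nearest full-window value.
moving_rms <- function(x, win) {
  win <- max(1L, as.integer(win))
  n <- length(x)
  if (win >= n) return(rep(sqrt(mean(x^2)), n))
  cs <- cumsum(c(0, x^2))
  m <- (cs[(win + 1):(n + 1)] - cs[1:(n - win + 1)]) / win  # window starts
  half <- win %/% 2
  out <- numeric(n)
  core <- seq_along(m) + half          # window centers
  out[core] <- m
  if (half > 0) out[seq_len(half)] <- m[1]
  if (core[length(core)] < n) out[(core[length(core)] + 1):n] <- m[length(m)]
  sqrt(pmax(out, 0))
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose modulus is the Hilbert envelope
#' and whose argument is the instantaneous phase.
#' @param x real-valued numeric vector
#' @return complex vector, same length as `x`
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("analytic_signal: series too short")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Forward-backward (zero-phase) IIR filtering with odd-reflection padding at
# both ends so edge transients decay inside the pad, not in the output.
zp_filtfilt <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1, 1000L)
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  xe <- c(left, x, right)
  y <- as.numeric(signal::filter(b, a, xe))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(p + 1):(p + n)]
}

# Zero-phase Butterworth band/low/high-pass. `n` is the prototype order as
# passed to signal::butter (a band-pass of prototype order n has order 2n).
zp_butter <- function(x, n, w, type) {
  flt <- signal::butter(n, w, type = type)
  zp_filtfilt(flt$b, flt$a, x)
}

# Staged decimation of an (envelope) signal to fs_out, anti-alias filtered.
resample_to <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > fs_out)
  fs <- fs_in
  while (fs > 25 * fs_out) {
    # decimate by 10 with a comfortable guard band
    x <- zp_butter(x, 4, 0.08, "low")
    x <- x[seq(1, length(x), by = 10)]
    fs <- fs / 10
  }
  x <- zp_butter(x, 4, (0.8 * fs_out / 2) / (fs / 2), "low")
  dur <- (length(x) - 1) / fs
  t_old <- seq(0, by = 1 / fs, length.out = length(x))
  t_new <- seq(0, dur, by = 1 / fs_out)
  stats::approx(t_old, x, xout = t_new)$y
}

# run-length encoding of a logical vector into (start, length) of TRUE runs
true_runs <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}
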