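# Seeded generators for speech-like audio, bursting sEMG, cohorts and
# latent-factor feature tables. Ground truth (segmentation, f0 contour,
# coupling) is returned alongside every signal so downstream stages can be
# tested against known answers.

#' Specification of a synthetic speech-like audio sample
#'
#' Voiced stretches are harmonic-rich (band-limited sawtooth source) at the
#' scheduled fundamental frequency, amplitude-modulated at a theta (syllable)
#' rate; scheduled pauses contain only the noise floor.
#'
#' @param duration_s duration in seconds
#' @param fs sampling rate in Hz
#' @param f0_contour data.frame with columns `start_s`, `end_s`, `f0_hz`
#'   giving the voiced segments; defaults to one segment spanning the sample
#'   at 120 Hz
#' @param pause_schedule data.frame with columns `onset_s`, `offset_s`;
#'   must be sorted and non-overlapping
#' @param theta_am_rate amplitude-modulation rate in Hz (syllable rate)
#' @param theta_am_depth modulation depth in `[0, 1]`
#' @param env_noise relative amplitude of slow broadband (0.5-20 Hz)
#'   envelope fluctuation, emulating the irregular amplitude modulation of
#'   natural speech (0 disables it; it is what keeps the theta modulation
#'   depth away from saturation)
#' @param noise_floor linear amplitude of the additive noise floor
#' @param seed integer seed; the generator is deterministic given the spec
#' @return an object of class `audio_spec`
#' @export
audio_spec <- function(duration_s, fs = 22050,
                       f0_contour = data.frame(start_s = 0, end_s = duration_s,
                                               f0_hz = 120),
                       pause_schedule = data.frame(onset_s = numeric(0),
                                                   offset_s = numeric(0)),
                       theta_am_rate = 5, theta_am_depth = 0.5,
                       env_noise = 0.25, noise_floor = 1e-3, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0)
  if (theta_am_depth < 0 || theta_am_depth > 1)
    stop("theta_am_depth must be in [0, 1]")
  ps <- pause_schedule
  if (nrow(ps) > 0) {
    if (any(ps$offset_s <= ps$onset_s)) stop("pause offsets must exceed onsets")
    if (is.unsorted(ps$onset_s)) stop("pauses must be sorted")
    if (nrow(ps) > 1 && any(ps$onset_s[-1] < ps$offset_s[-nrow(ps)]))
      stop("overlapping pauses")
    if (any(ps$onset_s < 0) || any(ps$offset_s > duration_s))
      stop("pauses outside the sample")
  }
  structure(list(duration_s = duration_s, fs = fs, f0_contour = f0_contour,
                 pause_schedule = ps, theta_am_rate = theta_am_rate,
                 theta_am_depth = theta_am_depth, env_noise = env_noise,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "audio_spec")
}

#' Specification of a synthetic three-channel sEMG sample
#'
#' Each channel is a burst envelope (raised-cosine ramps) multiplying a
#' mixture of a shared band-limited oscillatory drive and private broadband
#' noise, plus a baseline noise floor. The mixing weight `coupling` is the
#' ground truth for intermuscular-coherence tests.
#'
#' @param duration_s duration in seconds
#' @param fs sampling rate in Hz
#' @param burst_schedule data.frame with `onset_s`, `offset_s` of activity
#'   bursts; defaults to one burst spanning the sample
#' @param drive_bands list of `c(lo, hi)` Hz bands composing the shared drive
#' @param coupling shared-drive mixing weight in `[0, 1]`
#' @param am_rate,am_depth syllable-rate amplitude modulation of the burst
#'   envelope (the jaw muscles contract syllabically during speech);
#'   `am_depth = 0` disables it
#' @param noise_sd baseline noise amplitude
#' @param seed integer seed
#' @return an object of class `semg_spec`
#' @export
semg_spec <- function(duration_s, fs = 2000,
                      burst_schedule = data.frame(onset_s = 0.1,
                                                  offset_s = duration_s - 0.1),
                      drive_bands = list(c(8, 12), c(15, 25)),
                      coupling = 0.6, am_rate = 4.5, am_depth = 0,
                      noise_sd = 0.05, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0)
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  if (am_depth < 0 || am_depth > 1) stop("am_depth must be in [0, 1]")
  for (b in drive_bands)
    if (b[1] <= 0 || b[2] >= fs / 2 || b[1] >= b[2])
      stop("drive bands must lie within (0, fs/2)")
  structure(list(duration_s = duration_s, fs = fs,
                 burst_schedule = burst_schedule, drive_bands = drive_bands,
                 coupling = coupling, am_rate = am_rate, am_depth = am_depth,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "semg_spec")
}

# raised-cosine gate: 1 inside [on, off], cosine ramps of ramp_s at the edges
rc_gate <- function(t, on, off, ramp_s) {
  g <- numeric(length(t))
  g[t >= on & t <= off] <- 1
  if (ramp_s > 0) {
    up <- t >= on - ramp_s & t < on
    g[up] <- 0.5 * (1 + cos(pi * (on - t[up]) / ramp_s))
    dn <- t > off & t <= off + ramp_s
    g[dn] <- 0.5 * (1 + cos(pi * (t[dn] - off) / ramp_s))
  }
  g
}

#' Generate a synthetic speech-like audio waveform
#'
#' @param spec an [audio_spec()]
#' @return list with `audio` ([time_series()]), `segmentation` (ground-truth
#'   pause/speech events, class `mmb_segmentation`), and `f0` (data.frame of
#'   the scheduled voiced segments)
#' @examples
#' sp <- audio_spec(1.5, f0_contour = data.frame(start_s = 0, end_s = 1.5,
#'                                               f0_hz = 150))
#' out <- make_speech_audio(sp)
#' @export
make_speech_audio <- function(spec) {
  stopifnot(inherits(spec, "audio_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    t <- (seq_len(n) - 1) / spec$fs
    x <- numeric(n)
    # harmonic-rich voiced source, harmonics retained up to 5 kHz
    for (i in seq_len(nrow(spec$f0_contour))) {
      seg <- spec$f0_contour[i, ]
      idx <- t >= seg$start_s & t < seg$end_s
      if (!any(idx)) next
      f0 <- seg$f0_hz
      kmax <- max(1, floor(min(5000, 0.45 * spec$fs) / f0))
      tt <- t[idx] - seg$start_s
      s <- numeric(sum(idx))
      for (k in seq_len(kmax)) s <- s + sin(2 * pi * k * f0 * tt) / k
      x[idx] <- x[idx] + s
    }
    x <- 0.5 * x / max(abs(x), 1e-12)
    # theta-rate amplitude modulation with the stated depth
    am <- (1 + spec$theta_am_depth * cos(2 * pi * spec$theta_am_rate * t)) /
      (1 + spec$theta_am_depth)
    x <- x * am
    # slow broadband envelope fluctuation (natural amplitude irregularity),
    # synthesized at 200 Hz and interpolated up
    if (spec$env_noise > 0) {
      fs_lo <- 200
      n_lo <- ceiling(spec$duration_s * fs_lo) + 1
      sn0 <- zp_butter(stats::rnorm(n_lo), 2, c(0.5, 20) / (fs_lo / 2), "pass")
      sn <- stats::approx(seq(0, by = 1 / fs_lo, length.out = n_lo), sn0,
                          xout = t, rule = 2)$y
      x <- x * pmax(1 + spec$env_noise * sn / stats::sd(sn), 0.05)
    }
    # silence gate over scheduled pauses (10-ms raised-cosine edges)
    gate <- rep(1, n)
    ps <- spec$pause_schedule
    for (i in seq_len(nrow(ps)))
      gate <- gate * (1 - rc_gate(t, ps$onset_s[i] + 0.01,
                                  ps$offset_s[i] - 0.01, 0.01))
    x <- x * gate + spec$noise_floor * stats::rnorm(n)
    seg <- ground_truth_segmentation(ps, spec$duration_s)
    list(audio = time_series(x, spec$fs, "audio"),
         segmentation = seg, f0 = spec$f0_contour)
  })
}

# build the ground-truth event list from a pause schedule
ground_truth_segmentation <- function(ps, duration_s) {
  ev <- data.frame(kind = character(0), onset_s = numeric(0),
                   offset_s = numeric(0))
  cur <- 0
  for (i in seq_len(nrow(ps))) {
    if (ps$onset_s[i] > cur)
      ev <- rbind(ev, data.frame(kind = "speech", onset_s = cur,
                                 offset_s = ps$onset_s[i]))
    ev <- rbind(ev, data.frame(kind = "pause", onset_s = ps$onset_s[i],
                               offset_s = ps$offset_s[i]))
    cur <- ps$offset_s[i]
  }
  if (cur < duration_s)
    ev <- rbind(ev, data.frame(kind = "speech", onset_s = cur,
                               offset_s = duration_s))
  new_segmentation(ev, duration_s)
}

#' Generate a synthetic three-channel sEMG sample
#'
#' @param spec an [semg_spec()]
#' @return named list of three [time_series()] (`RTEMP`, `RMAS`, `RABD`) with
#'   the burst schedule and coupling attached as attributes `ground_truth`
#' @export
make_semg_triplet <- function(spec) {
  stopifnot(inherits(spec, "semg_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    t <- (seq_len(n) - 1) / spec$fs
    band_noise <- function() {
      z <- numeric(n)
      for (b in spec$drive_bands)
        z <- z + zp_butter(stats::rnorm(n), 2, c(b[1], b[2]) / (spec$fs / 2),
                           "pass")
      z / stats::sd(z)
    }
    shared <- band_noise()
    env <- numeric(n)
    bs <- spec$burst_schedule
    for (i in seq_len(nrow(bs)))
      env <- pmax(env, rc_gate(t, bs$onset_s[i], bs$offset_s[i], 0.05))
    if (spec$am_depth > 0)
      env <- env * (1 + spec$am_depth * cos(2 * pi * spec$am_rate * t)) /
        (1 + spec$am_depth)
    chans <- lapply(c("RTEMP", "RMAS", "RABD"), function(ch) {
      private <- band_noise()
      x <- env * (spec$coupling * shared + (1 - spec$coupling) * private) +
        spec$noise_sd * stats::rnorm(n)
      out <- time_series(x, spec$fs, ch)
      out
    })
    names(chans) <- c("RTEMP", "RMAS", "RABD")
    attr(chans, "ground_truth") <- list(burst_schedule = bs,
                                        coupling = spec$coupling)
    chans
  })
}

#' Assemble a full synthetic multimodal recording
#'
#' Convenience wrapper producing one [multimodal_recording()] whose audio and
#' sEMG share the same utterance timeline: sEMG bursts coincide with the
#' speech events of the audio pause schedule.
#'
#' @param aspec an [audio_spec()]
#' @param espec an [semg_spec()]; defaults to bursts matching the speech
#'   events of `aspec`
#' @param ... metadata passed to [multimodal_recording()]
#' @return an `mmb_recording` with ground truth in attribute `ground_truth`
#' @export
make_recording <- function(aspec, espec = NULL, ...) {
  a <- make_speech_audio(aspec)
  if (is.null(espec)) {
    sp <- as.data.frame(a$segmentation$events)
    sp <- sp[sp$kind == "speech", , drop = FALSE]
    espec <- semg_spec(aspec$duration_s,
                       burst_schedule = data.frame(onset_s = sp$onset_s,
                                                   offset_s = sp$offset_s),
                       am_rate = aspec$theta_am_rate,
                       am_depth = aspec$theta_am_depth,
                       seed = aspec$seed + 1000L)
  }
  e <- make_semg_triplet(espec)
  rec <- multimodal_recording(a$audio, e, ...)
  attr(rec, "ground_truth") <- list(segmentation = a$segmentation,
                                    f0 = a$f0,
                                    coupling = espec$coupling,
                                    theta_am_rate = aspec$theta_am_rate,
                                    theta_am_depth = aspec$theta_am_depth)
  rec
}

# Baseline cohort parameters: inter-participant means and jitter SDs.
# effect_map entries shift the "ALS" group means by multiples of these SDs.
cohort_baseline <- function() {
  list(coupling = c(mean = 0.60, sd = 0.08),
       am_depth = c(mean = 0.55, sd = 0.08),
       pause_dur = c(mean = 0.25, sd = 0.05),   # seconds, per pause
       f0_var = c(mean = 1.5, sd = 0.4),        # semitone SD of the contour
       speaking_rate = c(mean = 180, sd = 20))  # WPM
}

#' Generate a synthetic two-group cohort of multimodal recordings
#'
#' Group effects are injected at the signal-parameter level (coupling, theta
#' modulation depth, pause duration, f0 variability, speaking rate), so the
#' whole extraction pipeline is exercised end-to-end. `effect_map` shifts the
#' "ALS" group means in units of the inter-participant jitter SD.
#'
#' @param n_per_group participants per group; a single count or a length-2
#'   vector `c(control, ALS)`
#' @param effect_map named numeric vector of SD-unit shifts; recognised names
#'   are `coupling`, `am_depth`, `pause_dur`, `f0_var`, `speaking_rate`
#' @param n_sentences sentences per participant (19 mirrors the reading
#'   passage used for validation)
#' @param seed integer seed
#' @param duration_range range of per-sentence speech time in seconds
#'   (pauses extend the total duration beyond this)
#' @return list of `mmb_recording`
#' @export
make_cohort <- function(n_per_group, effect_map = numeric(), n_sentences = 19,
                        seed = 1L, duration_range = c(3.6, 4.3)) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  if (any(n_per_group < 2)) stop("need at least 2 participants per group")
  base <- cohort_baseline()
  bad <- setdiff(names(effect_map), names(base))
  if (length(bad)) stop("unknown effect_map entries: ", paste(bad, collapse = ", "))
  groups <- rep(c("control", "ALS"), n_per_group)
  recs <- list()
  with_seed(seed, {
    for (p in seq_along(groups)) {
      grp <- groups[p]
      par <- lapply(names(base), function(nm) {
        m <- base[[nm]]["mean"]; s <- base[[nm]]["sd"]
        if (grp == "ALS" && nm %in% names(effect_map))
          m <- m + effect_map[[nm]] * s
        stats::rnorm(1, m, s)
      })
      names(par) <- names(base)
      par$coupling <- min(max(par$coupling, 0), 1)
      par$am_depth <- min(max(par$am_depth, 0.05), 0.95)
      par$pause_dur <- max(par$pause_dur, 0.06)
      par$f0_var <- max(par$f0_var, 0.1)
      par$speaking_rate <- max(par$speaking_rate, 60)
      sex <- if (stats::runif(1) < 0.5) "M" else "F"
      f0_base <- if (sex == "M") stats::rnorm(1, 120, 10) else stats::rnorm(1, 210, 15)
      for (s_id in seq_len(n_sentences)) {
        # the sentence text is fixed, so speech time is drawn independently
        # of pausing and the total duration grows with the pause time
        speech_t <- stats::runif(1, duration_range[1], duration_range[2])
        d1 <- max(0.06, stats::rnorm(1, par$pause_dur, 0.2 * par$pause_dur))
        d2 <- max(0.06, stats::rnorm(1, par$pause_dur, 0.2 * par$pause_dur))
        b1 <- stats::runif(1, 0.28 * speech_t, 0.42 * speech_t)
        b2 <- stats::runif(1, 0.58 * speech_t, 0.75 * speech_t)
        pauses <- data.frame(onset_s = c(b1, b2 + d1),
                             offset_s = c(b1 + d1, b2 + d1 + d2))
        dur <- speech_t + d1 + d2
        # piecewise-constant f0 contour over ~0.6-s sub-chunks of the speech
        # events, jittered in semitones with SD par$f0_var
        bounds <- sort(c(0, pauses$onset_s, pauses$offset_s, dur))
        f0c <- NULL
        for (k in seq_len(length(bounds) - 1)) {
          if (k %% 2 == 0) next  # pause gap
          nsub <- max(1, round((bounds[k + 1] - bounds[k]) / 0.6))
          sub <- seq(bounds[k], bounds[k + 1], length.out = nsub + 1)
          st <- 12 * log2(f0_base) + stats::rnorm(nsub, 0, par$f0_var)
          f0c <- rbind(f0c, data.frame(start_s = sub[-(nsub + 1)],
                                       end_s = sub[-1],
                                       f0_hz = 2^(st / 12)))
        }
        sd_seed <- seed + 7919L * p + 13L * s_id
        am_rate <- stats::rnorm(1, 4.5, 0.3)
        asp <- audio_spec(dur, f0_contour = f0c, pause_schedule = pauses,
                          theta_am_rate = am_rate,
                          theta_am_depth = par$am_depth, seed = sd_seed)
        esp <- semg_spec(dur,
                         burst_schedule = data.frame(
                           onset_s = c(0.05, pauses$offset_s),
                           offset_s = c(pauses$onset_s, dur - 0.05)),
                         coupling = par$coupling, am_rate = am_rate,
                         am_depth = par$am_depth, seed = sd_seed + 1L)
        recs[[length(recs) + 1]] <- make_recording(
          asp, esp,
          participant_id = sprintf("P%02d", p), group = grp, sex = sex,
          speaking_rate_wpm = par$speaking_rate, sentence_id = s_id)
      }
    }
  })
  recs
}

#' Generate a feature table with a known latent-factor structure
#'
#' Rows are `loadings %*% factors + noise`, with iid standard-normal factor
#' scores and independent Gaussian uniqueness. Used for parameter-recovery
#' tests of the confirmatory factor model.
#'
#' @param n_samples number of rows
#' @param loadings features x factors matrix (dimnames used for column and
#'   factor names when present)
#' @param uniqueness per-feature residual variances (> 0); defaults to
#'   `1 - rowSums(loadings^2)`
#' @param seed integer seed
#' @return list with `table` (data.frame of features) and `factors` (matrix
#'   of the generating factor scores)
#' @export
make_factor_table <- function(n_samples, loadings, uniqueness = NULL,
                              seed = 1L) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings); f <- ncol(loadings)
  if (is.null(uniqueness)) uniqueness <- pmax(1 - rowSums(loadings^2), 1e-3)
  if (any(uniqueness <= 0)) stop("uniqueness must be positive")
  if (length(uniqueness) == 1) uniqueness <- rep(uniqueness, p)
  with_seed(seed, {
    fac <- matrix(stats::rnorm(n_samples * f), n_samples, f)
    eps <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    X <- fac %*% t(loadings) + eps %*% diag(sqrt(uniqueness), p)
    colnames(X) <- rownames(loadings)
    if (is.null(colnames(X))) colnames(X) <- paste0("feat", seq_len(p))
    colnames(fac) <- colnames(loadings)
    list(table = as.data.frame(X), factors = fac)
  })
}
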