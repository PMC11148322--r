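# Recurrence plots, determinism, and the two RQA parameterizations
# (sEMG segments and MFCC trajectories).

test_that("recurrence plots match an exhaustive pairwise oracle", {
  # toy series embedded at (m = 2, tau = 1); brute force over all pairs
  x <- c(0, 0, 1, 0, 0, 1)
  params <- rqa_params(2, 1, eps = 0.05)
  rp <- recurrence_plot(x, params)
  z <- (x - mean(x)) / sd(x)
  E <- cbind(z[1:5], z[2:6])
  D <- as.matrix(dist(E))
  expected <- D <= 0.05 * max(D)
  diag(expected) <- FALSE
  expect_equal(unname(rp$R), unname(expected))
  expect_true(isSymmetric(rp$R))
  expect_false(any(diag(rp$R)))
  expect_error(recurrence_plot(rep(1, 100), params), "constant")
  expect_error(recurrence_plot(x[1:3], rqa_params(2, 1, 0.1)), "too short")
})

test_that("periodic series form unbroken diagonals; DET separates sine from noise", {
  t <- seq(0, 10, length.out = 1000)
  params <- rqa_params(3, 5, 0.1)
  d_sine <- determinism(recurrence_plot(sin(2 * pi * t), params))
  expect_gt(d_sine, 0.95)
  d_noise <- vapply(1:10, function(s) {
    set.seed(s)
    determinism(recurrence_plot(rnorm(1000), params))
  }, numeric(1))
  expect_true(all(d_sine > d_noise))
})

test_that("DET equals the direct diagonal count on a constructed plot", {
  # one length-3 diagonal plus two isolated points (per triangle):
  # DET = 3/5 by direct count
  R <- matrix(FALSE, 8, 8)
  put <- function(i, j) R[cbind(c(i, j), c(j, i))] <<- TRUE
  put(c(1, 2, 3), c(5, 6, 7))   # diagonal of length 3
  put(1, 3); put(6, 8)          # isolated points
  rp <- structure(list(R = R, n_points = 8,
                       params = rqa_params(2, 1, 0.1)), class = "mmb_rp")
  expect_equal(determinism(rp), 3 / 5)
  # fast path (lmin = 2) agrees with the general DP path (lmin = 3)
  rp3 <- rp; rp3$params$lmin <- 3
  expect_equal(determinism(rp3), 3 / 5)
})

test_that("DET is monotone non-decreasing in the threshold", {
  for (s in 1:3) {
    set.seed(s)
    x <- rnorm(400)
    dets <- vapply(c(0.05, 0.15, 0.4), function(e)
      determinism(recurrence_plot(x, rqa_params(3, 2, e))), numeric(1))
    expect_true(all(diff(dets) >= 0))
  }
})

test_that("sEMG determinism averages over 1-s segments", {
  fs <- 2000
  one_sec <- sin(2 * pi * 7 * seq(0, 1 - 1 / fs, by = 1 / fs)) +
    0.05 * sin(2 * pi * 91 * seq(0, 1 - 1 / fs, by = 1 / fs))
  ch <- time_series(rep(one_sec, 3), fs)                  # 3 identical segments
  semg <- list(RTEMP = ch, RMAS = ch, RABD = ch)
  params <- rqa_params(8, 5, 0.1)                         # reduced m for speed
  out <- semg_determinism_features(semg, params)
  expect_named(out, c("DET_RTEMP", "DET_RMAS", "DET_RABD"))
  # identical segments: the mean equals any single segment's DET
  d1 <- determinism(recurrence_plot(one_sec, params))
  expect_equal(unname(out["DET_RTEMP"]), d1)
  # periodic bursts vs noise: paired comparison
  set.seed(2)
  noise <- time_series(rnorm(3 * fs), fs)
  out_n <- semg_determinism_features(list(RTEMP = noise, RMAS = noise,
                                          RABD = noise), params)
  expect_gt(out["DET_RTEMP"], out_n["DET_RTEMP"])
  expect_error(semg_determinism_features(
    list(RTEMP = time_series(rnorm(500), fs),
         RMAS = time_series(rnorm(500), fs),
         RABD = time_series(rnorm(500), fs)), params), "full segment")
})

test_that("MFCC determinism yields 13 named features, reversal-invariant", {
  rec <- fixture_recording(seed = 43, duration = 2.4)
  # trim so the frame grid tiles the signal exactly (25-ms frame, 10-ms hop);
  # then the reversed signal has exactly the reversed frame sequence
  flen <- round(0.025 * rec$audio$fs); hop <- round(0.010 * rec$audio$fs)
  n <- flen + floor((length(rec$audio$samples) - flen) / hop) * hop
  audio <- time_series(rec$audio$samples[seq_len(n)], rec$audio$fs)
  out <- mfcc_determinism_features(audio)
  expect_length(out, 13)
  expect_named(out, paste0("DET_mfcc", 1:13))
  expect_true(all(out >= 0 & out <= 1))
  # steady vowel-like tone beats white noise on the first coefficient
  set.seed(5)
  noise <- time_series(rnorm(n), audio$fs)
  out_n <- mfcc_determinism_features(noise)
  expect_gt(out["DET_mfcc1"], out_n["DET_mfcc1"])
  # time reversal leaves each DET unchanged (symmetric recurrence plots)
  rev_audio <- time_series(rev(audio$samples), audio$fs)
  expect_equal(mfcc_determinism_features(rev_audio), out, tolerance = 1e-9)
  expect_error(mfcc_determinism_features(
    time_series(rnorm(2205), 22050)), "few")
})
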