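make_sine_rec <- function(freqs_amp, fs = 500, dur = 20, n_ch = 4,
                          roles = rep("scalp", n_ch)) {
  t <- (0:(dur * fs - 1)) / fs
  x <- Reduce(`+`, lapply(freqs_amp, function(fa) fa[2] * sin(2 * pi * fa[1] * t)))
  quick_recording(matrix(rep(x, each = n_ch), n_ch, byrow = FALSE), fs, roles)
}

mid_ratio_db <- function(before, after, fs) {
  mid <- (5 * fs):(15 * fs)
  20 * log10(sd(after[mid]) / sd(before[mid]))
}

test_that("the drift filter removes DC and is -6 dB at half the cutoff", {
  fs <- 500
  rec <- quick_recording(matrix(3, 2, fs * 20), fs)
  hp <- highpass(rec, 1)
  expect_lt(max(abs(hp$data[, (5 * fs):(15 * fs)])), 1e-6 * 3)

  t <- (0:(fs * 40 - 1)) / fs
  for (f_probe in c(0.5, 10)) {
    rec <- quick_recording(matrix(sin(2 * pi * f_probe * t), 1), fs)
    hp <- highpass(rec, 1)
    g <- mid_ratio_db(rec$data[1, ], hp$data[1, ], fs)
    if (f_probe == 0.5) expect_lt(abs(g - (-6)), 0.5) else expect_lt(abs(g), 0.09)
  }
})

test_that("the EMG high-pass touches only EMG channels and has the right response", {
  fs <- 500
  t <- (0:(fs * 20 - 1)) / fs
  data <- rbind(sin(2 * pi * 5 * t), sin(2 * pi * 5 * t), sin(2 * pi * 40 * t))
  rec <- quick_recording(data, fs, roles = c("scalp", "emg", "emg"))
  out <- emg_highpass(rec)
  expect_identical(out$data[1, ], rec$data[1, ])
  expect_lt(mid_ratio_db(rec$data[2, ], out$data[2, ], fs), -20)
  expect_lt(abs(mid_ratio_db(rec$data[3, ], out$data[3, ], fs)), 0.09)
})

test_that("line-noise regression removes mains lines and leaves broadband intact", {
  fs <- 500
  set.seed(3)
  n <- fs * 20
  noise <- matrix(rnorm(2 * n), 2)
  rec <- quick_recording(noise, fs)
  rec$data[1, ] <- rec$data[1, ] + 5 * sin(2 * pi * 60 * (0:(n - 1)) / fs)
  out <- remove_line_noise(rec)
  pw <- function(x, f0) {
    ps <- welch_psd(x, fs)
    ps$db[which.min(abs(ps$freq - f0))]
  }
  expect_lt(pw(out$data[1, ], 60) - pw(rec$data[1, ], 60), -20)
  ## clean channel: PSD unchanged within 0.5 dB away from the lines
  ps0 <- welch_psd(rec$data[2, ], fs)
  ps1 <- welch_psd(out$data[2, ], fs)
  away <- abs(ps0$freq - 60) > 2 & abs(ps0$freq - 120) > 2 & ps0$freq > 1
  expect_lt(max(abs(ps1$db[away] - ps0$db[away])), 0.5)
})

test_that("bad-channel rejection flags only deviant channels", {
  set.seed(4)
  base <- matrix(rnorm(20 * 2000), 20)
  rec <- quick_recording(base, 500)
  out <- reject_bad_channels(rec)
  expect_equal(nrow(out$rejected), 0)

  rec$data[7, ] <- rec$data[7, ] * 10
  out <- reject_bad_channels(rec)
  expect_equal(out$rejected$label, "CH007")
  expect_equal(nrow(out$recording$data), 19)
})

test_that("average reference zeroes the per-role mean, is idempotent, drops rank by one", {
  set.seed(5)
  rec <- quick_recording(matrix(rnorm(8 * 1000), 8), 500)
  ar <- average_reference(rec)
  expect_lt(max(abs(colMeans(ar$data))), 1e-10)
  expect_equal(average_reference(ar)$data, ar$data)
  expect_equal(qr(ar$data)$rank, 7)
})

test_that("reference-guided cleaning removes shared artifacts, spares orthogonal data", {
  set.seed(6)
  fs <- 250
  n <- fs * 20
  brain <- matrix(rnorm(6 * n), 6)
  art <- matrix(rnorm(2 * n), 2)
  mix_art <- matrix(runif(12, 0.5, 1), 6, 2)

  ## orthogonal references: scalp unchanged (all canonical R2 below threshold)
  rec <- recording(rbind(brain, art), fs, c(rep("scalp", 6), rep("noise", 2)))
  out <- reference_guided_clean(rec, "noise", 0.65)
  expect_lt(max(abs(out$data[1:6, ] - brain)), 0.05)

  ## shared artifact: squared correlation with the artifact reduced >= 10x
  contaminated <- brain + 0.8 * (mix_art %*% art)
  rec2 <- recording(rbind(contaminated, art), fs, c(rep("scalp", 6), rep("noise", 2)))
  out2 <- reference_guided_clean(rec2, "noise", 0.65)
  r2_before <- max(cor(t(contaminated), t(art))^2)
  r2_after <- max(cor(t(out2$data[1:6, ]), t(art))^2)
  expect_lt(r2_after, r2_before / 10)
})

test_that("window rejection masks bursts and passes clean data", {
  set.seed(7)
  fs <- 250
  n <- fs * 30
  rec <- quick_recording(matrix(rnorm(10 * n), 10), fs)
  out <- reject_bad_windows(rec)
  expect_lt(mean(out$mask), 0.02)

  burst <- (10 * fs):(12 * fs)
  rec$data[1:8, burst] <- rec$data[1:8, burst] * 20
  out2 <- reject_bad_windows(rec)
  expect_gt(mean(out2$mask[burst]), 0.9)
  expect_lt(mean(out2$mask[-burst]), 0.1)
})

test_that("FastICA unmixes independent super-Gaussian sources", {
  set.seed(10)
  S <- matrix(rnorm(4 * 20000)^3, 4)
  A <- matrix(rnorm(32), 8, 4)
  rec <- quick_recording(A %*% S, 500)
  cs <- run_ica(rec, n_comp = 4, method = "fastica", seed = 2)
  P <- abs(cs$unmixing %*% A)
  P <- P / apply(P, 1, max)
  expect_lt(max(rowSums(P) - 1), 0.1)     # cross-talk per source
  cc <- cor(t(cs$activations))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  cs2 <- run_ica(rec, n_comp = 4, method = "fastica", seed = 2)
  expect_identical(cs$unmixing, cs2$unmixing)
})

test_that("SOBI unmixes spectrally distinct colored sources", {
  set.seed(11)
  fs <- 250
  n <- fs * 40
  ## narrowband sources at distinct frequencies (second-order separable)
  mk <- function(center) {
    sp <- source_spec(c(0, -62, 25), peaks = list(c(center, 3, 1.2)),
                      aperiodic_offset = -2, aperiodic_exponent = 0, burst = 0)
    simulate_source(sp, n / fs, fs)$signal
  }
  S <- rbind(mk(6), mk(10), mk(21))
  A <- matrix(rnorm(18), 6, 3)
  rec <- quick_recording(A %*% S + 0.01 * matrix(rnorm(6 * n), 6), fs)
  cs <- run_ica(rec, n_comp = 3, method = "sobi")
  P <- abs(cs$unmixing %*% A)
  P <- P / apply(P, 1, max)
  expect_lt(max(rowSums(P) - 1), 0.1)
})
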