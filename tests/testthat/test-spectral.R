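simple_events <- function(strides, stride_s = 1.2, t0 = 1.5) {
  rfs <- t0 + (seq_len(strides + 1) - 1) * stride_s
  ev <- data.frame(stride = seq_len(strides),
                   t_RFS = rfs[-length(rfs)],
                   t_LFO = rfs[-length(rfs)] + 0.12 * stride_s,
                   t_LFS = rfs[-length(rfs)] + 0.50 * stride_s,
                   t_RFO = rfs[-length(rfs)] + 0.62 * stride_s,
                   t_RFS_next = rfs[-1])
  class(ev) <- c("gait_events", "data.frame")
  ev
}

test_that("walking epochs span 5.25 s around the right foot strike", {
  for (fs in c(250, 500)) {
    acts <- matrix(rnorm(2 * 12 * fs), 2)
    es <- epoch_walking(acts, fs, simple_events(3), pre = 1, post = 4.25)
    expect_equal(dim(es$data)[3], round(5.25 * fs))
    expect_equal(dim(es$data)[1], 3)
    expect_equal(es$anchor_s, 1)
  }
})

test_that("epochs without a full window or with no events are dropped", {
  fs <- 100
  acts <- matrix(rnorm(8 * fs), 1)
  es0 <- epoch_walking(acts, fs, simple_events(0)[0, ])
  expect_equal(dim(es0$data)[1], 0)
  ## anchor at 0.5 s: the 1-s pre-window does not fit
  ev <- simple_events(1, t0 = 0.5)
  es1 <- epoch_walking(matrix(rnorm(2 * 12 * fs), 1), fs, ev)
  expect_equal(dim(es1$data)[1], 0)
  ## masked samples inside the window drop the epoch
  ev2 <- simple_events(1, t0 = 2)
  mask <- logical(12 * fs)
  mask[3 * fs] <- TRUE
  es2 <- epoch_walking(matrix(rnorm(12 * fs), 1), fs, ev2, mask = mask)
  expect_equal(dim(es2$data)[1], 0)
})

test_that("epochs with outlying event latencies are removed", {
  fs <- 100
  ev <- simple_events(50, stride_s = 1.0, t0 = 1.5)
  ## one epoch with doubled stride time
  ev$t_RFS_next[25] <- ev$t_RFS[25] + 2.0
  acts <- matrix(rnorm(70 * fs), 1)
  es <- epoch_walking(acts, fs, ev)
  n0 <- nrow(es$latencies)
  es2 <- reject_epoch_outliers(es)
  expect_equal(nrow(es2$latencies), n0 - 1)
  ## identical latencies: nothing removed
  es3 <- epoch_walking(acts, fs, simple_events(20, 1.0))
  expect_equal(nrow(reject_epoch_outliers(es3)$latencies), 20)
})

test_that("Welch PSDs find sinusoids and sit at the analytic white-noise level", {
  set.seed(30)
  fs <- 250
  x <- sin(2 * pi * 10 * (0:(fs * 30 - 1)) / fs) + rnorm(fs * 30, 0, 0.5)
  ps <- welch_psd(x, fs)
  expect_equal(ps$freq[which.max(ps$power)], 10)
  w <- rnorm(fs * 60, 0, 2)
  psw <- welch_psd(w, fs)
  lvl <- 10 * log10(2 * 4 / fs)
  expect_lt(abs(mean(psw$db[psw$freq > 5 & psw$freq < 100]) - lvl), 1)
})

test_that("subject-normalized PSDs have zero across-condition mean", {
  set.seed(31)
  acts <- list(Flat = matrix(rnorm(2 * 5000), 2),
               High = matrix(rnorm(2 * 5000), 2),
               rest = matrix(rnorm(2 * 5000), 2))
  ps <- compute_psd(acts, 250, normalize = "subject-mean-subtracted")
  expect_lt(max(abs(apply(ps$db, c(1, 2), mean))), 1e-9)
})

test_that("Morlet power is flat for a stationary sinusoid and tracks amplitude steps", {
  fs <- 250
  tt <- (0:(fs * 8 - 1)) / fs
  tf <- morlet_tf(sin(2 * pi * 10 * tt), fs, seq(4, 30, 2))
  mid <- tf$times > 2 & tf$times < 6
  expect_equal(tf$freqs[which.max(colMeans(tf$power[mid, ]))], 10)
  expect_lt(sd(tf$db[mid, tf$freqs == 10]), 0.5)

  x2 <- c(sin(2 * pi * 10 * tt[1:(4 * fs)]), 2 * sin(2 * pi * 10 * tt[-(1:(4 * fs))]))
  tf2 <- morlet_tf(x2, fs, seq(4, 30, 2))
  lo <- mean(tf2$db[tf2$times > 1 & tf2$times < 3, tf2$freqs == 10])
  hi <- mean(tf2$db[tf2$times > 5 & tf2$times < 7, tf2$freqs == 10])
  expect_lt(abs((hi - lo) - 20 * log10(2)), 1)
})

test_that("the cycles parameterization starts at 3 and expands sublinearly", {
  freqs <- seq(4, 30, 2)
  cyc <- gaitersp:::morlet_cycles(freqs, c(3, 0.8))
  expect_equal(cyc[1], 3)
  expect_true(all(diff(cyc) > 0))
  expect_equal(cyc[length(cyc)], 0.2 * 3 * 30 / 4, tolerance = 1e-8)
})

test_that("time warping is the identity for template-latency epochs and maps segments to anchors", {
  fs <- 100
  n_ep <- 6
  times <- seq(-1, 4.25, by = 1 / fs)
  lat <- data.frame(LFO = rep(0.15, n_ep), LFS = rep(0.60, n_ep),
                    RFO = rep(0.75, n_ep), RFS_next = rep(1.20, n_ep))
  freqs <- c(10, 20)
  ## power varies linearly in time: warped values must equal the grid times
  P <- array(rep(pmax(times, 0.01), each = n_ep), c(n_ep, length(times), 2))
  tf <- list(power = P, times = times, freqs = freqs)
  w <- timewarp_gait(tf, lat, n_grid = 100)
  grid_t <- seq(0, 1.20, length.out = 100)
  expect_lt(max(abs(w$power[1, , 1] - pmax(grid_t, 0.01))), 1e-6)
  expect_equal(w$anchor_pct, c(0, 0.15, 0.60, 0.75, 1.20) / 1.20 * 100,
               ignore_attr = TRUE)

  ## boxcar of elevated power between LFO and LFS lands on that grid segment
  P2 <- array(1, c(n_ep, length(times), 2))
  lat2 <- lat
  lat2[3, ] <- c(0.30, 0.80, 0.95, 1.50)   # one slow epoch
  for (e in seq_len(n_ep)) {
    sel <- times >= lat2$LFO[e] & times <= lat2$LFS[e]
    P2[e, sel, ] <- 10
  }
  w2 <- timewarp_gait(list(power = P2, times = times, freqs = freqs), lat2,
                      n_grid = 200)
  m <- apply(w2$power, c(2, 3), mean)
  pct <- w2$grid_pct
  inside <- pct > w2$anchor_pct[2] + 2 & pct < w2$anchor_pct[3] - 2
  outside <- pct < w2$anchor_pct[2] - 2 | pct > w2$anchor_pct[3] + 2
  expect_true(all(m[inside, 1] > 9))
  expect_true(all(m[outside, 1] < 1.5))
})

test_that("walking-vs-rest maps subtract per frequency and are antisymmetric", {
  walk <- matrix(c(1, 2, 3, 4), 2)
  rest <- c(1, 1)
  expect_equal(ersp_vs_rest(walk, rest), walk - 1)
  a <- matrix(rnorm(10), 5)
  b <- matrix(rnorm(10), 5)
  expect_equal(ersp_vs_rest(a, colMeans(b)) , -ersp_vs_rest(-a, -colMeans(b)))
})

test_that("ERSP normalization modes behave as projections with the right baselines", {
  set.seed(33)
  freqs <- seq(4, 30, 2)
  base <- matrix(rnorm(50 * length(freqs)), 50)
  maps <- list(Flat = base, High = base)
  maps$High[, freqs >= 8 & freqs <= 13] <- maps$High[, freqs >= 8 & freqs <= 13] + 2

  w <- normalize_ersp(maps, "within-condition")
  expect_lt(max(abs(colMeans(w$High))), 1e-9)
  ## idempotent projection
  w2 <- normalize_ersp(w, "within-condition")
  expect_equal(w2$High, w$High)

  cb <- normalize_ersp(maps, "common-baseline")
  alpha_cols <- freqs >= 8 & freqs <= 13
  expect_equal(mean(cb$High[, alpha_cols]) - mean(cb$Flat[, alpha_cols]), 2,
               tolerance = 1e-9)
  same <- normalize_ersp(list(A = base, B = base), "common-baseline")
  expect_equal(same$A, same$B)
})

test_that("peak-to-peak fluctuation equals twice a sinusoidal modulation amplitude", {
  freqs <- seq(4, 30, 2)
  grid <- seq_len(200)
  flat_map <- matrix(0, 200, length(freqs))
  expect_equal(peak_to_peak_fluctuation(flat_map, freqs, c(13, 30)), 0)
  A <- 1.5
  curve <- A * sin(2 * pi * grid / 200)
  map <- flat_map
  map[, freqs >= 13] <- curve
  expect_lt(abs(peak_to_peak_fluctuation(map, freqs, c(13, 30)) - 2 * A), 1e-3)
})

test_that("delta maps subtract elementwise and are antisymmetric", {
  a <- matrix(rnorm(12), 4)
  b <- matrix(rnorm(12), 4)
  expect_equal(delta_ersp(a, a), matrix(0, 4, 3))
  expect_equal(delta_ersp(a, b), -delta_ersp(b, a))
  expect_equal(group_delta(a, b), a - b)
  expect_error(delta_ersp(a, matrix(0, 2, 2)), "mismatch")
})
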