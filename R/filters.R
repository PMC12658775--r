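## Zero-phase FIR filtering and sliding-window line-noise regression.

## windowed-sinc (Hamming) high-pass kernel: passband edge `cutoff`,
## transition bandwidth tbw, hence -6 dB at cutoff - tbw/2
design_fir_highpass <- function(fs, cutoff, tbw = NULL) {
  assert_that(cutoff > 0 && cutoff < fs / 2,
              "highpass: cutoff must lie in (0, Nyquist)")
  if (is.null(tbw)) tbw <- min(max(cutoff * 0.25, 2), cutoff)
  fc <- cutoff - tbw / 2                 # -6 dB point of the kernel
  N <- ceiling(3.3 / (tbw / fs))
  if (N %% 2 == 1) N <- N + 1           # even order -> odd length, type I
  nn <- 0:N
  M <- N / 2
  lp <- 2 * fc / fs * sinc(2 * fc / fs * (nn - M))
  w <- 0.54 - 0.46 * cos(2 * pi * nn / N)
  lp <- lp * w
  lp <- lp / sum(lp)                     # unit DC gain
  hp <- -lp
  hp[M + 1] <- hp[M + 1] + 1             # spectral inversion
  hp
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## apply a linear-phase FIR once with group-delay compensation (zero net
## phase); edges padded by reflection to limit transients
fir_apply <- function(x, h) {
  M <- (length(h) - 1) / 2
  n <- length(x)
  pad <- min(M, n - 1)
  xe <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - (1:pad)])
  nf <- nextn(length(xe) + length(h) - 1, 2)
  X <- fft(c(xe, numeric(nf - length(xe))))
  H <- fft(c(h, numeric(nf - length(h))))
  y <- Re(fft(X * H, inverse = TRUE)) / nf
  y[(pad + M + 1):(pad + M + n)]
}

filter_rows <- function(data, rows, h) {
  for (i in rows) data[i, ] <- fir_apply(data[i, ], h)
  data
}

#' Zero-phase FIR high-pass filter
#'
#' Windowed-sinc (Hamming) FIR applied with group-delay compensation. With
#' the default 1 Hz cutoff the magnitude response is -6 dB at 0.5 Hz (the
#' transition band spans 0 to the cutoff).
#'
#' @param rec an `eeg_recording`.
#' @param cutoff passband edge in Hz (default 1).
#' @param roles channel roles to filter (default all).
#' @return the filtered recording.
#' @export
highpass <- function(rec, cutoff = 1.0, roles = unique(rec$roles)) {
  assert_that(rec$fs > 2 * cutoff, "highpass: cutoff at or above Nyquist")
  h <- design_fir_highpass(rec$fs, cutoff)
  rec$data <- filter_rows(rec$data, which(rec$roles %in% roles), h)
  rec
}

#' 20 Hz high-pass on EMG channels only
#'
#' @param rec an `eeg_recording`.
#' @param cutoff passband edge in Hz (default 20).
#' @return recording with EMG channels filtered; other roles untouched.
#' @export
emg_highpass <- function(rec, cutoff = 20) {
  highpass(rec, cutoff, roles = "emg")
}

#' Remove line noise by sliding-window sinusoidal regression
#'
#' In overlapping 4-second windows, sine/cosine pairs at each mains frequency
#' are fit by least squares and the fitted component subtracted; windows are
#' stitched with Hann-weighted overlap-add. Broadband content away from the
#' mains lines is unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param freqs line frequencies in Hz (default 60 and 120).
#' @param window window length in seconds.
#' @return the cleaned recording.
#' @export
remove_line_noise <- function(rec, freqs = c(60, 120), window = 4) {
  assert_that(all(freqs < rec$fs / 2), "remove_line_noise: freqs must be < Nyquist")
  fs <- rec$fs
  n <- ncol(rec$data)
  wlen <- min(n, round(window * fs))
  hop <- max(1, floor(wlen / 2))
  starts <- unique(c(seq(1, max(1, n - wlen + 1), by = hop), n - wlen + 1))
  wt <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1))
  wt <- pmax(wt, 1e-3)
  fitted <- matrix(0, nrow(rec$data), n)
  wsum <- numeric(n)
  for (s0 in starts) {
    idx <- s0:(s0 + wlen - 1)
    tt <- (idx - 1) / fs
    X <- do.call(cbind, lapply(freqs, function(f) cbind(sin(2 * pi * f * tt),
                                                        cos(2 * pi * f * tt))))
    cf <- lm.fit(X, t(rec$data[, idx, drop = FALSE]))$coefficients
    fit_w <- t(X %*% cf)
    fitted[, idx] <- fitted[, idx] + sweep(fit_w, 2, wt, `*`)
    wsum[idx] <- wsum[idx] + wt
  }
  fitted <- sweep(fitted, 2, wsum, `/`)
  rec$data <- rec$data - fitted
  rec
}
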