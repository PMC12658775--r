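## Epoching, PSDs, Morlet time-frequency maps time-warped to the gait cycle,
## and ERSP normalization / fluctuation metrics. dB is 10*log10(power)
## throughout.

#' Welch power spectral density
#'
#' Hann-tapered averaged periodogram (2-s segments, 50% overlap by default).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window segment length in seconds.
#' @param overlap fractional overlap.
#' @return list with `freq` (Hz), `power` (one-sided density), `db`
#'   (10*log10 power).
#' @export
welch_psd <- function(x, fs, window = 2, overlap = 0.5) {
  wlen <- min(length(x), round(window * fs))
  hop <- max(1, round(wlen * (1 - overlap)))
  starts <- seq(1, length(x) - wlen + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1))
  u <- sum(w^2)
  nf <- floor(wlen / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + wlen - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nf]
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * u * fs)
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  freq <- (0:(nf - 1)) * fs / wlen
  list(freq = freq, power = p, db = 10 * log10(pmax(p, 1e-20)))
}

#' Condition-wise PSD set with subject normalization
#'
#' Welch PSDs per component and condition. With
#' `normalize = "subject-mean-subtracted"` (paper convention) the mean dB
#' spectrum across conditions is subtracted per component, so the across-
#' condition mean is 0 dB at every frequency.
#'
#' @param activations named list (one entry per condition) of components x
#'   samples matrices.
#' @param fs sampling rate (Hz).
#' @param normalize "raw" or "subject-mean-subtracted".
#' @param window Welch segment (s).
#' @return object of class `psd_set`: `freq`, `db` (components x freq x
#'   condition array), `mode`.
#' @export
compute_psd <- function(activations, fs, normalize = c("raw", "subject-mean-subtracted"),
                        window = 2) {
  normalize <- match.arg(normalize)
  conds <- names(activations)
  assert_that(!is.null(conds), "compute_psd: activations must be a named list")
  first <- welch_psd(activations[[1]][1, ], fs, window)
  n_comp <- nrow(activations[[1]])
  db <- array(NA_real_, c(n_comp, length(first$freq), length(conds)),
              dimnames = list(NULL, NULL, conds))
  for (ci in seq_along(conds)) {
    for (k in seq_len(n_comp)) {
      db[k, , ci] <- welch_psd(activations[[ci]][k, ], fs, window)$db
    }
  }
  if (normalize == "subject-mean-subtracted") {
    mu <- apply(db, c(1, 2), mean)
    db <- sweep(db, c(1, 2), mu)
  }
  structure(list(freq = first$freq, db = db, mode = normalize), class = "psd_set")
}

#' Epoch walking data around right foot strikes
#'
#' One epoch per right foot strike whose full window (1 s before to 4.25 s
#' after, total 5.25 s) lies inside the recording and, if a mask is given,
#' contains no masked samples. Gait event latencies are stored per epoch
#' relative to the anchoring foot strike.
#'
#' @param activations components x samples matrix.
#' @param fs sampling rate (Hz).
#' @param events a `gait_events` table (times in s from recording start).
#' @param pre,post window extent around the anchor (s); defaults 1 and 4.25.
#' @param mask optional logical per-sample vector, `TRUE` = bad.
#' @return object of class `epoch_set`: `data` (epochs x components x
#'   samples), `latencies` (data.frame LFO, LFS, RFO, RFS_next in s),
#'   `anchor_s = pre`, `fs`, `times` (s relative to anchor).
#' @export
epoch_walking <- function(activations, fs, events, pre = 1, post = 4.25,
                          mask = NULL) {
  nsamp_epoch <- round((pre + post) * fs)
  n <- ncol(activations)
  keep <- list()
  lat <- list()
  for (i in seq_len(nrow(events))) {
    a <- round(events$t_RFS[i] * fs) + 1          # anchor sample
    i0 <- a - round(pre * fs)
    i1 <- i0 + nsamp_epoch - 1
    if (i0 < 1 || i1 > n) next
    if (!is.null(mask) && any(mask[i0:i1])) next
    keep[[length(keep) + 1]] <- i0
    lat[[length(lat) + 1]] <- data.frame(
      LFO = events$t_LFO[i] - events$t_RFS[i],
      LFS = events$t_LFS[i] - events$t_RFS[i],
      RFO = events$t_RFO[i] - events$t_RFS[i],
      RFS_next = events$t_RFS_next[i] - events$t_RFS[i])
  }
  n_ep <- length(keep)
  data <- array(NA_real_, c(n_ep, nrow(activations), nsamp_epoch))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- activations[, keep[[e]]:(keep[[e]] + nsamp_epoch - 1), drop = FALSE]
  }
  structure(list(data = data,
                 latencies = if (n_ep) do.call(rbind, lat) else
                   data.frame(LFO = numeric(), LFS = numeric(), RFO = numeric(),
                              RFS_next = numeric()),
                 anchor_s = pre, fs = fs,
                 times = (seq_len(nsamp_epoch) - 1) / fs - pre),
            class = "epoch_set")
}

#' Drop epochs with outlying gait event latencies
#'
#' For each of the LFO/LFS/RFO/next-RFS latencies, epochs whose latency lies
#' more than `k_sd` SD from that latency's mean are removed.
#'
#' @param es an `epoch_set`.
#' @param k_sd threshold (default 3).
#' @return the reduced `epoch_set`.
#' @export
reject_epoch_outliers <- function(es, k_sd = 3) {
  assert_that(nrow(es$latencies) >= 5, "reject_epoch_outliers: needs >= 5 epochs")
  L <- as.matrix(es$latencies)
  z <- scale(L)
  z[is.nan(z)] <- 0
  bad <- apply(abs(z) > k_sd, 1, any)
  if (any(bad)) ger_log("reject_epoch_outliers: removed %d epoch(s)", sum(bad))
  es$data <- es$data[!bad, , , drop = FALSE]
  es$latencies <- es$latencies[!bad, , drop = FALSE]
  es
}

## cycles-per-frequency under the EEGLAB-style [c0, fac] convention:
## c0 cycles at the lowest frequency, expanding as a power law so that the
## cycle count at the highest frequency equals (1 - fac) of the fixed-window
## (FFT-taper) count c0 * fmax / fmin
morlet_cycles <- function(freqs, cycles = c(3, 0.8)) {
  c0 <- cycles[1]
  fac <- cycles[2]
  f0 <- min(freqs)
  fmax <- max(freqs)
  if (fmax <= f0 || fac >= 1) return(rep(c0, length(freqs)))
  target <- (1 - fac) * c0 * fmax / f0
  q <- log(target / c0) / log(fmax / f0)
  c0 * (freqs / f0)^q
}

#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet convolution (FFT-based) of one signal; power returned on a
#' decimated time grid. The number of cycles per frequency follows the
#' `[3, 0.8]` expansion convention (see `morlet_cycles`).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param freqs analysis frequencies (Hz).
#' @param cycles length-2 cycles parameterization (default `c(3, 0.8)`).
#' @param out_step output decimation in samples (default ~100 Hz grid).
#' @return list with `power` (time x freq, linear), `db`, `times` (s, signal
#'   start = 0), `freqs`, `cycles`.
#' @export
morlet_tf <- function(x, fs, freqs, cycles = c(3, 0.8),
                      out_step = max(1L, round(fs / 100))) {
  n <- length(x)
  cyc <- morlet_cycles(freqs, cycles)
  keep_f <- rep(TRUE, length(freqs))
  out_idx <- seq(1, n, by = out_step)
  pw <- matrix(NA_real_, length(out_idx), length(freqs))
  nf <- nextn(2 * n, 2)
  X <- fft(c(x, numeric(nf - n)))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sig_t <- cyc[j] / (2 * pi * f)
    half <- ceiling(4 * sig_t * fs)
    if (2 * half + 1 > n) {
      ger_log("morlet_tf: %g Hz wavelet longer than signal, dropped", f)
      keep_f[j] <- FALSE
      next
    }
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig_t^2))
    w <- w / sum(Mod(w))                      # unit l1 envelope gain
    W <- fft(c(w, numeric(nf - length(w))))
    conv <- fft(X * W, inverse = TRUE)[seq_len(n + 2 * half)] / nf
    centered <- conv[(half + 1):(half + n)]
    pw[, j] <- Mod(centered[out_idx])^2
  }
  pw <- pw[, keep_f, drop = FALSE]
  list(power = pw, db = 10 * log10(pmax(pw, 1e-20)),
       times = (out_idx - 1) / fs, freqs = freqs[keep_f], cycles = cyc[keep_f])
}

## per-epoch TF maps for one component of an epoch_set: epochs x time x freq
morlet_tf_epochs <- function(es, component, freqs, cycles = c(3, 0.8),
                             out_step = max(1L, round(es$fs / 100))) {
  n_ep <- dim(es$data)[1]
  first <- morlet_tf(es$data[1, component, ], es$fs, freqs, cycles, out_step)
  arr <- array(NA_real_, c(n_ep, nrow(first$power), length(first$freqs)))
  arr[1, , ] <- first$power
  if (n_ep > 1) for (e in 2:n_ep) {
    arr[e, , ] <- morlet_tf(es$data[e, component, ], es$fs, freqs, cycles,
                            out_step)$power
  }
  list(power = arr, times = first$times - es$anchor_s, freqs = first$freqs)
}

#' Time-warp per-epoch time-frequency maps onto a common gait grid
#'
#' Each epoch's stride (right foot strike, left foot off, left foot strike,
#' right foot off, next right foot strike) is remapped piecewise-linearly so
#' that its five anchors land on the template anchors (the median latencies
#' across epochs). Power is linearly interpolated onto `n_grid` points
#' spanning 0-100% of the stride, then expressed in dB.
#'
#' @param tf output of `morlet_tf_epochs` (list: `power` epochs x time x freq,
#'   `times` seconds relative to the anchoring foot strike, `freqs`).
#' @param latencies data.frame of per-epoch latencies (LFO, LFS, RFO,
#'   RFS_next, seconds after the anchor).
#' @param n_grid number of gait-percentage points (default 200).
#' @return object of class `ersp_epochs`: `db` (epochs x grid x freq),
#'   `grid_pct`, `anchor_pct` (grid positions of the five events), `freqs`.
#' @export
timewarp_gait <- function(tf, latencies, n_grid = 200) {
  ok <- apply(latencies, 1, function(l) all(diff(c(0, l)) > 0))
  if (!all(ok)) ger_log("timewarp_gait: dropped %d epoch(s) with non-monotone latencies",
                        sum(!ok))
  assert_that(any(ok), "timewarp_gait: no epochs with monotone latencies")
  lat <- latencies[ok, , drop = FALSE]
  P <- tf$power[ok, , , drop = FALSE]
  tmpl <- c(0, apply(lat, 2, median))             # RFS, LFO, LFS, RFO, RFS_next
  T_str <- tmpl[5]
  grid_t <- seq(0, T_str, length.out = n_grid)
  n_ep <- dim(P)[1]
  out <- array(NA_real_, c(n_ep, n_grid, length(tf$freqs)))
  for (e in seq_len(n_ep)) {
    anchors_e <- c(0, as.numeric(lat[e, ]))
    te <- approx(tmpl, anchors_e, xout = grid_t)$y  # template time -> epoch time
    for (j in seq_along(tf$freqs)) {
      out[e, , j] <- approx(tf$times, P[e, , j], xout = te, rule = 2)$y
    }
  }
  structure(list(db = 10 * log10(pmax(out, 1e-20)), power = out,
                 grid_pct = grid_t / T_str * 100,
                 anchor_pct = tmpl / T_str * 100,
                 anchor_names = c("RFS", "LFO", "LFS", "RFO", "RFS_next"),
                 freqs = tf$freqs),
            class = "ersp_epochs")
}

#' Epoch-averaged ERSP map
#'
#' Averages linear power across epochs (and optionally across several
#' `ersp_epochs` objects, e.g. trials) and returns the dB map.
#'
#' @param ... one or more `ersp_epochs` objects on the same grid.
#' @return grid x freq dB matrix.
#' @export
ersp_mean_map <- function(...) {
  ws <- list(...)
  if (length(ws) == 1 && !inherits(ws[[1]], "ersp_epochs")) ws <- ws[[1]]
  acc <- 0
  n <- 0
  for (w in ws) {
    acc <- acc + apply(w$power, c(2, 3), sum)
    n <- n + dim(w$power)[1]
  }
  10 * log10(pmax(acc / n, 1e-20))
}

#' Walking-versus-rest spectral change
#'
#' Subtracts the resting mean dB spectrum from a walking dB map per frequency.
#'
#' @param walk_db gait-grid x freq dB map (or any time x freq dB matrix).
#' @param rest_db numeric vector, mean rest dB per frequency (same grid).
#' @return dB difference map.
#' @export
ersp_vs_rest <- function(walk_db, rest_db) {
  assert_that(ncol(walk_db) == length(rest_db),
              "ersp_vs_rest: frequency grids differ")
  sweep(walk_db, 2, rest_db)
}

#' Normalize gait-cycle ERSP maps
#'
#' Within-condition: each condition's own mean over the gait axis is
#' subtracted per frequency (the map then has zero gait-axis mean, the form
#' used for intra-stride fluctuation). Common-baseline: the across-condition
#' mean of the gait-axis means is subtracted from every condition, preserving
#' between-condition offsets.
#'
#' @param maps named list (condition -> grid x freq dB matrix).
#' @param mode "within-condition" or "common-baseline".
#' @return named list of normalized maps with attribute `baseline_mode`.
#' @export
normalize_ersp <- function(maps, mode = c("within-condition", "common-baseline")) {
  mode <- match.arg(mode)
  if (is.matrix(maps)) maps <- list(map = maps)
  if (mode == "within-condition") {
    out <- lapply(maps, function(m) sweep(m, 2, colMeans(m)))
  } else {
    base <- Reduce(`+`, lapply(maps, colMeans)) / length(maps)
    out <- lapply(maps, function(m) sweep(m, 2, base))
  }
  attr(out, "baseline_mode") <- mode
  out
}

#' Intra-stride peak-to-peak band fluctuation
#'
#' Band curve = mean dB over the band's frequencies at each gait-percentage
#' point of a within-condition normalized map; returns max - min of that
#' curve (no smoothing by default).
#'
#' @param map grid x freq dB matrix (within-condition normalized).
#' @param freqs frequency vector matching `ncol(map)`.
#' @param band length-2 Hz interval.
#' @param smooth optional moving-average window (grid points, default off).
#' @return peak-to-peak range in dB.
#' @export
peak_to_peak_fluctuation <- function(map, freqs, band, smooth = 0) {
  sel <- freqs >= band[1] & freqs <= band[2]
  assert_that(any(sel), "peak_to_peak_fluctuation: empty band")
  curve <- rowMeans(map[, sel, drop = FALSE])
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    curve <- as.numeric(stats::filter(curve, k, circular = TRUE))
  }
  max(curve) - min(curve)
}

#' Terrain-versus-flat and group difference ERSP maps
#'
#' @param ersp_uneven,ersp_flat dB maps on the same grid and baseline mode.
#' @return elementwise difference map.
#' @export
delta_ersp <- function(ersp_uneven, ersp_flat) {
  assert_that(all(dim(ersp_uneven) == dim(ersp_flat)),
              "delta_ersp: grid mismatch")
  ersp_uneven - ersp_flat
}

#' @rdname delta_ersp
#' @param delta_young,delta_old terrain-difference maps per group.
#' @export
group_delta <- function(delta_young, delta_old) {
  assert_that(all(dim(delta_young) == dim(delta_old)),
              "group_delta: grid mismatch")
  delta_young - delta_old
}
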