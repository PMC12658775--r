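## Channel and window rejection, reference-guided (CCA) artifact cleaning,
## average referencing, and ICA decomposition.

#' Reject bad channels by a robust amplitude criterion
#'
#' Per channel role, the robust amplitude metric (median absolute deviation of
#' the channel) is z-scored across channels of that role; channels more than
#' `k_sd` SD from the role mean are dropped. Rejections are logged.
#'
#' @param rec an `eeg_recording`.
#' @param k_sd rejection threshold in SD (default 3).
#' @param roles roles screened (default scalp and noise).
#' @return list with `recording` (channels removed) and `rejected`
#'   (data.frame: label, role, metric, z).
#' @export
reject_bad_channels <- function(rec, k_sd = 3, roles = c("scalp", "noise")) {
  rejected <- data.frame(label = character(), role = character(),
                         metric = numeric(), z = numeric())
  drop <- logical(nrow(rec$data))
  for (role in roles) {
    idx <- which(rec$roles == role)
    if (length(idx) < 4) next
    m <- apply(rec$data[idx, , drop = FALSE], 1, mad)
    s <- sd(m)
    z <- if (s > 0) (m - mean(m)) / s else rep(0, length(m))
    bad <- abs(z) > k_sd
    if (any(bad)) {
      rejected <- rbind(rejected,
                        data.frame(label = rownames(rec$data)[idx[bad]] %||%
                                     as.character(idx[bad]),
                                   role = role, metric = m[bad], z = z[bad]))
      drop[idx[bad]] <- TRUE
      ger_log("reject_bad_channels: dropped %d %s channel(s): %s",
              sum(bad), role, paste(which(bad), collapse = ","))
    }
    assert_that(mean(bad) <= 0.5,
                "reject_bad_channels: > 50%% of %s channels rejected, data unusable", role)
  }
  rec$data <- rec$data[!drop, , drop = FALSE]
  rec$roles <- rec$roles[!drop]
  if (!is.null(rec$positions)) rec$positions <- rec$positions[!drop, , drop = FALSE]
  list(recording = rec, rejected = rejected)
}

#' Average reference per channel role
#'
#' Subtracts, at each sample, the mean across channels of each role present
#' (scalp, noise, EMG referenced separately).
#'
#' @param rec an `eeg_recording`.
#' @return the re-referenced recording (per-role channel mean is 0 everywhere).
#' @export
average_reference <- function(rec) {
  for (role in unique(rec$roles)) {
    idx <- which(rec$roles == role)
    if (length(idx) < 2) next
    mu <- colMeans(rec$data[idx, , drop = FALSE])
    rec$data[idx, ] <- sweep(rec$data[idx, , drop = FALSE], 2, mu)
  }
  rec
}

## canonical correlation cleaning of one window: project out scalp canonical
## variates whose squared correlation with the reference subspace >= r2
cca_clean_window <- function(X, Y, r2) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  cc <- stats::cancor(Xc, Yc)
  sel <- which(cc$cor^2 >= r2)
  if (!length(sel)) return(X)
  U <- Xc %*% cc$xcoef[, sel, drop = FALSE]
  beta <- solve(crossprod(U) + diag(1e-12, ncol(U)), crossprod(U, Xc))
  X - U %*% beta
}

#' Reference-guided artifact removal (windowed CCA)
#'
#' In overlapping moving windows, canonical correlation analysis between the
#' scalp channels and the reference channels (noise or EMG role) identifies
#' shared subspaces; scalp canonical components with squared canonical
#' correlation at or above `r2` are projected out. Windows are stitched with
#' Hann-weighted overlap-add. Rank-deficient windows are skipped with a log
#' entry.
#'
#' @param rec an `eeg_recording`.
#' @param refs reference role: "noise" (default `r2 = 0.65`) or "emg"
#'   (paper default `r2 = 0.4`).
#' @param r2 squared canonical correlation threshold.
#' @param window window length in seconds (default 4).
#' @return the cleaned recording.
#' @export
reference_guided_clean <- function(rec, refs = c("noise", "emg"),
                                   r2 = if (match.arg(refs) == "noise") 0.65 else 0.4,
                                   window = 4) {
  refs <- match.arg(refs)
  scalp_idx <- which(rec$roles == "scalp")
  ref_idx <- which(rec$roles == refs)
  assert_that(length(ref_idx) >= 1, "reference_guided_clean: no %s channels", refs)
  n <- ncol(rec$data)
  fs <- rec$fs
  wlen <- min(n, round(window * fs))
  assert_that(wlen > length(scalp_idx) + length(ref_idx),
              "reference_guided_clean: window shorter than channel count")
  hop <- max(1, floor(wlen / 2))
  starts <- unique(c(seq(1, max(1, n - wlen + 1), by = hop), n - wlen + 1))
  wt <- pmax(0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1)), 1e-3)
  out <- matrix(0, length(scalp_idx), n)
  wsum <- numeric(n)
  for (s0 in starts) {
    idx <- s0:(s0 + wlen - 1)
    X <- t(rec$data[scalp_idx, idx, drop = FALSE])
    Y <- t(rec$data[ref_idx, idx, drop = FALSE])
    Xc <- tryCatch(cca_clean_window(X, Y, r2), error = function(e) {
      ger_log("reference_guided_clean: window at sample %d skipped (%s)",
              s0, conditionMessage(e))
      X
    })
    out[, idx] <- out[, idx] + t(Xc) * rep(wt, each = length(scalp_idx))
    wsum[idx] <- wsum[idx] + wt
  }
  rec$data[scalp_idx, ] <- sweep(out, 2, wsum, `/`)
  rec
}

#' Mark bad time windows
#'
#' Splits the recording into 1-second windows. A channel misbehaves in a
#' window when its correlation with a least-squares reconstruction from the
#' other scalp channels drops below `chan_crit` times that channel's own
#' typical (median across windows) reconstruction correlation, or its
#' amplitude z-score (relative to the channel's own robust level) exceeds
#' `z_tol`. Windows in which more than `win_crit` of scalp channels misbehave
#' are masked.
#'
#' @param rec an `eeg_recording`.
#' @param chan_crit channel-reconstruction correlation criterion (default 0.7).
#' @param win_crit maximal tolerated fraction of misbehaving channels
#'   (default 0.4).
#' @param z_tol upper amplitude tolerance in robust z units (default 10).
#' @param window window length in seconds (default 1).
#' @return list with `recording` (unchanged data), `mask` (logical per sample,
#'   `TRUE` = bad) and `window_frac` masked.
#' @export
reject_bad_windows <- function(rec, chan_crit = 0.7, win_crit = 0.4,
                               z_tol = 10, window = 1) {
  scalp_idx <- which(rec$roles == "scalp")
  X <- rec$data[scalp_idx, , drop = FALSE]
  n <- ncol(X)
  wlen <- max(8, round(window * rec$fs))
  n_win <- floor(n / wlen)
  ch_scale <- apply(X, 1, mad)
  ch_scale[ch_scale <= 0] <- 1e-9
  ## per-window reconstruction correlation of each channel from the others
  recon_cor <- function(seg) {
    segc <- seg - rowMeans(seg)
    G <- tcrossprod(segc)
    vapply(seq_len(nrow(seg)), function(i) {
      fit <- tryCatch({
        b <- solve(G[-i, -i] + diag(1e-8, nrow(seg) - 1), G[-i, i])
        crossprod(segc[-i, , drop = FALSE], b)
      }, error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      r <- suppressWarnings(cor(segc[i, ], as.numeric(fit)))
      if (is.finite(r)) r else 0
    }, 0)
  }
  cors <- vapply(seq_len(n_win), function(w) {
    recon_cor(X[, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE])
  }, numeric(nrow(X)))
  cors <- matrix(cors, nrow(X))
  ## calibration: a channel's typical reconstruction correlation
  typ <- apply(cors, 1, median, na.rm = TRUE)
  mask <- logical(n)
  n_bad_win <- 0
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    seg <- X[, idx, drop = FALSE]
    rms <- sqrt(rowMeans(seg^2))
    z <- rms / (1.4826 * ch_scale)   # robust amplitude z (MAD-scaled)
    bad_amp <- z > z_tol
    bad_cor <- cors[, w] < chan_crit * pmax(typ, 0)
    bad_cor[is.na(bad_cor)] <- FALSE
    frac_bad <- mean(bad_amp | bad_cor)
    if (frac_bad > win_crit) {
      mask[idx] <- TRUE
      n_bad_win <- n_bad_win + 1
      ger_log("reject_bad_windows: window %d masked (%.0f%% channels bad)",
              w, 100 * frac_bad)
    }
  }
  frac <- mean(mask)
  if (frac > 0.7) stopf("reject_bad_windows: %.0f%% of data masked, unusable", 100 * frac)
  if (frac > 0.4) warnf("reject_bad_windows: %.0f%% of data masked", 100 * frac)
  list(recording = rec, mask = mask, window_frac = frac)
}

## ---- ICA ----------------------------------------------------------------


## SOBI: second-order blind identification. Whitens the data, then jointly
## diagonalizes time-lagged covariance matrices by Jacobi (Givens) rotations
## (Cardoso-Souloumiac). Separates sources with distinct spectra -- the
## appropriate contrast for oscillatory EEG -- and is deterministic.
sobi_ica <- function(X, n_comp, lags = NULL, fs = NULL, tol = 1e-8,
                     max_sweeps = 100) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc / sqrt(n))
  assert_that(n_comp <= sum(sv$d > sv$d[1] * 1e-10),
              "run_ica: n_comp exceeds data rank")
  K <- diag(1 / sv$d[1:n_comp]) %*% t(sv$u[, 1:n_comp, drop = FALSE])
  Z <- K %*% Xc
  if (is.null(lags)) {
    step <- if (is.null(fs)) 2L else max(1L, round(fs / 250))
    lags <- unique(pmax(1L, round(step * c(1:10, 12, 15, 20, 30, 40, 60, 80, 100))))
  }
  Ms <- lapply(lags, function(l) {
    C <- tcrossprod(Z[, 1:(n - l), drop = FALSE], Z[, (1 + l):n, drop = FALSE]) / (n - l)
    (C + t(C)) / 2
  })
  m <- n_comp
  V <- diag(m)
  for (sweep in seq_len(max_sweeps)) {
    s_max <- 0
    for (p in 1:(m - 1)) for (q in (p + 1):m) {
      g <- vapply(Ms, function(M) c(M[p, p] - M[q, q], M[p, q] + M[q, p]),
                  numeric(2))
      G <- tcrossprod(g)
      ev <- eigen(G, symmetric = TRUE)$vectors[, 1]
      if (ev[1] < 0) ev <- -ev
      cth <- sqrt(0.5 + ev[1] / 2)
      sth <- 0.5 * ev[2] / cth
      if (abs(sth) < tol) next
      s_max <- max(s_max, abs(sth))
      R <- diag(m)
      R[p, p] <- cth; R[q, q] <- cth; R[p, q] <- -sth; R[q, p] <- sth
      Ms <- lapply(Ms, function(M) t(R) %*% M %*% R)
      V <- V %*% R
    }
    if (s_max < 10 * tol) break
  }
  ## order by activation variance in the original (pre-whitening) scale
  W <- t(V) %*% K
  A <- t(W) %*% solve(W %*% t(W))
  ord <- order(colSums(A^2), decreasing = TRUE)
  list(unmixing = W[ord, , drop = FALSE], it = sweep)
}

## symmetric FastICA with the logcosh contrast; X: channels x samples,
## assumed finite; returns unmixing W (comp x channels) with W %*% X the
## independent activations
fastica_symm <- function(X, n_comp, seed = 1L, max_iter = 1000, tol = 1e-6) {
  set.seed(seed)
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc / sqrt(n))
  assert_that(n_comp <= sum(sv$d > sv$d[1] * 1e-10),
              "run_ica: n_comp exceeds data rank")
  K <- diag(1 / sv$d[1:n_comp]) %*% t(sv$u[, 1:n_comp, drop = FALSE])  # whitener
  Z <- K %*% Xc                       # whitened, comp x samples
  W <- matrix(rnorm(n_comp^2), n_comp)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  it <- 0
  repeat {
    it <- it + 1
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- sym_decorrelate((G %*% t(Z)) / n - gp * W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
    if (it >= max_iter) {
      stopf("run_ica: no convergence after %d iterations (delta = %.2e)", it, delta)
    }
  }
  list(unmixing = W %*% K, it = it)
}

#' Independent component analysis of scalp channels
#'
#' Decomposes whitened scalp data into maximally independent components,
#' excluding masked samples from the estimation. Two estimators are provided:
#' `"sobi"` (default; joint diagonalization of time-lagged covariances, which
#' separates oscillatory sources by their spectral structure and is
#' deterministic) and `"fastica"` (symmetric FastICA, logcosh contrast, for
#' sources with non-Gaussian amplitude distributions). Both are deterministic
#' given `seed`.
#'
#' @param rec an `eeg_recording` (or list of recordings to concatenate, e.g.
#'   walking trials plus rest).
#' @param n_comp number of components; defaults to scalp rank - 1 (average
#'   reference removes one dimension).
#' @param mask optional logical per-sample vector (or list of vectors),
#'   `TRUE` = excluded from estimation.
#' @param seed RNG seed for the FastICA random orthogonal start (default 1).
#' @param method "sobi" or "fastica".
#' @param max_iter,tol convergence controls.
#' @return object of class `component_set`: `unmixing` (comp x channels),
#'   `mixing` (channels x comp), `activations` (comp x samples of the
#'   concatenated input), `scalp_idx`, `fs`, `positions`.
#' @export
run_ica <- function(rec, n_comp = NULL, mask = NULL, seed = 1L,
                    method = c("sobi", "fastica"),
                    max_iter = 1000, tol = 1e-6) {
  method <- match.arg(method)
  recs <- if (inherits(rec, "eeg_recording")) list(rec) else rec
  masks <- if (is.null(mask)) lapply(recs, function(r) logical(ncol(r$data)))
           else if (is.logical(mask)) list(mask) else mask
  scalp_idx <- which(recs[[1]]$roles == "scalp")
  X_fit <- do.call(cbind, lapply(seq_along(recs), function(i) {
    recs[[i]]$data[scalp_idx, !masks[[i]], drop = FALSE]
  }))
  X_all <- do.call(cbind, lapply(recs, function(r) r$data[scalp_idx, , drop = FALSE]))
  if (is.null(n_comp)) {
    ## PCA reduction: keep dimensions clearly above the sensor-noise floor
    ## (eigenvalue > 2% of the largest), capped at rank - 1 (average
    ## reference removes one dimension)
    sv <- svd(X_fit - rowMeans(X_fit), nu = 0, nv = 0)
    ev <- sv$d^2
    n_comp <- max(2, min(sum(ev > 0.02 * ev[1]), 20, sum(ev > ev[1] * 1e-12) - 1))
  }
  fit <- if (method == "sobi") {
    sobi_ica(X_fit, n_comp, fs = recs[[1]]$fs)
  } else {
    fastica_symm(X_fit, n_comp, seed = seed, max_iter = max_iter, tol = tol)
  }
  W <- fit$unmixing
  A <- t(W) %*% solve(W %*% t(W))      # Moore-Penrose right inverse
  acts <- W %*% (X_all - rowMeans(X_all))
  structure(list(unmixing = W, mixing = A, activations = acts,
                 scalp_idx = scalp_idx, fs = recs[[1]]$fs,
                 positions = recs[[1]]$positions[scalp_idx, , drop = FALSE],
                 n_iter = fit$it, seed = seed,
                 boundaries = cumsum(vapply(recs, function(r) ncol(r$data), 0))),
            class = "component_set")
}
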