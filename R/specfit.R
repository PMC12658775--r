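## Spectral PCA muscle-artifact correction and aperiodic/periodic spectral
## parameterization (band power on the flattened spectrum).

#' Fit a spectral PCA model
#'
#' Uncentered PCA (SVD) over an observations x frequency matrix of spectral
#' changes versus rest (components as rows; for ERSP corrections, component x
#' gait-time observations). The first principal component, which carries the
#' largest eigenvalue and in contaminated data shows the rising muscle
#' profile, is designated for removal. The same model (weighting matrix) is
#' applied to every condition of a subject.
#'
#' @param X observations x frequency matrix (dB change vs rest).
#' @param removed indices of principal components to remove (default 1).
#' @return object of class `spca_model`: `eigvec` (freq x k, orthonormal),
#'   `eigval`, `removed`, `rank`.
#' @export
fit_spca <- function(X, removed = 1L) {
  X <- as.matrix(X)
  k <- min(dim(X))
  if (nrow(X) < ncol(X))
    ger_log("fit_spca: fewer observations (%d) than frequencies (%d); reduced-rank fit",
            nrow(X), ncol(X))
  sv <- svd(X, nu = 0, nv = k)
  structure(list(eigvec = sv$v, eigval = sv$d[seq_len(k)]^2,
                 removed = as.integer(removed), rank = k),
            class = "spca_model")
}

#' Apply a spectral PCA correction
#'
#' Projects spectra onto the model's principal-component space, zeroes the
#' removed set, and back-projects. With an empty removal set (and full-rank
#' model) this is the identity. For PSDs, pass the resting-condition spectrum
#' in `add_back` so downstream aperiodic fitting sees absolute spectra.
#'
#' @param model a `spca_model`.
#' @param X observations x frequency matrix on the same frequency grid.
#' @param removed removal set override (default the model's).
#' @param add_back optional vector (length = n freq) added back after
#'   correction, e.g. the resting PSD.
#' @return corrected matrix, same shape as `X`.
#' @export
apply_spca <- function(model, X, removed = model$removed, add_back = NULL) {
  X <- as.matrix(X)
  assert_that(ncol(X) == nrow(model$eigvec),
              "apply_spca: frequency grid mismatch (%d vs %d)",
              ncol(X), nrow(model$eigvec))
  V <- model$eigvec
  scores <- X %*% V
  if (length(removed)) scores[, removed] <- 0
  out <- scores %*% t(V)
  if (length(removed) == 0) {
    ## keep exact identity even when the basis is rank-deficient
    out <- out + (X - (X %*% V) %*% t(V))
  }
  if (!is.null(add_back)) out <- sweep(out, 2, add_back, `+`)
  out
}

## Gaussian peak in log10-power over linear frequency
gauss_pk <- function(f, center, height, width) {
  height * exp(-(f - center)^2 / (2 * width^2))
}

#' Parameterize a power spectrum into aperiodic and periodic parts
#'
#' Fits, in log10-power units, an aperiodic model
#' `log10 P(f) = offset - exponent * log10 f` robustly (ordinary fit followed
#' by a refit on the points least elevated above it, so narrowband peaks do
#' not bias the slope), then extracts up to `max_peaks` Gaussian peaks (in
#' log10 power over linear frequency) from the flattened spectrum by
#' iterative fitting, enforcing the peak-width and minimum-height
#' constraints, and finally refits the aperiodic component on the
#' peak-subtracted spectrum. The flattened spectrum is the dB spectrum minus
#' the dB aperiodic fit.
#'
#' @param freq frequency vector (Hz).
#' @param psd_db power spectral density in dB (10*log10 power).
#' @param freq_range fit range in Hz (default `c(3, 40)`).
#' @param peak_width allowed peak standard-deviation-equivalent width range
#'   in Hz (default `c(1, 8)`, interpreted as full width limits; the Gaussian
#'   SD is bounded by `peak_width / 2`).
#' @param min_height minimum peak height in log10-power units (default 0.05,
#'   i.e. 0.5 dB).
#' @param max_peaks maximum number of peaks (default 2).
#' @return object of class `spectral_fit`: `offset`, `exponent` (log10
#'   units), `peaks` (data.frame center/height/width; height in log10 power),
#'   `freq`, `flattened_db`, `aperiodic_db`, `r_squared`, `converged`.
#' @export
fit_spectral_model <- function(freq, psd_db, freq_range = c(3, 40),
                               peak_width = c(1, 8), min_height = 0.05,
                               max_peaks = 2) {
  sel <- freq >= freq_range[1] & freq <= freq_range[2]
  f <- freq[sel]
  p <- psd_db[sel] / 10                       # log10 power
  assert_that(all(is.finite(p)), "fit_spectral_model: spectrum must be positive over the fit range")
  lf <- log10(f)

  ap_fit <- function(ff, pp) {
    cf <- coef(lm(pp ~ log10(ff)))
    c(offset = unname(cf[1]), exponent = unname(-cf[2]))
  }
  ap_eval <- function(ap, ff) ap[1] - ap[2] * log10(ff)

  ## robust aperiodic fit: iteratively exclude points far from the line in
  ## either direction, so narrowband peaks and band-limited dips do not bias
  ## the slope
  ap_robust <- function(ff, pp) {
    ap <- ap_fit(ff, pp)
    for (iter in 1:2) {
      r <- pp - ap_eval(ap, ff)
      s <- mad(r)
      keep <- abs(r) <= pmax(2.5 * s, 1e-3)
      if (sum(keep) < 8) break
      ap <- ap_fit(ff[keep], pp[keep])
    }
    ap
  }
  ap <- ap_robust(f, p)

  ## iterative peak extraction from the flattened spectrum
  sd_lo <- peak_width[1] / 2
  sd_hi <- peak_width[2] / 2
  flat <- p - ap_eval(ap, f)
  peaks <- list()
  converged <- TRUE
  for (k in seq_len(max_peaks)) {
    i_max <- which.max(flat)
    h0 <- flat[i_max]
    if (h0 < min_height) break
    c0 <- f[i_max]
    ## half-maximum width guess
    above <- flat >= h0 / 2
    w0 <- max(sd_lo, min(sd_hi, sum(above & abs(f - c0) < 10) * mean(diff(f)) / 2.355))
    fit <- tryCatch(
      minpack.lm::nlsLM(flat ~ gauss_pk(f, center, height, width),
                        start = list(center = c0, height = h0, width = w0),
                        lower = c(freq_range[1], min_height / 2, sd_lo),
                        upper = c(freq_range[2], 5, sd_hi),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) { converged <- FALSE; break }
    cf <- coef(fit)
    if (cf[["height"]] < min_height) break
    peaks[[k]] <- cf
    flat <- flat - gauss_pk(f, cf[["center"]], cf[["height"]], cf[["width"]])
  }

  ## refit aperiodic on the peak-subtracted spectrum
  peak_sum <- numeric(length(f))
  for (pk in peaks) peak_sum <- peak_sum + gauss_pk(f, pk[["center"]],
                                                    pk[["height"]], pk[["width"]])
  ap <- ap_robust(f, p - peak_sum)
  flattened <- (p - ap_eval(ap, f)) * 10      # back to dB
  model <- ap_eval(ap, f) + peak_sum
  ss_res <- sum((p - model)^2)
  r2 <- 1 - ss_res / sum((p - mean(p))^2)

  pk_df <- if (length(peaks)) {
    d <- as.data.frame(do.call(rbind, peaks))
    d[order(-d$height), , drop = FALSE]
  } else data.frame(center = numeric(), height = numeric(), width = numeric())
  structure(list(offset = unname(ap[1]), exponent = unname(ap[2]),
                 peaks = pk_df, freq = f, flattened_db = flattened,
                 aperiodic_db = ap_eval(ap, f) * 10,
                 r_squared = r2, converged = converged,
                 freq_range = freq_range),
            class = "spectral_fit")
}

#' Average band power of a flattened spectrum
#'
#' Mean of the flattened dB spectrum over the band's frequency bins.
#'
#' @param freq frequency vector (Hz).
#' @param flattened_db flattened spectrum (dB) on the same grid.
#' @param band length-2 Hz interval (default bands: theta 4-8, alpha 8-13,
#'   beta 13-30).
#' @return scalar dB.
#' @export
band_power <- function(freq, flattened_db, band) {
  sel <- freq >= band[1] & freq <= band[2]
  assert_that(any(sel), "band_power: no frequency bins inside the band")
  mean(flattened_db[sel])
}
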