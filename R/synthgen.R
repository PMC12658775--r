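## Synthetic multi-subject gait-EEG generator with known ground truth.
##
## Cortical sources are band-decomposed colored noise: the total source
## spectrum follows 10^(offset - exponent*log10 f) times Gaussian-in-log-power
## oscillatory peaks. The signal is synthesized as a sum of band-limited
## components (theta/alpha/beta/remainder) filtered from a single white-noise
## draw with disjoint spectral masks, so per-band dB shifts and within-stride
## amplitude modulation have exact power bookkeeping: a condition shift of
## d dB multiplies that band's PSD by 10^(d/10) exactly.

#' Simulation configuration
#'
#' @param n_young,n_old subjects per age group.
#' @param conditions ordered terrain labels; "rest" is always simulated once
#'   per subject in addition.
#' @param fs sampling rate in Hz (default 500).
#' @param n_scalp number of scalp electrodes (desk-scale default 32).
#' @param n_noise number of mechanically coupled noise electrodes (must equal
#'   `n_scalp`).
#' @param n_emg number of neck-muscle EMG electrodes.
#' @param trial_duration walking-trial duration in seconds.
#' @param n_trials walking trials per condition (default 2).
#' @param head_radius model head radius (mm).
#' @param bands named list of frequency band edges (Hz).
#' @param emg_scalp_frac fraction of scalp channels receiving EMG
#'   contamination.
#' @param line_freqs mains frequencies added to all channels (Hz).
#' @param seed integer seed for the dataset-level RNG stream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_young = 4, n_old = 4,
                       conditions = c("Flat", "Low", "Med", "High"),
                       fs = 500, n_scalp = 32, n_noise = n_scalp, n_emg = 4,
                       trial_duration = 60, n_trials = 2, head_radius = 90,
                       bands = list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30)),
                       emg_scalp_frac = 0.25, line_freqs = c(60, 120),
                       seed = 1L) {
  assert_that(n_noise == n_scalp, "sim_config: n_noise must equal n_scalp")
  assert_that(trial_duration > 0, "sim_config: durations must be positive")
  fmax <- max(unlist(bands), line_freqs)
  assert_that(fs > 2 * fmax, "sim_config: fs must exceed twice the largest frequency")
  structure(list(n_young = n_young, n_old = n_old, conditions = conditions,
                 fs = fs, n_scalp = n_scalp, n_noise = n_noise, n_emg = n_emg,
                 trial_duration = trial_duration, n_trials = n_trials,
                 head_radius = head_radius, bands = bands,
                 emg_scalp_frac = emg_scalp_frac, line_freqs = line_freqs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Cortical source specification
#'
#' @param location 3-vector, dipole position in head coordinates (mm).
#' @param orientation 3-vector dipole orientation (normalized internally).
#' @param aperiodic_offset log10 power at 1 Hz.
#' @param aperiodic_exponent 1/f exponent (>= 0).
#' @param peaks list of `c(center, height, width)` triples: Gaussian peaks in
#'   log10 power over linear frequency (Hz, log10-power, Hz).
#' @param condition_shift band power shifts in dB: a bands x conditions matrix
#'   or a bands x conditions x groups array (groups "young", "old").
#' @param group_shift dB per band and group (bands x 2 matrix) added to all
#'   conditions.
#' @param gait_modulation list of entries `list(band=, p2p=, cycles=, phase=)`
#'   describing a zero-mean cosine amplitude modulation of that band across
#'   the stride, in dB peak-to-peak; `p2p` may be a conditions x groups
#'   matrix.
#' @param burst SD of the log amplitude envelope applied to each band
#'   component (waxing/waning oscillations); 0 disables burstiness.
#' @return object of class `source_spec`.
#' @export
source_spec <- function(location, orientation = location / sqrt(sum(location^2)),
                        aperiodic_offset = 1.0, aperiodic_exponent = 1.5,
                        peaks = list(c(10, 0.5, 1.5)),
                        condition_shift = NULL, group_shift = NULL,
                        gait_modulation = list(), burst = 0.4) {
  assert_that(aperiodic_exponent >= 0, "source_spec: exponent must be >= 0")
  o <- orientation / sqrt(sum(orientation^2))
  structure(list(location = as.numeric(location), orientation = as.numeric(o),
                 aperiodic_offset = aperiodic_offset,
                 aperiodic_exponent = aperiodic_exponent,
                 peaks = peaks, condition_shift = condition_shift,
                 group_shift = group_shift, gait_modulation = gait_modulation,
                 burst = burst),
            class = "source_spec")
}

## aperiodic + peaks model in log10 power over linear frequency
source_log10_psd <- function(spec, f) {
  lf <- log10(pmax(f, 0.25))
  g <- spec$aperiodic_offset - spec$aperiodic_exponent * lf
  for (pk in spec$peaks) {
    g <- g + pk[2] * exp(-(f - pk[1])^2 / (2 * pk[3]^2))
  }
  g
}

## frequency grid of an n-point FFT (two-sided)
fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1
  f <- k / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]   # fold to |f|
  f
}

## filter a white-noise FFT to one-sided PSD S(f): gain sqrt(S * fs / 2)
## applied two-sided; returns the real time series
shape_fft <- function(W, S, fs) {
  g <- sqrt(pmax(S, 0) * fs / 2)
  g[1] <- 0
  Re(fft(W * g, inverse = TRUE)) / length(W)
}

## dB shift looked up from a source's condition/group tables for one band
band_shift_db <- function(spec, band, condition, group) {
  d <- 0
  cs <- spec$condition_shift
  if (!is.null(cs)) {
    if (length(dim(cs)) == 3) {
      if (band %in% dimnames(cs)[[1]] && condition %in% dimnames(cs)[[2]])
        d <- d + cs[band, condition, group]
    } else if (band %in% rownames(cs) && condition %in% colnames(cs)) {
      d <- d + cs[band, condition]
    }
  }
  gs <- spec$group_shift
  if (!is.null(gs) && band %in% rownames(gs) && group %in% colnames(gs))
    d <- d + gs[band, group]
  d
}

## zero-mean gait modulation (dB) for one band evaluated at phases in [0,1)
gait_mod_db <- function(spec, band, phase, condition, group) {
  g <- numeric(length(phase))
  for (gm in spec$gait_modulation) {
    if (!identical(gm$band, band)) next
    p2p <- gm$p2p
    if (is.matrix(p2p)) p2p <- p2p[condition, group]
    cyc <- gm$cycles %||% 2
    off <- gm$phase %||% 0
    g <- g + (p2p / 2) * cos(2 * pi * cyc * (phase - off))
  }
  g
}

## synthesize one source's time series; returns the signal and the exact
## per-band dB shifts applied (ground truth)
simulate_source_signal <- function(spec, n, fs, bands, phase = NULL,
                                   condition = "rest", group = "young") {
  f <- fft_freqs(n, fs)
  S <- 10^source_log10_psd(spec, f)
  masks <- list()
  rest_mask <- rep(TRUE, n)
  for (b in names(bands)) {
    m <- f >= bands[[b]][1] & f < bands[[b]][2]
    masks[[b]] <- m
    rest_mask <- rest_mask & !m
  }
  W <- fft(rnorm(n))
  shifts <- setNames(numeric(length(bands)), names(bands))
  x <- shape_fft(W, S * rest_mask, fs)
  for (b in names(bands)) {
    d <- if (condition == "rest") 0 else band_shift_db(spec, b, condition, group)
    shifts[b] <- d
    xb <- shape_fft(W, S * masks[[b]] * 10^(d / 10), fs)
    ## waxing-and-waning band amplitude (bursty oscillations, as in real
    ## EEG); the envelope is normalized to unit mean square so the injected
    ## band-power shifts stay exact
    env_b <- burst_envelope(n, fs, sd_log = spec$burst %||% 0.4)
    xb <- xb * env_b
    if (!is.null(phase) && condition != "rest") {
      g <- gait_mod_db(spec, b, phase, condition, group)
      env <- ifelse(is.na(phase), 1, 10^(g / 20))
      xb <- xb * env
    }
    x <- x + xb
  }
  list(signal = x, shifts = shifts)
}

## smooth (~1 s scale) lognormal amplitude envelope, unit mean square
burst_envelope <- function(n, fs, sd_log = 0.4, tau = 1) {
  if (sd_log <= 0) return(rep(1, n))
  f <- fft_freqs(n, fs)
  S <- exp(-(f / (1 / tau))^2)
  e <- shape_fft(fft(rnorm(n)), S, fs)
  e <- exp(sd_log * e / sd(e))
  e / sqrt(mean(e^2))
}

## rising-spectrum EMG artifact: flat to 20 Hz, +0.3 dB/Hz above
emg_signal <- function(n, fs, rms = 8) {
  f <- fft_freqs(n, fs)
  S <- 10^(0.3 * pmax(0, f - 20) / 10)
  x <- shape_fft(fft(rnorm(n)), S, fs)
  x * rms / sd(x)
}

#' Simulate one multi-channel recording
#'
#' Mixes the cortical sources to scalp channels through the dipolar forward
#' model, applies per-band condition/group shifts and within-stride gait
#' modulation, and adds EMG contamination (on EMG channels and a fraction of
#' scalp channels), 60/120 Hz line noise, and sensor noise. Noise-role
#' channels carry the artifact + line-noise mixture of their paired scalp
#' channel but none of the cortical sources.
#'
#' @param sources list of [source_spec()].
#' @param gait output of [simulate_gait()], or `NULL` for seated rest.
#' @param cfg a [sim_config()].
#' @param condition condition label (must be in `cfg$conditions` or "rest").
#' @param group "young" or "old".
#' @param seed integer seed.
#' @param duration trial length (s), default `cfg$trial_duration`.
#' @param sensor_noise_uv,line_amp_uv,emg_amp_uv,emg_scalp_uv amplitude knobs
#'   (microvolt RMS / sinusoid amplitude).
#' @param clean if `TRUE`, omit EMG, line noise and sensor noise (oracle use).
#' @return object of class `eeg_recording` with fields `data` (channels x
#'   samples, microvolts), `fs`, `roles`, `positions`, labels, and a `truth`
#'   list (mixing matrix, source signals' band shifts, events).
#' @export
simulate_recording <- function(sources, gait, cfg, condition, group = "young",
                               seed = NULL, duration = cfg$trial_duration,
                               sensor_noise_uv = 1, line_amp_uv = 2,
                               emg_amp_uv = 8, emg_scalp_uv = 1.5,
                               clean = FALSE) {
  assert_that(condition %in% c(cfg$conditions, "rest"),
              "simulate_recording: unknown condition label '%s'", condition)
  assert_that(length(sources) >= 1, "simulate_recording: need >= 1 source")
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$fs
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- if (is.null(gait)) NULL else gait_phase(t, gait$events)

  montage <- spherical_montage(cfg$n_scalp, cfg$head_radius)
  S <- matrix(0, length(sources), n)
  shifts <- list()
  for (j in seq_along(sources)) {
    sim <- simulate_source_signal(sources[[j]], n, fs, cfg$bands, phase,
                                  condition, group)
    S[j, ] <- sim$signal
    shifts[[j]] <- sim$shifts
  }
  A <- vapply(sources, function(sp)
    dipole_forward(sp$location, sp$orientation, montage), numeric(cfg$n_scalp))
  A <- A / rep(apply(abs(A), 2, max), each = cfg$n_scalp)   # unit peak gain

  scalp <- A %*% S
  art <- matrix(0, cfg$n_scalp, n)
  emg_ch <- matrix(0, cfg$n_emg, n)
  if (!clean) {
    emg_src <- t(vapply(seq_len(cfg$n_emg), function(k) emg_signal(n, fs, emg_amp_uv),
                        numeric(n)))
    emg_ch <- emg_src + matrix(rnorm(cfg$n_emg * n, 0, sensor_noise_uv), cfg$n_emg)
    n_cont <- max(1, round(cfg$emg_scalp_frac * cfg$n_scalp))
    cont_idx <- sample(cfg$n_scalp, n_cont)
    wts <- matrix(runif(n_cont * cfg$n_emg, 0.3, 1), n_cont)
    art[cont_idx, ] <- art[cont_idx, ] + (wts %*% emg_src) * (emg_scalp_uv / emg_amp_uv)
    for (lf in cfg$line_freqs) {
      amp <- runif(cfg$n_scalp, 0.5, 1) * line_amp_uv
      phs <- runif(cfg$n_scalp, 0, 2 * pi)
      art <- art + amp * sin(2 * pi * lf * matrix(t, cfg$n_scalp, n, byrow = TRUE) + phs)
    }
    scalp <- scalp + art + matrix(rnorm(cfg$n_scalp * n, 0, sensor_noise_uv), cfg$n_scalp)
  }
  noise_ch <- art + matrix(rnorm(cfg$n_noise * n, 0, 0.5 * sensor_noise_uv), cfg$n_noise)

  data <- rbind(scalp, noise_ch, emg_ch)
  roles <- c(rep("scalp", cfg$n_scalp), rep("noise", cfg$n_noise),
             rep("emg", cfg$n_emg))
  labels <- c(sprintf("EEG%03d", seq_len(cfg$n_scalp)),
              sprintf("NOI%03d", seq_len(cfg$n_noise)),
              sprintf("EMG%03d", seq_len(cfg$n_emg)))
  positions <- rbind(montage, montage, matrix(NA_real_, cfg$n_emg, 3))
  rownames(data) <- labels

  recording(data, fs, roles, positions = positions, condition = condition,
            group = group,
            truth = list(mixing = A, source_shifts = shifts,
                         events = if (is.null(gait)) NULL else gait$events,
                         sources = sources))
}

#' Multichannel recording container
#'
#' @param data channels x samples matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param roles character vector, one of "scalp", "noise", "emg" per channel.
#' @param positions channels x 3 electrode positions (mm; NA for EMG).
#' @param subject,group,condition,trial metadata labels.
#' @param truth optional ground-truth list (simulated data only).
#' @return object of class `eeg_recording`.
#' @export
recording <- function(data, fs, roles, positions = NULL, subject = NA,
                      group = NA, condition = NA, trial = NA, truth = NULL) {
  assert_that(is.matrix(data) && !anyNA(data), "recording: data must be a matrix without NAs")
  assert_that(length(roles) == nrow(data), "recording: one role per channel required")
  structure(list(data = data, fs = fs, roles = roles, positions = positions,
                 subject = subject, group = group, condition = condition,
                 trial = trial, truth = truth),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              paste(sprintf("%s:%d", names(table(x$roles)), table(x$roles)),
                    collapse = " ")))
  invisible(x)
}

#' Named effect-template scenarios
#'
#' Returns the cortical source set encoding a scenario's terrain/age effects.
#' `"null"` has no condition, group or gait-phase effects. `"paper-like"`
#' encodes: a young-only parieto-occipital alpha/beta reduction growing with
#' terrain unevenness, a terrain-only (both-group) sensorimotor alpha/beta
#' reduction, a both-group occipital theta increase, sensorimotor beta
#' gait-phase modulation (synchronization in double support, desynchronization
#' in swing) of 3 dB peak-to-peak, and a young-only terrain-dependent increase
#' in occipital alpha intra-stride fluctuation.
#'
#' @param name "null" or "paper-like".
#' @param cfg a [sim_config()] (for band names and conditions).
#' @return list of [source_spec()].
#' @export
scenario_sources <- function(name = c("paper-like", "null"), cfg = sim_config()) {
  name <- match.arg(name)
  conds <- cfg$conditions
  bands <- names(cfg$bands)
  zero_cs <- function() {
    a <- array(0, c(length(bands), length(conds), 2),
               dimnames = list(bands, conds, c("young", "old")))
    a
  }
  locs <- list(occipital = c(0, -62, 25),
               parietal_l = c(-32, -48, 52),
               sensorimotor_l = c(-42, -12, 58),
               sensorimotor_r = c(42, -12, 58),
               frontal = c(0, 35, 60))
  ## per-region peak frequencies differ slightly (as individual alpha/beta
  ## frequencies do across cortex), which also makes the sources spectrally
  ## identifiable
  peaks <- list(
    occipital = list(c(6, 0.25, 1.5), c(10, 0.7, 1.2), c(20, 0.3, 3)),
    parietal_l = list(c(11.5, 0.5, 1.2), c(17, 0.35, 2.5)),
    sensorimotor_l = list(c(9, 0.4, 1.2), c(21, 0.45, 3)),
    sensorimotor_r = list(c(10.5, 0.4, 1.2), c(24, 0.45, 3)),
    frontal = list(c(5, 0.4, 1.2), c(15, 0.25, 2)))

  mk <- function(region) {
    cs <- zero_cs()
    gm <- list()
    if (name == "paper-like") {
      if (region %in% c("occipital", "parietal_l")) {
        cs["alpha", , "young"] <- c(0, -0.8, -1.4, -2.0)
        cs["alpha", , "old"] <- c(0, 0, 0, -0.2)
        cs["beta", , "young"] <- c(0, -0.6, -1.0, -1.5)
        cs["beta", , "old"] <- c(0, 0, 0, -0.1)
      }
      if (region == "occipital") {
        cs["theta", , "young"] <- cs["theta", , "old"] <- c(0, 0.5, 0.9, 1.5)
        p2p <- cbind(young = c(1.0, 1.5, 2.0, 2.5), old = rep(1.0, 4))
        rownames(p2p) <- conds
        gm <- c(gm, list(list(band = "alpha", p2p = p2p, cycles = 2, phase = 0.05)))
      }
      if (region %in% c("sensorimotor_l", "sensorimotor_r")) {
        cs["alpha", , "young"] <- cs["alpha", , "old"] <- c(0, -0.7, -1.1, -1.6)
        cs["beta", , "young"] <- cs["beta", , "old"] <- c(0, -0.7, -1.1, -1.6)
        gm <- c(gm, list(list(band = "beta", p2p = 3, cycles = 2, phase = 0.05)))
      }
    }
    expo <- c(occipital = 1.5, parietal_l = 1.4, sensorimotor_l = 1.6,
              sensorimotor_r = 1.45, frontal = 1.7)[[region]]
    source_spec(location = locs[[region]],
                aperiodic_offset = 1.0, aperiodic_exponent = expo,
                peaks = peaks[[region]], condition_shift = cs,
                gait_modulation = gm)
  }
  lapply(setNames(names(locs), names(locs)), mk)
}

#' Generate a full synthetic dataset
#'
#' One seated-rest recording plus `cfg$n_trials` walking recordings per
#' terrain condition for every subject. Subject-level random intercepts
#' (per band, SD `subject_sd` dB) are added to all condition shifts; walking
#' speeds are drawn per subject around group means. All ground truth (sources,
#' per-subject shifts, gait events, mixing matrices) is retained.
#'
#' @param cfg a [sim_config()].
#' @param scenario scenario name, see [scenario_sources()].
#' @param subject_sd SD of the per-subject, per-band dB intercept.
#' @return object of class `synthetic_dataset`: `subjects` (data.frame),
#'   `recordings` (list with subject/condition/trial metadata), `gait` (per
#'   subject x condition), `truth`.
#' @export
generate_dataset <- function(cfg = sim_config(), scenario = "paper-like",
                             subject_sd = 0.3) {
  set.seed(cfg$seed)
  base_sources <- scenario_sources(scenario, cfg)
  n_sub <- cfg$n_young + cfg$n_old
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n_sub)),
    group = c(rep("young", cfg$n_young), rep("old", cfg$n_old)),
    speed = round(c(rnorm(cfg$n_young, 0.70, 0.10), rnorm(cfg$n_old, 0.35, 0.10)), 3))
  subjects$speed <- pmax(0.15, subjects$speed)

  bands <- names(cfg$bands)
  intercepts <- matrix(rnorm(n_sub * length(bands), 0, subject_sd), n_sub,
                       dimnames = list(subjects$subject, bands))
  seeds <- sample.int(2^30, n_sub * (length(cfg$conditions) * (cfg$n_trials + 1) + 2))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }

  recordings <- list()
  gait_all <- list()
  for (s in seq_len(n_sub)) {
    sub <- subjects$subject[s]
    grp <- subjects$group[s]
    ## per-subject sources: add the band intercept to every condition shift
    subj_sources <- lapply(base_sources, function(sp) {
      cs <- sp$condition_shift
      for (b in bands) cs[b, , ] <- cs[b, , ] + intercepts[sub, b]
      sp$condition_shift <- cs
      sp
    })
    rest <- simulate_recording(subj_sources, gait = NULL, cfg, "rest", grp,
                               seed = next_seed())
    rest$subject <- sub
    rest$trial <- 1L
    recordings[[length(recordings) + 1L]] <- rest
    for (cond in cfg$conditions) {
      for (tr in seq_len(cfg$n_trials)) {
        g <- simulate_gait(default_gait_spec(cond, grp), cfg$trial_duration,
                           cfg$fs, seed = next_seed())
        gait_all[[paste(sub, cond, tr, sep = ".")]] <- g
        rec <- simulate_recording(subj_sources, g, cfg, cond, grp,
                                  seed = next_seed())
        rec$subject <- sub
        rec$trial <- tr
        recordings[[length(recordings) + 1L]] <- rec
      }
    }
  }
  structure(list(cfg = cfg, scenario = scenario, subjects = subjects,
                 recordings = recordings, gait = gait_all,
                 truth = list(sources = base_sources, intercepts = intercepts)),
            class = "synthetic_dataset")
}
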