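## Clean-source oracle pathways: run the spectral/statistical stages on
## noiseless source signals with known injected effects. These power the
## parameter-recovery studies (and are handy for calibrating scenario effect
## sizes) without the cost of the full sensor-level pipeline.

#' Synthesize one cortical source signal
#'
#' Band-decomposed colored noise following the source's aperiodic + peaks
#' spectrum, with the condition/group band shifts and (when gait events are
#' given) the within-stride amplitude modulation applied. This is the signal
#' a perfect unmixing would recover.
#'
#' @param spec a [source_spec()].
#' @param duration seconds.
#' @param fs sampling rate (Hz).
#' @param bands band-edge list (see [sim_config()]).
#' @param condition,group labels selecting the injected shifts.
#' @param gait optional [simulate_gait()] output supplying the gait phase.
#' @param seed integer seed.
#' @return list: `signal` (numeric), `shifts` (exact injected dB per band),
#'   `fs`.
#' @export
simulate_source <- function(spec, duration, fs = 250,
                            bands = list(theta = c(4, 8), alpha = c(8, 13),
                                         beta = c(13, 30)),
                            condition = "rest", group = "young",
                            gait = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  phase <- if (is.null(gait)) NULL else
    gait_phase((seq_len(n) - 1) / fs, gait$events)
  sim <- simulate_source_signal(spec, n, fs, bands, phase, condition, group)
  c(sim, list(fs = fs))
}

#' Band-power table from clean sources under a scenario
#'
#' For every subject and terrain condition, synthesizes the scenario's
#' source signals (with subject-level random intercepts), runs the PSD
#' pathway (Welch spectrum, aperiodic/periodic fit, flattened band power) and
#' returns the per-(subject, condition, region, band) outcome table that the
#' mixed-model stage consumes.
#'
#' @param n_young,n_old subjects per group.
#' @param duration seconds of signal per condition.
#' @param fs sampling rate (Hz).
#' @param scenario scenario name (see [scenario_sources()]).
#' @param regions which scenario sources to analyze.
#' @param subject_sd SD of the per-subject per-band intercept (dB).
#' @param seed integer seed.
#' @return data.frame: subject, group, condition, speed, region, band, value.
#' @export
clean_source_band_table <- function(n_young = 12, n_old = 12, duration = 30,
                                    fs = 250, scenario = "paper-like",
                                    regions = c("occipital", "sensorimotor_l"),
                                    subject_sd = 0.3, seed = 1L) {
  set.seed(seed)
  cfg <- sim_config(n_young = n_young, n_old = n_old, fs = fs,
                    trial_duration = duration, seed = seed)
  sources <- scenario_sources(scenario, cfg)[regions]
  n_sub <- n_young + n_old
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n_sub)),
    group = c(rep("young", n_young), rep("old", n_old)),
    speed = pmax(0.15, c(rnorm(n_young, 0.70, 0.10), rnorm(n_old, 0.35, 0.10))))
  bands <- cfg$bands
  intercepts <- matrix(rnorm(n_sub * length(bands), 0, subject_sd), n_sub,
                       dimnames = list(subjects$subject, names(bands)))
  rows <- list()
  for (s in seq_len(n_sub)) {
    sub <- subjects$subject[s]
    grp <- subjects$group[s]
    for (region in regions) {
      sp <- sources[[region]]
      cs <- sp$condition_shift
      for (b in names(bands)) cs[b, , ] <- cs[b, , ] + intercepts[sub, b]
      sp$condition_shift <- cs
      for (cond in cfg$conditions) {
        sim <- simulate_source(sp, duration, fs, bands, cond, grp)
        ps <- welch_psd(sim$signal, fs)
        fit <- fit_spectral_model(ps$freq, ps$db)
        for (b in names(bands)) {
          rows[[length(rows) + 1]] <- data.frame(
            subject = sub, group = grp, condition = cond,
            speed = subjects$speed[s], region = region, band = b,
            value = band_power(fit$freq, fit$flattened_db, bands[[b]]),
            truth_shift = sim$shifts[[b]])
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Null gait-warped ERSP epoch set
#'
#' Generates a component whose spectral power is stationary across the gait
#' cycle (1/f background plus an unmodulated alpha oscillation), walks it
#' through epoching, Morlet decomposition and gait-cycle time warping, and
#' returns the per-epoch warped maps. Used for error-rate studies of the
#' bootstrap masking procedure.
#'
#' @param n_epochs minimum number of epochs to return.
#' @param fs sampling rate (Hz).
#' @param freqs analysis frequencies (Hz).
#' @param n_grid gait-percentage grid points.
#' @param seed integer seed.
#' @return an `ersp_epochs` object.
#' @export
simulate_null_ersp_epochs <- function(n_epochs = 40, fs = 250,
                                      freqs = seq(4, 30, 2), n_grid = 50,
                                      seed = 1L) {
  set.seed(seed)
  spec <- source_spec(c(0, -62, 25), peaks = list(c(10, 0.5, 1.5)))
  duration <- ceiling((n_epochs + 8) * 1.25 + 6)
  g <- simulate_gait(default_gait_spec("Flat", "young"), duration, fs,
                     seed = seed + 1)
  sim <- simulate_source(spec, duration, fs, condition = "Flat",
                         gait = g, seed = seed + 2)
  es <- epoch_walking(matrix(sim$signal, 1), fs, g$events)
  es <- reject_epoch_outliers(es)
  tf <- morlet_tf_epochs(es, 1, freqs)
  timewarp_gait(tf, es$latencies, n_grid)
}
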