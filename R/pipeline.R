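## Configuration, the fixed preprocessing chain, per-subject analysis and the
## one-command end-to-end driver.

#' Pipeline configuration with study defaults
#'
#' Every stage parameter appears exactly once, with its default value and a
#' one-line description. Overrides are supplied as named arguments matching
#' the nested structure, e.g. `pipeline_config(stats = list(n_boot = 500))`.
#'
#' @param ... named overrides merged over the defaults (per section).
#' @return object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    simulation = list(
      n_young = 4, n_old = 4, fs = 500, n_scalp = 32, n_emg = 4,
      trial_duration = 60, n_trials = 2, scenario = "paper-like", seed = 1L,
      note = "desk-scale synthetic study: subjects per group, Hz, channels, s"),
    filters = list(
      highpass_hz = 1, emg_highpass_hz = 20, line_freqs = c(60, 120),
      note = "drift high-pass (-6 dB at half cutoff), EMG high-pass, mains lines"),
    rejection = list(
      chan_k_sd = 3, chan_crit = 0.7, win_crit = 0.4, win_z_tol = 10,
      note = "bad-channel z threshold; window rejection criteria"),
    cca = list(
      r2_noise = 0.65, r2_emg = 0.4, window_s = 4,
      note = "squared canonical correlation thresholds, moving window"),
    behavior = list(
      force_threshold_n = 20, outlier_k_sd = 2.5, min_strides = 5,
      note = "gait event force threshold; per-trial outlier rule"),
    epoching = list(
      pre_s = 1, post_s = 4.25, event_k_sd = 3,
      note = "5.25-s epochs around right foot strike; latency outlier rule"),
    spectral = list(
      welch_window_s = 2, morlet_cycles = c(3, 0.8),
      freqs = seq(4, 30, 1), n_grid = 200,
      bands = list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30)),
      fooof_range = c(3, 40), peak_width = c(1, 8), min_peak_height = 0.05,
      max_peaks = 2,
      note = "PSD/time-frequency/aperiodic-fit parameters and band edges"),
    clustering = list(
      k = 11, outlier_k_sd = 3, nstart = 100, min_frac = 0.5, seed = 1L,
      note = "k-means on dipole locations; outlier and membership rules"),
    stats = list(
      alpha = 0.05, n_boot = 4000, n_perm_psd = 2000, n_perm_cluster = 10000,
      lmm_outlier_k_sd = 8,
      note = "significance level and resampling iteration counts"),
    ica = list(method = "sobi", seed = 1L, max_iter = 1000,
               note = "ICA estimator, determinism and controls"))
  over <- list(...)
  for (sec in names(over)) {
    assert_that(sec %in% names(defaults), "pipeline_config: unknown section '%s'", sec)
    for (key in names(over[[sec]])) defaults[[sec]][[key]] <- over[[sec]][[key]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Write / read a pipeline configuration (lossless JSON round-trip)
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgify <- function(x) {
    if (is.data.frame(x)) x <- as.list(x)
    x
  }
  do.call(pipeline_config, lapply(raw, cfgify))
}

#' Fixed preprocessing chain for one recording
#'
#' Order: high-pass, EMG high-pass, line-noise removal, bad-channel
#' rejection, average reference, reference-guided cleaning against noise
#' electrodes then EMG electrodes, bad-window marking, re-reference. Every
#' rejection is returned in the log.
#'
#' @param rec an `eeg_recording`.
#' @param config a [pipeline_config()].
#' @return list: `recording` (cleaned), `mask` (bad samples), `log`
#'   (data.frame of rejection decisions and counts).
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  log <- list()
  rec <- highpass(rec, config$filters$highpass_hz)
  rec <- emg_highpass(rec, config$filters$emg_highpass_hz)
  rec <- remove_line_noise(rec, config$filters$line_freqs, config$cca$window_s)
  bc <- reject_bad_channels(rec, config$rejection$chan_k_sd)
  rec <- bc$recording
  log$channels_rejected <- nrow(bc$rejected)
  rec <- average_reference(rec)
  rec <- reference_guided_clean(rec, "noise", config$cca$r2_noise, config$cca$window_s)
  if (any(rec$roles == "emg"))
    rec <- reference_guided_clean(rec, "emg", config$cca$r2_emg, config$cca$window_s)
  bw <- reject_bad_windows(rec, config$rejection$chan_crit,
                           config$rejection$win_crit, config$rejection$win_z_tol)
  rec <- average_reference(bw$recording)
  log$window_frac_masked <- bw$window_frac
  list(recording = rec, mask = bw$mask,
       log = data.frame(step = names(log), value = unlist(log)))
}

## indices of the concatenated activation matrix belonging to each input
ica_segments <- function(cs) {
  ends <- cs$boundaries
  starts <- c(1, head(ends, -1) + 1)
  Map(function(s, e) s:e, starts, ends)
}

#' Preprocess and decompose all recordings of one subject
#'
#' Runs [preprocess_recording()] on every trial, then one ICA on the
#' concatenated (walking + rest) cleaned data with masked samples excluded,
#' and scores/fits dipoles for every component.
#'
#' @param recordings list of the subject's `eeg_recording`s (walking trials
#'   and the rest trial).
#' @param config a [pipeline_config()].
#' @return list: `cs` (scored `component_set`), `meta` (data.frame with
#'   condition/trial per recording), `masks`, `logs`.
#' @export
preprocess_subject <- function(recordings, config = pipeline_config()) {
  pre <- lapply(recordings, preprocess_recording, config = config)
  cleaned <- lapply(pre, `[[`, "recording")
  masks <- lapply(pre, `[[`, "mask")
  ## a channel dropped in any trial is dropped everywhere (common montage)
  keep_lab <- Reduce(intersect, lapply(cleaned, function(r) rownames(r$data)))
  cleaned <- lapply(cleaned, function(r) {
    sel <- rownames(r$data) %in% keep_lab
    r$data <- r$data[sel, , drop = FALSE]
    r$roles <- r$roles[sel]
    r$positions <- r$positions[sel, , drop = FALSE]
    r
  })
  cs <- run_ica(cleaned, mask = masks, seed = config$ica$seed,
                method = config$ica$method, max_iter = config$ica$max_iter)
  cs <- score_components(cs)
  meta <- data.frame(
    condition = vapply(recordings, function(r) as.character(r$condition), ""),
    trial = vapply(recordings, function(r) as.integer(r$trial), 0L))
  list(cs = cs, meta = meta, masks = masks,
       logs = lapply(pre, `[[`, "log"))
}

## per-condition activation list for one component set
activations_by_condition <- function(cs, meta, component = NULL) {
  segs <- ica_segments(cs)
  out <- list()
  for (cond in unique(meta$condition)) {
    idx <- unlist(segs[meta$condition == cond])
    out[[cond]] <- cs$activations[, idx, drop = FALSE]
  }
  out
}

#' Full spectral analysis for one subject
#'
#' For every retained component: condition-wise Welch PSDs, walking-vs-rest
#' changes, subject-level sPCA muscle correction (separate bases for PSD and
#' ERSP observations, PC1 removed), aperiodic/periodic fits and band powers
#' on the corrected absolute spectra, gait-warped ERSPs and per-band
#' intra-stride peak-to-peak fluctuations.
#'
#' @param sub output of [preprocess_subject()].
#' @param gait named list `condition.trial -> simulate_gait()` output (or
#'   detected events) for the subject's walking trials.
#' @param config a [pipeline_config()].
#' @param components component indices to analyze (default: retained).
#' @return list: `band` and `p2p` data.frames (component, condition, band,
#'   value), `freqs`, plus the sPCA models.
#' @export
subject_spectra <- function(sub, gait, config = pipeline_config(),
                            components = NULL) {
  cs <- sub$cs
  meta <- sub$meta
  sp <- config$spectral
  if (is.null(components)) components <- which(cs$scores$retained)
  assert_that(length(components) >= 1, "subject_spectra: no retained components")
  conds <- setdiff(unique(meta$condition), "rest")
  segs <- ica_segments(cs)

  ## --- PSDs -----------------------------------------------------------
  acts <- activations_by_condition(cs, meta)
  grid <- welch_psd(acts[[1]][1, ], cs$fs, sp$welch_window_s)$freq
  fsel <- grid >= 2 & grid <= 45
  psd <- function(x) welch_psd(x, cs$fs, sp$welch_window_s)$db[fsel]
  rest_psd <- t(vapply(components, function(k) psd(acts[["rest"]][k, ]),
                       numeric(sum(fsel))))
  walk_psd <- lapply(conds, function(cond)
    t(vapply(components, function(k) psd(acts[[cond]][k, ]), numeric(sum(fsel)))))
  names(walk_psd) <- conds
  change <- lapply(walk_psd, function(W) W - rest_psd)
  psd_model <- fit_spca(Reduce(`+`, change) / length(change))

  band_rows <- list()
  for (cond in conds) {
    corrected <- apply_spca(psd_model, change[[cond]])
    for (i in seq_along(components)) {
      abs_psd <- corrected[i, ] + rest_psd[i, ]
      fit <- fit_spectral_model(grid[fsel], abs_psd, sp$fooof_range,
                                sp$peak_width, sp$min_peak_height, sp$max_peaks)
      for (b in names(sp$bands)) {
        band_rows[[length(band_rows) + 1]] <- data.frame(
          component = components[i], condition = cond, band = b,
          value = band_power(fit$freq, fit$flattened_db, sp$bands[[b]]))
      }
    }
  }

  ## --- gait-warped ERSPs ----------------------------------------------
  rest_idx <- unlist(segs[meta$condition == "rest"])
  p2p_rows <- list()
  ersp_maps <- list()
  for (i in seq_along(components)) {
    k <- components[i]
    rest_tf <- morlet_tf(cs$activations[k, rest_idx], cs$fs, sp$freqs,
                         sp$morlet_cycles)
    rest_db <- 10 * log10(pmax(colMeans(rest_tf$power), 1e-20))
    vs_rest <- list()
    for (cond in conds) {
      warped <- list()
      rows <- which(meta$condition == cond)
      for (r in rows) {
        key <- paste(cond, meta$trial[r], sep = ".")
        g <- gait[[key]]
        if (is.null(g)) next
        es <- epoch_walking(cs$activations[, segs[[r]], drop = FALSE], cs$fs,
                            g$events, config$epoching$pre_s,
                            config$epoching$post_s,
                            mask = sub$masks[[r]])
        if (dim(es$data)[1] < 5) next
        es <- reject_epoch_outliers(es, config$epoching$event_k_sd)
        tf <- morlet_tf_epochs(es, k, sp$freqs, sp$morlet_cycles)
        warped[[length(warped) + 1]] <- timewarp_gait(tf, es$latencies, sp$n_grid)
      }
      if (!length(warped)) next
      mm <- ersp_mean_map(warped)
      vs_rest[[cond]] <- ersp_vs_rest(mm, rest_db[seq_len(ncol(mm))])
    }
    ersp_maps[[as.character(k)]] <- vs_rest
  }

  ## sPCA over ERSP observations: rows = (component x gait-time), cols = freq
  ersp_obs <- do.call(rbind, lapply(ersp_maps, function(vs)
    if (length(vs)) Reduce(`+`, vs) / length(vs) else NULL))
  ersp_model <- if (!is.null(ersp_obs) && nrow(ersp_obs) > 1) fit_spca(ersp_obs) else NULL
  for (i in seq_along(components)) {
    k <- components[i]
    vs <- ersp_maps[[as.character(k)]]
    if (!length(vs)) next
    corr <- lapply(vs, function(m)
      if (is.null(ersp_model)) m else apply_spca(ersp_model, m))
    nm <- normalize_ersp(corr, "within-condition")
    for (cond in names(nm)) {
      for (b in names(sp$bands)) {
        p2p_rows[[length(p2p_rows) + 1]] <- data.frame(
          component = k, condition = cond, band = b,
          value = peak_to_peak_fluctuation(nm[[cond]], sp$freqs, sp$bands[[b]]))
      }
    }
  }
  list(band = do.call(rbind, band_rows), p2p = do.call(rbind, p2p_rows),
       freqs = grid[fsel], psd_model = psd_model, ersp_model = ersp_model,
       ersp_maps = ersp_maps)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Simulation (if needed), behavior metrics, per-subject preprocessing + ICA,
#' dipole clustering across subjects, spectral metrics per retained
#' component, and terrain x age mixed models per (cluster, band) for band
#' power and intra-stride fluctuation.
#'
#' @param dataset a `synthetic_dataset` (from [generate_dataset()]); if
#'   `NULL`, one is generated from `config$simulation`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for CSV tables and the manifest.
#' @return list: `behavior`, `behavior_stats`, `components`, `clusters`,
#'   `band_table`, `p2p_table`, `band_stats`, `p2p_stats`, `manifest`.
#' @export
run_all <- function(config = pipeline_config(), dataset = NULL, out_dir = NULL) {
  sim <- config$simulation
  if (is.null(dataset)) {
    cfg <- sim_config(n_young = sim$n_young, n_old = sim$n_old, fs = sim$fs,
                      n_scalp = sim$n_scalp, n_emg = sim$n_emg,
                      trial_duration = sim$trial_duration,
                      n_trials = sim$n_trials,
                      bands = config$spectral$bands, seed = sim$seed)
    dataset <- generate_dataset(cfg, sim$scenario)
  }
  cfg <- dataset$cfg
  rejections <- list()

  ## stage 1: behavior ---------------------------------------------------
  behavior <- behavior_table(dataset, config$behavior$force_threshold_n)
  behavior_stats <- list()
  for (metric in c("step_duration_cov", "sacral_ap_cov", "sacral_ml_cov")) {
    tab <- behavior[behavior$usable, c("subject", "group", "condition", "speed", metric)]
    names(tab)[5] <- "value"
    behavior_stats[[metric]] <- tryCatch(
      lmm_contrasts(tab, config$stats$alpha, config$stats$lmm_outlier_k_sd),
      error = function(e) NULL)
  }

  ## stage 2: preprocessing + ICA per subject ----------------------------
  subs <- list()
  comp_rows <- list()
  for (s in seq_len(nrow(dataset$subjects))) {
    sid <- dataset$subjects$subject[s]
    recs <- Filter(function(r) identical(r$subject, sid), dataset$recordings)
    sub <- preprocess_subject(recs, config)
    subs[[sid]] <- sub
    sc <- sub$cs$scores
    ret <- sc[sc$retained, , drop = FALSE]
    if (nrow(ret)) {
      comp_rows[[sid]] <- data.frame(subject = sid,
                                     group = dataset$subjects$group[s],
                                     component = ret$component,
                                     x = ret$x, y = ret$y, z = ret$z,
                                     brain_score = ret$brain_score)
    }
    rejections[[sid]] <- list(
      components_rejected = sum(!sc$retained),
      window_frac = mean(vapply(sub$masks, mean, 0)))
  }
  components <- do.call(rbind, comp_rows)
  assert_that(!is.null(components) && nrow(components) >= 2,
              "run_all: no retained brain components")

  ## stage 3: clustering --------------------------------------------------
  k_eff <- min(config$clustering$k, nrow(components) - 1,
               length(dataset$truth$sources) %||% config$clustering$k)
  clusters <- cluster_components(components, k = k_eff,
                                 k_sd = config$clustering$outlier_k_sd,
                                 nstart = config$clustering$nstart,
                                 seed = config$clustering$seed,
                                 min_frac = config$clustering$min_frac)

  ## stage 4: spectral metrics per retained (subject, cluster) component -
  band_rows <- list(); p2p_rows <- list()
  for (s in seq_len(nrow(dataset$subjects))) {
    sid <- dataset$subjects$subject[s]
    rows <- which(clusters$components$subject == sid & clusters$kept)
    if (!length(rows)) next
    comp_idx <- clusters$components$component[rows]
    gait_sub <- dataset$gait[grep(paste0("^", sid, "\\."), names(dataset$gait))]
    names(gait_sub) <- sub(paste0("^", sid, "\\."), "", names(gait_sub))
    spec <- tryCatch(subject_spectra(subs[[sid]], gait_sub, config, comp_idx),
                     error = function(e) {
                       warnf("run_all: spectral stage failed for %s (%s)", sid,
                             conditionMessage(e))
                       NULL
                     })
    if (is.null(spec)) next
    decorate <- function(df) {
      if (is.null(df)) return(NULL)
      df$cluster <- clusters$assignment[rows][match(df$component, comp_idx)]
      df$subject <- sid
      df$group <- dataset$subjects$group[s]
      df$speed <- dataset$subjects$speed[s]
      df
    }
    band_rows[[sid]] <- decorate(spec$band)
    p2p_rows[[sid]] <- decorate(spec$p2p)
  }
  band_table <- do.call(rbind, band_rows)
  p2p_table <- do.call(rbind, p2p_rows)

  ## stage 5: mixed models per (cluster, band) ---------------------------
  fit_tables <- function(tab) {
    out <- list()
    if (is.null(tab)) return(out)
    for (cl in sort(unique(tab$cluster))) {
      for (b in unique(tab$band)) {
        d <- tab[tab$cluster == cl & tab$band == b,
                 c("subject", "group", "condition", "speed", "value")]
        if (length(unique(d$subject)) < 4) next
        out[[sprintf("cluster%02d.%s", cl, b)]] <- tryCatch(
          lmm_contrasts(d, config$stats$alpha, config$stats$lmm_outlier_k_sd),
          error = function(e) NULL)
      }
    }
    out
  }
  band_stats <- fit_tables(band_table)
  p2p_stats <- fit_tables(p2p_table)

  ## manifest + outputs ---------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = checksum32(as.character(cfg_json)),
    package_version = as.character(utils::packageVersion("gaitersp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    rejections = rejections,
    outputs = list())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (is.null(df)) return(NULL)
      p <- file.path(out_dir, name)
      write.csv(df, p, row.names = FALSE)
      manifest$outputs[[name]] <<- checksum32(readLines(p))
    }
    wr(behavior, "behavior.csv")
    wr(band_table, "band_power.csv")
    wr(p2p_table, "p2p_fluctuation.csv")
    wr(components, "components.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(behavior = behavior, behavior_stats = behavior_stats,
       components = components, clusters = clusters,
       band_table = band_table, p2p_table = p2p_table,
       band_stats = band_stats, p2p_stats = p2p_stats, manifest = manifest)
}
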