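test_that("degenerate stride variance yields identical stride durations", {
  g <- simulate_gait(gait_spec(stride_mean = 1.2, stride_cv = 0), 20, fs = 100,
                     seed = 1)
  expect_true(all(abs(g$stride_durations - 1.2) < 1e-12))
})

test_that("generated stride durations have the requested CV", {
  g <- simulate_gait(gait_spec(stride_mean = 1.2, stride_cv = 0.05), 250,
                     fs = 100, seed = 2)
  expect_gte(length(g$stride_durations), 180)
  cv <- sd(g$stride_durations) / mean(g$stride_durations)
  expect_lt(abs(cv - 0.05), 0.015)
})

test_that("gait event detection round-trips the generated forces within one sample", {
  for (seed in 1:3) {
    g <- simulate_gait(gait_spec(stride_mean = 1.2, stride_cv = 0.05), 60,
                       fs = 500, seed = seed)
    ev <- detect_gait_events(g$force_left, g$force_right)
    expect_equal(nrow(ev), nrow(g$events))
    err <- abs(as.matrix(ev[, -1]) - as.matrix(g$events[, -1])) * 500
    expect_lte(max(err), 1 + 1e-9)
  }
})

test_that("non-positive stride mean is rejected", {
  expect_error(gait_spec(stride_mean = -1), "positive")
})

test_that("recordings are bit-identical under the same seed", {
  cfg <- sim_config(n_young = 1, n_old = 0, fs = 250, n_scalp = 8, n_emg = 2,
                    trial_duration = 10)
  src <- scenario_sources("null", cfg)[1:2]
  g <- simulate_gait(default_gait_spec(), 10, 250, seed = 5)
  r1 <- simulate_recording(src, g, cfg, "Flat", "young", seed = 7)
  r2 <- simulate_recording(src, g, cfg, "Flat", "young", seed = 7)
  expect_identical(r1$data, r2$data)
})

test_that("an unknown condition label is rejected", {
  cfg <- sim_config(n_young = 1, n_old = 0, fs = 250, n_scalp = 8,
                    trial_duration = 10)
  src <- scenario_sources("null", cfg)[1]
  expect_error(simulate_recording(src, NULL, cfg, "Steep", seed = 1),
               "unknown condition")
})

test_that("the aperiodic exponent of a clean source is recovered within 0.1", {
  sp <- source_spec(c(0, -62, 25), aperiodic_exponent = 1.5,
                    peaks = list(c(10, 0.5, 1.3)), burst = 0)
  err <- vapply(1:4, function(seed) {
    sim <- simulate_source(sp, 60, 250, test_bands, seed = seed)
    ps <- welch_psd(sim$signal, 250)
    fit_spectral_model(ps$freq, ps$db)$exponent - 1.5
  }, 0)
  expect_lt(abs(mean(err)), 0.1)
})

test_that("an injected alpha condition shift appears in oracle Welch band power", {
  cs <- zero_shift()
  cs["alpha", "High", ] <- -2
  sp <- source_spec(c(0, -62, 25), peaks = list(c(10, 0.6, 1.3)),
                    condition_shift = cs, burst = 0)
  d <- vapply(1:5, function(seed) {
    f <- simulate_source(sp, 120, 250, test_bands, "Flat", "young", seed = seed)
    h <- simulate_source(sp, 120, 250, test_bands, "High", "young", seed = seed + 50)
    pf <- welch_psd(f$signal, 250)
    ph <- welch_psd(h$signal, 250)
    sel <- pf$freq >= 8 & pf$freq <= 13
    mean(ph$db[sel] - pf$db[sel])
  }, 0)
  expect_lt(abs(mean(d) - (-2)), 0.3)
})

test_that("doubling a condition shift doubles the oracle band-power difference", {
  measure <- function(shift) {
    cs <- zero_shift()
    cs["alpha", "High", ] <- shift
    sp <- source_spec(c(0, -62, 25), peaks = list(c(10, 0.6, 1.3)),
                      condition_shift = cs, burst = 0)
    mean(vapply(1:4, function(seed) {
      f <- simulate_source(sp, 90, 250, test_bands, "Flat", "young", seed = seed)
      h <- simulate_source(sp, 90, 250, test_bands, "High", "young", seed = seed + 50)
      pf <- welch_psd(f$signal, 250)
      ph <- welch_psd(h$signal, 250)
      sel <- pf$freq >= 9 & pf$freq <= 12
      mean(ph$db[sel] - pf$db[sel])
    }, 0))
  }
  d2 <- measure(-2)
  d4 <- measure(-4)
  expect_lt(abs(d4 / d2 - 2), 0.25)
})

test_that("the paper-like scenario has a young-only occipital alpha reduction", {
  cfg <- sim_config()
  occ <- scenario_sources("paper-like", cfg)$occipital
  young <- occ$condition_shift["alpha", "High", "young"] -
    occ$condition_shift["alpha", "Flat", "young"]
  old <- occ$condition_shift["alpha", "High", "old"] -
    occ$condition_shift["alpha", "Flat", "old"]
  expect_lt(young, 0)
  expect_lt(abs(old), 0.5)
  expect_lt(young, old)
})

test_that("gait modulation profiles are zero-mean over the stride", {
  cfg <- sim_config()
  src <- scenario_sources("paper-like", cfg)$sensorimotor_l
  ph <- seq(0, 1, length.out = 1000)[-1000]
  g <- gaitersp:::gait_mod_db(src, "beta", ph, "Flat", "young")
  expect_lt(abs(mean(g)), 1e-10)
  expect_gt(max(g) - min(g), 2.9)
})

test_that("generate_dataset returns a consistent desk-scale dataset", {
  cfg <- sim_config(n_young = 2, n_old = 2, fs = 250, n_scalp = 12, n_emg = 2,
                    trial_duration = 15, n_trials = 1, seed = 3)
  ds <- generate_dataset(cfg, "paper-like")
  expect_s3_class(ds, "synthetic_dataset")
  ## one rest + 4 walking recordings per subject
  expect_length(ds$recordings, 4 * 5)
  ## truth events inside the recording; full-column-rank mixing
  for (rec in ds$recordings[2:3]) {
    if (!is.null(rec$truth$events)) {
      expect_lte(max(rec$truth$events$t_RFS_next), 15)
      expect_gte(min(rec$truth$events$t_RFS), 0)
    }
    expect_equal(qr(rec$truth$mixing)$rank, ncol(rec$truth$mixing))
  }
  ## determinism at dataset level
  ds2 <- generate_dataset(cfg, "paper-like")
  expect_identical(ds$recordings[[2]]$data, ds2$recordings[[2]]$data)
})
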