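test_that("no threshold crossings give an empty event table", {
  z <- force_trace(rep(0, 1000), 100, "left")
  z2 <- force_trace(rep(0, 1000), 100, "right")
  ev <- detect_gait_events(z, z2)
  expect_s3_class(ev, "gait_events")
  expect_equal(nrow(ev), 0)
})

test_that("a force ramp crosses the threshold at the first sample at or above it", {
  fs <- 100
  ramp <- seq(0, 40, length.out = 2 * fs + 1)   # 20 N reached at t = 1.00 s
  cr <- gaitersp:::threshold_crossings(ramp, fs, 20)
  expect_equal((cr$up - 1) / fs, 1.00)
})

test_that("detected events equal the linear-scan crossing oracle", {
  g <- simulate_gait(gait_spec(stride_mean = 1.1, stride_cv = 0.04), 30,
                     fs = 200, seed = 9)
  ev <- detect_gait_events(g$force_left, g$force_right)
  oR <- oracle_crossings(g$force_right$samples, 200)
  oL <- oracle_crossings(g$force_left$samples, 200)
  expect_true(all(ev$t_RFS %in% oR$up))
  expect_true(all(ev$t_RFO %in% oR$down))
  expect_true(all(ev$t_LFS %in% oL$up))
  expect_true(all(ev$t_LFO %in% oL$down))
})

test_that("mismatched trace durations are rejected", {
  a <- force_trace(rep(0, 100), 100, "left")
  b <- force_trace(rep(0, 50), 100, "right")
  expect_error(detect_gait_events(a, b), "matching duration")
})

test_that("the outlier rule keeps constant data and drops a single extreme value", {
  expect_equal(remove_outliers(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  x <- c(rep(0, 9), 100)          # z of 100 is 2.85 with sample sd ~31.6
  expect_equal(remove_outliers(x), rep(0, 9))
  expect_equal(formals(remove_outliers)$k_sd, 2.5)
})

test_that("coefficient of variation matches hand computations and is scale invariant", {
  expect_equal(coefficient_of_variation(c(7, 7, 7)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  x <- rlnorm(20)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("sacral excursion is the per-stride range", {
  ev <- data.frame(stride = 1:2, t_RFS = c(0, 1), t_LFO = c(0.1, 1.1),
                   t_LFS = c(0.5, 1.5), t_RFO = c(0.6, 1.6),
                   t_RFS_next = c(1, 2))
  expect_equal(sacral_excursion(rep(3, 220), ev, 100), c(0, 0))
  t <- (0:219) / 100
  expect_equal(sacral_excursion(2.5 * sin(2 * pi * t), ev, 100), c(5, 5),
               tolerance = 1e-6)
})

test_that("recovered excursion CV matches the generating CV", {
  g <- simulate_gait(gait_spec(stride_mean = 1.0, stride_cv = 0.02,
                               sacral_ml_cv = 0.15), 220, fs = 100, seed = 4)
  ex <- sacral_excursion(g$sacral_ml, g$events, 100)
  expect_gte(length(ex), 190)
  expect_lt(abs(coefficient_of_variation(ex) - 0.15), 0.02)
})

test_that("recovered step-duration CoV is unbiased across variability levels", {
  for (cv in c(0.02, 0.05, 0.10)) {
    est <- vapply(1:60, function(seed) {
      g <- simulate_gait(gait_spec(stride_mean = 1.1, stride_cv = cv), 60,
                         fs = 100, seed = 7000 + seed)
      ev <- detect_gait_events(g$force_left, g$force_right)
      steps <- remove_outliers(gaitersp:::step_durations(ev))
      coefficient_of_variation(steps)
    }, 0)
    expect_lt(abs(mean(est) - cv), 0.01)
  }
})

test_that("behavior summaries flag sparse cells and recover terrain-graded variability", {
  ## unusable cell: fewer than 5 strides
  g <- simulate_gait(gait_spec(), 5, fs = 100, seed = 1)
  ev <- detect_gait_events(g$force_left, g$force_right)
  sm <- behavior_summary(list(list(events = ev, sacral_ap = g$sacral_ap,
                                   sacral_ml = g$sacral_ml, fs = 100)))
  expect_false(sm$usable)

  ## monotone increase of step-duration CoV with terrain
  cfg <- sim_config(n_young = 1, n_old = 0, fs = 100, n_scalp = 4, n_emg = 1,
                    trial_duration = 120, n_trials = 2, line_freqs = c(30),
                    bands = list(alpha = c(8, 13)), seed = 11)
  ds <- list(cfg = cfg,
             subjects = data.frame(subject = "S01", group = "young", speed = 0.7),
             gait = list())
  for (cond in cfg$conditions) {
    for (tr in 1:2) {
      ds$gait[[paste("S01", cond, tr, sep = ".")]] <-
        simulate_gait(default_gait_spec(cond, "young"), 120, 100,
                      seed = 100 + tr + 10 * match(cond, cfg$conditions))
    }
  }
  class(ds) <- "synthetic_dataset"
  bt <- behavior_table(ds)
  covs <- bt$step_duration_cov[match(cfg$conditions, bt$condition)]
  expect_true(all(diff(covs) > 0))
})
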