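test_that("the dipole fit round-trips the forward model", {
  mont <- spherical_montage(32)
  truth <- c(0, -62, 25)
  map <- dipole_forward(truth, c(0.6, 0.2, 0.77), mont)
  fd <- fit_dipole(map, mont)
  expect_lt(sqrt(sum((fd$location - truth)^2)), 5)
  expect_lt(fd$rv, 0.01)

  fd2 <- fit_dipole(4.2 * map, mont)
  expect_equal(fd2$location, fd$location)
  expect_equal(fd2$rv, fd$rv)
})

test_that("white-noise maps fit poorly", {
  mont <- spherical_montage(32)
  rvs <- vapply(1:6, function(s) {
    set.seed(s)
    fit_dipole(rnorm(32), mont)$rv
  }, 0)
  expect_gt(mean(rvs), 0.5)
})

test_that("component scoring retains dipolar 1/f components and rejects muscle", {
  set.seed(20)
  fs <- 250
  n <- fs * 40
  mont <- spherical_montage(16)
  brain_map <- dipole_forward(c(0, -62, 25), c(0, -0.6, 0.8), mont)
  emg_map <- rnorm(16)
  brain_sig <- simulate_source(source_spec(c(0, -62, 25),
                                           peaks = list(c(10, 0.6, 1.3))),
                               n / fs, fs)$signal
  emg_sig <- gaitersp:::emg_signal(n, fs)
  cs <- structure(list(
    unmixing = diag(2), mixing = cbind(brain_map, emg_map),
    activations = rbind(brain_sig, emg_sig),
    scalp_idx = 1:16, fs = fs, positions = mont), class = "component_set")
  cs <- score_components(cs)
  expect_true(cs$scores$retained[1])
  expect_false(cs$scores$retained[2])
  expect_gt(cs$scores$psd_slope_2_40[2], 0)   # rising muscle spectrum
  expect_lt(cs$scores$psd_slope_2_40[1], 0)
})

test_that("a map from a dipole at 1.2 times the head radius is rejected", {
  mont <- spherical_montage(32)
  far_map <- dipole_forward(c(0, -93, 60), c(0, -0.8, 0.6), mont)
  fd <- fit_dipole(far_map, mont)
  expect_gt(sqrt(sum(fd$location^2)), 90)
  set.seed(1)
  cs <- structure(list(
    unmixing = diag(1), mixing = cbind(far_map),
    activations = matrix(simulate_source(source_spec(c(0, -62, 25)), 30, 250)$signal, 1),
    scalp_idx = 1:32, fs = 250, positions = mont), class = "component_set")
  cs <- score_components(cs)
  expect_false(cs$scores$retained[1])
  expect_match(cs$scores$reason[1], "outside head")
})

test_that("k-means clustering recovers well-separated blobs and applies the rules", {
  set.seed(21)
  k <- 5
  centers <- matrix(rnorm(k * 3, 0, 40), k)
  n_per <- 12
  truth_lab <- rep(seq_len(k), each = n_per)
  xyz <- centers[truth_lab, ] + matrix(rnorm(k * n_per * 3, 0, 2), k * n_per)
  comps <- data.frame(
    subject = sprintf("S%02d", rep(1:6, length.out = k * n_per)),
    group = rep(c("young", "old"), length.out = k * n_per),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    brain_score = runif(k * n_per, 0.5, 1))
  cm <- cluster_components(comps, k = k, seed = 2)
  ## adjusted agreement: every true blob maps to a single k-means label
  agree <- mean(vapply(seq_len(k), function(b) {
    lab <- cm$assignment[truth_lab == b]
    max(table(lab)) / length(lab)
  }, 0))
  expect_gt(agree, 0.95)

  ## a component far from every centroid is an outlier
  comps2 <- rbind(comps, data.frame(subject = "S01", group = "young",
                                    x = 500, y = 500, z = 500, brain_score = 0.9))
  cm2 <- cluster_components(comps2, k = k, seed = 2)
  expect_true(cm2$outlier[nrow(comps2)])

  ## one component per (subject, cluster): the higher brain score wins
  dup <- comps[1, ]
  dup$brain_score <- comps$brain_score[1] + 0.05
  dup$x <- dup$x + 0.5
  comps3 <- rbind(comps, dup)
  cm3 <- cluster_components(comps3, k = k, seed = 2)
  same <- which(comps3$subject == dup$subject &
                  cm3$assignment == cm3$assignment[nrow(comps3)])
  expect_equal(sum(cm3$kept[same]), 1)
  expect_true(cm3$kept[nrow(comps3)])
  expect_error(cluster_components(comps[1:3, ], k = 5), "exceeds")
})

test_that("cluster-count diagnostics cover the requested range", {
  set.seed(22)
  xyz <- matrix(rnorm(90, 0, 30), 30)
  d <- evaluate_cluster_counts(xyz, k_range = 3:5)
  expect_equal(d$k, 3:5)
  expect_true(all(is.finite(d$calinski_harabasz)))
  expect_true(all(d$silhouette >= -1 & d$silhouette <= 1))
})
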