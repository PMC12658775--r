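test_that("BH adjustment matches p.adjust and keeps step-up monotonicity", {
  set.seed(50)
  for (r in 1:5) {
    p <- runif(200)^(r / 2)
    f <- fdr_bh(p)
    expect_equal(f$p_adjusted, p.adjust(p, "BH"))
    o <- order(p)
    expect_true(all(diff(f$p_adjusted[o]) >= -1e-12))
    expect_true(all(f$p_adjusted >= p - 1e-12))
  }
  expect_true(all(fdr_bh(rep(0.001, 100))$mask))
})

test_that("BH keeps the false-discovery proportion at the nominal level on nulls", {
  set.seed(51)
  fdp <- vapply(1:200, function(r) {
    f <- fdr_bh(runif(1000))
    as.numeric(any(f$mask))          # all nulls: FDP is 1 if anything is flagged
  }, 0)
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("bootstrap ERSP masking controls the flagged fraction on null maps", {
  set.seed(52)
  fr <- vapply(1:8, function(r) {
    E <- array(rnorm(40 * 50 * 12), c(40, 50, 12))
    mean(bootstrap_ersp_mask(E, n_boot = 200, seed = r)$mask)
  }, 0)
  expect_lte(mean(fr), 0.05 + 2 * sqrt(0.05 / (8 * 600)))
})

test_that("bootstrap ERSP masking detects a strong injected modulation", {
  set.seed(53)
  E <- array(rnorm(40 * 50 * 12), c(40, 50, 12))
  mod <- 10 * sin(2 * pi * (1:50) / 50)
  E[, , 5] <- E[, , 5] + rep(mod, each = 40)
  m <- bootstrap_ersp_mask(E, n_boot = 400, seed = 3)
  expect_gt(mean(m$mask[abs(mod) > 5, 5]), 0.95)
  expect_lt(mean(m$mask[, -5]), 0.05)
  expect_gte(min(m$p), 1 / 401)      # observed statistic included in the null
})

test_that("the permutation PSD test holds its type-I rate under label exchange", {
  set.seed(54)
  rates <- vapply(1:20, function(r) {
    psd <- matrix(rnorm(20 * 30), 20)
    res <- permutation_psd_test(psd, rep(c("A", "B"), each = 10),
                                subjects = paste0("s", 1:20), n_perm = 200,
                                correct = FALSE, seed = r)
    mean(res$p <= 0.05)
  }, 0)
  rate <- mean(rates)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / (20 * 30)))
})

test_that("the permutation PSD test localizes a band-confined group effect", {
  set.seed(55)
  freqs <- 3:40
  psd <- matrix(rnorm(20 * length(freqs), 0, 0.3), 20)
  beta <- freqs >= 13 & freqs <= 30
  psd[1:10, beta] <- psd[1:10, beta] + 3
  res <- permutation_psd_test(psd, rep(c("young", "old"), each = 10),
                              subjects = paste0("s", 1:20), n_perm = 500, seed = 2)
  expect_true(all(res$mask[beta]))
  outside <- freqs < 11 | freqs > 32    # >= 2 Hz from the band edges
  expect_false(any(res$mask[outside]))
})

test_that("within-subject terrain permutations respect exchangeability blocks", {
  set.seed(56)
  n_sub <- 12
  conds <- c("Flat", "Low", "Med", "High")
  psd <- matrix(rnorm(n_sub * 4 * 20), n_sub * 4)
  subj <- rep(paste0("s", 1:n_sub), each = 4)
  labs <- rep(conds, n_sub)
  res <- permutation_psd_test(psd, labs, subj, n_perm = 300, correct = FALSE, seed = 3)
  expect_lte(mean(res$p <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

test_that("cluster-based permutation controls family-wise error and finds blocks", {
  set.seed(57)
  any_sig <- vapply(1:15, function(r) {
    A <- array(rnorm(8 * 20 * 10), c(8, 20, 10))
    B <- array(rnorm(8 * 20 * 10), c(8, 20, 10))
    cp <- cluster_permutation_tf(A, B, n_perm = 150, seed = r)
    as.numeric(any(cp$mask))
  }, 0)
  expect_lte(mean(any_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / 15))

  A <- array(rnorm(10 * 40 * 12), c(10, 40, 12))
  B <- array(rnorm(10 * 40 * 12), c(10, 40, 12))
  A[, 10:20, 4:6] <- A[, 10:20, 4:6] + 8
  cp <- cluster_permutation_tf(A, B, n_perm = 300, seed = 2)
  expect_gt(mean(cp$mask[10:20, 4:6]), 0.95)
  expect_lt(mean(cp$mask[30:40, 8:12]), 0.05)
})

make_lmm_table <- function(effect = TRUE, n = 12, sigma = 0.5, seed = 1) {
  set.seed(seed)
  conds <- c("Flat", "Low", "Med", "High")
  d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)), condition = conds,
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n, "young", "old")
  d$speed <- ifelse(d$group == "young", 0.7, 0.35) + rnorm(nrow(d), 0, 0.02)
  u <- rnorm(2 * n, 0, 0.3)
  names(u) <- sprintf("s%02d", 1:(2 * n))
  eff <- if (effect) ifelse(d$group == "young",
                            c(0, -0.7, -1.3, -2)[match(d$condition, conds)], 0) else 0
  d$value <- u[d$subject] + eff + rnorm(nrow(d), 0, sigma)
  d
}

test_that("mixed-model contrasts detect a young-only terrain effect with high power", {
  hits <- vapply(1:25, function(r) {
    res <- lmm_contrasts(make_lmm_table(TRUE, n = 15, seed = 100 + r))
    as.numeric(res$model_variant == "with-interaction")
  }, 0)
  expect_gt(mean(hits), 0.8)
  ## effect sizes and pairwise output have the documented structure
  res <- lmm_contrasts(make_lmm_table(TRUE, n = 15, seed = 1))
  expect_true(all(res$anova$partial_eta_sq >= 0 & res$anova$partial_eta_sq <= 1))
  expect_true(all(res$pairwise$condition$p_fdr >= res$pairwise$condition$p.value - 1e-12))
})

test_that("mixed-model contrasts hold the nominal interaction rate on null data", {
  hits <- vapply(1:60, function(r) {
    res <- lmm_contrasts(make_lmm_table(FALSE, n = 10, seed = 300 + r))
    as.numeric(res$model_variant == "with-interaction")
  }, 0)
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("extreme outliers are excluded before model fitting", {
  ## the z of a single outlier saturates near sqrt(n), so the 8 SD rule needs
  ## enough observations to be able to fire at all
  d <- make_lmm_table(FALSE, n = 15, seed = 5)
  d$value[3] <- d$value[3] + 100    # ~11 SD with the outlier included
  res <- lmm_contrasts(d)
  expect_equal(res$n_excluded, 1)
})
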