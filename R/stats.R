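## Resampling significance masking, FDR control, and terrain x age mixed
## models. Permutation and bootstrap p-values always include the observed
## statistic in the null (p >= 1 / (n_iter + 1)).

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p_(i) * m / i` with a cumulative minimum taken
#' from the largest p downwards, capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and `mask` (`p_adjusted <= q`).
#' @export
fdr_bh <- function(p, q = 0.05) {
  assert_that(all(p >= 0 & p <= 1), "fdr_bh: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  list(p_adjusted = adj, mask = adj <= q)
}

#' Bootstrap significance mask for within-condition ERSP maps
#'
#' Tests, per gait-percentage x frequency bin, whether power deviates from the
#' gait-cycle mean. Epoch maps are first demeaned along the gait axis per
#' frequency; the observed statistic is the across-epoch mean deviation. The
#' null is built by resampling epochs with replacement and shuffling the
#' gait-axis bins (baseline-shuffled null: under no gait-phase structure the
#' bins are exchangeable). Two-sided bin p-values are corrected by
#' Benjamini-Hochberg across the whole grid.
#'
#' @param ersp an `ersp_epochs` object (epochs x grid x freq dB) or a bare
#'   3-d array.
#' @param alpha significance level (default 0.05).
#' @param n_boot bootstrap iterations (paper default 4000; reducible).
#' @param seed RNG seed.
#' @return object of class `sig_mask`: `mask`, `p`, `p_adjusted` (grid x
#'   freq), `statistic` (mean deviation map, dB), `method`, `n_iterations`,
#'   `alpha`, `correction`.
#' @export
bootstrap_ersp_mask <- function(ersp, alpha = 0.05, n_boot = 4000, seed = 1L) {
  E <- if (inherits(ersp, "ersp_epochs")) ersp$db else ersp
  assert_that(length(dim(E)) == 3, "bootstrap_ersp_mask: need epochs x grid x freq")
  n_ep <- dim(E)[1]
  assert_that(n_ep >= 20, "bootstrap_ersp_mask: needs >= 20 epochs")
  set.seed(seed)
  n_t <- dim(E)[2]
  n_f <- dim(E)[3]
  ## demean each epoch along the gait axis per frequency
  mu <- apply(E, c(1, 3), mean)
  Ec <- E - aperm(array(mu, c(n_ep, n_f, n_t)), c(1, 3, 2))
  M <- matrix(Ec, n_ep, n_t * n_f)         # epochs x bins
  obs <- colMeans(M)
  exceed <- numeric(n_t * n_f)
  aobs <- abs(obs)
  col0 <- (seq_len(n_f) - 1) * n_t
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_ep, n_ep, replace = TRUE)
    acc <- numeric(n_t * n_f)
    for (e in idx) {
      ## independent gait-axis shuffle per resampled epoch breaks any
      ## coherent gait-phase structure while preserving per-epoch spectra
      perm <- sample.int(n_t)
      acc <- acc + M[e, rep(col0, each = n_t) + perm]
    }
    exceed <- exceed + (abs(acc / n_ep) >= aobs)
  }
  p <- (1 + exceed) / (n_boot + 1)
  fdr <- fdr_bh(p, alpha)
  structure(list(mask = matrix(fdr$mask, n_t, n_f),
                 p = matrix(p, n_t, n_f),
                 p_adjusted = matrix(fdr$p_adjusted, n_t, n_f),
                 statistic = matrix(obs, n_t, n_f),
                 method = "bootstrap", n_iterations = n_boot,
                 alpha = alpha, correction = "fdr"),
            class = "sig_mask")
}

## one-way F statistic per column of Y for grouping g (levels >= 2)
fstat_cols <- function(Y, g) {
  g <- as.factor(g)
  n <- nrow(Y)
  k <- nlevels(g)
  gm <- colMeans(Y)
  ssb <- numeric(ncol(Y))
  ssw <- numeric(ncol(Y))
  for (lev in levels(g)) {
    Yl <- Y[g == lev, , drop = FALSE]
    ml <- colMeans(Yl)
    ssb <- ssb + nrow(Yl) * (ml - gm)^2
    ssw <- ssw + colSums(sweep(Yl, 2, ml)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Nonparametric permutation test on flattened PSDs
#'
#' Per-frequency F statistic for a terrain or age factor with a permutation
#' null: for a between-subject factor (age) group labels are permuted across
#' subjects; for a within-subject factor (terrain) condition labels are
#' permuted within each subject (the exchangeability blocks). Main effects
#' only. Raw p-values are optionally corrected by Benjamini-Hochberg across
#' frequency.
#'
#' @param psd matrix of flattened PSDs, one row per (subject, condition)
#'   observation, columns = frequencies.
#' @param labels factor of interest, one entry per row.
#' @param subjects subject id per row (defines exchangeability blocks; if the
#'   factor is constant within subject it is treated as between-subject).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations (paper default 2000; reducible).
#' @param correct apply FDR across frequency (default TRUE).
#' @param seed RNG seed.
#' @return `sig_mask` over frequency: `mask`, `p`, `p_adjusted`, `statistic`.
#' @export
permutation_psd_test <- function(psd, labels, subjects, alpha = 0.05,
                                 n_perm = 2000, correct = TRUE, seed = 1L) {
  psd <- as.matrix(psd)
  labels <- as.factor(labels)
  assert_that(nlevels(labels) >= 2, "permutation_psd_test: factor needs >= 2 levels")
  ## drop subjects with unbalanced condition sets
  tab <- table(subjects)
  full <- names(tab)[tab == max(tab)]
  if (length(full) < length(tab)) {
    ger_log("permutation_psd_test: dropped %d unbalanced subject(s)",
            length(tab) - length(full))
    keep <- subjects %in% full
    psd <- psd[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
    subjects <- subjects[keep]
  }
  set.seed(seed)
  between <- all(vapply(split(as.character(labels), subjects),
                        function(l) length(unique(l)) == 1, logical(1)))
  obs <- fstat_cols(psd, labels)
  count <- numeric(length(obs))
  sub_levels <- unique(subjects)
  for (b in seq_len(n_perm)) {
    if (between) {
      ## permute subject-level labels
      sub_lab <- vapply(sub_levels, function(s)
        as.character(labels[subjects == s][1]), character(1))
      new_sub <- sample(sub_lab)
      perm_lab <- new_sub[match(subjects, sub_levels)]
    } else {
      perm_lab <- as.character(labels)
      for (s in sub_levels) {
        i <- which(subjects == s)
        perm_lab[i] <- sample(perm_lab[i])
      }
    }
    count <- count + (fstat_cols(psd, perm_lab) >= obs)
  }
  p <- (1 + count) / (n_perm + 1)
  fdr <- fdr_bh(p, alpha)
  structure(list(mask = if (correct) fdr$mask else p <= alpha,
                 p = p, p_adjusted = fdr$p_adjusted, statistic = obs,
                 method = "permutation", n_iterations = n_perm,
                 alpha = alpha, correction = if (correct) "fdr" else "none"),
            class = "sig_mask")
}

## 4-connected components of a logical matrix; returns integer labels
label_clusters <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- v[1] + d[1]; jj <- v[2] + d[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

## two-sample t per bin for arrays units x t x f
tstat_bins <- function(A, B) {
  na <- dim(A)[1]; nb <- dim(B)[1]
  ma <- apply(A, c(2, 3), mean); mb <- apply(B, c(2, 3), mean)
  va <- apply(A, c(2, 3), var); vb <- apply(B, c(2, 3), var)
  sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp * (1 / na + 1 / nb) + 1e-24)
}

#' Cluster-based permutation test on time-frequency maps
#'
#' Two-sample comparison of per-unit (subject) gait-grid x frequency maps.
#' Bin-level t statistics are thresholded at the two-sided bin-level alpha;
#' contiguous supra-threshold clusters (4-connectivity, positive and negative
#' separately) are scored by their summed t; the null distribution of the
#' maximum cluster score is built by permuting unit labels (Monte Carlo).
#'
#' @param maps_a,maps_b arrays units x grid x freq (dB), e.g. young vs old
#'   terrain-difference maps.
#' @param alpha cluster significance level and bin-forming level (0.05).
#' @param n_perm permutations (paper default 10000; reducible).
#' @param seed RNG seed.
#' @return `sig_mask` with `mask` (grid x freq), `clusters` (data.frame id,
#'   score, p), `statistic` (t map).
#' @export
cluster_permutation_tf <- function(maps_a, maps_b, alpha = 0.05,
                                   n_perm = 10000, seed = 1L) {
  na <- dim(maps_a)[1]; nb <- dim(maps_b)[1]
  set.seed(seed)
  tcrit <- qt(1 - alpha / 2, na + nb - 2)
  find_clusters <- function(tmap) {
    out <- list()
    for (sgn in c(1, -1)) {
      lab <- label_clusters(sgn * tmap > tcrit)
      for (c in seq_len(max(lab))) {
        out[[length(out) + 1]] <- list(cells = lab == c,
                                       score = sum(tmap[lab == c]))
      }
    }
    out
  }
  t_obs <- tstat_bins(maps_a, maps_b)
  obs_cl <- find_clusters(t_obs)
  all_maps <- array(NA_real_, c(na + nb, dim(maps_a)[2], dim(maps_a)[3]))
  all_maps[seq_len(na), , ] <- maps_a
  all_maps[na + seq_len(nb), , ] <- maps_b
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(na + nb)
    tp <- tstat_bins(all_maps[idx[seq_len(na)], , , drop = FALSE],
                     all_maps[idx[na + seq_len(nb)], , , drop = FALSE])
    cl <- find_clusters(tp)
    max_null[b] <- if (length(cl)) max(vapply(cl, function(x) abs(x$score), 0)) else 0
  }
  mask <- matrix(FALSE, dim(maps_a)[2], dim(maps_a)[3])
  cl_df <- data.frame(id = integer(), score = numeric(), p = numeric())
  for (i in seq_along(obs_cl)) {
    p <- (1 + sum(max_null >= abs(obs_cl[[i]]$score))) / (n_perm + 1)
    cl_df <- rbind(cl_df, data.frame(id = i, score = obs_cl[[i]]$score, p = p))
    if (p <= alpha) mask[obs_cl[[i]]$cells] <- TRUE
  }
  structure(list(mask = mask, clusters = cl_df, statistic = t_obs,
                 p = cl_df$p, method = "cluster-permutation",
                 n_iterations = n_perm, alpha = alpha, correction = "cluster"),
            class = "sig_mask")
}

#' Terrain x age linear mixed-model contrasts
#'
#' Fits `value ~ condition * group + speed + (1 | subject)` after excluding
#' values more than `k_sd` (default 8) SD from the mean. F tests use
#' Satterthwaite degrees of freedom; partial eta-squared is computed from the
#' F statistic and its degrees of freedom. If the interaction is not
#' significant at `alpha` the model is refit without it. Pairwise terrain and
#' group contrasts (estimated marginal means) are FDR adjusted.
#'
#' @param table data.frame with columns `subject`, `group`, `condition`,
#'   `speed`, `value`.
#' @param alpha significance level (default 0.05).
#' @param k_sd outlier exclusion threshold in SD (default 8).
#' @return object of class `contrast_result`: `anova` (term, F, df1, df2, p,
#'   partial_eta_sq), `pairwise` (FDR-adjusted), `model_variant`, `n_excluded`.
#' @export
lmm_contrasts <- function(table, alpha = 0.05, k_sd = 8) {
  req <- c("subject", "group", "condition", "speed", "value")
  assert_that(all(req %in% names(table)),
              "lmm_contrasts: table needs columns %s", paste(req, collapse = ", "))
  v <- table$value
  keep <- is.finite(v) & abs(v - mean(v, na.rm = TRUE)) <= k_sd * sd(v, na.rm = TRUE)
  n_excl <- sum(!keep)
  if (n_excl) ger_log("lmm_contrasts: excluded %d outlier value(s) (> %g SD)",
                      n_excl, k_sd)
  d <- table[keep, , drop = FALSE]
  d$condition <- factor(d$condition, levels = unique(table$condition))
  d$group <- factor(d$group)
  d$subject <- factor(d$subject)

  fit_model <- function(formula) {
    tryCatch(
      lmerTest::lmer(formula, data = d,
                     control = lme4::lmerControl(check.conv.singular =
                                                   lme4::.makeCC(action = "ignore", tol = 1e-4))),
      error = function(e) {
        warnf("lmm_contrasts: mixed fit failed (%s); refitting with lm", conditionMessage(e))
        NULL
      })
  }
  anova_table <- function(m) {
    a <- anova(m, type = 3)
    F <- a[["F value"]]
    df1 <- a[["NumDF"]]
    df2 <- a[["DenDF"]]
    data.frame(term = rownames(a), F = F, df1 = df1, df2 = df2,
               p = a[["Pr(>F)"]],
               partial_eta_sq = pmin(1, pmax(0, F * df1 / (F * df1 + df2))))
  }

  m <- fit_model(value ~ condition * group + speed + (1 | subject))
  assert_that(!is.null(m), "lmm_contrasts: model could not be fit")
  a <- anova_table(m)
  inter_p <- a$p[grepl(":", a$term)]
  variant <- "with-interaction"
  if (length(inter_p) && (is.na(inter_p) || inter_p >= alpha)) {
    m <- fit_model(value ~ condition + group + speed + (1 | subject))
    a <- anova_table(m)
    variant <- "refit-no-interaction"
  }

  ## pairwise contrasts: terrain (within group if interaction retained) + group
  pw <- list()
  spec <- if (variant == "with-interaction") ~ condition | group else ~ condition
  em <- suppressMessages(emmeans::emmeans(m, spec))
  ct <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                              adjust = "none"))
  ct$p_fdr <- fdr_bh(ct$p.value)$p_adjusted
  pw$condition <- ct
  if (nlevels(d$group) >= 2) {
    emg <- suppressMessages(emmeans::emmeans(m, ~ group))
    cg <- as.data.frame(summary(emmeans::contrast(emg, method = "pairwise"),
                                adjust = "none"))
    cg$p_fdr <- fdr_bh(cg$p.value)$p_adjusted
    pw$group <- cg
  }
  structure(list(anova = a, pairwise = pw, model_variant = variant,
                 n_excluded = n_excl, model = m),
            class = "contrast_result")
}
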