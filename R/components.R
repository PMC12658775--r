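## Component retention scoring and k-means dipole clustering.

#' Score and select brain components
#'
#' Fits an equivalent dipole to each component's scalp map, computes the PSD
#' slope over 2-40 Hz from the component activation, and a transparent
#' heuristic `brain_score` in `[0, 1]` built from three equally weighted
#' subscores: dipolarity of the scalp map (1 - residual variance), 1/f-ness
#' of the spectrum (negative slope mapped through a logistic), and a low
#' high-frequency power fraction (> 30 Hz). A component is retained when all
#' four criteria pass: `brain_score >= 0.5`, negative 2-40 Hz PSD slope,
#' dipole residual variance < 0.15, and dipole inside the head radius.
#'
#' @param cs a `component_set` from [run_ica()].
#' @param head_radius model head radius in mm (default 90).
#' @param rv_max residual variance criterion (default 0.15).
#' @param score_min brain-score criterion (default 0.5).
#' @return `cs` with a `scores` data.frame added: brain_score, psd_slope_2_40
#'   (dB per decade), dipole x/y/z (mm), rv, retained, plus the rejection
#'   reason per component.
#' @export
score_components <- function(cs, head_radius = 90, rv_max = 0.15, score_min = 0.5) {
  n_comp <- nrow(cs$unmixing)
  out <- data.frame(component = seq_len(n_comp), brain_score = NA_real_,
                    psd_slope_2_40 = NA_real_, x = NA_real_, y = NA_real_,
                    z = NA_real_, rv = NA_real_, retained = FALSE,
                    reason = "")
  for (i in seq_len(n_comp)) {
    dp <- fit_dipole(cs$mixing[, i], cs$positions, head_radius)
    ps <- welch_psd(cs$activations[i, ], cs$fs)
    sel <- ps$freq >= 2 & ps$freq <= 40
    fit <- lm(ps$db[sel] ~ log10(ps$freq[sel]))
    slope <- coef(fit)[2]
    hf <- sum(ps$power[ps$freq > 30]) / sum(ps$power[ps$freq > 1])
    s_dip <- max(0, 1 - dp$rv)
    s_slope <- 1 / (1 + exp(slope / 4))            # ~1 for steep negative slopes
    s_hf <- max(0, 1 - 2 * hf)
    score <- mean(c(s_dip, s_slope, s_hf))
    radius <- sqrt(sum(dp$location^2))
    ok_score <- score >= score_min
    ok_slope <- slope < 0
    ok_rv <- dp$rv < rv_max
    ok_in <- radius < head_radius
    reasons <- c("low brain_score", "non-negative PSD slope",
                 "high dipole residual variance", "dipole outside head")[
                   !c(ok_score, ok_slope, ok_rv, ok_in)]
    out[i, c("brain_score", "psd_slope_2_40", "x", "y", "z", "rv")] <-
      c(score, slope, dp$location, dp$rv)
    out$retained[i] <- ok_score && ok_slope && ok_rv && ok_in
    out$reason[i] <- paste(reasons, collapse = "; ")
    if (!out$retained[i])
      ger_log("score_components: component %d rejected (%s)", i, out$reason[i])
  }
  cs$scores <- out
  cs
}

#' Cluster retained components by dipole location
#'
#' K-means (many restarts) on dipole coordinates pooled across subjects.
#' Components farther than `k_sd` pooled within-cluster SDs from every
#' centroid are flagged outliers. Clusters containing components from fewer
#' than half of the young subjects or half of the old subjects are dropped.
#' Within each (subject, cluster) pair only the component with the maximal
#' brain score is kept.
#'
#' @param components data.frame with columns `subject`, `group`, `x`, `y`,
#'   `z`, `brain_score` (one row per retained component).
#' @param k number of clusters (default 11, desk-scale data may use fewer).
#' @param k_sd outlier distance criterion in pooled SD units (default 3).
#' @param nstart k-means restarts (default 100).
#' @param seed RNG seed.
#' @param min_frac minimal fraction of each group's subjects per retained
#'   cluster (default 0.5).
#' @return object of class `cluster_model`: `centroids`, `assignment`,
#'   `outlier`, `kept` (per component, after all rules), `cluster_retained`,
#'   `k`.
#' @export
cluster_components <- function(components, k = 11, k_sd = 3, nstart = 100,
                               seed = 1L, min_frac = 0.5) {
  assert_that(nrow(components) >= k,
              "cluster_components: k = %d exceeds %d components", k, nrow(components))
  set.seed(seed)
  xyz <- as.matrix(components[, c("x", "y", "z")])
  km <- kmeans(xyz, centers = k, nstart = nstart, iter.max = 100)
  assign <- km$cluster
  ## pooled spatial scale: RMS of member-to-own-centroid distances
  d_own <- sqrt(rowSums((xyz - km$centers[assign, , drop = FALSE])^2))
  s <- sqrt(mean(d_own^2))
  if (!is.finite(s) || s == 0) s <- max(max(d_own), 1e-9)
  d_all <- vapply(seq_len(k), function(c)
    sqrt(rowSums(sweep(xyz, 2, km$centers[c, ])^2)), numeric(nrow(xyz)))
  outlier <- apply(d_all, 1, min) > k_sd * s
  ## degenerate (singleton) clusters are dissolved as outliers
  tiny <- as.integer(names(which(table(assign) < 2)))
  outlier <- outlier | assign %in% tiny
  if (any(outlier))
    ger_log("cluster_components: %d outlier component(s) (> %g SD)", sum(outlier), k_sd)

  groups <- unique(components$group)
  n_by_group <- vapply(groups, function(g)
    length(unique(components$subject[components$group == g])), 0L)
  cluster_retained <- vapply(seq_len(k), function(c) {
    memb <- components[assign == c & !outlier, , drop = FALSE]
    all(vapply(groups, function(g)
      length(unique(memb$subject[memb$group == g])) >= min_frac * n_by_group[[g]],
      logical(1)))
  }, logical(1))

  ## one component per (subject, cluster): keep max brain_score
  kept <- !outlier & cluster_retained[assign]
  for (c in seq_len(k)) {
    idx <- which(assign == c & kept)
    if (!length(idx)) next
    for (sub in unique(components$subject[idx])) {
      ii <- idx[components$subject[idx] == sub]
      if (length(ii) > 1) {
        keep_one <- ii[which.max(components$brain_score[ii])]
        kept[setdiff(ii, keep_one)] <- FALSE
        ger_log("cluster_components: subject %s cluster %d: kept 1 of %d components",
                sub, c, length(ii))
      }
    }
  }
  structure(list(k = k, centroids = km$centers, assignment = assign,
                 outlier = outlier, cluster_retained = cluster_retained,
                 kept = kept, components = components),
            class = "cluster_model")
}

#' Cluster-count diagnostics
#'
#' Calinski-Harabasz and Davies-Bouldin indices plus the mean silhouette
#' width over a range of k, as a report to support the choice of k.
#'
#' @param xyz n x 3 dipole locations.
#' @param k_range candidate cluster counts (default 9:14).
#' @param seed,nstart k-means controls.
#' @return data.frame with one row per k.
#' @export
evaluate_cluster_counts <- function(xyz, k_range = 9:14, seed = 1L, nstart = 50) {
  set.seed(seed)
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  res <- lapply(k_range, function(k) {
    km <- kmeans(xyz, k, nstart = nstart, iter.max = 100)
    ## Calinski-Harabasz
    ch <- (km$betweenss / (k - 1)) / (km$tot.withinss / (n - k))
    ## Davies-Bouldin
    sig <- vapply(seq_len(k), function(c) {
      m <- xyz[km$cluster == c, , drop = FALSE]
      mean(sqrt(rowSums(sweep(m, 2, km$centers[c, ])^2)))
    }, 0)
    db <- mean(vapply(seq_len(k), function(i) {
      max(vapply(setdiff(seq_len(k), i), function(j)
        (sig[i] + sig[j]) / sqrt(sum((km$centers[i, ] - km$centers[j, ])^2)), 0))
    }, 0))
    ## mean silhouette
    D <- as.matrix(dist(xyz))
    sil <- mean(vapply(seq_len(n), function(i) {
      a <- mean(D[i, km$cluster == km$cluster[i] & seq_len(n) != i])
      b <- min(vapply(setdiff(seq_len(k), km$cluster[i]), function(c)
        mean(D[i, km$cluster == c]), 0))
      if (!is.finite(a)) 0 else (b - a) / max(a, b)
    }, 0))
    data.frame(k = k, calinski_harabasz = ch, davies_bouldin = db, silhouette = sil)
  })
  do.call(rbind, res)
}
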