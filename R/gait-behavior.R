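## Gait event detection from insole vertical force and the behavioral
## variability measures (step-duration and sacral-excursion CoV).

## indices of upward/downward threshold crossings with a debounce interval
threshold_crossings <- function(x, fs, threshold, debounce = 0.05) {
  above <- x >= threshold
  up <- which(above & !c(TRUE, above[-length(above)]))
  down <- which(!above & c(FALSE, above[-length(above)]))
  drop_chatter <- function(idx) {
    if (length(idx) < 2) return(idx)
    keep <- c(TRUE, diff(idx) > debounce * fs)
    idx[keep]
  }
  list(up = drop_chatter(up), down = drop_chatter(down))
}

#' Detect gait events from per-foot insole forces
#'
#' Foot strike is the upward crossing of the force threshold, foot off the
#' downward crossing (event time = time of the first sample at or above /
#' below the threshold). Events are assembled into strides anchored at right
#' foot strikes: each stride needs left foot off, left foot strike and right
#' foot off, in that order, between consecutive right foot strikes; incomplete
#' leading/trailing strides are dropped.
#'
#' @param left,right [force_trace()] objects of equal duration and rate.
#' @param threshold detection threshold in Newtons (default 20).
#' @param debounce minimum interval between accepted crossings (s).
#' @return a `gait_events` data.frame (possibly 0 rows) with columns
#'   `t_RFS, t_LFO, t_LFS, t_RFO, t_RFS_next` in seconds.
#' @export
detect_gait_events <- function(left, right, threshold = 20, debounce = 0.05) {
  assert_that(inherits(left, "force_trace") && inherits(right, "force_trace"),
              "detect_gait_events: inputs must be force_trace objects")
  assert_that(threshold > 0, "detect_gait_events: threshold must be positive")
  assert_that(length(left$samples) == length(right$samples) && left$fs == right$fs,
              "detect_gait_events: traces must have matching duration and rate")
  fs <- right$fs
  r <- threshold_crossings(right$samples, fs, threshold, debounce)
  l <- threshold_crossings(left$samples, fs, threshold, debounce)
  t_of <- function(idx) (idx - 1) / fs

  empty <- data.frame(stride = integer(), t_RFS = numeric(), t_LFO = numeric(),
                      t_LFS = numeric(), t_RFO = numeric(), t_RFS_next = numeric())
  class(empty) <- c("gait_events", "data.frame")
  if (length(r$up) < 2) return(empty)

  rows <- list()
  for (i in seq_len(length(r$up) - 1)) {
    t0 <- t_of(r$up[i]); t1 <- t_of(r$up[i + 1])
    lfo <- t_of(l$down[t_of(l$down) > t0 & t_of(l$down) < t1])
    lfs <- t_of(l$up[t_of(l$up) > t0 & t_of(l$up) < t1])
    rfo <- t_of(r$down[t_of(r$down) > t0 & t_of(r$down) < t1])
    if (length(lfo) < 1 || length(lfs) < 1 || length(rfo) < 1) next
    lfo <- lfo[1]; lfs <- lfs[lfs > lfo][1]; rfo <- rfo[rfo > lfs][1]
    if (is.na(lfs) || is.na(rfo)) next
    rows[[length(rows) + 1]] <- data.frame(stride = NA_integer_, t_RFS = t0,
                                           t_LFO = lfo, t_LFS = lfs,
                                           t_RFO = rfo, t_RFS_next = t1)
  }
  if (!length(rows)) return(empty)
  ev <- do.call(rbind, rows)
  ev$stride <- seq_len(nrow(ev))
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Per-stride sacral peak-to-peak excursion
#'
#' For each stride (right foot strike to the next), the range (max - min) of
#' the sacral excursion trace. Strides extending past the trace are skipped
#' with a log entry.
#'
#' @param trace numeric vector (AP or ML sacral excursion, mm).
#' @param events a `gait_events` table.
#' @param fs sampling rate of `trace` (Hz).
#' @return numeric vector, one peak-to-peak value per usable stride.
#' @export
sacral_excursion <- function(trace, events, fs) {
  n <- length(trace)
  out <- numeric(0)
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$t_RFS[i] * fs) + 1
    i1 <- ceiling(events$t_RFS_next[i] * fs)
    if (i0 < 1 || i1 > n) {
      ger_log("sacral_excursion: stride %d outside trace, skipped", i)
      next
    }
    seg <- trace[i0:i1]
    out <- c(out, max(seg) - min(seg))
  }
  out
}

## step durations from an event table: RFS->LFS and LFS->next RFS
step_durations <- function(events) {
  c(rbind(events$t_LFS - events$t_RFS, events$t_RFS_next - events$t_LFS))
}

#' Behavioral variability summary per (subject, condition)
#'
#' Computes the step-duration CoV and sacral-excursion CoVs from gait events
#' and sacral traces, pooling trials within a condition after per-trial
#' outlier removal (values beyond `k_sd` SD of the within-trial mean are
#' dropped once, non-iteratively).
#'
#' @param trials list of trials; each a list with `events`, `sacral_ap`,
#'   `sacral_ml`, `fs` (the structure returned by [simulate_gait()], or built
#'   from detected events).
#' @param k_sd outlier threshold in SD (default 2.5).
#' @param min_strides minimum retained strides; below this the cell is flagged
#'   unusable (default 5).
#' @return data.frame with `step_duration_cov`, `sacral_ap_cov`,
#'   `sacral_ml_cov`, `n_strides_used`, `usable`.
#' @export
behavior_summary <- function(trials, k_sd = 2.5, min_strides = 5) {
  steps <- list(); aps <- list(); mls <- list(); n_str <- 0
  for (tr in trials) {
    ev <- tr$events
    if (is.null(ev) || nrow(ev) == 0) next
    n_str <- n_str + nrow(ev)
    steps[[length(steps) + 1]] <- remove_outliers(step_durations(ev), k_sd)
    if (!is.null(tr$sacral_ap))
      aps[[length(aps) + 1]] <- remove_outliers(sacral_excursion(tr$sacral_ap, ev, tr$fs), k_sd)
    if (!is.null(tr$sacral_ml))
      mls[[length(mls) + 1]] <- remove_outliers(sacral_excursion(tr$sacral_ml, ev, tr$fs), k_sd)
  }
  usable <- n_str >= min_strides
  if (!usable) ger_log("behavior_summary: only %d strides, flagged unusable", n_str)
  cov_or_na <- function(lst) {
    v <- unlist(lst)
    if (length(v) >= 2 && usable) coefficient_of_variation(v) else NA_real_
  }
  data.frame(step_duration_cov = cov_or_na(steps),
             sacral_ap_cov = cov_or_na(aps),
             sacral_ml_cov = cov_or_na(mls),
             n_strides_used = n_str, usable = usable)
}

#' Behavior table for a synthetic dataset
#'
#' Re-detects gait events from the generated insole forces (20 N threshold)
#' and assembles the per-(subject, condition) behavioral summaries.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param threshold force threshold (N).
#' @return data.frame with subject, group, condition, speed and the summary
#'   columns of [behavior_summary()].
#' @export
behavior_table <- function(dataset, threshold = 20) {
  cfg <- dataset$cfg
  rows <- list()
  for (s in seq_len(nrow(dataset$subjects))) {
    sub <- dataset$subjects$subject[s]
    for (cond in cfg$conditions) {
      trials <- list()
      for (tr in seq_len(cfg$n_trials)) {
        g <- dataset$gait[[paste(sub, cond, tr, sep = ".")]]
        if (is.null(g)) next
        ev <- detect_gait_events(g$force_left, g$force_right, threshold)
        trials[[tr]] <- list(events = ev, sacral_ap = g$sacral_ap,
                             sacral_ml = g$sacral_ml, fs = g$fs)
      }
      sm <- behavior_summary(trials)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject = sub, group = dataset$subjects$group[s],
                   condition = cond, speed = dataset$subjects$speed[s]), sm)
    }
  }
  do.call(rbind, rows)
}
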