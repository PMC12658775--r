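## Gait simulator: stride timing, insole vertical force and sacral excursion
## traces with known ground truth.

#' Gait specification for one (condition, group) cell
#'
#' @param stride_mean mean stride duration in seconds (right foot strike to
#'   next right foot strike).
#' @param stride_cv coefficient of variation of stride duration (>= 0).
#' @param event_phase named fractions of the stride at which left foot off,
#'   left foot strike and right foot off occur; must satisfy
#'   0 < LFO < LFS < RFO < 1.
#' @param sacral_ap_mean,sacral_ml_mean mean per-stride peak-to-peak sacral
#'   excursion, anteroposterior / mediolateral (mm).
#' @param sacral_ap_cv,sacral_ml_cv coefficients of variation of the
#'   per-stride excursions.
#' @return object of class `gait_spec`.
#' @export
gait_spec <- function(stride_mean = 1.25, stride_cv = 0.05,
                      event_phase = c(LFO = 0.12, LFS = 0.50, RFO = 0.62),
                      sacral_ap_mean = 15, sacral_ml_mean = 40,
                      sacral_ap_cv = 0.15, sacral_ml_cv = 0.15) {
  assert_that(is.numeric(stride_mean) && stride_mean > 0,
              "invalid gait spec: stride_mean must be positive")
  assert_that(stride_cv >= 0 && sacral_ap_cv >= 0 && sacral_ml_cv >= 0,
              "invalid gait spec: CVs must be >= 0")
  ph <- event_phase[c("LFO", "LFS", "RFO")]
  assert_that(!anyNA(ph) && 0 < ph[1] && ph[1] < ph[2] && ph[2] < ph[3] && ph[3] < 1,
              "invalid gait spec: need 0 < LFO < LFS < RFO < 1")
  structure(list(stride_mean = stride_mean, stride_cv = stride_cv,
                 event_phase = ph,
                 sacral_ap_mean = sacral_ap_mean, sacral_ml_mean = sacral_ml_mean,
                 sacral_ap_cv = sacral_ap_cv, sacral_ml_cv = sacral_ml_cv),
            class = "gait_spec")
}

#' Default gait parameters by terrain condition and age group
#'
#' Stride-time variability and sacral-excursion variability increase with
#' terrain unevenness, more steeply for older adults; older adults walk with
#' longer, more variable strides at their slower self-selected speeds.
#'
#' @param condition one of "Flat", "Low", "Med", "High".
#' @param group "young" or "old".
#' @return a [gait_spec()].
#' @export
default_gait_spec <- function(condition = "Flat", group = "young") {
  cond <- match.arg(condition, c("Flat", "Low", "Med", "High"))
  grp <- match.arg(group, c("young", "old"))
  i <- match(cond, c("Flat", "Low", "Med", "High"))
  if (grp == "young") {
    gait_spec(stride_mean = c(1.20, 1.22, 1.25, 1.28)[i],
              stride_cv   = c(0.030, 0.040, 0.055, 0.075)[i],
              sacral_ap_cv = c(0.12, 0.15, 0.18, 0.22)[i],
              sacral_ml_cv = c(0.12, 0.15, 0.18, 0.22)[i])
  } else {
    gait_spec(stride_mean = c(1.45, 1.48, 1.52, 1.56)[i],
              stride_cv   = c(0.040, 0.060, 0.085, 0.120)[i],
              sacral_ap_cv = c(0.15, 0.20, 0.26, 0.33)[i],
              sacral_ml_cv = c(0.15, 0.20, 0.26, 0.33)[i])
  }
}

#' Insole force trace
#' @param samples vertical ground reaction force in Newtons.
#' @param fs sampling rate (Hz).
#' @param foot "left" or "right".
#' @return object of class `force_trace`.
#' @export
force_trace <- function(samples, fs, foot = c("left", "right")) {
  assert_that(fs > 0, "force_trace: fs must be positive")
  assert_that(all(is.finite(samples)), "force_trace: non-finite samples")
  structure(list(samples = as.numeric(samples), fs = fs, foot = match.arg(foot)),
            class = "force_trace")
}

## truncated normal draws: mean m, sd s, truncated to m +/- 3.5 s and > lo
rtruncnorm_strides <- function(n, m, s, lo = 0.2 * m) {
  if (s == 0) return(rep(m, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, m, s)
      if (x > lo && abs(x - m) <= 3.5 * s) break
    }
    out[i] <- x
  }
  out
}

## smooth half-sine stance "bump" that crosses `thr` exactly at (a0, b0);
## returns the force contribution evaluated at times t
stance_bump <- function(t, a0, b0, peak = 700, thr = 20) {
  x <- asin(thr / peak)
  m <- x * (b0 - a0) / (pi - 2 * x)
  a <- a0 - m
  b <- b0 + m
  f <- numeric(length(t))
  in_b <- t >= a & t <= b
  f[in_b] <- peak * sin(pi * (t[in_b] - a) / (b - a))
  f
}

#' Simulate gait events, insole forces and sacral excursions
#'
#' Stride durations are drawn from a truncated normal distribution with the
#' spec's mean and CV; foot strike / foot off times follow the spec's event
#' phases. Per-foot force traces are smooth loading curves that cross the
#' 20 N detection threshold exactly at each true foot strike (upward) and
#' foot off (downward). Sacral traces oscillate once (ML) or twice (AP) per
#' stride with per-stride peak-to-peak amplitudes of the stated mean and CV.
#'
#' @param spec a [gait_spec()].
#' @param duration trace duration in seconds (>= 3 stride means).
#' @param fs sampling rate (Hz).
#' @param seed optional integer seed.
#' @param peak_force peak stance force (N); only its ratio to the 20 N
#'   threshold matters.
#' @return list with `events` (data.frame: t_RFS, t_LFO, t_LFS, t_RFO,
#'   t_RFS_next), `force_left`/`force_right` ([force_trace()]), `sacral_ap`,
#'   `sacral_ml` (mm), `stride_durations`, `fs`, `t`.
#' @export
simulate_gait <- function(spec, duration, fs = 500, seed = NULL, peak_force = 700) {
  assert_that(inherits(spec, "gait_spec"), "simulate_gait: spec must be a gait_spec")
  assert_that(spec$stride_mean > 0, "invalid gait spec: non-positive stride mean")
  assert_that(duration >= 3 * spec$stride_mean,
              "simulate_gait: duration must cover >= 3 strides")
  if (!is.null(seed)) set.seed(seed)

  m <- spec$stride_mean
  ## draw strides to fill the trace, leaving margins for the stance bumps
  t0 <- 0.6 * m
  n_max <- ceiling((duration - t0) / (0.5 * m)) + 2
  durs <- rtruncnorm_strides(n_max, m, spec$stride_cv * m)
  rfs <- t0 + c(0, cumsum(durs))
  ## keep strides whose next RFS fits with margin for the trailing bump
  keep <- which(rfs[-1] <= duration - 0.3 * m)
  assert_that(length(keep) >= 1, "simulate_gait: duration too short for any stride")
  n_str <- max(keep)
  durs <- durs[seq_len(n_str)]
  rfs <- rfs[seq_len(n_str + 1)]

  ph <- spec$event_phase
  events <- data.frame(
    stride = seq_len(n_str),
    t_RFS = rfs[seq_len(n_str)],
    t_LFO = rfs[seq_len(n_str)] + ph[["LFO"]] * durs,
    t_LFS = rfs[seq_len(n_str)] + ph[["LFS"]] * durs,
    t_RFO = rfs[seq_len(n_str)] + ph[["RFO"]] * durs,
    t_RFS_next = rfs[seq_len(n_str) + 1])
  class(events) <- c("gait_events", "data.frame")

  nsamp <- round(duration * fs)
  t <- (seq_len(nsamp) - 1) / fs

  ## right foot stance: RFS_i -> RFO_i
  f_right <- numeric(nsamp)
  for (i in seq_len(n_str)) {
    f_right <- f_right + stance_bump(t, events$t_RFS[i], events$t_RFO[i], peak_force)
  }
  ## trailing (truncated) right stance so the last stride's closing RFS is
  ## present in the force trace
  f_right <- f_right + stance_bump(t, events$t_RFS_next[n_str],
                                   events$t_RFS_next[n_str] + ph[["RFO"]] * durs[n_str],
                                   peak_force)
  ## left foot stance: LFS_{i-1} -> LFO_i (a virtual stance precedes stride 1)
  f_left <- numeric(nsamp)
  lfs_prev <- events$t_RFS[1] - (1 - ph[["LFS"]]) * durs[1]
  for (i in seq_len(n_str)) {
    f_left <- f_left + stance_bump(t, lfs_prev, events$t_LFO[i], peak_force)
    lfs_prev <- events$t_LFS[i]
  }
  ## trailing left stance ends past the last stride if it fits
  lfo_next <- events$t_RFS_next[n_str] + ph[["LFO"]] * durs[n_str]
  if (lfo_next < duration - 0.05) {
    f_left <- f_left + stance_bump(t, lfs_prev, lfo_next, peak_force)
  }

  ## sacral excursions: per-stride peak-to-peak amplitudes with stated mean/CV
  draw_p2p <- function(mean, cv, n) {
    if (cv == 0) return(rep(mean, n))
    pmax(0.05 * mean, rnorm(n, mean, cv * mean))
  }
  p2p_ap <- draw_p2p(spec$sacral_ap_mean, spec$sacral_ap_cv, n_str)
  p2p_ml <- draw_p2p(spec$sacral_ml_mean, spec$sacral_ml_cv, n_str)
  sac_ap <- numeric(nsamp)
  sac_ml <- numeric(nsamp)
  for (i in seq_len(n_str)) {
    idx <- which(t >= events$t_RFS[i] & t < events$t_RFS_next[i])
    p <- (t[idx] - events$t_RFS[i]) / durs[i]
    sac_ap[idx] <- (p2p_ap[i] / 2) * sin(4 * pi * p)
    sac_ml[idx] <- (p2p_ml[i] / 2) * sin(2 * pi * p)
  }

  list(events = events,
       force_left = force_trace(f_left, fs, "left"),
       force_right = force_trace(f_right, fs, "right"),
       sacral_ap = sac_ap, sacral_ml = sac_ml,
       stride_durations = durs,
       truth_p2p = list(ap = p2p_ap, ml = p2p_ml),
       fs = fs, t = t, duration = duration)
}

#' Instantaneous gait phase
#'
#' Piecewise-linear phase in `[0, 1)` within each stride (right foot strike to
#' next right foot strike); `NA` outside any stride. This is the same warping
#' model used by [timewarp_gait()].
#'
#' @param t time points (s).
#' @param events a gait event table.
#' @return numeric vector of phases, `NA` outside strides.
#' @export
gait_phase <- function(t, events) {
  ph <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(events))) {
    idx <- which(t >= events$t_RFS[i] & t < events$t_RFS_next[i])
    ph[idx] <- (t[idx] - events$t_RFS[i]) / (events$t_RFS_next[i] - events$t_RFS[i])
  }
  ph
}
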