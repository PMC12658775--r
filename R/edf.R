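## Minimal EDF (European Data Format, 16-bit) writer/reader plus a JSON
## sidecar carrying channel roles, montage positions and study labels. One
## 1-second data record per second; the sidecar stores the exact sample count
## so padding in the last record is trimmed on read.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf("%-*s", width, x)
}

#' Write a recording to EDF with a JSON sidecar
#'
#' Data are scaled per channel to the 16-bit digital range; the round-trip
#' error is bounded by one quantization step of `max(|x|) / 32767` per
#' channel. The sidecar (same path, `.json`) stores roles, positions, labels
#' and the exact sample count.
#'
#' @param rec an `eeg_recording`.
#' @param path output path ending in `.edf`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  data <- rec$data
  nch <- nrow(data)
  fs <- rec$fs
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  if (pad > 0) data <- cbind(data, matrix(0, nch, pad))

  pmax_ch <- pmax(apply(abs(data), 1, max), 1e-6)
  dig <- round(sweep(data, 1, pmax_ch / 32767, `/`))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nch), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(nch, 4))
  writeChar(hdr, con, eos = NULL)
  labels <- rownames(rec$data) %||% sprintf("CH%03d", seq_len(nch))
  field <- function(vals, width) writeChar(paste(vapply(vals, edf_pad, "", width = width),
                                                 collapse = ""), con, eos = NULL)
  field(labels, 16)
  field(rep("", nch), 80)
  field(rep("uV", nch), 8)
  field(sprintf("%.6g", -pmax_ch), 8)
  field(sprintf("%.6g", pmax_ch), 8)
  field(rep("-32767", nch), 8)
  field(rep("32767", nch), 8)
  field(rep("", nch), 80)
  field(rep(fs, nch), 8)
  field(rep("", nch), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
  }

  sidecar <- list(roles = rec$roles, labels = labels,
                  positions = rec$positions, fs = fs, n_samples = n,
                  subject = rec$subject, group = rec$group,
                  condition = rec$condition, trial = rec$trial)
  jsonlite::write_json(sidecar, sub("\\.edf$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path to the `.edf` file; the `.json` sidecar must sit next to
#'   it.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path) {
  sidecar_path <- sub("\\.edf$", ".json", path)
  if (!file.exists(sidecar_path)) {
    stopf(paste("read_recording: missing sidecar %s; required fields:",
                "roles, labels, fs, n_samples (optional: positions, subject,",
                "group, condition, trial)"), sidecar_path)
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)

  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0")) stopf("read_recording: malformed EDF header (version '%s')", version)
  rd(80 + 80 + 8 + 8)
  hdr_bytes <- suppressWarnings(as.integer(trimws(rd(8))))
  rd(44)
  n_rec <- suppressWarnings(as.integer(trimws(rd(8))))
  dur <- suppressWarnings(as.numeric(trimws(rd(8))))
  nch <- suppressWarnings(as.integer(trimws(rd(4))))
  if (anyNA(c(hdr_bytes, n_rec, dur, nch)) || nch < 1 ||
      hdr_bytes != 256 * (1 + nch)) {
    stopf("read_recording: malformed EDF header (inconsistent sizes)")
  }
  labels <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  rd(nch * 80)                       # transducer
  rd(nch * 8)                        # physical dimension
  pmin_ch <- as.numeric(trimws(vapply(seq_len(nch), function(i) rd(8), "")))
  pmax_ch <- as.numeric(trimws(vapply(seq_len(nch), function(i) rd(8), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(nch), function(i) rd(8), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(nch), function(i) rd(8), "")))
  rd(nch * 80)                       # prefiltering
  spr <- as.integer(trimws(vapply(seq_len(nch), function(i) rd(8), "")))
  rd(nch * 32)
  if (anyNA(c(pmin_ch, pmax_ch, dmin, dmax, spr)))
    stopf("read_recording: malformed EDF signal headers")

  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = sum(spr), size = 2, endian = "little")
    ofs <- 0
    for (ch in seq_len(nch)) {
      seg <- raw[(ofs + 1):(ofs + spr[ch])]
      gain <- (pmax_ch[ch] - pmin_ch[ch]) / (dmax[ch] - dmin[ch])
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        pmin_ch[ch] + (seg - dmin[ch]) * gain
      ofs <- ofs + spr[ch]
    }
  }
  n <- side$n_samples %||% ncol(data)
  data <- data[, seq_len(n), drop = FALSE]
  rownames(data) <- labels
  pos <- side$positions
  if (!is.null(pos)) pos <- matrix(unlist(pos), ncol = 3)
  recording(data, fs = side$fs, roles = side$roles, positions = pos,
            subject = side$subject %||% NA, group = side$group %||% NA,
            condition = side$condition %||% NA, trial = side$trial %||% NA)
}

#' Write / read gait events as a tab-separated table
#'
#' Columns: `onset_s`, `event` (RFS/LFO/LFS/RFO), `stride_index`.
#'
#' @param events a `gait_events` table.
#' @param path output `.tsv` path.
#' @return `path` invisibly (write) or a `gait_events` table (read).
#' @export
write_events_tsv <- function(events, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    data.frame(onset_s = as.numeric(events[i, c("t_RFS", "t_LFO", "t_LFS", "t_RFO")]),
               event = c("RFS", "LFO", "LFS", "RFO"),
               stride_index = events$stride[i])
  }))
  ## closing foot strike of the final stride
  if (nrow(events)) {
    long <- rbind(long, data.frame(onset_s = events$t_RFS_next[nrow(events)],
                                   event = "RFS",
                                   stride_index = events$stride[nrow(events)] + 1L))
  }
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  long <- utils::read.delim(path)
  strides <- sort(unique(long$stride_index))
  get <- function(ev, s) long$onset_s[long$event == ev & long$stride_index == s][1]
  ev <- data.frame(stride = strides,
                   t_RFS = vapply(strides, function(s) get("RFS", s), 0),
                   t_LFO = vapply(strides, function(s) get("LFO", s), 0),
                   t_LFS = vapply(strides, function(s) get("LFS", s), 0),
                   t_RFO = vapply(strides, function(s) get("RFO", s), 0))
  ev$t_RFS_next <- c(ev$t_RFS[-1], NA)
  ev <- ev[stats::complete.cases(ev), , drop = FALSE]
  class(ev) <- c("gait_events", "data.frame")
  ev
}
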