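## shared builders for the test suite

test_bands <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))

## a zeroed bands x conditions x groups shift array
zero_shift <- function(conds = c("Flat", "Low", "Med", "High")) {
  array(0, c(3, length(conds), 2),
        dimnames = list(names(test_bands), conds, c("young", "old")))
}

## small scalp-only recording from an explicit data matrix
quick_recording <- function(data, fs = 500, roles = rep("scalp", nrow(data))) {
  rownames(data) <- sprintf("CH%03d", seq_len(nrow(data)))
  mont <- spherical_montage(max(4, nrow(data)))[seq_len(nrow(data)), , drop = FALSE]
  recording(data, fs, roles, positions = mont)
}

## linear-scan threshold-crossing oracle: first sample at/above (strike) or
## below (off) the threshold
oracle_crossings <- function(x, fs, thr = 20) {
  up <- which(x >= thr & c(FALSE, x[-length(x)] < thr))
  down <- which(x < thr & c(FALSE, x[-length(x)] >= thr))
  list(up = (up - 1) / fs, down = (down - 1) / fs)
}

## direct step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}
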