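#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd median mad rnorm runif qnorm approx fft nextn
#'   convolve coef lm lm.fit optim kmeans quantile cor var anova as.formula
#'   p.adjust predict pt spline qt dist setNames
#' @importFrom utils write.csv read.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Sample coefficient of variation
#'
#' Standard deviation divided by the mean. The variability measure used for
#' step durations and sacral excursions.
#'
#' @param values numeric vector, length >= 2.
#' @return unitless scalar.
#' @export
coefficient_of_variation <- function(values) {
  assert_that(length(values) >= 2, "coefficient_of_variation() needs >= 2 values")
  m <- mean(values)
  assert_that(abs(m) > .Machine$double.eps * 100,
              "coefficient_of_variation() undefined for zero mean")
  sd(values) / m
}

#' Remove outliers by a z-score rule
#'
#' Drops values more than `k_sd` sample standard deviations away from the
#' mean. The rule is applied once (no re-iteration). With zero variance the
#' input is returned unchanged.
#'
#' @param values numeric vector, length >= 2.
#' @param k_sd rejection threshold in standard deviations (default 2.5).
#' @return the retained values, order preserved.
#' @export
remove_outliers <- function(values, k_sd = 2.5) {
  assert_that(length(values) >= 2, "remove_outliers() needs >= 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(values)
  values[abs(values - mean(values)) <= k_sd * s]
}

## simple deterministic string checksum (polynomial, 32-bit), adequate for
## run-manifest identity checks
checksum32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (i in seq_along(bytes)) {
    h <- (h * 31 + bytes[i]) %% 2147483647
  }
  sprintf("%08x", h)
}

## per-package logger: records rejection decisions etc.; messages suppressed
## unless options(gaitersp.verbose = TRUE)
ger_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (isTRUE(getOption("gaitersp.verbose", FALSE))) message("[gaitersp] ", msg)
  invisible(msg)
}
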