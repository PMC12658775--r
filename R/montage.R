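## Idealized spherical montage and the dipolar forward model shared by the
## synthetic generator and the dipole fitter. Electrode and source positions
## live in model coordinates (mm), head centre at the origin.

#' Idealized spherical electrode montage
#'
#' Places `n` electrodes quasi-uniformly on the upper portion of a sphere
#' (a Fibonacci lattice restricted to z > -0.25 R, mimicking scalp coverage).
#'
#' @param n number of electrodes.
#' @param radius head radius in mm (default 90).
#' @return an n x 3 matrix of positions (mm), rows named E001...
#' @export
spherical_montage <- function(n, radius = 90) {
  assert_that(n >= 4, "montage needs >= 4 electrodes")
  ## Fibonacci lattice over the spherical cap z/R in (-0.25, 1]
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- 1 - (i / n) * 1.25            # from 1 down to -0.25
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i / golden
  pos <- radius * cbind(r * cos(phi), r * sin(phi), z)
  rownames(pos) <- sprintf("E%03d", seq_len(n))
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Dipolar forward projection
#'
#' Potential of a current dipole in a homogeneous volume conductor, sampled at
#' the montage electrodes and average-referenced. Units are arbitrary
#' (proportional to dipole moment); the same model is used for simulation and
#' for equivalent-dipole fitting, so scaling cancels.
#'
#' @param location 3-vector, dipole position (mm).
#' @param moment 3-vector, dipole moment direction/magnitude.
#' @param montage electrode positions, n x 3 (mm).
#' @return numeric vector of n average-referenced potentials.
#' @export
dipole_forward <- function(location, moment, montage) {
  d <- sweep(montage, 2, location)           # n x 3 vectors electrode - dipole
  r3 <- rowSums(d^2)^(3 / 2)
  v <- as.vector(d %*% moment) / r3
  v - mean(v)
}

## basis of unit-moment forward maps at a location: n_elec x 3
dipole_basis <- function(location, montage) {
  cbind(dipole_forward(location, c(1, 0, 0), montage),
        dipole_forward(location, c(0, 1, 0), montage),
        dipole_forward(location, c(0, 0, 1), montage))
}

#' Fit an equivalent current dipole to a scalp map
#'
#' Single-dipole fit in the package's spherical-montage forward model. The
#' moment is solved linearly at each candidate location; the location is
#' optimized by Nelder-Mead from several deterministic starting points.
#' Residual variance (RV) is the fraction of map variance unexplained by the
#' forward-projected dipole.
#'
#' @param scalp_map numeric vector of channel weights (one ICA mixing column).
#' @param montage electrode positions, n x 3 (mm).
#' @param head_radius model head radius in mm (default 90); the search allows
#'   locations out to 1.4 x radius so that far-field artifact maps can be
#'   recognized (and later rejected) by the inside-the-head criterion.
#' @return list with `location` (mm), `moment`, `rv` in `[0, 1]`.
#' @export
fit_dipole <- function(scalp_map, montage, head_radius = 90) {
  v <- scalp_map - mean(scalp_map)
  ss <- sum(v^2)
  if (ss <= 0) return(list(location = c(0, 0, 0), moment = c(0, 0, 0), rv = 1))
  rmax <- 1.4 * head_radius

  cost <- function(p) {
    if (sqrt(sum(p^2)) >= rmax) return(1 + sqrt(sum(p^2)) / head_radius)
    B <- dipole_basis(p, montage)
    fit <- tryCatch(lm.fit(B, v), error = function(e) NULL)
    if (is.null(fit)) return(1)
    sum(fit$residuals^2) / ss
  }

  ## deterministic multistart: centre + 6 axis points at half radius
  starts <- rbind(c(0, 0, 20),
                  0.5 * head_radius * diag(3),
                  -0.5 * head_radius * diag(3)[1:2, ],
                  c(0, 0, 0.7 * head_radius))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[s, ], cost, method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) return(list(location = c(0, 0, 0), moment = c(0, 0, 0), rv = 1))
  loc <- best$par
  B <- dipole_basis(loc, montage)
  m <- lm.fit(B, v)$coefficients
  m[!is.finite(m)] <- 0
  rv <- min(1, max(0, best$value))
  list(location = as.numeric(loc), moment = as.numeric(m), rv = rv)
}
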