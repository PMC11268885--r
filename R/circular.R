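#' Wrap angles to the circle
#'
#' Wraps angles in degrees into the half-open interval (-180, 180]. The
#' boundary case of exactly 180 degrees (mod 360) maps to +180 by convention,
#' so the wrap is deterministic on the full circle.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in (-180, 180].
#' @export
wrap180 <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  # x %% 360 never returns 360 for finite x, so only the -180 edge needs care
  w[w == -180] <- 180
  w
}

#' Wrap angles to [0, 360)
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in [0, 360).
#' @export
wrap360 <- function(x) x %% 360

#' Signed circular difference
#'
#' Signed difference `a - b` on the circle, in degrees, wrapped to
#' (-180, 180]. Antisymmetric except at the 180-degree boundary, which maps
#' to +180 for both orders.
#'
#' @param a,b Angles in degrees (any real values; reduced mod 360).
#' @return Signed difference in degrees, in (-180, 180].
#' @examples
#' circ_diff(10, 350)  # +20
#' circ_diff(350, 10)  # -20
#' circ_diff(0, 180)   # +180 (boundary convention)
#' @export
circ_diff <- function(a, b) wrap180(a - b)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Mean resultant length of a sample of angles
#'
#' @param deg Angles in degrees.
#' @return Mean resultant length R in [0, 1].
#' @export
resultant_length <- function(deg) {
  th <- deg2rad(deg)
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Circular standard deviation
#'
#' sigma = sqrt(-2 log R), with R the mean resultant length of the angles.
#' Input is taken in degrees; the result is in radians so that its reciprocal
#' (memory precision) is scale-consistent.
#'
#' @param deg Numeric vector of angles in degrees; at least 2 finite values.
#' @return Circular SD in radians (0 when all angles coincide).
#' @export
circular_sd <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) < 2L)
    stop("circular_sd() needs at least 2 finite angles")
  R <- resultant_length(deg)
  R <- min(R, 1)  # guard FP overshoot
  sqrt(-2 * log(R))
}

#' Memory precision (reciprocal circular SD)
#'
#' Precision of a set of response errors, defined as 1/sigma with sigma the
#' circular standard deviation in radians. A degenerate sample with sigma = 0
#' (all errors identical) is rejected unless a finite `cap` is supplied, in
#' which case the capped value is returned with attribute `capped = TRUE`.
#'
#' @param errors Response errors in degrees.
#' @param cap Optional finite precision returned when sigma = 0.
#' @return Precision in 1/radians.
#' @export
memory_precision <- function(errors, cap = NULL) {
  s <- circular_sd(errors)
  if (s == 0) {
    if (is.null(cap))
      stop("all errors identical (sigma = 0); precision undefined, supply `cap`")
    return(structure(cap, capped = TRUE))
  }
  1 / s
}

#' Closed-form circular SD of a von Mises distribution
#'
#' sigma(kappa) = sqrt(-2 log(I1(kappa)/I0(kappa))), in radians. Used as the
#' calibration oracle for the behavioral noise simulator.
#'
#' @param kappa Concentration parameter (> 0).
#' @return Circular SD in radians.
#' @export
vm_circular_sd <- function(kappa) {
  stopifnot(kappa > 0)
  # expon.scaled avoids overflow for large kappa; the ratio is unchanged
  R <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(-2 * log(R))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Mean direction `mu` in degrees,
#' concentration `kappa`. Returns angles in degrees in [0, 360).
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (> 0). Large kappa approaches a wrapped normal
#'   with SD 1/sqrt(kappa) radians.
#' @return Numeric vector of angles in degrees.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa > 0)
  if (n == 0L) return(numeric(0))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, ceiling(1.3 * (n - length(out))))  # batched rejection
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    out <- c(out, (sign(u3 - 0.5) * acos(f))[ok])
  }
  wrap360(mu + rad2deg(out[seq_len(n)]))
}

#' Fisher-Lee circular correlation coefficient
#'
#' Pairwise-sine estimator:
#' r = sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) /
#'     sqrt(sum sin^2(a_i - a_j) * sum sin^2(b_i - b_j)).
#' Invariant to adding a constant angle to either list; +1 for b = a,
#' -1 for b = -a.
#'
#' @param a,b Paired angle vectors in degrees (equal length >= 2).
#' @return Correlation in [-1, 1]; NA with a warning for degenerate
#'   (zero circular variance) input.
#' @export
circ_cor <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ar <- deg2rad(a); br <- deg2rad(b)
  sa <- outer(ar, ar, `-`); sb <- outer(br, br, `-`)
  ut <- upper.tri(sa)
  num <- sum(sin(sa[ut]) * sin(sb[ut]))
  d1 <- sum(sin(sa[ut])^2); d2 <- sum(sin(sb[ut])^2)
  if (d1 == 0 || d2 == 0) {
    warning("degenerate (zero-variance) input; circular correlation undefined")
    return(NA_real_)
  }
  num / sqrt(d1 * d2)
}
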