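# Circular statistics: phase-locking value, mean direction, Rayleigh test.

#' Phase-locking value of a set of angles
#'
#' Modulus of the mean resultant vector, `|mean(exp(i * theta))|`:
#' 0 for uniform angles, 1 for identical angles.
#'
#' @param angles angles in radians.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(angles) {
  if (length(angles) == 0) stop("empty angle set")
  Mod(mean(exp(1i * angles)))
}

#' Circular mean direction
#'
#' @param angles angles in radians.
#' @return mean angle in `(-pi, pi]`.
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0) stop("empty angle set")
  Arg(mean(exp(1i * angles)))
}

#' Rayleigh test of circular uniformity
#'
#' Statistic `z = n * PLV^2`; p value via the standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - z n)) - (1 + 2n))`.
#'
#' @param angles angles in radians.
#' @return list with `z` and `p`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n == 0) stop("empty angle set")
  r <- plv(angles)
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - z * n)) - (1 + 2 * n))
  list(z = z, p = min(max(p, 0), 1))
}

#' Summarize a set of circular angles
#'
#' @param angles angles in radians.
#' @return a `phase_stats` object: `angles`, `mean_angle`, `plv`,
#'   `rayleigh_z`, `rayleigh_p`, `n`.
#' @export
phase_stats <- function(angles) {
  if (length(angles) == 0) stop("empty angle set")
  rt <- rayleigh_test(angles)
  structure(list(angles = angles, mean_angle = circular_mean(angles),
                 plv = plv(angles), rayleigh_z = rt$z, rayleigh_p = rt$p,
                 n = length(angles)),
            class = "phase_stats")
}

#' @export
print.phase_stats <- function(x, ...) {
  cat(sprintf("<phase_stats> n = %d, mean angle = %.2f rad, PLV = %.3f, Rayleigh z = %.2f (p = %.3g)\n",
              x$n, x$mean_angle, x$plv, x$rayleigh_z, x$rayleigh_p))
  invisible(x)
}
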