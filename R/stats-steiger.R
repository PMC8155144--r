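#' Steiger's Z for two dependent correlations sharing a variable
#'
#' Compares r(x,y) against r(x,z) measured on the same n cases, using
#' Steiger's Z1* statistic: the difference of Fisher z transforms scaled by
#' the common-element covariance term evaluated at the averaged
#' correlation,
#' \deqn{Z = (z_{xy} - z_{xz}) \sqrt{\frac{n-3}{2 - 2 s}}, \quad
#'       s = \frac{\bar\psi}{(1-\bar r^2)^2},}
#' with \eqn{\bar r = (r_{xy}+r_{xz})/2} and
#' \eqn{\bar\psi = r_{yz}(1-2\bar r^2) - \tfrac12 \bar r^2
#' (1 - 2\bar r^2 - r_{yz}^2)}. Two-tailed p from the standard normal.
#' Z is exactly 0 when the two correlations are equal and flips sign when
#' they are swapped.
#'
#' @param r_xy,r_xz The two correlations being compared (share variable x).
#' @param r_yz The correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @return One-row tibble: `r_xy`, `r_xz`, `r_yz`, `n`, `statistic`,
#'   `p.value`.
#' @export
#' @examples
#' steiger_z(0.473, -0.085, 0.1, 37)
steiger_z <- function(r_xy, r_xz, r_yz, n) {
  rs <- c(r_xy, r_xz, r_yz)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    abort("correlations must be finite with |r| < 1.")
  }
  if (n < 4) abort("need n >= 4.")
  z_xy <- atanh(r_xy)
  z_xz <- atanh(r_xz)
  rbar <- (r_xy + r_xz) / 2
  psi <- r_yz * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_yz^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z_xy - z_xz) * sqrt((n - 3) / (2 - 2 * s))
  tibble(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz, n = n,
         statistic = z, p.value = 2 * pnorm(-abs(z)))
}
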