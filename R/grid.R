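#' Build a square imaging grid
#'
#' Discretizes the square domain of interest into `pixels` x `pixels` square
#' cells. Pixel centers are enumerated row-major: x increases fastest, then y,
#' with the origin at the domain center. Each cell carries the equivalent
#' radius `a_eq = sqrt(dx * dy / pi)` of the equal-area disc used by the
#' pulse-basis method-of-moments discretization.
#'
#' @param extent Side length of the square domain, in meters.
#' @param pixels Number of pixels per side (integer, >= 2).
#' @return An object of class `mwi_grid`: a list with fields `extent`, `M`,
#'   `N = M^2`, `dx`, `dy`, `centers` (N x 2 matrix of pixel-center
#'   coordinates, meters) and `a_eq` (equivalent cell radius, meters).
#' @examples
#' g <- build_grid(0.18, 64)
#' g$dx           # 0.0028125 m
#' @export
build_grid <- function(extent, pixels) {
  if (!is_number(extent) || extent <= 0)
    abort_argument("`extent` must be a positive length in meters, got %s",
                   format(extent))
  if (!is_count(pixels) || pixels < 2)
    abort_argument("`pixels` must be an integer >= 2, got %s", format(pixels))
  M <- as.integer(pixels)
  dx <- extent / M
  ax <- -extent / 2 + (seq_len(M) - 0.5) * dx
  centers <- cbind(x = rep(ax, times = M), y = rep(ax, each = M))
  structure(list(
    extent = extent, M = M, N = M * M, dx = dx, dy = dx,
    centers = centers, a_eq = sqrt(dx * dx / pi)
  ), class = "mwi_grid")
}

#' @export
print.mwi_grid <- function(x, ...) {
  cat(sprintf("<mwi_grid> %d x %d pixels over %.3g x %.3g m (dx = %.4g m)\n",
              x$M, x$M, x$extent, x$extent, x$dx))
  invisible(x)
}

#' Describe the homogeneous background medium
#'
#' Collects the background relative permittivity, conductivity, and the
#' frequency list of the acquisition, together with the per-frequency angular
#' frequency and background wavenumber `k_b = omega * sqrt(eps_b * mu0)`.
#'
#' @param eps_rb Background relative permittivity (dimensionless).
#' @param sigma_b Background conductivity, S/m.
#' @param frequencies Vector of F distinct positive frequencies, Hz.
#' @return An object of class `mwi_medium` with fields `eps_rb`, `sigma_b`,
#'   `eps_b` (absolute permittivity, F/m), `mu0`, `frequencies`, `omega`,
#'   `k_b` and `F` (number of frequencies).
#' @examples
#' med <- background_medium(10, 0, frequencies = c(3e8, 6e8))
#' med$k_b
#' @export
background_medium <- function(eps_rb, sigma_b = 0, frequencies) {
  if (!is_number(eps_rb) || eps_rb < 1)
    abort_argument("`eps_rb` must be a relative permittivity >= 1")
  if (!is_number(sigma_b) || sigma_b < 0)
    abort_argument("`sigma_b` must be a non-negative conductivity in S/m")
  if (!is.numeric(frequencies) || length(frequencies) < 1 ||
      any(!is.finite(frequencies)) || any(frequencies <= 0))
    abort_argument("`frequencies` must be one or more positive values in Hz")
  if (anyDuplicated(frequencies))
    abort_argument("`frequencies` must be distinct")
  frequencies <- as.numeric(frequencies)
  omega <- 2 * pi * frequencies
  eps_b <- eps_rb * .eps0
  structure(list(
    eps_rb = eps_rb, sigma_b = sigma_b, eps_b = eps_b, mu0 = .mu0,
    frequencies = frequencies, omega = omega,
    k_b = omega * sqrt(eps_b * .mu0), F = length(frequencies)
  ), class = "mwi_medium")
}

#' Default 15-frequency acquisition band
#'
#' Equispaced frequency list from 600 kHz to 600 MHz, the default scattered
#' field sampling band for the circular validation experiment.
#'
#' @param n Number of frequencies.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function(n = 15) {
  if (!is_count(n) || n < 1) abort_argument("`n` must be a positive integer")
  if (n == 1) return(600e6)
  seq(600e3, 600e6, length.out = n)
}
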