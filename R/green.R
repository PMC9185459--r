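# Discretized 2D Green operators for the pulse-basis method-of-moments EFIE.
#
# Off-diagonal coefficient (source cell replaced by the equal-area disc of
# radius a, target at distance R > 0):
#   g = -(j/2) * pi * k_b * a * J1(k_b a) * H0^(2)(k_b R)
# Self term (observation inside the source cell):
#   g_nn = -(j/2) * (pi * k_b * a * H1^(2)(k_b a) - 2j)
# Both follow from k_b^2 * integral of -(j/4) H0^(2) over the disc.

green_coeff <- function(kb, a, dist) {
  -0.5i * pi * kb * a * besselJ(kb * a, 1) * hankel2(kb * dist, 0)
}

green_self <- function(kb, a) {
  -0.5i * (pi * kb * a * hankel2(kb * a, 1) - 2i)
}

#' Domain-to-domain Green matrix
#'
#' Builds the `N x N` (or `|subset| x |subset|`) matrix of discretized Green
#' coefficients between pixel cells of a grid at background wavenumber
#' `k_b`, with the equal-area-disc self term on the diagonal. Because pixel
#' centers lie on a regular lattice, the radial kernel is evaluated once per
#' lattice displacement and then indexed, so the cost of Bessel evaluations
#' is O(M^2) rather than O(N^2).
#'
#' @param grid An [build_grid()] grid.
#' @param k_b Background wavenumber, 1/m.
#' @param subset Optional integer vector of pixel indices; the matrix is
#'   restricted to those cells (used for compact-support scatterers).
#' @return Complex symmetric matrix.
#' @export
green_domain <- function(grid, k_b, subset = NULL) {
  if (!inherits(grid, "mwi_grid")) abort_argument("`grid` must be an mwi_grid")
  if (!is_number(k_b) || k_b <= 0) abort_argument("`k_b` must be positive")
  M <- grid$M
  idx <- if (is.null(subset)) seq_len(grid$N) else as.integer(subset)
  if (length(idx) < 1 || any(idx < 1 | idx > grid$N))
    abort_argument("`subset` indices out of range")
  # kernel table over all lattice displacements
  rel <- (1 - M):(M - 1)
  D <- grid$dx * sqrt(outer(rel^2, rel^2, "+"))
  tab <- matrix(0i, 2 * M - 1, 2 * M - 1)
  nz <- D > 0
  tab[nz] <- green_coeff(k_b, grid$a_eq, D[nz])
  tab[M, M] <- green_self(k_b, grid$a_eq)
  ix <- ((idx - 1L) %% M) + 1L
  iy <- ((idx - 1L) %/% M) + 1L
  lin <- outer(ix, ix, "-") + M + (2L * M - 1L) * (outer(iy, iy, "-") + M - 1L)
  matrix(tab[lin], length(idx), length(idx))
}

#' Domain-to-receiver Green matrix
#'
#' The `Nr x N` matrix mapping contrast currents in the grid cells to
#' scattered fields at the receiver positions, using the same equal-area
#' disc coefficient as [green_domain()] with receiver-to-cell distances.
#' No self term arises; a receiver coincident with a pixel center is an
#' error (singular kernel).
#'
#' @param grid An [build_grid()] grid.
#' @param array An [antenna_array()] (its receivers are used), or an
#'   `n x 2` matrix of receiver positions in meters.
#' @param k_b Background wavenumber, 1/m.
#' @param subset Optional pixel-index subset (columns restricted).
#' @return Complex `Nr x length(subset)` matrix.
#' @export
green_data <- function(grid, array, k_b, subset = NULL) {
  if (!inherits(grid, "mwi_grid")) abort_argument("`grid` must be an mwi_grid")
  if (!is_number(k_b) || k_b <= 0) abort_argument("`k_b` must be positive")
  rec <- if (inherits(array, "mwi_array")) array$rec else array
  if (!is.matrix(rec) || ncol(rec) != 2)
    abort_argument("receiver positions must be an n x 2 matrix")
  idx <- if (is.null(subset)) seq_len(grid$N) else as.integer(subset)
  cx <- grid$centers[idx, 1]; cy <- grid$centers[idx, 2]
  D <- sqrt(outer(rec[, 1], cx, "-")^2 + outer(rec[, 2], cy, "-")^2)
  if (any(D < grid$dx * 1e-9))
    abort_argument("a receiver coincides with a pixel center (singular kernel)")
  matrix(green_coeff(k_b, grid$a_eq, D), nrow(rec), length(idx))
}
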