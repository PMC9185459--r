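#' Circular antenna array
#'
#' `n_sources` transmitting line sources and `n_receivers` receiving
#' antennas, each equispaced on a circle of the given radius centered at the
#' origin.
#'
#' @param n_sources Number of line sources (Ni).
#' @param n_receivers Number of receivers (Nr).
#' @param radius Array radius, meters.
#' @param source_offset,receiver_offset Angular offsets, radians.
#' @return An object of class `mwi_array` with position matrices `src`
#'   (Ni x 2) and `rec` (Nr x 2).
#' @export
antenna_array <- function(n_sources, n_receivers, radius,
                          source_offset = 0, receiver_offset = 0) {
  if (!is_count(n_sources) || n_sources < 1)
    abort_argument("`n_sources` must be a positive integer")
  if (!is_count(n_receivers) || n_receivers < 1)
    abort_argument("`n_receivers` must be a positive integer")
  if (!is_number(radius) || radius <= 0)
    abort_argument("`radius` must be positive (meters)")
  circ <- function(n, off) {
    th <- 2 * pi * (seq_len(n) - 1) / n + off
    cbind(x = radius * cos(th), y = radius * sin(th))
  }
  structure(list(n_sources = as.integer(n_sources),
                 n_receivers = as.integer(n_receivers),
                 radius = radius,
                 src = circ(n_sources, source_offset),
                 rec = circ(n_receivers, receiver_offset)),
            class = "mwi_array")
}

#' Incident line-source fields
#'
#' Unit-amplitude 2D line-source fields
#' `E_i(r_n; r_p) = A * H0^(2)(k_b |r_n - r_p|)` evaluated at every pixel
#' center, for every source and frequency.
#'
#' @param array An [antenna_array()].
#' @param grid An [build_grid()] grid.
#' @param medium An [background_medium()].
#' @param amplitude Source amplitude `A` (default 1).
#' @param subset Optional pixel-index subset.
#' @return Complex array with dimensions `(pixels, sources, frequencies)`.
#' @export
incident_fields <- function(array, grid, medium, amplitude = 1,
                            subset = NULL) {
  if (!inherits(array, "mwi_array")) abort_argument("`array` must be an mwi_array")
  if (!inherits(grid, "mwi_grid")) abort_argument("`grid` must be an mwi_grid")
  if (!inherits(medium, "mwi_medium")) abort_argument("`medium` must be an mwi_medium")
  idx <- if (is.null(subset)) seq_len(grid$N) else as.integer(subset)
  D <- sqrt(outer(grid$centers[idx, 1], array$src[, 1], "-")^2 +
            outer(grid$centers[idx, 2], array$src[, 2], "-")^2)
  if (any(D < grid$dx * 1e-9))
    abort_argument("a source coincides with a pixel center (singular field)")
  out <- base::array(0i, dim = c(length(idx), array$n_sources, medium$F))
  if (amplitude == 0) return(out)
  for (f in seq_len(medium$F))
    out[, , f] <- amplitude * hankel2(medium$k_b[f] * D, 0)
  out
}

#' Solve the discretized state equation for the total field
#'
#' Solves `(I - G_D diag(chi)) E_t = E_i` for one frequency; columns of
#' `E_i` are independent incidences. The linear-system residual is checked
#' and a near-singular (resonant) system raises a solver error with a
#' conditioning diagnostic.
#'
#' @param E_i Complex `N x L` matrix (or length-N vector) of incident fields.
#' @param G_D Complex `N x N` domain Green matrix.
#' @param chi Complex contrast vector, length N.
#' @param check Verify the residual of the solve (default `TRUE`; inner
#'   loops that monitor their own residuals may disable it).
#' @return Complex `N x L` matrix of total fields.
#' @export
solve_total_field <- function(E_i, G_D, chi, check = TRUE) {
  if (is.vector(E_i)) E_i <- matrix(E_i, ncol = 1)
  N <- nrow(E_i)
  if (!is.matrix(G_D) || nrow(G_D) != N || ncol(G_D) != N ||
      length(chi) != N)
    abort_argument("inconsistent dimensions between E_i, G_D and chi")
  if (all(chi == 0)) return(E_i)
  A <- -G_D * rep(chi, each = N)
  diag(A) <- diag(A) + 1
  E_t <- tryCatch(solve(A, E_i), error = function(e)
    abort_solver("total-field system is singular or near-singular: %s",
                 conditionMessage(e)))
  if (check) {
    rel <- sqrt(sum(Mod(A %*% E_t - E_i)^2)) /
      max(sqrt(sum(Mod(E_i)^2)), 1e-300)
    if (!is.finite(rel) || rel > 1e-8)
      abort_solver(
        "total-field solve residual %.3g exceeds tolerance (rcond ~ %.3g)",
        rel, rcond(A))
  }
  E_t
}

#' Scattered field at the receivers
#'
#' Evaluates the discretized data equation
#' `E_s,m = sum_n g_mn chi_n E_t,n` for each receiver row of `G_S`.
#'
#' @param G_S Complex `Nr x N` receiver Green matrix.
#' @param chi Complex contrast vector, length N.
#' @param E_t Complex `N x L` total-field matrix (or length-N vector).
#' @return Complex `Nr x L` matrix.
#' @export
scattered_at_receivers <- function(G_S, chi, E_t) {
  if (is.vector(E_t)) E_t <- matrix(E_t, ncol = 1)
  if (ncol(G_S) != nrow(E_t) || length(chi) != nrow(E_t))
    abort_argument("inconsistent dimensions between G_S, chi and E_t")
  G_S %*% (chi * E_t)
}

#' Simulate a multi-source multi-frequency scattering dataset
#'
#' Renders the phantom on a fine grid, solves the forward problem for every
#' frequency and source, and samples the scattered field at the receivers.
#' The total-field system is solved exactly (dense LU) on the support of the
#' contrast, which is compact for a phantom in its background medium.
#' Optional complex white Gaussian noise is added at a prescribed SNR,
#' defined on the per-frequency dataset norm.
#'
#' @param phantom An `mwi_phantom` (re-rendered at `fine_pixels` if needed;
#'   see [render_phantom()]).
#' @param array An [antenna_array()].
#' @param medium An [background_medium()].
#' @param fine_pixels Simulation grid pixels per side.
#' @param noise_snr_db Optional SNR in dB; `NULL` (default) for noiseless.
#' @param noise_seed Seed for the noise draw.
#' @param born If `TRUE`, use the first-order Born approximation
#'   (`E_t = E_i`) instead of the full total-field solve.
#' @return An object of class `mwi_dataset`: complex array `E_s` with
#'   dimensions `(F, L, Nr)` plus the array, medium and provenance metadata
#'   needed to rebuild the inversion operators.
#' @export
simulate_dataset <- function(phantom, array, medium, fine_pixels,
                             noise_snr_db = NULL, noise_seed = 1L,
                             born = FALSE) {
  if (!inherits(phantom, "mwi_phantom"))
    abort_argument("`phantom` must be an mwi_phantom")
  if (!is_count(fine_pixels) || fine_pixels < 2)
    abort_argument("`fine_pixels` must be an integer >= 2")
  if (phantom$grid$M != fine_pixels)
    phantom <- render_phantom(phantom, fine_pixels)
  grid <- phantom$grid
  supp <- which(phantom$labels != "background" |
                phantom$eps_r != phantom$eps_bg |
                phantom$sigma != phantom$sigma_bg)
  rec_d <- sqrt(outer(array$rec[, 1], grid$centers[supp, 1], "-")^2 +
                outer(array$rec[, 2], grid$centers[supp, 2], "-")^2)
  if (length(supp) && any(rec_d < grid$dx / 2))
    abort_argument("a receiver lies inside the phantom support")
  L <- array$n_sources
  Es <- base::array(0i, dim = c(medium$F, L, array$n_receivers))
  if (length(supp)) {
    E_i <- incident_fields(array, grid, medium, subset = supp)
    skey <- sprintf("%d_%d_%.6g_%.6g", grid$M, length(supp),
                    sum(as.numeric(supp)), sum(as.numeric(supp)^2))
    rkey <- sprintf("%d_%.9g", array$n_receivers, array$radius)
    # domain Green blocks above ~32 MB are not memoized (a 150-grid
    # support block is ~200 MB; caching one per frequency would exhaust
    # memory long before it paid off)
    cache_ok <- length(supp) <= 1500
    for (f in seq_len(medium$F)) {
      chi <- contrast_map(phantom, medium, f)[supp]
      kb <- medium$k_b[f]
      G_S <- cache_get(sprintf("GSsub|%s|%s|%.12g", skey, rkey, kb),
                       green_data(grid, array, kb, subset = supp))
      if (born) {
        E_t <- E_i[, , f, drop = TRUE]
      } else {
        G_D <- if (cache_ok)
          cache_get(sprintf("GDsub|%s|%.12g", skey, kb),
                    green_domain(grid, kb, subset = supp))
        else green_domain(grid, kb, subset = supp)
        E_t <- solve_total_field(E_i[, , f, drop = TRUE], G_D, chi)
      }
      Es[f, , ] <- t(scattered_at_receivers(G_S, chi, E_t))
    }
  }
  noise <- list(type = "none")
  if (!is.null(noise_snr_db)) {
    Es <- with_seed(noise_seed, {
      for (f in seq_len(medium$F)) {
        p_sig <- mean(Mod(Es[f, , ])^2)
        sd_n <- sqrt(p_sig * 10^(-noise_snr_db / 10) / 2)
        Es[f, , ] <- Es[f, , ] +
          complex(real = rnorm(L * array$n_receivers, sd = sd_n),
                  imaginary = rnorm(L * array$n_receivers, sd = sd_n))
      }
      Es
    })
    noise <- list(type = "awgn", snr_db = noise_snr_db,
                  seed = as.integer(noise_seed))
  }
  structure(list(E_s = Es, array = array, medium = medium,
                 fine_M = grid$M, extent = grid$extent,
                 noise = noise, born = born),
            class = "mwi_dataset")
}

#' @export
print.mwi_dataset <- function(x, ...) {
  cat(sprintf(
    "<mwi_dataset> %d frequencies x %d sources x %d receivers (fine grid %d)\n",
    dim(x$E_s)[1], dim(x$E_s)[2], dim(x$E_s)[3], x$fine_M))
  invisible(x)
}

#' Re-render a generated phantom at a different resolution
#'
#' Phantoms produced by [circular_phantom()] or [synthetic_breast_phantom()]
#' carry their generating parameters and can be re-rendered on any grid over
#' the same extent; hand-built phantoms cannot.
#'
#' @param phantom An `mwi_phantom`.
#' @param pixels Target pixels per side.
#' @return An `mwi_phantom` on the new grid.
#' @export
render_phantom <- function(phantom, pixels) {
  if (phantom$grid$M == pixels) return(phantom)
  g <- build_grid(phantom$grid$extent, pixels)
  kind <- phantom$meta$kind %||% "custom"
  if (kind == "circular") {
    circular_phantom(g, background_eps = phantom$eps_bg,
                     tumor_center = phantom$meta$tumor_center,
                     sigma_b = phantom$sigma_bg)
  } else if (kind == "breast") {
    synthetic_breast_phantom(phantom$meta$class_id, phantom$meta$tumor,
                             phantom$meta$seed, grid = g,
                             eps_rb = phantom$eps_bg,
                             sigma_b = phantom$sigma_bg)
  } else {
    abort_argument("phantom of kind '%s' cannot be re-rendered", kind)
  }
}
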