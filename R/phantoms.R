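#' @section Phantom objects:
#' A phantom map (`mwi_phantom`) stores per-pixel relative permittivity and
#' conductivity on an [build_grid()] grid together with region labels and the
#' background values the phantom is immersed in. Pixels labelled
#' `"background"` hold the background values exactly, so the complex contrast
#' vanishes there identically.
#' @name phantoms
NULL

# Subsample points for anti-aliased (area-averaged) rendering: each pixel
# is sampled on a k x k lattice so sub-pixel structures (small tumors,
# curved region boundaries) contribute their partial-volume fraction and
# every distinct phantom specification yields a distinct map.
supersample_points <- function(grid, k = 4L) {
  o <- ((seq_len(k) - 0.5) / k - 0.5) * grid$dx
  ox <- rep(o, times = k); oy <- rep(o, each = k)
  k2 <- k * k
  cbind(rep(grid$centers[, 1], each = k2) + rep(ox, grid$N),
        rep(grid$centers[, 2], each = k2) + rep(oy, grid$N))
}

# Majority region label per pixel from per-subsample integer codes;
# ties resolved in favor of the code listed first.
majority_label <- function(region, k2, N, codes, names) {
  best_cnt <- rep(-1L, N)
  lab <- character(N)
  for (i in seq_along(codes)) {
    cnt <- colSums(matrix(region == codes[i], k2, N))
    take <- cnt > best_cnt
    lab[take] <- names[i]
    best_cnt[take] <- cnt[take]
  }
  lab
}

new_phantom <- function(grid, eps_r, sigma, labels, eps_bg, sigma_bg,
                        meta = list()) {
  stopifnot(length(eps_r) == grid$N, length(sigma) == grid$N,
            length(labels) == grid$N)
  structure(list(grid = grid, eps_r = eps_r, sigma = sigma, labels = labels,
                 eps_bg = eps_bg, sigma_bg = sigma_bg, meta = meta),
            class = "mwi_phantom")
}

#' @export
print.mwi_phantom <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<mwi_phantom> %d x %d pixels; eps_r in [%.3g, %.3g]\n",
              x$grid$M, x$grid$M, min(x$eps_r), max(x$eps_r)))
  cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Concentric-circle validation phantom
#'
#' The circular breast model used for validating the quadratic-programming
#' inversion: an 8 cm diameter disc with relative permittivity 40 containing
#' a 6 cm disc with permittivity 4.5, plus a 1 cm "tumor" disc with
#' permittivity 57 at a configurable position inside the inner disc. The
#' phantom is lossless: conductivity equals the background value everywhere.
#'
#' @param grid An [build_grid()] grid.
#' @param background_eps Background relative permittivity (default 10).
#' @param tumor_center Tumor-center coordinates (m), inside the 6 cm disc.
#' @param sigma_b Background conductivity, S/m (default 0).
#' @return An `mwi_phantom`.
#' @examples
#' ph <- circular_phantom(build_grid(0.18, 64))
#' @export
circular_phantom <- function(grid, background_eps = 10,
                             tumor_center = c(0.015, 0), sigma_b = 0) {
  if (!inherits(grid, "mwi_grid")) abort_argument("`grid` must be an mwi_grid")
  if (!is.numeric(tumor_center) || length(tumor_center) != 2)
    abort_argument("`tumor_center` must be an (x, y) pair in meters")
  if (sqrt(sum(tumor_center^2)) >= 0.03)
    abort_argument("tumor center (%.3g, %.3g) m lies outside the 6 cm disc",
                   tumor_center[1], tumor_center[2])
  k <- 4L; k2 <- k * k
  pts <- supersample_points(grid, k)
  r <- sqrt(rowSums(pts^2))
  rt <- sqrt((pts[, 1] - tumor_center[1])^2 + (pts[, 2] - tumor_center[2])^2)
  region <- integer(length(r))                  # 0 = background
  region[r <= 0.04] <- 1L                       # annulus, eps 40
  region[r <= 0.03] <- 2L                       # interior, eps 4.5
  region[rt <= 0.005] <- 3L                     # tumor, eps 57
  epsv <- c(background_eps, 40, 4.5, 57)[region + 1L]
  eps <- colMeans(matrix(epsv, k2, grid$N))
  # a pixel is background only when untouched by any region, so labelled
  # background implies exactly zero contrast; mixed boundary pixels take
  # their majority tissue label
  labels <- majority_label(region, k2, grid$N, codes = 3:1,
                           names = c("tumor", "interior", "annulus"))
  labels[colSums(matrix(region > 0L, k2, grid$N)) == 0L] <- "background"
  new_phantom(grid, eps, rep(sigma_b, grid$N), labels,
              eps_bg = background_eps, sigma_bg = sigma_b,
              meta = list(kind = "circular", tumor_center = tumor_center))
}

#' Tumor specification
#'
#' @param diameter Tumor diameter, meters.
#' @param center Tumor center (x, y), meters.
#' @return A `tumor_spec` list.
#' @export
tumor_spec <- function(diameter, center) {
  if (!is_number(diameter) || diameter <= 0 || diameter > 0.02)
    abort_argument("`diameter` must be a tumor diameter in (0, 0.02] m")
  if (!is.numeric(center) || length(center) != 2 || any(!is.finite(center)))
    abort_argument("`center` must be an (x, y) pair in meters")
  structure(list(diameter = diameter, center = as.numeric(center)),
            class = "tumor_spec")
}

#' The nine tumor positions of the training sweep
#'
#' @return A 9 x 2 matrix of (x, y) tumor centers in meters:
#'   combinations of 0 and +/-1.9 cm.
#' @export
tumor_positions <- function() {
  p <- 0.019
  m <- rbind(c(0, 0), c(0, p), c(0, -p), c(p, 0), c(-p, 0),
             c(p, p), c(-p, p), c(p, -p), c(-p, -p))
  colnames(m) <- c("x", "y")
  m
}

#' The three tumor diameters of the training sweep
#' @return Numeric vector c(0.003, 0.005, 0.008) m.
#' @export
tumor_diameters <- function() c(0.003, 0.005, 0.008)

# Class-calibrated fibroglandular area fractions of the breast interior,
# increasing from almost-entirely-fatty (class 1) to very dense (class 4).
.gland_fractions <- c(0.12, 0.30, 0.50, 0.70)

# Breast geometry and tissue permittivities (values at ~1 GHz)
.breast_geom <- list(r_outer = 0.072, r_inner = 0.068,
                     eps_skin = 38, eps_fat = 5, eps_gland_lo = 38,
                     eps_gland_hi = 52, eps_tumor = 60)

# Smooth random texture: a seeded sum of Gaussian blobs. A continuous
# function of position, so rendering is resolution-independent.
.blob_field <- function(seed, r_inner) {
  with_seed(seed, {
    K <- 40L
    rad <- r_inner * 0.95 * sqrt(runif(K))
    th <- runif(K, 0, 2 * pi)
    cx <- rad * cos(th); cy <- rad * sin(th)
    sd <- runif(K, 0.008, 0.020)
    amp <- rnorm(K)
    list(cx = cx, cy = cy, sd = sd, amp = amp)
  })
}

.eval_field <- function(fld, pts) {
  v <- numeric(nrow(pts))
  for (k in seq_along(fld$amp)) {
    d2 <- (pts[, 1] - fld$cx[k])^2 + (pts[, 2] - fld$cy[k])^2
    v <- v + fld$amp[k] * exp(-d2 / (2 * fld$sd[k]^2))
  }
  v
}

#' Synthetic layered breast phantom
#'
#' Procedurally generates a 2D breast slice of one of four density classes:
#' an outer skin ring, a fatty interior, and fibroglandular tissue drawn as
#' thresholded smooth random blobs whose area fraction increases with
#' `class_id`. A tumor disc with permittivity near the top of the
#' physiological 2.5-67 range is implanted at one of the nine sweep
#' positions (see [tumor_positions()]). Conductivity is derived from the
#' permittivity map via the linear regression model
#' [conductivity_from_permittivity()]. Identical arguments (including
#' `seed`) produce bit-identical phantoms, and the blob threshold is
#' calibrated on a fixed internal reference grid so the same phantom can be
#' rendered consistently at any resolution.
#'
#' @param class_id Breast density class, 1 (fatty) to 4 (very dense).
#' @param tumor A [tumor_spec()]; its center must be one of the nine sweep
#'   positions.
#' @param seed Integer seed controlling the fibroglandular texture.
#' @param grid Render grid (default: 64 x 64 over 18 cm).
#' @param eps_rb,sigma_b Background (immersion medium) properties.
#' @return An `mwi_phantom` with labels in
#'   background/skin/fat/gland/tumor and all tissue permittivities in
#'   `[2.5, 67]`.
#' @export
synthetic_breast_phantom <- function(class_id, tumor, seed,
                                     grid = build_grid(0.18, 64),
                                     eps_rb = 10, sigma_b = 0) {
  if (!is_count(class_id) || !(class_id %in% 1:4))
    abort_argument("`class_id` must be one of 1, 2, 3, 4")
  if (!inherits(tumor, "tumor_spec"))
    abort_argument("`tumor` must be a tumor_spec()")
  pos <- tumor_positions()
  d <- sqrt((pos[, 1] - tumor$center[1])^2 + (pos[, 2] - tumor$center[2])^2)
  if (min(d) > 1e-9)
    abort_argument(
      "tumor center (%.4g, %.4g) m is not one of the nine sweep positions",
      tumor$center[1], tumor$center[2])
  if (!is_count(seed)) abort_argument("`seed` must be an integer")
  g <- .breast_geom
  fld <- .blob_field(seed, g$r_inner)

  # class threshold from a fixed reference grid, independent of `grid`
  ref <- build_grid(grid$extent, 160L)
  rr <- sqrt(rowSums(ref$centers^2))
  vref <- .eval_field(fld, ref$centers[rr <= g$r_inner, , drop = FALSE])
  thr <- stats::quantile(vref, 1 - .gland_fractions[class_id], names = FALSE)
  vmax <- max(vref)

  k <- 4L; k2 <- k * k
  pts <- supersample_points(grid, k)
  r <- sqrt(rowSums(pts^2))
  region <- integer(length(r))                  # 0 = background
  region[r <= g$r_outer] <- 2L                  # skin
  inner <- r <= g$r_inner
  region[inner] <- 1L                           # fat
  epsv <- rep(eps_rb, length(r))
  epsv[region == 2L] <- g$eps_skin
  epsv[region == 1L] <- g$eps_fat
  v <- .eval_field(fld, pts[inner, , drop = FALSE])
  gl_in <- v > thr
  gl <- inner; gl[inner] <- gl_in
  region[gl] <- 3L                              # gland
  t01 <- pmin(1, pmax(0, (v[gl_in] - thr) / max(vmax - thr, 1e-12)))
  epsv[gl] <- g$eps_gland_lo + (g$eps_gland_hi - g$eps_gland_lo) * t01
  rt <- sqrt((pts[, 1] - tumor$center[1])^2 + (pts[, 2] - tumor$center[2])^2)
  region[rt <= tumor$diameter / 2] <- 4L        # tumor
  epsv[region == 4L] <- g$eps_tumor

  eps <- colMeans(matrix(epsv, k2, grid$N))
  labels <- majority_label(region, k2, grid$N, codes = c(4L, 3L, 2L, 1L),
                           names = c("tumor", "gland", "skin", "fat"))
  labels[colSums(matrix(region > 0L, k2, grid$N)) == 0L] <- "background"
  tissue <- labels != "background"
  sigma <- rep(sigma_b, grid$N)
  sigma[tissue] <- conductivity_from_permittivity(eps[tissue])
  new_phantom(grid, eps, sigma, labels, eps_bg = eps_rb, sigma_bg = sigma_b,
              meta = list(kind = "breast", class_id = as.integer(class_id),
                          tumor = tumor, seed = as.integer(seed)))
}

#' Enumerate the 108-phantom training sweep
#'
#' All combinations of 4 density classes, 3 tumor diameters and 9 tumor
#' positions, in a fixed deterministic order (class, then diameter, then
#' position).
#'
#' @return A data frame with columns `class_id`, `diameter`, `x`, `y`.
#' @export
phantom_sweep <- function() {
  pos <- tumor_positions()
  out <- expand.grid(position = seq_len(nrow(pos)),
                     diameter = tumor_diameters(),
                     class_id = 1:4, KEEP.OUT.ATTRS = FALSE)
  data.frame(class_id = out$class_id, diameter = out$diameter,
             x = pos[out$position, 1], y = pos[out$position, 2])
}

#' Complex contrast of a phantom in a background medium
#'
#' Computes the per-pixel complex contrast
#' `chi = (eps_r - eps_rb)/eps_rb - 1i * (sigma - sigma_b)/(omega * eps_b)`
#' at one frequency of the medium. Background pixels have exactly zero
#' contrast.
#'
#' @param phantom An `mwi_phantom`.
#' @param medium An [background_medium()].
#' @param frequency_index Index into the medium's frequency list.
#' @return Complex vector of length `N`.
#' @export
contrast_map <- function(phantom, medium, frequency_index = 1L) {
  if (!inherits(phantom, "mwi_phantom"))
    abort_argument("`phantom` must be an mwi_phantom")
  if (!inherits(medium, "mwi_medium"))
    abort_argument("`medium` must be an mwi_medium")
  if (!is_count(frequency_index) || frequency_index < 1 ||
      frequency_index > medium$F)
    abort_argument("`frequency_index` out of range 1..%d", medium$F)
  omega <- medium$omega[frequency_index]
  if (omega == 0) abort_argument("zero angular frequency")
  complex(real = (phantom$eps_r - medium$eps_rb) / medium$eps_rb,
          imaginary = -(phantom$sigma - medium$sigma_b) / (omega * medium$eps_b))
}

#' Invert a contrast map back to material maps
#'
#' Inverse of [contrast_map()]: recovers relative permittivity and
#' conductivity from a complex contrast at a given frequency.
#'
#' @param chi Complex contrast vector.
#' @param medium An [background_medium()].
#' @param frequency_index Frequency index used for the conductivity scaling.
#' @return List with numeric vectors `eps_r` and `sigma`.
#' @export
maps_from_contrast <- function(chi, medium, frequency_index = 1L) {
  omega <- medium$omega[frequency_index]
  list(eps_r = medium$eps_rb * (1 + Re(chi)),
       sigma = medium$sigma_b - Im(chi) * omega * medium$eps_b)
}

#' Area-weighted box resampling of a square map
#'
#' Resamples an `M x M` pixel map to `M_out x M_out` by exact pixel-area
#' overlap averaging (used for the fine-to-coarse grid split).
#'
#' @param mat Square numeric matrix.
#' @param M_out Output pixels per side.
#' @return `M_out x M_out` matrix.
#' @export
box_resample <- function(mat, M_out) {
  M_in <- nrow(mat)
  if (ncol(mat) != M_in) abort_argument("`mat` must be square")
  if (!is_count(M_out) || M_out < 1)
    abort_argument("`M_out` must be a positive integer")
  # W[i, j] = overlap of output cell i with input cell j (unit total length)
  W <- matrix(0, M_out, M_in)
  for (i in seq_len(M_out)) {
    lo <- (i - 1) / M_out; hi <- i / M_out
    j0 <- floor(lo * M_in) + 1; j1 <- ceiling(hi * M_in)
    for (j in j0:min(j1, M_in)) {
      W[i, j] <- max(0, min(hi, j / M_in) - max(lo, (j - 1) / M_in))
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W %*% mat %*% t(W)
}

# Reshape an N-vector on a grid to an M x M matrix (x = rows, y = cols).
grid_matrix <- function(values, grid) {
  matrix(values, nrow = grid$M, ncol = grid$M)
}
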