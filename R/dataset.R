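#' Default scaled study conditions for the breast-phantom sweep
#'
#' Problem sizes used by [make_training_set()] and the end-to-end pipeline
#' for the 108-phantom sweep: simulation (fine) grid, inversion grid,
#' frequency list, array geometry, and Born-iteration settings. Chosen so a
#' full sweep runs on a single CPU in minutes while keeping the fine grid
#' strictly finer than the inversion grid (no inverse crime).
#'
#' @param inversion_pixels Inversion/reconstruction grid side (default 32).
#' @param fine_pixels Simulation grid side (default 48).
#' @param n_freq Number of frequencies, equispaced over 600 MHz-1 GHz (the
#'   breast experiments operate around 1 GHz, where the 18 cm domain spans
#'   3/5 of a background wavelength).
#' @param n_sources,n_receivers Array size (18 sources and 18 receivers in
#'   the breast-phantom experiments).
#' @param iterations Born iterations per reconstruction (default 5).
#' @return List of class `sweep_config`.
#' @export
sweep_config <- function(inversion_pixels = 32L, fine_pixels = 40L,
                         n_freq = 4L, n_sources = 12L, n_receivers = 18L,
                         iterations = 5L) {
  structure(list(extent = 0.18, inversion_pixels = as.integer(inversion_pixels),
                 fine_pixels = as.integer(fine_pixels),
                 frequencies = seq(600e6, 1e9, length.out = n_freq),
                 n_sources = as.integer(n_sources),
                 n_receivers = as.integer(n_receivers),
                 radius = 0.10, eps_rb = 10, sigma_b = 0,
                 iterations = as.integer(iterations)),
            class = "sweep_config")
}

#' Assemble the 108-pair refiner training set
#'
#' For every phantom of the sweep (4 classes x 3 tumor diameters x 9
#' positions, see [phantom_sweep()]): generate the phantom, simulate its
#' scattered-field dataset on the fine grid, reconstruct it with the
#' Born-QP method on the inversion grid, and pair the reconstructed
#' permittivity map (input) with the ground-truth map rendered at the same
#' resolution (target). Pairs are produced in the deterministic sweep
#' order; a failed reconstruction is skipped with a warning. A seeded
#' shuffle defines the train/validation split.
#'
#' @param config A [sweep_config()].
#' @param base_seed Integer seed; the tissue texture of class `c` uses
#'   `base_seed + c` (one anatomy per class, as in a per-class phantom
#'   repository), and the split shuffle uses `base_seed`.
#' @param split Training fraction (default 0.9; floor rule).
#' @param subset Optional row indices of [phantom_sweep()] to restrict the
#'   sweep (for quick runs).
#' @param progress Print one line per phantom.
#' @return Object of class `mwi_training_set`: `pairs` (list of
#'   input/target map pairs with provenance), `train_idx`, `val_idx`,
#'   `sweep` (the sweep rows used), `config`.
#' @export
make_training_set <- function(config = sweep_config(), base_seed = 7L,
                              split = 0.9, subset = NULL, progress = FALSE) {
  sweep <- phantom_sweep()
  if (!is.null(subset)) sweep <- sweep[subset, , drop = FALSE]
  med <- background_medium(config$eps_rb, config$sigma_b, config$frequencies)
  arr <- antenna_array(config$n_sources, config$n_receivers, config$radius)
  inv_grid <- build_grid(config$extent, config$inversion_pixels)
  fine_grid <- build_grid(config$extent, config$fine_pixels)
  bconf <- bim_config(iterations = config$iterations, init = "constant_min")
  pairs <- list()
  for (i in seq_len(nrow(sweep))) {
    row <- sweep[i, ]
    tum <- tumor_spec(row$diameter, c(row$x, row$y))
    ph_fine <- synthetic_breast_phantom(row$class_id, tum,
                                        seed = base_seed + row$class_id,
                                        grid = fine_grid,
                                        eps_rb = config$eps_rb,
                                        sigma_b = config$sigma_b)
    pair <- tryCatch({
      ds <- simulate_dataset(ph_fine, arr, med, config$fine_pixels)
      rec <- bim_reconstruct(ds, inv_grid, bconf)
      truth <- render_phantom(ph_fine, config$inversion_pixels)
      list(input = grid_matrix(rec$eps_r, inv_grid),
           target = grid_matrix(truth$eps_r, inv_grid),
           provenance = list(class_id = row$class_id,
                             diameter = row$diameter,
                             center = c(row$x, row$y),
                             residuals = rec$residuals))
    }, error = function(e) {
      warning(sprintf("phantom %d (class %d) skipped: %s", i, row$class_id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(pair)) pairs[[length(pairs) + 1]] <- pair
    if (progress)
      message(sprintf("  phantom %d/%d (class %d, d = %g mm) done",
                      i, nrow(sweep), row$class_id, 1000 * row$diameter))
  }
  n <- length(pairs)
  perm <- with_seed(base_seed, sample(n))
  n_tr <- max(1L, floor(split * n))
  structure(list(pairs = pairs, train_idx = perm[seq_len(n_tr)],
                 val_idx = if (n_tr < n) perm[(n_tr + 1):n] else integer(0),
                 sweep = sweep, config = config, base_seed = base_seed),
            class = "mwi_training_set")
}

#' @export
print.mwi_training_set <- function(x, ...) {
  cat(sprintf("<mwi_training_set> %d pairs (%d train / %d validation)\n",
              length(x$pairs), length(x$train_idx), length(x$val_idx)))
  invisible(x)
}
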