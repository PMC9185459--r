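# Shared small fixtures. All built in code; heavier shared objects are
# memoized for the session so independent test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# A small lossless scatterer with compact support on a coarse grid,
# weak or strong contrast, used across forward/inverse tests.
toy_phantom <- function(grid, chi_scale = 0.01, seed = 3) {
  supp <- which(rowSums(abs(grid$centers) < 0.25 * grid$extent) == 2)
  chi <- complex(grid$N)
  chi[supp] <- withr::with_seed(seed, complex(
    real = runif(length(supp), 0.5, 1) * chi_scale))
  labels <- rep("background", grid$N)
  labels[supp] <- "tissue"
  ph <- bimqp:::new_phantom(grid, 10 * (1 + Re(chi)), rep(0, grid$N),
                            labels, eps_bg = 10, sigma_bg = 0,
                            meta = list(kind = "custom"))
  list(phantom = ph, chi = chi, support = supp)
}

toy_medium <- function(n_freq = 2) {
  background_medium(10, 0, seq(3e8, 6e8, length.out = n_freq))
}

# Small inversion scenario: compact scatterer on a 4 x 4 grid, two
# frequencies, overdetermined receiver set, true total fields available.
inverse_scenario <- function(chi_scale = 0.01) {
  g <- build_grid(0.18, 4)
  med <- toy_medium(2)
  arr <- antenna_array(3, 18, 0.10)
  toy <- toy_phantom(g, chi_scale = chi_scale)
  ds <- suppressWarnings(simulate_dataset(toy$phantom, arr, med, 4))
  GS <- lapply(1:2, function(f) green_data(g, arr, med$k_b[f]))
  Ei <- incident_fields(arr, g, med)
  Et <- base::array(0i, c(g$N, 3, 2))
  for (f in 1:2)
    Et[, , f] <- solve_total_field(Ei[, , f],
                                   green_domain(g, med$k_b[f]), toy$chi)
  list(g = g, med = med, arr = arr, ds = ds, GS = GS, Ei = Ei, Et = Et,
       chi = toy$chi)
}

# Frozen circular-model acquisition (printed configuration), shared by the
# acceptance tests that reconstruct it and that count its dimensions.
circular_dataset <- function() {
  fixture("circular_ds", {
    grid <- build_grid(0.18, 150)
    ph <- circular_phantom(grid)
    med <- background_medium(10, 0, default_frequencies(15))
    arr <- antenna_array(18, 30, 0.10)
    list(dataset = simulate_dataset(ph, arr, med, 150), phantom = ph)
  })
}

# The full 108-phantom sweep with reconstructions (expensive; computed
# once per test session and reused by the criteria that need it).
sweep_training_set <- function() {
  fixture("sweep_ts", make_training_set(base_seed = 7L))
}
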