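test_that("incident line-source fields have the right geometry", {
  g <- build_grid(0.18, 16)
  med <- toy_medium()
  arr <- antenna_array(4, 4, 0.10)
  Ei <- incident_fields(arr, g, med)
  expect_equal(dim(Ei), c(g$N, 4, 2))
  # two pixels equidistant from the source on the +x axis see equal fields
  d <- sqrt((g$centers[, 1] - 0.1)^2 + g$centers[, 2]^2)
  pair <- which(abs(d - d[137]) < 1e-12)
  expect_true(length(pair) >= 2)
  expect_equal(Ei[pair[1], 1, 1], Ei[pair[2], 1, 1])
  # zero amplitude gives identically zero fields
  expect_true(all(incident_fields(arr, g, med, amplitude = 0) == 0))
  # far-zone amplitude decay ~ 1/sqrt(distance)
  rfar <- build_grid(0.0005, 2)
  arr_far <- antenna_array(1, 1, 10)   # 10 m away at ~2 wavelengths/m
  E1 <- incident_fields(arr_far, rfar, med)[1, 1, 2]
  arr_far2 <- antenna_array(1, 1, 20)
  E2 <- incident_fields(arr_far2, rfar, med)[1, 1, 2]
  expect_lt(abs(Mod(E2) / Mod(E1) - 1 / sqrt(2)), 0.05 / sqrt(2))
})

test_that("total-field solve satisfies the state equation", {
  g <- build_grid(0.18, 8)
  med <- toy_medium()
  arr <- antenna_array(3, 6, 0.12)
  GD <- green_domain(g, med$k_b[1])
  Ei <- incident_fields(arr, g, med)[, , 1]
  # no scatterer: total field equals the incident field exactly
  expect_identical(solve_total_field(Ei, GD, complex(g$N)), Ei)
  # weak contrast: two-term Neumann series is accurate to O(|chi|^2)
  chi <- complex(real = rep(1e-3, g$N))
  Et <- solve_total_field(Ei, GD, chi)
  neumann <- Ei + GD %*% (chi * Ei)
  expect_lt(max(Mod(Et - neumann)) / max(Mod(Et)), 1e-5)
  # three-pixel system vs explicit dense inversion
  idx <- c(10, 30, 50)
  chi3 <- complex(real = c(0.4, -0.2, 0.9), imaginary = c(0, -0.3, 0.1))
  A3 <- diag(3) - GD[idx, idx] %*% diag(chi3)
  Et3 <- solve_total_field(Ei[idx, ], GD[idx, idx], chi3)
  expect_equal(Et3, solve(A3, Ei[idx, ]), tolerance = 1e-12)
  expect_error(solve_total_field(Ei, GD[1:4, 1:4], chi),
               class = "bimqp_argument_error")
})

test_that("the data equation is linear in the contrast", {
  g <- build_grid(0.18, 8)
  med <- toy_medium()
  arr <- antenna_array(3, 6, 0.12)
  GS <- green_data(g, arr, med$k_b[1])
  Ei <- incident_fields(arr, g, med)[, , 1]
  chi <- complex(real = runif(g$N), imaginary = -runif(g$N) / 10)
  expect_true(all(scattered_at_receivers(GS, complex(g$N), Ei) == 0))
  Es1 <- scattered_at_receivers(GS, chi, Ei)
  expect_equal(scattered_at_receivers(GS, 3 * chi, Ei), 3 * Es1)
})

test_that("simulated datasets are deterministic, reciprocal and Born-consistent", {
  g <- build_grid(0.18, 24)
  med <- toy_medium(3)
  toy <- toy_phantom(g, chi_scale = 0.5)
  arr <- antenna_array(8, 8, 0.10)   # co-located sources and receivers
  ds1 <- simulate_dataset(toy$phantom, arr, med, 24)
  ds2 <- simulate_dataset(toy$phantom, arr, med, 24)
  expect_identical(ds1$E_s, ds2$E_s)
  expect_equal(dim(ds1$E_s), c(3, 8, 8))
  # reciprocity: swapping a co-located source and receiver changes nothing
  for (f in 1:3) {
    E <- ds1$E_s[f, , ]
    expect_lt(max(Mod(E - t(E))) / max(Mod(E)), 1e-6)
  }
  # homogeneous phantom: no scattering
  ph0 <- bimqp:::new_phantom(g, rep(10, g$N), rep(0, g$N),
                             rep("background", g$N), 10, 0)
  expect_true(all(simulate_dataset(ph0, arr, med, 24)$E_s == 0))
  # first-Born agreement for very weak scatterers
  weak <- toy_phantom(g, chi_scale = 1e-3)
  full <- simulate_dataset(weak$phantom, arr, med, 24)
  born <- simulate_dataset(weak$phantom, arr, med, 24, born = TRUE)
  rel <- sqrt(sum(Mod(full$E_s - born$E_s)^2) / sum(Mod(full$E_s)^2))
  expect_lt(rel, 1e-3)
})

test_that("scattered fields converge under grid refinement", {
  med <- toy_medium(1)
  arr <- antenna_array(4, 8, 0.10)
  tum <- tumor_spec(0.008, c(0, 0))
  sim_at <- function(M) {
    ph <- synthetic_breast_phantom(1, tum, seed = 4,
                                   grid = build_grid(0.18, M))
    as.vector(simulate_dataset(ph, arr, med, M)$E_s)
  }
  e24 <- sim_at(24); e48 <- sim_at(48); e96 <- sim_at(96)
  d1 <- sqrt(sum(Mod(e48 - e24)^2) / sum(Mod(e48)^2))
  d2 <- sqrt(sum(Mod(e96 - e48)^2) / sum(Mod(e96)^2))
  expect_lt(d2, d1)
})

test_that("noise is seeded, reproducible and at the requested level", {
  g <- build_grid(0.18, 24)
  med <- toy_medium(2)
  toy <- toy_phantom(g, chi_scale = 0.5)
  arr <- antenna_array(6, 8, 0.10)
  clean <- simulate_dataset(toy$phantom, arr, med, 24)
  n1 <- simulate_dataset(toy$phantom, arr, med, 24, noise_snr_db = 20,
                         noise_seed = 42)
  n2 <- simulate_dataset(toy$phantom, arr, med, 24, noise_snr_db = 20,
                         noise_seed = 42)
  expect_identical(n1$E_s, n2$E_s)
  expect_false(identical(n1$E_s, clean$E_s))
  snr_emp <- mean(Mod(clean$E_s)^2) / mean(Mod(n1$E_s - clean$E_s)^2)
  expect_lt(abs(10 * log10(snr_emp) - 20), 2)
})
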