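test_that("build_grid produces centered, correctly pitched grids", {
  g <- build_grid(0.18, 64)
  expect_equal(g$dx, 0.0028125)
  expect_equal(g$N, 64^2)
  expect_equal(g$a_eq, sqrt(g$dx * g$dy / pi))
  expect_true(all(abs(g$centers) < 0.09))

  g150 <- build_grid(0.18, 150)
  expect_equal(g150$N, 22500)

  g2 <- build_grid(0.18, 2)
  expect_equal(sort(unique(g2$centers[, 1])), c(-0.045, 0.045))
  expect_equal(g2$centers[1, ], c(x = -0.045, y = -0.045))
  expect_equal(g2$centers[4, ], c(x = 0.045, y = 0.045))

  expect_error(build_grid(-1, 16), class = "bimqp_argument_error")
  expect_error(build_grid(0.18, 1), class = "bimqp_argument_error")
})

test_that("circular phantom has the printed region permittivities", {
  g <- build_grid(0.18, 64)
  ph <- circular_phantom(g, tumor_center = c(0, 0))
  at <- function(x, y) which.min((g$centers[, 1] - x)^2 +
                                 (g$centers[, 2] - y)^2)
  expect_equal(ph$eps_r[at(0, 0.038)], 40)   # annulus between 6 and 8 cm
  expect_equal(ph$eps_r[at(0.07, 0.07)], 10) # background
  expect_equal(ph$eps_r[at(0, 0)], 57)       # tumor at the origin
  expect_equal(ph$eps_r[at(0, 0.02)], 4.5)   # inner disc
  expect_true(all(ph$sigma == 0))
  expect_error(circular_phantom(g, tumor_center = c(0.05, 0)),
               class = "bimqp_argument_error")
})

test_that("breast phantoms are deterministic and class-ordered", {
  g <- build_grid(0.18, 64)
  tum <- tumor_spec(0.008, c(0, 0.019))
  a <- synthetic_breast_phantom(2, tum, seed = 5, grid = g)
  b <- synthetic_breast_phantom(2, tum, seed = 5, grid = g)
  expect_identical(a$eps_r, b$eps_r)
  expect_identical(a$sigma, b$sigma)
  expect_identical(a$labels, b$labels)

  counts <- vapply(1:4, function(cl)
    sum(synthetic_breast_phantom(cl, tum, seed = 5, grid = g)$labels ==
        "gland"), integer(1))
  expect_true(all(diff(counts) > 0))

  expect_true(all(a$eps_r >= 2.5 & a$eps_r <= 67))
  expect_true(all(a$sigma >= 0))
  # sigma follows the linear regression model on tissue pixels
  tissue <- a$labels != "background"
  expect_equal(a$sigma[tissue],
               conductivity_from_permittivity(a$eps_r[tissue]))

  expect_error(synthetic_breast_phantom(5, tum, 1, grid = g),
               class = "bimqp_argument_error")
  expect_error(
    synthetic_breast_phantom(1, tumor_spec(0.005, c(0.01, 0.01)), 1,
                             grid = g),
    class = "bimqp_argument_error")
})

test_that("the training sweep enumerates 108 distinct phantoms", {
  sweep <- phantom_sweep()
  expect_equal(nrow(sweep), 108)
  expect_equal(nrow(unique(sweep)), 108)
  g <- build_grid(0.18, 32)
  maps <- t(vapply(seq_len(nrow(sweep)), function(i) {
    row <- sweep[i, ]
    synthetic_breast_phantom(row$class_id,
                             tumor_spec(row$diameter, c(row$x, row$y)),
                             seed = 7 + row$class_id, grid = g)$eps_r
  }, numeric(g$N)))
  expect_equal(anyDuplicated(maps), 0)
})

test_that("contrast maps follow the adopted convention and vanish on background", {
  g <- build_grid(0.18, 32)
  med <- background_medium(10, 0.05, frequencies = c(1e9, 2e9))
  ph <- circular_phantom(g, tumor_center = c(0, 0), sigma_b = 0.05)
  chi <- contrast_map(ph, med, 1)
  at <- function(x, y) which.min((g$centers[, 1] - x)^2 +
                                 (g$centers[, 2] - y)^2)
  expect_equal(chi[at(0, 0.037)], complex(real = 3))   # (40 - 10) / 10
  expect_true(all(chi[ph$labels == "background"] == 0))
  expect_true(all(Im(chi) == 0))                       # sigma == sigma_b

  # uniform phantom equal to the background: identically zero contrast
  ph0 <- bimqp:::new_phantom(g, rep(10, g$N), rep(0.05, g$N),
                             rep("background", g$N), 10, 0.05)
  expect_true(all(contrast_map(ph0, med, 2) == 0))
  # round trip back to material maps
  maps <- maps_from_contrast(chi, med, 1)
  expect_equal(maps$eps_r, ph$eps_r)
  expect_equal(maps$sigma, ph$sigma)
})

test_that("fine rendering box-averaged to coarse matches direct rendering", {
  tum <- tumor_spec(0.008, c(0.019, 0))
  fine <- synthetic_breast_phantom(3, tum, seed = 9,
                                   grid = build_grid(0.18, 150))
  coarse <- synthetic_breast_phantom(3, tum, seed = 9,
                                     grid = build_grid(0.18, 64))
  avg <- box_resample(matrix(fine$eps_r, 150), 64)
  direct <- matrix(coarse$eps_r, 64)
  # away from region boundaries the two renderings agree; boundary pixels
  # (where the label differs from a neighbor's) may differ by partial-volume
  lab <- matrix(coarse$labels, 64)
  interior <- matrix(TRUE, 64, 64)
  for (dx in -1:1) for (dy in -1:1) {
    shifted <- lab[pmin(pmax(1:64 + dx, 1), 64), pmin(pmax(1:64 + dy, 1), 64)]
    interior <- interior & (shifted == lab)
  }
  expect_gt(mean(interior), 0.5)
  expect_lt(max(abs(avg[interior] - direct[interior])), 1.5)
  expect_lt(mean(abs(avg[interior] - direct[interior])), 0.1)
})
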