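test_that("domain Green matrix is symmetric with decaying off-diagonals", {
  g <- build_grid(0.18, 8)
  kb <- toy_medium()$k_b[2]
  GD <- green_domain(g, kb)
  expect_equal(max(Mod(GD - t(GD))), 0)
  # magnitude decays with pixel separation along a grid row
  row <- Mod(GD[1, 2:8])
  expect_true(all(diff(row) < 0))
  expect_error(green_domain(g, -1), class = "bimqp_argument_error")
})

test_that("Green coefficients match 2D quadrature of the continuous kernel", {
  skip_if_not_installed("pracma")
  # 2x2 block of cells at 1 GHz in an eps_rb = 10 background, sized so the
  # cells are sub-wavelength (k_b * dx ~ 0.66) - the regime in which the
  # pulse-basis equal-area-disc coefficient is a valid discretization
  g <- build_grid(0.02, 2)
  med <- background_medium(10, 0, 1e9)
  kb <- med$k_b[1]
  GD <- green_domain(g, kb)
  gl <- pracma::gaussLegendre(24, -g$dx / 2, g$dx / 2)
  wij <- outer(gl$w, gl$w)
  # off-diagonal: quadrature of k^2 * (-j/4) H0^(2)(k|r_m - r'|) over cell n
  for (m in 1:2) for (n in 3:4) {
    xs <- outer(g$centers[n, 1] + gl$x, rep(1, 24))
    ys <- outer(rep(1, 24), g$centers[n, 2] + gl$x)
    d <- sqrt((xs - g$centers[m, 1])^2 + (ys - g$centers[m, 2])^2)
    oracle <- kb^2 * (-0.25i) * sum(wij * bimqp:::hankel2(kb * d, 0))
    expect_lt(Mod(GD[m, n] - oracle) / Mod(oracle), 0.01)
  }
  # self term: polar quadrature over the equal-area disc (singularity
  # integrable; r * H0 is bounded)
  a <- g$a_eq
  glr <- pracma::gaussLegendre(400, 0, a)
  oracle_d <- kb^2 * (-0.25i) * 2 * pi *
    sum(glr$w * glr$x * bimqp:::hankel2(kb * glr$x, 0))
  expect_lt(Mod(GD[1, 1] - oracle_d) / Mod(oracle_d), 1e-6)
})

test_that("receiver Green matrix behaves like sampled point radiation", {
  g1 <- build_grid(0.01, 2)  # small block of 4 cells
  kb <- toy_medium()$k_b[1]
  rec <- rbind(c(0.05, 0), c(0.1, 0), c(0.05, 0.02), c(0.05, -0.02))
  GS <- green_data(g1, rec, kb)
  # farther receiver at the same angle sees weaker entries
  expect_true(all(Mod(GS[2, ]) < Mod(GS[1, ])))
  # receivers mirrored about the x-axis see mirrored pixels
  mirror <- c(3L, 4L, 1L, 2L)  # pixel reflection y -> -y on the 2x2 grid
  expect_equal(GS[3, ], GS[4, mirror])
  # single-cell grid: column equals the discretized point radiation
  gp <- build_grid(0.005, 2)
  GS1 <- green_data(gp, rec, kb, subset = 1L)
  d <- sqrt((rec[, 1] - gp$centers[1, 1])^2 + (rec[, 2] - gp$centers[1, 2])^2)
  expect_equal(GS1[, 1], bimqp:::green_coeff(kb, gp$a_eq, d))
  # coincident receiver and pixel center is singular
  expect_error(green_data(g1, rbind(g1$centers[1, ]), kb),
               class = "bimqp_argument_error")
})
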