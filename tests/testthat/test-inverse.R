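test_that("the stacked QP has the documented dimensions and objective", {
  sc <- inverse_scenario()
  sys <- assemble_qp(sc$ds, sc$Et, sc$GS, lambda = 0, grid = sc$g)
  expect_equal(sys$dims$n_eq, 2 * 2 * 3 * 18)       # 216 equality rows
  expect_equal(sys$dims$n_unknowns, 216 + 2 * 16)   # slack + contrast
  dn <- qp_dense(sys)
  expect_equal(dim(dn$B), c(216, 32))
  expect_equal(dim(dn$Aeq), c(216, 216 + 32))
  # with lambda = 0 the objective at any chi equals the data misfit of the
  # eliminated-slack form, i.e. the least-squares mismatch
  chi_try <- complex(real = runif(16, -0.1, 0.1),
                     imaginary = runif(16, -0.1, 0.1))
  x <- c(Re(chi_try), Im(chi_try))
  expect_equal(qp_objective(sys, chi_try)$objective,
               sum((dn$beq - as.vector(dn$B %*% x))^2))
  # spatially constant contrast has zero gradient penalty
  sys_l <- assemble_qp(sc$ds, sc$Et, sc$GS, lambda = 2, grid = sc$g)
  expect_equal(qp_objective(sys_l, rep(0.3 + 0.1i, 16))$penalty, 0)
})

test_that("QP updates equal the dense least-squares oracle when unconstrained", {
  sc <- inverse_scenario()
  sys <- assemble_qp(sc$ds, sc$Et, sc$GS, lambda = 0, grid = sc$g)
  sol <- solve_qp(sys)
  # oracle: normal-equations least squares on the materialized real form
  dn <- qp_dense(sys)
  x_ls <- qr.solve(dn$B, dn$beq)
  chi_ls <- complex(real = x_ls[1:16], imaginary = x_ls[17:32])
  expect_lt(max(Mod(sol$chi - chi_ls)), 1e-6)
  expect_lt(max(Mod(sol$chi - sc$chi)), 1e-6)
  expect_lt(sol$kkt_residual, 1e-6)
})

test_that("degenerate QP cases are handled exactly", {
  sc <- inverse_scenario()
  # all-zero data: global minimum at the origin
  ds0 <- sc$ds; ds0$E_s[] <- 0i
  sys0 <- assemble_qp(ds0, sc$Et, sc$GS, lambda = 0.5, grid = sc$g)
  sol0 <- solve_qp(sys0)
  expect_equal(max(Mod(sol0$chi)), 0)
  expect_equal(sol0$objective, 0)
  # tight box [c, c]: the solution is pinned regardless of data
  sysc <- assemble_qp(sc$ds, sc$Et, sc$GS, lambda = 0.5, grid = sc$g,
                      bounds = list(re = c(0.2, 0.2), im = c(-0.1, -0.1)))
  expect_equal(solve_qp(sysc)$chi, rep(0.2 - 0.1i, 16))
})

test_that("active box constraints reach KKT stationarity", {
  sc <- inverse_scenario(chi_scale = 0.5)
  # bounds deliberately tighter than the true contrast so they activate
  sys <- assemble_qp(sc$ds, sc$Et, sc$GS, lambda = 1e-8, grid = sc$g,
                     bounds = list(re = c(0, 0.3), im = c(-0.1, 0)))
  sol <- solve_qp(sys)
  expect_true(sol$bounded)
  expect_lt(sol$kkt_residual, 1e-6)
  expect_true(all(Re(sol$chi) >= 0 & Re(sol$chi) <= 0.3))
  expect_true(all(Im(sol$chi) >= -0.1 & Im(sol$chi) <= 0))
  # the constrained optimum beats nearby feasible perturbations
  f0 <- qp_objective(sys, sol$chi)$objective
  set.seed(1)
  for (k in 1:5) {
    pert <- sol$chi + complex(real = runif(16, -1, 1),
                              imaginary = runif(16, -1, 1)) * 1e-3
    pert <- complex(real = pmin(pmax(Re(pert), 0), 0.3),
                    imaginary = pmin(pmax(Im(pert), -0.1), 0))
    expect_gte(qp_objective(sys, pert)$objective, f0 - 1e-10)
  }
})

test_that("increasing the Tikhonov weight never roughens the solution", {
  sc <- inverse_scenario(chi_scale = 0.3)
  pens <- vapply(c(1e-6, 1e-4, 1e-2, 1), function(lam) {
    sys <- assemble_qp(sc$ds, sc$Et, sc$GS, lambda = lam, grid = sc$g)
    solve_qp(sys)$penalty
  }, numeric(1))
  expect_true(all(diff(pens) <= 1e-8))
})

test_that("initial guesses follow their declared strategies", {
  sc <- inverse_scenario()
  # constant_min: uniform contrast at the minimum permittivity
  expect_equal(initial_guess(sc$ds, sc$g, "constant_min"),
               rep(complex(real = -0.75), 16))
  # zero data with regularization: Born initialization stays at zero
  ds0 <- sc$ds; ds0$E_s[] <- 0i
  expect_equal(max(Mod(initial_guess(ds0, sc$g, "born_zero", lambda = 1))), 0)
  # weak scatterer: first-Born inversion recovers the truth, both at the
  # reference frequency alone and jointly over all sources and frequencies
  chi_b <- initial_guess(sc$ds, sc$g, "born_zero", lambda = 0)
  expect_lt(sqrt(sum(Mod(chi_b - sc$chi)^2) / sum(Mod(sc$chi)^2)), 0.05)
  chi_m <- initial_guess(sc$ds, sc$g, "multi_freq_source", lambda = 0)
  expect_lt(sqrt(sum(Mod(chi_m - sc$chi)^2) / sum(Mod(sc$chi)^2)), 0.05)
  expect_error(initial_guess(sc$ds, sc$g, "nonsense"))
})

test_that("Born iterations recover weak scatterers and leave zero data at zero", {
  sc <- inverse_scenario()
  cfg <- bim_config(iterations = 3, lambda = 1e-10, init = "born_zero")
  rec <- suppressWarnings(bim_reconstruct(sc$ds, sc$g, cfg))
  truth <- matrix(10 * (1 + Re(sc$chi)), 4)
  expect_lt(relative_error(truth, matrix(rec$eps_r, 4))$Re, 1e-2)
  expect_equal(length(rec$chi_iterations), 3)
  expect_equal(length(rec$residuals), 3)
  expect_lte(rec$residuals[3], rec$residuals[1] + 1e-12)
  expect_true(all(rec$eps_r >= 2.5 & rec$eps_r <= 67))
  # zero-contrast dataset: the zero map is a fixed point
  ds0 <- sc$ds; ds0$E_s[] <- 0i
  rec0 <- suppressWarnings(bim_reconstruct(ds0, sc$g,
    bim_config(iterations = 2, lambda = 1e-6, init = "born_zero")))
  for (k in 1:2) expect_equal(max(Mod(rec0$chi_iterations[[k]])), 0)
  # inversion on the simulation grid warns about the inverse crime
  expect_warning(bim_reconstruct(sc$ds, sc$g, cfg), regexp = "inverse crime")
})
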