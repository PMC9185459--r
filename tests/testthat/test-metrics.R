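test_that("the Frobenius relative error and accuracy behave as defined", {
  truth <- matrix(c(3, 4, 0, 0), 2)
  expect_equal(relative_error(truth, truth)$Re, 0)
  expect_equal(relative_error(truth, truth)$accuracy, 100)
  expect_equal(relative_error(truth, 2 * truth)$Re, 1)
  # hand-computed: |truth|_F = 5, difference norm = 5
  expect_equal(relative_error(truth, matrix(0, 2, 2))$Re, 1)
  # averaging over multiple tests
  rep2 <- relative_error(list(truth, truth), list(truth, 2 * truth))
  expect_equal(rep2$Nt, 2)
  expect_equal(rep2$Re, 0.5)
  expect_equal(rep2$per_test, c(0, 1))
  # accuracy + 100 * Re == 100 identically
  set.seed(8)
  for (k in 1:10) {
    tr <- matrix(runif(16, 1, 60), 4)
    es <- matrix(runif(16, 1, 60), 4)
    r <- relative_error(tr, es)
    expect_equal(r$accuracy + 100 * r$Re, 100)
  }
  expect_error(relative_error(matrix(0, 2, 2), truth),
               class = "bimqp_argument_error")
  expect_error(relative_error(truth, matrix(1, 3, 3)),
               class = "bimqp_argument_error")
})

test_that("the conductivity regression matches its printed coefficients", {
  expect_equal(conductivity_from_permittivity(10), 0.143)
  expect_equal(conductivity_from_permittivity(67), 1.226)
  expect_equal(conductivity_from_permittivity(0.047 / 0.019), 0)
  # floored at zero below the root of the linear model
  expect_equal(conductivity_from_permittivity(1), 0)
  m <- matrix(c(2.5, 10, 40, 67), 2)
  expect_equal(dim(conductivity_from_permittivity(m)), c(2, 2))
})
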