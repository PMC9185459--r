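test_that("the network architecture follows the doubling/halving contract", {
  cfg <- refiner_config(input_size = 64, depth = 4, base_channels = 16)
  m <- build_refiner(cfg)
  expect_equal(m$arch$channels, c(16, 32, 64, 128))
  expect_equal(m$arch$bottleneck_size, 8)
  ops <- m$plan$ops
  convs <- Filter(function(o) o$type == "conv", ops)
  names(convs) <- vapply(convs, `[[`, "", "name")
  # contracting: channels double level to level
  for (i in 1:4) {
    expect_equal(convs[[sprintf("enc%d_conv1", i)]]$cout, 16 * 2^(i - 1))
    expect_equal(convs[[sprintf("enc%d_conv2", i)]]$cin, 16 * 2^(i - 1))
  }
  # expanding: 2x2 up-convolutions halve the channels, and the two 3x3
  # convolutions after concatenation consume the doubled (skip) channels
  for (i in 3:1) {
    up <- convs[[sprintf("dec%d_upconv", i)]]
    expect_equal(up$k, 2)
    expect_equal(up$cout * 2, up$cin)
    expect_equal(convs[[sprintf("dec%d_conv1", i)]]$cin, 2 * up$cout)
  }
  expect_equal(convs[["out_proj"]]$cout, 1)
  # weight shapes match the declared plan
  for (o in convs)
    expect_equal(dim(m$params[[o$name]]$W), c(o$cout, o$k^2 * o$cin))
  expect_error(refiner_config(input_size = 50, depth = 4),
               class = "bimqp_argument_error")
})

test_that("initialization and inference are deterministic and well shaped", {
  cfg <- refiner_config(input_size = 32, depth = 3, base_channels = 4,
                        seed = 9)
  m1 <- build_refiner(cfg); m2 <- build_refiner(cfg)
  expect_identical(m1$params, m2$params)
  # all-zeros (minimum-permittivity) input: finite output of the same shape
  out <- refine(m1, matrix(2.5, 32, 32))
  expect_equal(dim(out), c(32, 32))
  expect_true(all(is.finite(out)))
  expect_true(all(out >= 2.5 & out <= 67))
  inp <- matrix(runif(32 * 32, 2.5, 67), 32)
  expect_identical(refine(m1, inp), refine(m1, inp))
  expect_error(refine(m1, matrix(5, 16, 16)), class = "bimqp_argument_error")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- refiner_config(input_size = 8, depth = 2, base_channels = 3,
                        seed = 2)
  m <- build_refiner(cfg)
  set.seed(5)
  X <- base::array(rnorm(8 * 8 * 2), c(1, 8, 8, 2))
  Tg <- base::array(rnorm(8 * 8 * 2), c(1, 8, 8, 2))
  lossfn <- function(mod) {
    fw <- bimqp:::refiner_forward(mod, X, train = TRUE)
    list(loss = mean((fw$out - Tg)^2), fw = fw)
  }
  l0 <- lossfn(m)
  grads <- bimqp:::refiner_backward(m, l0$fw$caches,
                                    2 * (l0$fw$out - Tg) / length(Tg))
  rels <- c()
  for (nm in c("enc1_conv1", "enc1_bn1", "enc2_conv2", "dec1_upconv",
               "dec1_conv2", "out_proj")) {
    for (fld in names(grads[[nm]])) {
      v <- m$params[[nm]][[fld]]
      for (k in sample(length(v), min(3, length(v)))) {
        h <- 1e-5
        mp <- m; mp$params[[nm]][[fld]][k] <- v[k] + h
        mm <- m; mm$params[[nm]][[fld]][k] <- v[k] - h
        num <- (lossfn(mp)$loss - lossfn(mm)$loss) / (2 * h)
        an <- grads[[nm]][[fld]][k]
        rels <- c(rels, abs(num - an) / max(abs(num), abs(an), 1e-8))
      }
    }
  }
  # finite differences cross ReLU kinks occasionally; the bulk must agree
  expect_lt(median(rels), 1e-3)
  expect_lt(max(rels), 0.05)
})

test_that("training reduces the loss and can memorize a structured map", {
  g <- build_grid(0.18, 16)
  ph <- synthetic_breast_phantom(2, tumor_spec(0.008, c(0, 0)), seed = 3,
                                 grid = g)
  tgt <- matrix(ph$eps_r, 16)
  inp <- box_resample(box_resample(tgt, 4), 16)   # blurred stand-in
  cfg <- refiner_config(input_size = 16, depth = 2, base_channels = 8,
                        seed = 2, epochs = 300, lr = 5e-3, batch_size = 1)
  m <- build_refiner(cfg)
  tr <- train_refiner(m, list(list(input = inp, target = tgt)),
                      train_idx = 1L, val_idx = integer(0))
  expect_equal(nrow(tr$history), 300)
  expect_lt(tr$history$train[300], tr$history$train[1])
  out <- refine(tr$model, inp)
  expect_lt(relative_error(tgt, out)$Re, 0.12)
  expect_lt(relative_error(tgt, out)$Re, relative_error(tgt, inp)$Re / 2)
  # training is deterministic given the seeds
  tr2 <- train_refiner(build_refiner(cfg),
                       list(list(input = inp, target = tgt)),
                       train_idx = 1L, val_idx = integer(0))
  expect_identical(tr$history, tr2$history)
})

test_that("the train/validation split follows the seeded floor rule", {
  pairs <- replicate(108, list(input = matrix(5, 4, 4),
                               target = matrix(6, 4, 4)), simplify = FALSE)
  cfg <- refiner_config(input_size = 4, depth = 2, base_channels = 2,
                        seed = 31, epochs = 1, val_fraction = 0.1)
  m <- build_refiner(cfg)
  tr1 <- train_refiner(m, pairs)
  expect_length(tr1$train_idx, 97)    # floor(0.9 * 108)
  expect_length(tr1$val_idx, 11)
  expect_length(intersect(tr1$train_idx, tr1$val_idx), 0)
  tr2 <- train_refiner(m, pairs)
  expect_identical(tr1$train_idx, tr2$train_idx)
})
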