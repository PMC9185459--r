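# Convolutional encoder-decoder refiner, implemented directly on base R
# arrays (layout: channels, height, width, batch) with im2col convolutions
# executed as BLAS matrix products. The contracting path applies, per
# resolution level, two 3x3 convolutions each followed by batch
# normalization and ReLU, then a 2x2 max-pool of stride 2 with channel
# doubling; the expanding path upsamples (nearest neighbor), halves the
# channels with a 2x2 convolution, concatenates the corresponding
# contracting feature map, and applies two 3x3 convolutions with ReLU.
# A final 1x1 projection produces the single-channel output map.

#' Refiner configuration
#'
#' @param input_size Input map side length (pixels); must be divisible by
#'   `2^(depth - 1)`.
#' @param depth Number of resolution levels (contracting levels plus
#'   bottleneck).
#' @param base_channels Feature channels at the first level; doubled at
#'   each contraction, halved at each expansion.
#' @param seed Seed for weight initialization and training shuffles.
#' @param epochs,lr,batch_size Training schedule (Adam optimizer).
#' @param val_fraction Train/validation split fraction held out.
#' @param loss Loss name; `"mse"` (pixel-wise squared error) is supported.
#' @param clip_range Physical output clip range (relative permittivity).
#' @param norm_range Range used to normalize maps to `[0, 1]`.
#' @return List of class `refiner_config`.
#' @export
refiner_config <- function(input_size = 64L, depth = 4L, base_channels = 16L,
                           seed = 1L, epochs = 200L, lr = 1e-3,
                           batch_size = 16L, val_fraction = 0.1,
                           loss = "mse", clip_range = c(2.5, 67),
                           norm_range = c(2.5, 67)) {
  if (!is_count(input_size) || !is_count(depth) || depth < 2)
    abort_argument("`input_size` and `depth` must be integers (depth >= 2)")
  if (input_size %% 2^(depth - 1) != 0)
    abort_argument("input size %d is not divisible by 2^(depth-1) = %d",
                   input_size, 2^(depth - 1))
  if (!identical(loss, "mse")) abort_argument("unsupported loss '%s'", loss)
  structure(list(input_size = as.integer(input_size),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, loss = loss,
                 clip_range = clip_range, norm_range = norm_range),
            class = "refiner_config")
}

# ---- tensor primitives (layout C, H, W, B) --------------------------------

# Convolutions run in compiled code (src/conv.cpp): im2col + BLAS gemm,
# with the patch matrix cached for the backward pass.
conv_fw <- function(X, W, b, k, pt, pl) {
  r <- conv_fw_cpp(X, W, b, k, pt, pl)
  list(out = r$out,
       cache = list(Xcol = r$Xcol, dims = dim(X), k = k, pt = pt, pl = pl))
}

conv_bw <- function(dY, W, cache) {
  r <- conv_bw_cpp(dY, W, cache$Xcol, as.integer(cache$dims),
                   cache$k, cache$pt, cache$pl)
  list(dX = r$dX, dW = r$dW, db = as.vector(r$db))
}

bn_fw <- function(X, par, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(X); C <- d[1]; n <- prod(d[-1])
  Xm <- matrix(X, C)
  if (train) {
    mu <- rowMeans(Xm)
    v <- rowMeans((Xm - mu)^2)
    par$rm <- (1 - momentum) * par$rm + momentum * mu
    par$rv <- (1 - momentum) * par$rv + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- par$rm; v <- par$rv
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * invstd          # length-C vectors recycle along dim 1
  list(out = xhat * par$gamma + par$beta, par = par,
       cache = list(xhat = xhat, invstd = invstd, n = n, C = C))
}

bn_bw <- function(dY, par, cache) {
  C <- cache$C; n <- cache$n
  dYm <- matrix(dY, C); xh <- matrix(cache$xhat, C)
  dgamma <- rowSums(dYm * xh)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * par$gamma
  dX <- (dxhat - rowMeans(dxhat) - xh * rowMeans(dxhat * xh)) *
    cache$invstd
  list(dX = base::array(dX, dim(dY)), dgamma = dgamma, dbeta = dbeta)
}

pool_fw <- function(X) {
  d <- dim(X); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  A <- base::array(X, c(C, 2, H / 2, W, B))
  X1 <- A[, 1, , , , drop = FALSE]; X2 <- A[, 2, , , , drop = FALSE]
  m1 <- pmax(X1, X2); mask1 <- X1 >= X2
  m1 <- base::array(m1, c(C, H / 2, W, B))
  A2 <- base::array(m1, c(C, H / 2, 2, W / 2, B))
  Y1 <- A2[, , 1, , , drop = FALSE]; Y2 <- A2[, , 2, , , drop = FALSE]
  Y <- pmax(Y1, Y2); mask2 <- Y1 >= Y2
  list(out = base::array(Y, c(C, H / 2, W / 2, B)),
       cache = list(mask1 = mask1, mask2 = mask2, dims = d))
}

pool_bw <- function(dY, cache) {
  d <- cache$dims; C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  dA2 <- base::array(0, c(C, H / 2, 2, W / 2, B))
  dYa <- base::array(dY, c(C, H / 2, 1, W / 2, B))
  dA2[, , 1, , ] <- dYa * cache$mask2
  dA2[, , 2, , ] <- dYa * !cache$mask2
  dm1 <- base::array(dA2, c(C, H / 2, W, B))
  dA <- base::array(0, c(C, 2, H / 2, W, B))
  dm1a <- base::array(dm1, c(C, 1, H / 2, W, B))
  dA[, 1, , , ] <- dm1a * cache$mask1
  dA[, 2, , , ] <- dm1a * !cache$mask1
  base::array(dA, d)
}

up_fw <- function(X) {
  d <- dim(X)
  X[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), ,
    drop = FALSE]
}

up_bw <- function(dY) {
  d <- dim(dY); C <- d[1]; H2 <- d[2]; W2 <- d[3]; B <- d[4]
  A <- base::array(dY, c(C, 2, H2 / 2, 2, W2 / 2, B))
  base::array(A[, 1, , 1, , ] + A[, 2, , 1, , ] +
              A[, 1, , 2, , ] + A[, 2, , 2, , ],
              c(C, H2 / 2, W2 / 2, B))
}

# ---- model construction ---------------------------------------------------

# Execution plan: ops run sequentially; "push"/"concat" manage the skip
# stack connecting contracting and expanding levels.
refiner_plan <- function(config) {
  D <- config$depth; base_c <- config$base_channels
  ch <- base_c * 2^(0:(D - 1))
  ops <- list()
  add <- function(type, name = NULL, ...) {
    ops[[length(ops) + 1]] <<- c(list(type = type, name = name), list(...))
  }
  cin <- 1L
  for (i in seq_len(D - 1)) {
    add("conv", sprintf("enc%d_conv1", i), cin = cin, cout = ch[i], k = 3L,
        pt = 1L, pl = 1L)
    add("bn", sprintf("enc%d_bn1", i), c = ch[i]); add("relu")
    add("conv", sprintf("enc%d_conv2", i), cin = ch[i], cout = ch[i], k = 3L,
        pt = 1L, pl = 1L)
    add("bn", sprintf("enc%d_bn2", i), c = ch[i]); add("relu")
    add("push"); add("pool")
    cin <- ch[i]
  }
  add("conv", sprintf("enc%d_conv1", D), cin = cin, cout = ch[D], k = 3L,
      pt = 1L, pl = 1L)
  add("bn", sprintf("enc%d_bn1", D), c = ch[D]); add("relu")
  add("conv", sprintf("enc%d_conv2", D), cin = ch[D], cout = ch[D], k = 3L,
      pt = 1L, pl = 1L)
  add("bn", sprintf("enc%d_bn2", D), c = ch[D]); add("relu")
  for (i in (D - 1):1) {
    add("up")
    add("conv", sprintf("dec%d_upconv", i), cin = ch[i + 1], cout = ch[i],
        k = 2L, pt = 0L, pl = 0L)
    add("concat")
    add("conv", sprintf("dec%d_conv1", i), cin = 2L * ch[i], cout = ch[i],
        k = 3L, pt = 1L, pl = 1L)
    add("relu")
    add("conv", sprintf("dec%d_conv2", i), cin = ch[i], cout = ch[i], k = 3L,
        pt = 1L, pl = 1L)
    add("relu")
  }
  add("conv", "out_proj", cin = ch[1], cout = 1L, k = 1L, pt = 0L, pl = 0L)
  list(ops = ops, channels = ch)
}

#' Build the encoder-decoder refinement network
#'
#' Constructs the model with He-initialized weights, seeded by
#' `config$seed`; identical configurations yield identical initial
#' parameters.
#'
#' @param config A [refiner_config()].
#' @return Object of class `mwi_refiner` with the layer plan, parameters,
#'   and architecture summary (`$arch`: per-level channel counts).
#' @export
build_refiner <- function(config = refiner_config()) {
  if (!inherits(config, "refiner_config"))
    abort_argument("`config` must be a refiner_config()")
  plan <- refiner_plan(config)
  params <- list()
  with_seed(config$seed, {
    for (op in plan$ops) {
      if (op$type == "conv") {
        fan_in <- op$k^2 * op$cin
        params[[op$name]] <- list(
          W = matrix(stats::rnorm(op$cout * fan_in, sd = sqrt(2 / fan_in)),
                     op$cout, fan_in),
          b = numeric(op$cout))
      } else if (op$type == "bn") {
        params[[op$name]] <- list(gamma = rep(1, op$c), beta = numeric(op$c),
                                  rm = numeric(op$c), rv = rep(1, op$c))
      }
    }
  })
  n_par <- sum(vapply(params, function(p)
    sum(lengths(lapply(p, as.numeric))), numeric(1)))
  structure(list(config = config, plan = plan, params = params,
                 arch = list(depth = config$depth, channels = plan$channels,
                             bottleneck_size =
                               config$input_size / 2^(config$depth - 1),
                             n_parameters = n_par)),
            class = "mwi_refiner")
}

#' @export
print.mwi_refiner <- function(x, ...) {
  cat(sprintf(
    "<mwi_refiner> depth %d, channels %s, input %dx%d, %d parameters\n",
    x$config$depth, paste(x$plan$channels, collapse = "-"),
    x$config$input_size, x$config$input_size, x$arch$n_parameters))
  invisible(x)
}

# Forward pass; X is (1, H, W, B). Returns output and (if train) caches.
refiner_forward <- function(model, X, train = FALSE) {
  skips <- list(); caches <- vector("list", length(model$plan$ops))
  x <- X
  for (j in seq_along(model$plan$ops)) {
    op <- model$plan$ops[[j]]
    if (op$type == "conv") {
      p <- model$params[[op$name]]
      r <- conv_fw(x, p$W, p$b, op$k, op$pt, op$pl)
      x <- r$out; if (train) caches[[j]] <- r$cache
    } else if (op$type == "bn") {
      r <- bn_fw(x, model$params[[op$name]], train)
      x <- r$out
      if (train) {
        model$params[[op$name]] <- r$par
        caches[[j]] <- r$cache
      }
    } else if (op$type == "relu") {
      if (train) caches[[j]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (op$type == "push") {
      skips[[length(skips) + 1]] <- x
    } else if (op$type == "pool") {
      r <- pool_fw(x); x <- r$out; if (train) caches[[j]] <- r$cache
    } else if (op$type == "up") {
      if (train) caches[[j]] <- dim(x)
      x <- up_fw(x)
    } else if (op$type == "concat") {
      s <- skips[[length(skips)]]; skips[[length(skips)]] <- NULL
      d <- dim(x)
      z <- base::array(0, c(d[1] + dim(s)[1], d[2], d[3], d[4]))
      z[seq_len(d[1]), , , ] <- x
      z[d[1] + seq_len(dim(s)[1]), , , ] <- s
      if (train) caches[[j]] <- list(c_main = d[1], c_skip = dim(s)[1])
      x <- z
    }
  }
  list(out = x, caches = caches, model = model)
}

# Backward pass; returns gradients named like params.
refiner_backward <- function(model, caches, dOut) {
  grads <- list(); dskips <- list()
  dx <- dOut
  for (j in rev(seq_along(model$plan$ops))) {
    op <- model$plan$ops[[j]]
    if (op$type == "conv") {
      p <- model$params[[op$name]]
      r <- conv_bw(dx, p$W, caches[[j]])
      grads[[op$name]] <- list(W = r$dW, b = r$db)
      dx <- r$dX
    } else if (op$type == "bn") {
      r <- bn_bw(dx, model$params[[op$name]], caches[[j]])
      grads[[op$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dx <- r$dX
    } else if (op$type == "relu") {
      dx <- dx * caches[[j]]$mask
    } else if (op$type == "push") {
      ds <- dskips[[length(dskips)]]; dskips[[length(dskips)]] <- NULL
      dx <- dx + ds
    } else if (op$type == "pool") {
      dx <- pool_bw(dx, caches[[j]])
    } else if (op$type == "up") {
      dx <- up_bw(dx)
    } else if (op$type == "concat") {
      cm <- caches[[j]]$c_main
      dskips[[length(dskips) + 1]] <-
        dx[cm + seq_len(caches[[j]]$c_skip), , , , drop = FALSE]
      dx <- dx[seq_len(cm), , , , drop = FALSE]
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) lapply(p[intersect(names(p),
    c("W", "b", "gamma", "beta"))], function(v) list(m = v * 0, v = v * 0)))
}

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    for (fld in names(grads[[nm]])) {
      g <- grads[[nm]][[fld]]
      st <- state[[nm]][[fld]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t); vhat <- st$v / (1 - b2^t)
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[fld]] <- st
    }
  }
  list(params = params, state = state)
}

#' Step-decay learning-rate schedule for the sweep refiner
#'
#' A short warmup, a high-rate phase that carries most of the fitting, and
#' a decayed phase that sharpens the converged solution (the evaluation
#' metric rewards per-map sharpness that a constant rate leaves on the
#' table). Returned as one rate per epoch for [train_refiner()]'s `lr`.
#'
#' @param epochs Total epochs (default 250).
#' @return Numeric vector of length `epochs`.
#' @export
refiner_schedule <- function(epochs = 250L) {
  sched <- c(rep(1e-3, 10), rep(5e-3, 140), rep(1e-3, epochs))
  sched[seq_len(epochs)]
}

norm_map <- function(x, rng) (x - rng[1]) / (rng[2] - rng[1])
denorm_map <- function(x, rng) x * (rng[2] - rng[1]) + rng[1]

# Stack a list of M x M maps into a (1, M, M, B) input tensor.
stack_maps <- function(maps, rng) {
  M <- nrow(maps[[1]])
  base::array(vapply(maps, function(m) norm_map(as.matrix(m), rng),
                     numeric(M * M)),
              c(1, M, M, length(maps)))
}

#' Train the refinement network
#'
#' Minimizes the pixel-wise squared error between refined and ground-truth
#' permittivity maps (normalized to `[0, 1]`) with the Adam optimizer over
#' seeded shuffled mini-batches. Training is deterministic given the model
#' seed.
#'
#' @param model An [build_refiner()] model.
#' @param pairs List of training pairs, each `list(input = <M x M matrix>,
#'   target = <M x M matrix>)`, or an `mwi_training_set`.
#' @param train_idx,val_idx Optional explicit split; defaults to a seeded
#'   shuffle split by `config$val_fraction` (or the split stored in an
#'   `mwi_training_set`).
#' @param epochs,lr,batch_size Overrides of the model config.
#' @param keep_best Restore the parameters from the epoch with the lowest
#'   validation loss (early-stopping checkpoint); ignored when there is no
#'   validation split.
#' @param verbose Print the loss every 10 epochs.
#' @return List with the trained `model` and `history` (data frame of
#'   per-epoch train/validation loss), plus `best_epoch` when `keep_best`
#'   applies.
#' @export
train_refiner <- function(model, pairs, train_idx = NULL, val_idx = NULL,
                          epochs = NULL, lr = NULL, batch_size = NULL,
                          keep_best = TRUE, verbose = FALSE) {
  cfg <- model$config
  if (inherits(pairs, "mwi_training_set")) {
    train_idx <- train_idx %||% pairs$train_idx
    val_idx <- val_idx %||% pairs$val_idx
    pairs <- pairs$pairs
  }
  n <- length(pairs)
  if (n < 1) abort_argument("`pairs` must contain at least one pair")
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  # a scalar learning rate is constant; a vector is recycled/truncated to
  # one rate per epoch (step-decay schedules)
  lr_by_epoch <- rep_len(lr, epochs)
  batch_size <- batch_size %||% cfg$batch_size
  if (is.null(train_idx)) {
    perm <- with_seed(cfg$seed, sample(n))
    n_tr <- max(1L, floor((1 - cfg$val_fraction) * n))
    train_idx <- perm[seq_len(n_tr)]
    val_idx <- if (n_tr < n) perm[(n_tr + 1):n] else integer(0)
  }
  rng <- cfg$norm_range
  Xall <- stack_maps(lapply(pairs, `[[`, "input"), rng)
  Tall <- stack_maps(lapply(pairs, `[[`, "target"), rng)
  state <- adam_init(model$params)
  hist <- data.frame(epoch = seq_len(epochs), train = NA_real_,
                     val = NA_real_)
  t_step <- 0L
  best <- list(val = Inf, params = NULL, epoch = NA_integer_)
  with_seed(cfg$seed + 1L, {
    for (e in seq_len(epochs)) {
      ord <- sample(train_idx)
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1, length(ord))]
        X <- Xall[, , , bidx, drop = FALSE]
        Tg <- Tall[, , , bidx, drop = FALSE]
        fw <- refiner_forward(model, X, train = TRUE)
        model <- fw$model
        err <- fw$out - Tg
        loss <- mean(err^2)
        if (!is.finite(loss))
          abort_training("training diverged (non-finite loss) at epoch %d", e)
        losses <- c(losses, loss)
        dOut <- 2 * err / length(err)
        grads <- refiner_backward(model, fw$caches, dOut)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, state, lr_by_epoch[e], t_step)
        model$params <- upd$params
        state <- upd$state
      }
      hist$train[e] <- mean(losses)
      if (length(val_idx)) {
        pv <- refiner_forward(model,
                              Xall[, , , val_idx, drop = FALSE])$out
        hist$val[e] <- mean((pv - Tall[, , , val_idx, drop = FALSE])^2)
        if (keep_best && hist$val[e] < best$val) {
          best <- list(val = hist$val[e], params = model$params, epoch = e)
        }
      }
      if (verbose && (e %% 10 == 0 || e == 1))
        message(sprintf("  epoch %d: train %.5f val %s", e, hist$train[e],
                        format(hist$val[e], digits = 4)))
    }
  })
  if (keep_best && !is.null(best$params)) model$params <- best$params
  list(model = model, history = hist,
       train_idx = train_idx, val_idx = val_idx, best_epoch = best$epoch)
}

#' Refine a reconstructed permittivity map
#'
#' Single inference pass through the trained network; the output is
#' de-normalized and clipped to the physical permittivity range.
#'
#' @param model A trained `mwi_refiner`.
#' @param bim_map `M x M` matrix of reconstructed relative permittivity.
#' @return `M x M` refined permittivity matrix.
#' @export
refine <- function(model, bim_map) {
  if (!inherits(model, "mwi_refiner"))
    abort_argument("`model` must be an mwi_refiner")
  bim_map <- as.matrix(bim_map)
  M <- model$config$input_size
  if (!all(dim(bim_map) == c(M, M)))
    abort_argument("map shape %d x %d does not match the model input %d x %d",
                   nrow(bim_map), ncol(bim_map), M, M)
  X <- stack_maps(list(bim_map), model$config$norm_range)
  out <- refiner_forward(model, X)$out
  y <- denorm_map(matrix(out, M, M), model$config$norm_range)
  pmin(pmax(y, model$config$clip_range[1]), model$config$clip_range[2])
}
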