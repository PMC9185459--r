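# Born iterative method with each contrast update posed as a real-valued,
# Tikhonov-regularized quadratic program stacked over all sources and
# frequencies:
#
#   min  sum_m |d_m|^2  +  lambda * ||grad chi||^2
#   s.t. d_m + sum_n g_mn chi_n E^t_n = Etilde^s_m    (all f, l, receivers)
#        box bounds on Re(chi), Im(chi)
#
# Eliminating the slack d through the equality rows gives the equivalent
# bound-constrained regularized least-squares problem in chi, whose complex
# normal equations are assembled frequency-block-wise as
#   A^H A = sum_f K_f o C_f,   K_f = G_S^H G_S,  C_f = Conj(E) E^T,
# (o = Hadamard product), so the cost is independent of the number of
# stacked rows. Box-activated solutions are refined by an active-set
# iteration on the 2N-dimensional real form.

#' Discrete gradient roughness penalty
#'
#' Sparse `N x N` matrix `P = D' D` where `D` stacks forward first
#' differences in x and y with replicate (zero-flux) boundary handling, so
#' `chi' P chi = ||grad chi||^2` on the pixel lattice.
#'
#' @param grid An [build_grid()] grid.
#' @return A sparse symmetric matrix (class `dgCMatrix`).
#' @export
gradient_penalty <- function(grid) {
  cache_get(sprintf("P|%g|%d", grid$extent, grid$M),
            .gradient_penalty(grid))
}

.gradient_penalty <- function(grid) {
  M <- grid$M
  idx <- matrix(seq_len(grid$N), M, M)  # rows = x, cols = y
  from <- c(idx[-M, ], idx[, -M])
  to <- c(idx[-1, ], idx[, -1])
  nd <- length(from)
  D <- Matrix::sparseMatrix(i = rep(seq_len(nd), 2), j = c(from, to),
                            x = rep(c(-1, 1), each = nd),
                            dims = c(nd, grid$N))
  Matrix::crossprod(D)
}

# Cache key for the (grid, receiver array, frequency list) geometry.
operator_key <- function(grid, array, medium) {
  sprintf("%g|%d|%d|%.9g|%s", grid$extent, grid$M, array$n_receivers,
          array$radius, paste(sprintf("%.9g", medium$k_b), collapse = ","))
}

default_bounds <- function(medium, eps_range = c(2.5, 67),
                           sigma_range = c(0, 4), ref_index = NULL) {
  ref_index <- ref_index %||% ((medium$F + 1L) %/% 2L)
  w <- medium$omega[ref_index] * medium$eps_b
  list(re = sort((eps_range - medium$eps_rb) / medium$eps_rb),
       im = sort(-(sigma_range - medium$sigma_b) / w),
       eps_range = eps_range, sigma_range = sigma_range,
       ref_index = as.integer(ref_index))
}

#' Assemble the stacked contrast-update quadratic program
#'
#' Builds one QP covering all `F x L` incidences that share a single complex
#' contrast vector: objective `sum |d_m|^2 + lambda * ||grad chi||^2`,
#' equality rows `d_m + sum_n g_mn chi_n E^t_n = Etilde^s_m` split into real
#' and imaginary parts, and box bounds on `Re(chi)`, `Im(chi)`. The system
#' is stored implicitly (per-frequency operators); [qp_dense()] materializes
#' the explicit real form for small problems.
#'
#' @param dataset An `mwi_dataset` of measured scattered fields.
#' @param E_t Complex array `(N, L, F)` of current total-field estimates.
#' @param G_S_list List of `F` complex `Nr x N` receiver Green matrices.
#' @param lambda Tikhonov weight (>= 0), or `NULL` for the scale-free
#'   default `tr(A^H A) / tr(P)`, which balances the data and roughness
#'   curvatures; see the methods vignette for how this weight was chosen.
#' @param bounds Box bounds as returned by the internal default: a list with
#'   `re` and `im` ranges for the contrast parts.
#' @param grid The inversion grid.
#' @param freq_subset Optional indices restricting the stacked frequencies.
#' @param op_key Optional cache key identifying the (grid, receiver,
#'   frequency) geometry; when given, geometry-constant operator products
#'   are memoized across repeated assemblies.
#' @return An object of class `mwi_qp`.
#' @export
assemble_qp <- function(dataset, E_t, G_S_list, lambda = NULL, bounds = NULL,
                        grid, freq_subset = NULL, op_key = NULL) {
  if (!inherits(dataset, "mwi_dataset"))
    abort_argument("`dataset` must be an mwi_dataset")
  dm <- dim(dataset$E_s)
  freq_subset <- freq_subset %||% seq_len(dm[1])
  Fn <- length(freq_subset); L <- dm[2]; Nr <- dm[3]
  N <- grid$N
  if (length(G_S_list) != Fn)
    abort_argument("`G_S_list` must have one matrix per stacked frequency")
  if (!all(dim(E_t) == c(N, L, Fn)))
    abort_argument("`E_t` must be a complex (N, L, F) array matching G_S_list")
  for (f in seq_len(Fn))
    if (!all(dim(G_S_list[[f]]) == c(Nr, N)))
      abort_argument("G_S_list[[%d]] must be %d x %d", f, Nr, N)
  if (!is.null(lambda) && (!is_number(lambda) || lambda < 0))
    abort_argument("`lambda` must be a non-negative scalar")
  bounds <- bounds %||% default_bounds(dataset$medium)
  P <- gradient_penalty(grid)
  if (is.null(lambda)) {
    tr_data <- 0
    for (f in seq_len(Fn)) {
      cn <- colSums(Mod(G_S_list[[f]])^2)
      tr_data <- tr_data + sum(cn * rowSums(Mod(E_t[, , f, drop = FALSE])^2))
    }
    lambda <- tr_data / sum(Matrix::diag(P))
  }
  structure(list(
    G_S = G_S_list, E_t = E_t,
    E_s = dataset$E_s[freq_subset, , , drop = FALSE],
    lambda = lambda, bounds = bounds, P = P, grid = grid,
    op_key = op_key,
    dims = list(F = Fn, L = L, Nr = Nr, N = N,
                n_eq = 2L * Fn * L * Nr,
                n_unknowns = 2L * Fn * L * Nr + 2L * N)
  ), class = "mwi_qp")
}

#' @export
print.mwi_qp <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<mwi_qp> %d equality rows, %d unknowns (slack %d + contrast %d), lambda = %.3g\n",
    d$n_eq, d$n_unknowns, 2 * d$F * d$L * d$Nr, 2 * d$N, x$lambda))
  invisible(x)
}

# Complex stacked map A chi, returned as (Nr x L x F) array.
qp_apply <- function(system, chi) {
  d <- system$dims
  out <- base::array(0i, c(d$Nr, d$L, d$F))
  for (f in seq_len(d$F))
    out[, , f] <- system$G_S[[f]] %*% (chi * system$E_t[, , f])
  out
}

# Measured data as (Nr x L x F) array.
qp_rhs <- function(system) {
  aperm(system$E_s, c(3, 2, 1))
}

#' Objective value of a QP system at a feasible point
#'
#' With the slack eliminated through the equality rows, the objective at a
#' contrast `chi` is the data misfit `sum |Etilde - A chi|^2` plus
#' `lambda * ||grad chi||^2`.
#'
#' @param system An `mwi_qp`.
#' @param chi Complex contrast vector.
#' @return List with `objective`, `misfit` and `penalty` components.
#' @export
qp_objective <- function(system, chi) {
  res <- qp_rhs(system) - qp_apply(system, chi)
  misfit <- sum(Mod(res)^2)
  pen <- sum(Re(chi) * as.vector(system$P %*% Re(chi))) +
    sum(Im(chi) * as.vector(system$P %*% Im(chi)))
  list(objective = misfit + system$lambda * pen, misfit = misfit,
       penalty = pen)
}

#' Materialize the explicit real-valued QP
#'
#' Expands the implicit system into the stacked real form: equality matrix
#' `[I | B]` over unknowns `[Re d; Im d; Re chi; Im chi]`-style stacking
#' (slack first), right-hand side, and per-variable box bounds. Intended
#' for small systems (tests, dense oracles); memory grows as
#' `n_eq * 2N`.
#'
#' @param system An `mwi_qp`.
#' @return List with `B` (real `n_eq x 2N` data matrix), `Aeq = [I B]`,
#'   `beq`, `lambda`, `P_real`, and bound vectors `lower`, `upper` for the
#'   contrast part.
#' @export
qp_dense <- function(system) {
  d <- system$dims
  Ac <- matrix(0i, d$F * d$L * d$Nr, d$N)
  r <- 0L
  for (f in seq_len(d$F)) for (l in seq_len(d$L)) {
    Ac[r + seq_len(d$Nr), ] <- system$G_S[[f]] *
      rep(system$E_t[, l, f], each = d$Nr)
    r <- r + d$Nr
  }
  bc <- as.vector(vapply(seq_len(d$F), function(f)
    as.vector(t(system$E_s[f, , ])), complex(d$L * d$Nr)))
  B <- rbind(cbind(Re(Ac), -Im(Ac)), cbind(Im(Ac), Re(Ac)))
  beq <- c(Re(bc), Im(bc))
  Pr <- as.matrix(Matrix::bdiag(system$P, system$P))
  list(B = B, Aeq = cbind(diag(nrow(B)), B), beq = beq,
       lambda = system$lambda, P_real = Pr,
       lower = c(rep(system$bounds$re[1], d$N), rep(system$bounds$im[1], d$N)),
       upper = c(rep(system$bounds$re[2], d$N), rep(system$bounds$im[2], d$N)))
}

# Complex normal-equation blocks: H = A^H A + lambda P, c = A^H b.
# The receiver Gram matrices K_f = G_S^H G_S and the dense penalty are
# geometry constants, memoized when the system carries an op_key.
qp_normal <- function(system) {
  d <- system$dims
  H <- matrix(0i, d$N, d$N)
  cc <- complex(d$N)
  for (f in seq_len(d$F)) {
    G <- system$G_S[[f]]
    E <- system$E_t[, , f]
    K <- if (is.null(system$op_key)) Conj(t(G)) %*% G else
      cache_get(sprintf("K|%s|%d", system$op_key, f), Conj(t(G)) %*% G)
    C <- Conj(E) %*% t(E)
    H <- H + K * C
    Bt <- Conj(t(G)) %*% t(system$E_s[f, , ])   # N x L
    cc <- cc + rowSums(Conj(E) * Bt)
  }
  Pd <- if (is.null(system$op_key)) as.matrix(system$P) else
    cache_get(sprintf("Pd|%g|%d", system$grid$extent, d$N),
              as.matrix(system$P))
  H <- H + system$lambda * Pd
  list(H = H, c = cc)
}

#' Solve the contrast-update quadratic program
#'
#' Finds the global minimizer of the convex QP assembled by [assemble_qp()].
#' The unconstrained regularized normal equations are solved first; if any
#' box bound is active, the solution is refined by an active-set iteration
#' on the real form, with a projected-gradient (L-BFGS-B) polish as a
#' fallback. The KKT projected-gradient residual of the returned point is
#' reported.
#'
#' @param system An `mwi_qp`.
#' @param tol Relative tolerance on the KKT (projected-gradient) residual.
#' @param warm Optional complex contrast vector used to warm-start the
#'   projected-Newton iteration (e.g. the previous Born iterate).
#' @param max_iter Cap on projected-Newton iterations when bounds are
#'   active. Defaults to full convergence for small systems and a fixed
#'   budget (with warm starts across Born iterations) at production sizes,
#'   where the ill-conditioned free-set Hessian makes exact stationarity
#'   uneconomical; see the methods vignette.
#' @return List of class `mwi_qp_solution`: `chi` (complex vector),
#'   `objective`, `misfit`, `penalty`, `kkt_residual`, `bounded`
#'   (were bounds active), `iterations`.
#' @export
solve_qp <- function(system, tol = 1e-8, warm = NULL, max_iter = NULL) {
  d <- system$dims
  nb <- qp_normal(system)
  lo <- c(rep(system$bounds$re[1], d$N), rep(system$bounds$im[1], d$N))
  hi <- c(rep(system$bounds$re[2], d$N), rep(system$bounds$im[2], d$N))
  scale_ref <- max(Mod(nb$c), max(Mod(diag(nb$H))), 1e-300)
  slack <- 1e-10 * max(hi - lo)
  max_iter <- max_iter %||% (if (d$N > 256) 12L else 200L)

  chi0 <- tryCatch(as.vector(solve(nb$H, nb$c)), error = function(e)
    abort_solver("QP normal equations are singular: %s (increase lambda)",
                 conditionMessage(e)))
  x <- c(Re(chi0), Im(chi0))
  bounded <- any(x < lo - slack | x > hi + slack)
  iters <- 0L
  if (bounded) {
    n2 <- 2L * d$N
    Hr <- matrix(0, n2, n2)
    idx1 <- seq_len(d$N); idx2 <- d$N + idx1
    Hr[idx1, idx1] <- Re(nb$H); Hr[idx2, idx2] <- Re(nb$H)
    Hr[idx1, idx2] <- -Im(nb$H); Hr[idx2, idx1] <- Im(nb$H)
    cr <- c(Re(nb$c), Im(nb$c))
    if (!is.null(warm)) x <- c(Re(warm), Im(warm))
    x <- pmin(pmax(x, lo), hi)
    eps_a <- 1e-8 * max(hi - lo)
    Hx <- as.vector(Hr %*% x)
    f_cur <- 0.5 * sum(x * Hx) - sum(cr * x)
    for (it in seq_len(max_iter)) {
      iters <- it
      g <- Hx - cr
      fixed <- (x <= lo + eps_a & g > 0) | (x >= hi - eps_a & g < 0)
      if (max(abs(proj_grad(g, x, lo, hi, eps_a))) <= tol * scale_ref) break
      free <- !fixed
      if (!any(free)) break
      rhs <- cr[free] - as.vector(Hr[free, fixed, drop = FALSE] %*% x[fixed])
      Hff <- Hr[free, free, drop = FALSE]
      xf <- tryCatch({
        R <- chol(Hff)
        backsolve(R, backsolve(R, rhs, transpose = TRUE))
      }, error = function(e)
        tryCatch(solve(Hff, rhs), error = function(e2) NULL))
      if (is.null(xf)) break
      dvec <- numeric(length(x))
      dvec[free] <- as.vector(xf) - x[free]
      # exact quadratic step along the Newton direction, truncated at the
      # first blocking bound, so the step stays feasible and the objective
      # update is analytic (one matvec per iteration)
      gd <- sum(g * dvec)
      Hd <- as.vector(Hr %*% dvec)
      dHd <- sum(dvec * Hd)
      alpha_star <- if (dHd > 0) min(1, -gd / dHd) else 1
      pos <- dvec > 0; neg <- dvec < 0
      alpha_max <- suppressWarnings(min(
        if (any(pos)) (hi[pos] - x[pos]) / dvec[pos] else Inf,
        if (any(neg)) (lo[neg] - x[neg]) / dvec[neg] else Inf))
      stepped <- FALSE
      if (alpha_max < 0.1 * alpha_star) {
        # severely blocked: try the clipped full step, which activates
        # many bounds at once (one extra matvec to verify descent)
        xc <- pmin(pmax(x + alpha_star * dvec, lo), hi)
        Hxc <- as.vector(Hr %*% xc)
        fc <- 0.5 * sum(xc * Hxc) - sum(cr * xc)
        if (fc < f_cur) {
          x <- xc; Hx <- Hxc; f_cur <- fc; stepped <- TRUE
        }
      }
      if (!stepped) {
        alpha <- max(min(alpha_star, alpha_max), 0)
        if (alpha <= 0) break
        x <- pmin(pmax(x + alpha * dvec, lo), hi)
        Hx <- Hx + alpha * Hd
        f_new <- f_cur + alpha * gd + 0.5 * alpha^2 * dHd
        if (abs(f_cur - f_new) <= 1e-14 * max(abs(f_cur), 1) &&
            alpha * max(abs(dvec)) <= slack) { f_cur <- f_new; break }
        f_cur <- f_new
      }
    }
    g <- Hx - cr
    kkt <- max(abs(proj_grad(g, x, lo, hi, eps_a))) / scale_ref
  } else {
    # unconstrained stationary point: KKT residual is the linear residual
    kkt <- max(Mod(nb$H %*% chi0 - nb$c)) / scale_ref
  }
  chi <- complex(real = x[seq_len(d$N)], imaginary = x[d$N + seq_len(d$N)])
  obj <- qp_objective(system, chi)
  structure(list(chi = chi, objective = obj$objective, misfit = obj$misfit,
                 penalty = obj$penalty, kkt_residual = kkt,
                 bounded = bounded, iterations = iters),
            class = "mwi_qp_solution")
}

proj_grad <- function(g, x, lo, hi, eps_a) {
  pg <- g
  pg[x <= lo + eps_a] <- pmin(g[x <= lo + eps_a], 0)
  pg[x >= hi - eps_a] <- pmax(g[x >= hi - eps_a], 0)
  pg
}

#' Initial contrast guess
#'
#' Three strategies for initializing the Born iteration: `born_zero` solves
#' the contrast-update QP once with `E_t = E_i` (first-order Born
#' linearization) at the reference frequency using all sources;
#' `multi_freq_source` does the same jointly over all frequencies and
#' sources; `constant_min` returns the uniform contrast corresponding to
#' the minimum permittivity of the configured range (default 2.5).
#'
#' @param dataset An `mwi_dataset`.
#' @param grid Inversion grid.
#' @param mode One of `"born_zero"`, `"multi_freq_source"`,
#'   `"constant_min"`.
#' @param lambda,bounds Passed to [assemble_qp()] for the Born modes.
#' @param eps_min Minimum permittivity for `constant_min`.
#' @return Complex contrast vector of length `grid$N`.
#' @export
initial_guess <- function(dataset, grid,
                          mode = c("multi_freq_source", "born_zero",
                                   "constant_min"),
                          lambda = NULL, bounds = NULL, eps_min = 2.5) {
  mode <- match.arg(mode)
  med <- dataset$medium
  bounds <- bounds %||% default_bounds(med)
  if (mode == "constant_min") {
    return(rep(complex(real = (eps_min - med$eps_rb) / med$eps_rb), grid$N))
  }
  fsub <- if (mode == "born_zero") bounds$ref_index else seq_len(med$F)
  E_i <- incident_fields(dataset$array, grid, med)[, , fsub, drop = FALSE]
  key <- operator_key(grid, dataset$array, med)
  G_S <- lapply(fsub, function(f)
    cache_get(sprintf("GS|%s|%d", key, f),
              green_data(grid, dataset$array, med$k_b[f])))
  sys <- assemble_qp(dataset, E_i, G_S, lambda = lambda, bounds = bounds,
                     grid = grid, freq_subset = fsub,
                     op_key = paste0(key, "|", paste(fsub, collapse = ",")))
  solve_qp(sys)$chi
}

#' Configuration for the Born iterative reconstruction
#'
#' @param iterations Number of contrast updates (the circular validation
#'   uses 10; the breast-phantom runs use 5).
#' @param lambda Tikhonov weight, `NULL` for the scale-free default.
#' @param init Initial-guess mode, see [initial_guess()].
#' @param eps_range,sigma_range Physical box bounds translated into the
#'   contrast box.
#' @param ref_freq_index Reference frequency index for the conductivity
#'   scaling of the shared contrast (default: mid-band).
#' @param tol QP solver tolerance.
#' @param verbose Print per-iteration residuals.
#' @return List of class `bim_config`.
#' @export
bim_config <- function(iterations = 10L, lambda = NULL,
                       init = "multi_freq_source",
                       eps_range = c(2.5, 67), sigma_range = c(0, 4),
                       ref_freq_index = NULL, tol = 1e-8, verbose = FALSE) {
  if (!is_count(iterations) || iterations < 1)
    abort_argument("`iterations` must be a positive integer")
  structure(list(iterations = as.integer(iterations), lambda = lambda,
                 init = init, eps_range = eps_range,
                 sigma_range = sigma_range, ref_freq_index = ref_freq_index,
                 tol = tol, verbose = verbose),
            class = "bim_config")
}

#' Born iterative reconstruction with quadratic-programming updates
#'
#' Alternates (a) a total-field solve on the inversion grid with the current
#' contrast estimate and (b) a Tikhonov-regularized QP contrast update
#' stacked over all sources and frequencies, for a fixed number of
#' iterations. Records the contrast and relative data residual at every
#' iteration and recovers the final permittivity and conductivity maps from
#' the contrast at the reference frequency, clipped to the configured
#' physical ranges.
#'
#' @param dataset An `mwi_dataset`.
#' @param grid Inversion grid (an [build_grid()] grid).
#' @param config A [bim_config()].
#' @return Object of class `mwi_recon` with fields `chi_iterations` (list),
#'   `residuals`, `chi`, `eps_r`, `sigma`, `grid`, `config`, `medium`.
#' @export
bim_reconstruct <- function(dataset, grid, config = bim_config()) {
  if (!inherits(dataset, "mwi_dataset"))
    abort_argument("`dataset` must be an mwi_dataset")
  if (!inherits(grid, "mwi_grid")) abort_argument("`grid` must be an mwi_grid")
  if (!is.null(dataset$fine_M) && dataset$fine_M == grid$M)
    warning("inversion grid equals the simulation grid (inverse crime)",
            call. = FALSE)
  med <- dataset$medium
  bounds <- default_bounds(med, config$eps_range, config$sigma_range,
                           config$ref_freq_index)
  key <- operator_key(grid, dataset$array, med)
  G_S <- lapply(seq_len(med$F), function(f)
    cache_get(sprintf("GS|%s|%d", key, f),
              green_data(grid, dataset$array, med$k_b[f])))
  G_D <- lapply(seq_len(med$F), function(f)
    cache_get(sprintf("GDfull|%g|%d|%.12g", grid$extent, grid$M, med$k_b[f]),
              green_domain(grid, med$k_b[f])))
  E_i <- incident_fields(dataset$array, grid, med)
  data_norm <- sqrt(sum(Mod(dataset$E_s)^2))

  chi <- initial_guess(dataset, grid, config$init, lambda = config$lambda,
                       bounds = bounds)
  chi_iter <- list()
  residuals <- numeric(0)
  L <- dataset$array$n_sources
  E_t <- base::array(0i, c(grid$N, L, med$F))
  for (k in seq_len(config$iterations)) {
    for (f in seq_len(med$F)) {
      E_t[, , f] <- tryCatch(
        solve_total_field(E_i[, , f], G_D[[f]], chi, check = FALSE),
        error = function(e) {
          partial <- list(chi_iterations = chi_iter, residuals = residuals,
                          chi = chi, iteration = k, frequency = f)
          abort_solver(
            "forward solve failed at iteration %d, frequency %d: %s",
            k, f, conditionMessage(e), data = partial)
        })
    }
    sys <- assemble_qp(dataset, E_t, G_S, lambda = config$lambda,
                       bounds = bounds, grid = grid, op_key = key)
    sol <- solve_qp(sys, tol = config$tol, warm = if (k > 1) chi)
    chi <- sol$chi
    chi_iter[[k]] <- chi
    residuals[k] <- if (data_norm > 0) sqrt(sol$misfit) / data_norm else 0
    if (isTRUE(config$verbose))
      message(sprintf("  BIM iteration %d: data residual %.4f", k,
                      residuals[k]))
  }
  maps <- maps_from_contrast(chi, med, bounds$ref_index)
  eps_r <- pmin(pmax(maps$eps_r, config$eps_range[1]), config$eps_range[2])
  sigma <- pmin(pmax(maps$sigma, config$sigma_range[1]),
                config$sigma_range[2])
  structure(list(chi_iterations = chi_iter, residuals = residuals,
                 chi = chi, eps_r = eps_r, sigma = sigma, grid = grid,
                 config = config, medium = med,
                 bounds = bounds),
            class = "mwi_recon")
}

#' @export
print.mwi_recon <- function(x, ...) {
  cat(sprintf(
    "<mwi_recon> %d x %d map after %d iterations; final data residual %.4f\n",
    x$grid$M, x$grid$M, length(x$residuals),
    if (length(x$residuals)) x$residuals[length(x$residuals)] else NA))
  invisible(x)
}
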