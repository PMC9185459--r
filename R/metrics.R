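#' Frobenius-norm relative reconstruction error
#'
#' For each of `Nt` test pairs, the ratio of the Frobenius norm of the
#' difference between the original and the reconstructed relative
#' permittivity maps to the Frobenius norm of the original; the report
#' averages the per-test ratios and states the accuracy
#' `100 * (1 - Re)` in percent.
#'
#' @param truth_maps A numeric matrix, or list of matrices, of original
#'   permittivity maps.
#' @param estimate_maps Matching matrix or list of reconstructed maps.
#' @return Object of class `mwi_error_report`: `Re` (mean relative error),
#'   `accuracy` (percent), `per_test`, `Nt`.
#' @examples
#' truth <- matrix(c(3, 4, 0, 0), 2)
#' relative_error(truth, truth)$Re        # 0
#' relative_error(truth, 2 * truth)$Re    # 1
#' @export
relative_error <- function(truth_maps, estimate_maps) {
  if (!is.list(truth_maps)) truth_maps <- list(truth_maps)
  if (!is.list(estimate_maps)) estimate_maps <- list(estimate_maps)
  if (length(truth_maps) != length(estimate_maps))
    abort_argument("truth and estimate lists must have equal length")
  per <- vapply(seq_along(truth_maps), function(j) {
    tr <- as.matrix(truth_maps[[j]]); es <- as.matrix(estimate_maps[[j]])
    if (!all(dim(tr) == dim(es)))
      abort_argument("map shapes differ in test %d", j)
    denom <- sqrt(sum(tr^2))
    if (denom == 0)
      abort_argument("all-zero truth map in test %d: relative error undefined",
                     j)
    sqrt(sum((tr - es)^2)) / denom
  }, numeric(1))
  re <- mean(per)
  structure(list(Re = re, accuracy = 100 * (1 - re), per_test = per,
                 Nt = length(per)), class = "mwi_error_report")
}

#' @export
print.mwi_error_report <- function(x, ...) {
  cat(sprintf("<mwi_error_report> Re = %.4f (accuracy %.2f%%) over %d test%s\n",
              x$Re, x$accuracy, x$Nt, if (x$Nt == 1) "" else "s"))
  invisible(x)
}

#' Conductivity from permittivity (linear regression model)
#'
#' The tissue conductivity regression `sigma = 0.019 * eps_r - 0.047` S/m,
#' floored at zero (the linear model turns negative below eps_r ~ 2.474,
#' just under the 2.5 lower end of the breast permittivity range).
#'
#' @param eps_map Numeric vector or matrix of relative permittivities.
#' @return Conductivities in S/m, same shape as the input.
#' @examples
#' conductivity_from_permittivity(10)   # 0.143
#' @export
conductivity_from_permittivity <- function(eps_map) {
  pmax(0.019 * eps_map - 0.047, 0)
}
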