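## Two-block partial least squares path modeling (Lohmoller algorithm):
## each gene is a latent variable reflected by its SNP dosages (mode A),
## the inner estimate uses the centroid scheme (sign of the score
## correlation), and the path coefficient between the two latent scores
## equals their Pearson correlation.

#' Configuration for the two-block PLS path model fitter
#'
#' @param tol convergence tolerance: iteration stops when no weight
#'   component changes by more than `tol` (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @param init starting weights: `"ones"` (equal weights, the standard
#'   deterministic default) or `"dominant_eigvec"` (first eigenvector of
#'   the block covariance; useful for degenerate sign-balance cases where
#'   equal weights annihilate the score).
#' @return an object of class `plspm_config`.
#' @export
plspm_config <- function(tol = 1e-6, max_iter = 300,
                         init = c("ones", "dominant_eigvec")) {
  init <- match.arg(init)
  stopifnot(is.numeric(tol), length(tol) == 1, tol > 0, tol < 1,
            max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), init = init),
            class = "plspm_config")
}

init_code <- function(cfg) if (cfg$init == "dominant_eigvec") 1L else 0L

#' Center and scale the columns of a SNP block
#'
#' @param raw numeric matrix (n x p), n >= 3, no constant column.
#' @return matrix whose columns have mean 0 and variance 1 (divisor n-1).
#' @export
standardize_block <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 3) stop("need at least 3 samples to standardize")
  v <- apply(raw, 2, var)
  if (any(v < 1e-24)) {
    bad <- colnames(raw)[v < 1e-24] %||% which(v < 1e-24)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         " (monomorphic SNPs should have been removed by preprocessing)")
  }
  out <- scale(raw)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Fit the two-block PLS path model
#'
#' Alternates outer estimation (latent scores as weighted sums of their
#' standardized indicators, rescaled to unit variance), centroid inner
#' estimation (each block's inner estimate is the other score times
#' `e = sign(cor(xi, eta))`), and mode-A weight updates (weight = correlation
#' of each indicator with its block's inner estimate, vector rescaled to
#' unit norm) until the largest weight change drops below `config$tol`.
#' The returned path coefficient is the Pearson correlation of the two
#' latent scores.
#'
#' Sign indeterminacy is resolved deterministically: by default each
#' block's weight vector is flipped so its largest-magnitude component is
#' positive; with `align_to`, it is instead flipped to have positive
#' inner product with a caller-supplied reference.  [coassoc_test()] uses
#' the latter, aligning the case and control fits (and every resampled
#' refit) to one pooled label-blind reference, which makes the two path
#' coefficients comparable and the whole statistic equivariant under
#' allele recoding.
#'
#' @param X,Y numeric matrices (n x p, n x q) for the two gene blocks.
#' @param config a [plspm_config()].
#' @param standardize if `TRUE` (default) blocks are standardized first;
#'   set to `FALSE` only if `X`, `Y` are already column-standardized.
#' @param align_to optional list with elements `weights_a`, `weights_b`:
#'   reference weight vectors the fitted weights are sign-aligned to
#'   (positive inner product).  Used by [coassoc_test()] to orient the
#'   case and control fits to one pooled reference so their path
#'   coefficients are comparable and the test is equivariant under
#'   allele recoding.
#' @return an object of class `plspm_fit`: unit-norm `weights_a`/`weights_b`,
#'   unit-variance `scores_a`/`scores_b`, `loadings_a`/`loadings_b`
#'   (correlation of each SNP with its own score), `path_coefficient`,
#'   `n_iterations`, `converged`, `inner_sign`.
#' @export
plspm_two_block <- function(X, Y, config = plspm_config(),
                            standardize = TRUE, align_to = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (standardize) {
    X <- standardize_block(X)
    Y <- standardize_block(Y)
  }
  ref_a <- align_to$weights_a %||% numeric(0)
  ref_b <- align_to$weights_b %||% numeric(0)
  f <- cpp_plspm_fit(X, Y, config$tol, config$max_iter, init_code(config),
                     ref_a, ref_b)
  if (isTRUE(f$e_tie))
    warning("cor(xi, eta) hit 0 exactly during iteration; centroid sign e defaulted to +1")
  if (!f$converged)
    warning("PLS path model did not converge in ", config$max_iter,
            " iterations")
  structure(list(weights_a = setNames(drop(f$weights_a), colnames(X)),
                 weights_b = setNames(drop(f$weights_b), colnames(Y)),
                 scores_a = drop(f$scores_a), scores_b = drop(f$scores_b),
                 loadings_a = setNames(drop(f$loadings_a), colnames(X)),
                 loadings_b = setNames(drop(f$loadings_b), colnames(Y)),
                 path_coefficient = f$path_coefficient,
                 n_iterations = f$n_iterations, converged = f$converged,
                 inner_sign = f$inner_sign, config = config),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat("Two-block PLS path model fit\n")
  cat(sprintf("  path coefficient: %.6f\n", x$path_coefficient))
  cat(sprintf("  %d + %d indicators, %d iterations (%s)\n",
              length(x$weights_a), length(x$weights_b), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.plspm_fit <- function(object, ...) {
  c(path_coefficient = object$path_coefficient)
}

#' Check that the path coefficient is direction-free
#'
#' Fits both (X, Y) and (Y, X) and reports whether the two path
#' coefficients agree to 1e-8 (they must: the statistic is a correlation,
#' the structural arrow carries no direction).
#'
#' @inheritParams plspm_two_block
#' @return `TRUE`/`FALSE`.
#' @export
path_symmetry_check <- function(X, Y, config = plspm_config()) {
  b_xy <- plspm_two_block(X, Y, config)$path_coefficient
  b_yx <- plspm_two_block(Y, X, config)$path_coefficient
  abs(b_xy - b_yx) < 1e-8
}
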