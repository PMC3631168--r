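#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash used to give every resampling stream
#' (bootstrap, permutation) and every simulated dataset its own seed, so
#' that results do not depend on execution order or worker count.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream/dataset index.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483629
  s <- ((as.double(master) %% m) * 69069 + (as.double(index) %% m) * 1234567 +
          as.double(index)^2 %% m) %% m
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact binomial confidence interval for a rejection rate
#'
#' @param x number of rejections.
#' @param n number of replicates.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)` (Clopper-Pearson).
#' @export
exact_binom_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(0, 1))
  ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
  c(ci[1], ci[2])
}

# stable short hash of an R object (for provenance lines in output tables)
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

# add-one permutation p-value estimator: valid, never zero.  The tie
# comparison uses a 1e-12 relative tolerance so that label assignments
# equivalent to the observed one (computed along a different
# floating-point path) still count as >=.
perm_pvalue <- function(obs, perm) {
  (1 + sum(abs(perm) >= abs(obs) * (1 - 1e-12))) / (1 + length(perm))
}
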