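# Fixture builders shared across the test files.  Everything is generated
# in code under fixed seeds; no binary fixtures.

# independent-SNP case-control dataset with a null phenotype
toy_dataset <- function(n_case = 30, n_ctrl = 30, p = 3, q = 4, seed = 1,
                        mafs_a = NULL, mafs_b = NULL) {
  set.seed(seed)
  mafs_a <- mafs_a %||% rep(0.3, p)
  mafs_b <- mafs_b %||% rep(0.4, q)
  n <- n_case + n_ctrl
  dos <- cbind(
    sapply(mafs_a, function(f) rbinom(n, 2, f)),
    sapply(mafs_b, function(f) rbinom(n, 2, f)))
  colnames(dos) <- c(paste0("a", seq_len(p)), paste0("b", seq_len(q)))
  gom <- setNames(rep(c("GA", "GB"), c(p, q)), colnames(dos))
  genotype_dataset(dos, gom, c(rep(1L, n_case), rep(0L, n_ctrl)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# swap case/control labels of a dataset
swap_labels <- function(ds) {
  genotype_dataset(ds$dosages, ds$gene_of_snp, 1L - ds$phenotype,
                   ds$sample_ids)
}

# correlated two-block continuous data for fitter-level tests
random_blocks <- function(n, p, q, seed, shared = 1) {
  set.seed(seed)
  common <- matrix(rnorm(n * shared), n, shared)
  X <- matrix(rnorm(n * p), n, p) + common %*% matrix(rnorm(shared * p),
                                                      shared, p)
  Y <- matrix(rnorm(n * q), n, q) + common %*% matrix(rnorm(shared * q),
                                                      shared, q)
  list(X = X, Y = Y)
}

# first singular vectors of the cross-correlation matrix, sign-aligned to
# the package's convention (largest-magnitude component positive):
# the independent oracle for the converged mode-A/centroid fixed point
svd_oracle <- function(X, Y) {
  n <- nrow(X)
  C <- crossprod(X, Y) / (n - 1)
  s <- svd(C)
  u <- s$u[, 1]; v <- s$v[, 1]
  if (u[which.max(abs(u))] < 0) u <- -u
  if (v[which.max(abs(v))] < 0) v <- -v
  list(u = u, v = v, beta = drop(cor(X %*% u, Y %*% v)))
}

fixture_path <- function(f) system.file("extdata", f, package = "coassoc")
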