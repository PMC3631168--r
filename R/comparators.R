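## The four benchmark tests: single-SNP logistic with min-p permutation
## adjustment, PCA-based logistic interaction, the first-canonical-
## correlation difference (CCU), and the covariance-difference statistic
## with Moore-Penrose fallback.

#' Maximum-likelihood logistic regression fit
#'
#' Thin validated wrapper around IRLS (`glm.fit`) returning Wald
#' statistics per term.  Non-convergence and (quasi-)separation are
#' reported through `converged = FALSE`, never as silent garbage.
#'
#' @param design numeric model matrix (n x k), including the intercept
#'   column if one is wanted.
#' @param y 0/1 response vector.
#' @return an object of class `logistic_fit`: `coefficients`, `se`, `z`,
#'   `p`, `converged`.
#' @export
fit_logistic <- function(design, y) {
  design <- as.matrix(design)
  y <- as.numeric(y)
  if (nrow(design) <= ncol(design))
    stop("need more observations than parameters")
  if (length(unique(y)) < 2) stop("response must contain both classes")
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dep <- setdiff(seq_len(ncol(design)), qr_d$pivot[seq_len(qr_d$rank)])
    nm <- colnames(design)[dep] %||% dep
    stop("rank-deficient design: collinear column(s) ",
         paste(nm, collapse = ", "))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(design, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  w <- fit$weights
  xtwx <- crossprod(design * sqrt(w))
  covb <- tryCatch(solve(xtwx), error = function(e) NULL)
  converged <- fit$converged && !sep_warn && !is.null(covb) &&
    max(abs(beta)) < 25
  se <- if (is.null(covb)) rep(NA_real_, length(beta)) else sqrt(diag(covb))
  z <- beta / se
  structure(list(coefficients = beta, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), converged = converged,
                 separation = sep_warn),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p),
        digits = 4)
  invisible(x)
}

comparator_result <- function(method, statistic, p_value, detail,
                              ...) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 detail = detail, ...),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g\n", x$method,
              x$statistic, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.comparator_result <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic, p_value = x$p_value)
}

get_blocks <- function(ds, gene_a, gene_b) {
  if (anyNA(ds$dosages))
    stop("dataset contains missing dosages; run preprocess_genotypes() first")
  list(A = ds$dosages[, gene_block(ds, gene_a), drop = FALSE],
       B = ds$dosages[, gene_block(ds, gene_b), drop = FALSE],
       y = ds$phenotype)
}

#' Single-SNP logistic interaction scan with min-p permutation adjustment
#'
#' For every SNP pair (one SNP from each gene) fits
#' `logit P(y=1) = b0 + b1 snp_a + b2 snp_b + b3 snp_a*snp_b` and takes the
#' Wald p-value of the product term; the observed statistic is the
#' smallest p-value over all pairs, and its significance is assessed
#' against the permutation distribution of the minimum (max-T style:
#' phenotype labels permuted, minimum re-taken over all pairs), with the
#' add-one estimator.  Pairs whose fit fails (separation, collinearity)
#' are skipped and counted.
#'
#' @param ds a preprocessed [genotype_dataset()].
#' @param gene_a,gene_b gene labels.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return a `comparator_result`; `detail` holds the best pair
#'   (`snp_a`, `snp_b`, `p_unadj`, `p_adj`) and the full per-pair p matrix.
#' @export
snp_logistic_minp <- function(ds, gene_a, gene_b, n_perm = 1000, seed = 1L) {
  bl <- get_blocks(ds, gene_a, gene_b)
  set.seed(seed)
  res <- cpp_snp_logistic_minp(bl$A, bl$B, as.numeric(bl$y),
                               as.integer(n_perm))
  if (isTRUE(res$error))
    stop("logistic fit failed for every SNP pair of ", gene_a, " x ", gene_b)
  pmat <- res$p_matrix
  dimnames(pmat) <- list(colnames(bl$A), colnames(bl$B))
  best <- which(pmat == res$min_p, arr.ind = TRUE)[1, ]
  p_adj <- (1 + sum(res$perm_min_p <= res$min_p)) / (1 + n_perm)
  n_fail <- length(pmat) - res$n_pairs_ok
  if (n_fail > 0)
    message(n_fail, " SNP pair(s) skipped (logistic fit failed)")
  comparator_result(
    "snp_logistic", statistic = res$min_p, p_value = p_adj,
    detail = data.frame(snp_a = rownames(pmat)[best[1]],
                        snp_b = colnames(pmat)[best[2]],
                        p_unadj = res$min_p, p_adj = p_adj),
    p_matrix = pmat, n_perm = as.integer(n_perm), seed = as.integer(seed),
    n_pairs_failed = n_fail)
}

#' PCA-based logistic interaction test
#'
#' Summarizes each gene by the first principal component of its pooled
#' (cases + controls) standardized dosage block -- pooling avoids leaking
#' the phenotype into the score -- and tests the product term of
#' `logit P(y=1) = b0 + b1 PC1_A + b2 PC1_B + b3 PC1_A*PC1_B` by Wald.
#' PC sign is fixed by making the largest-magnitude loading positive.
#'
#' @inheritParams snp_logistic_minp
#' @return a `comparator_result` (statistic = Wald z of the product term);
#'   `converged` flags logistic failure.
#' @export
pca_logistic_test <- function(ds, gene_a, gene_b) {
  bl <- get_blocks(ds, gene_a, gene_b)
  pc1 <- function(M) {
    pr <- prcomp(standardize_block(M), center = FALSE, scale. = FALSE)
    v <- pr$rotation[, 1]
    if (v[which.max(abs(v))] < 0) v <- -v
    drop(standardize_block(M) %*% v)
  }
  pa <- pc1(bl$A); pb <- pc1(bl$B)
  design <- cbind(`(Intercept)` = 1, pc1_a = pa, pc1_b = pb,
                  interaction = pa * pb)
  fit <- fit_logistic(design, bl$y)
  comparator_result("pca_logistic", statistic = unname(fit$z[4]),
                    p_value = unname(fit$p[4]),
                    detail = data.frame(term = colnames(design),
                                        estimate = unname(fit$coefficients),
                                        se = unname(fit$se),
                                        p = unname(fit$p)),
                    converged = fit$converged)
}

#' Canonical-correlation (CCU) co-association test
#'
#' The first canonical correlation between the two SNP blocks is computed
#' within each stratum; the statistic is
#' `(cc1_case - cc1_control) / sqrt(var_case + var_control)` with
#' stratified-bootstrap variances, and the p-value comes from the same
#' label-permutation scheme as [coassoc_test()] (numerator-only).
#'
#' Singular within-block correlation matrices fall back to a logged ridge
#' (`1e-8` on the diagonal).
#'
#' @inheritParams coassoc_test
#' @return a `comparator_result` with `cc1_case`, `cc1_control`,
#'   `var_case`, `var_control` attached.
#' @export
ccu_test <- function(ds, gene_a, gene_b, plan = resampling_plan(),
                     config = plspm_config(), min_stratum = 10) {
  bl <- get_blocks(ds, gene_a, gene_b)
  case <- bl$y == 1L
  p <- ncol(bl$A); q <- ncol(bl$B)
  for (nn in c(sum(case), sum(!case)))
    if (nn <= p + q)
      stop("stratum size ", nn, " must exceed p + q = ", p + q)
  ridged <- FALSE
  c1 <- cpp_cc1(standardize_block(bl$A[case, , drop = FALSE]),
                standardize_block(bl$B[case, , drop = FALSE]))
  c0 <- cpp_cc1(standardize_block(bl$A[!case, , drop = FALSE]),
                standardize_block(bl$B[!case, , drop = FALSE]))
  ridged <- isTRUE(c1$ridged) || isTRUE(c0$ridged)
  if (ridged) message("singular within-block correlation; ridge 1e-8 applied")

  boot_seed <- derive_seed(plan$seed, 1L)
  boot1 <- { set.seed(boot_seed)
    cpp_ccu_boot(bl$A[case, , drop = FALSE], bl$B[case, , drop = FALSE],
                 plan$n_boot, plan$max_boot_fail) }
  boot0 <- { set.seed(boot_seed)
    cpp_ccu_boot(bl$A[!case, , drop = FALSE], bl$B[!case, , drop = FALSE],
                 plan$n_boot, plan$max_boot_fail) }
  if (isTRUE(boot1$error) || isTRUE(boot0$error))
    stop("more than 10% of CCU bootstrap replicates failed")
  v1 <- var(drop(boot1$cc1)); v0 <- var(drop(boot0$cc1))
  diff <- c1$cc1 - c0$cc1
  stat <- u_statistic(diff, sqrt(v1 + v0))

  set.seed(derive_seed(plan$seed, 2L))
  pm <- cpp_ccu_perm(bl$A, bl$B, as.integer(bl$y), plan$n_perm)
  if (isTRUE(pm$error)) stop("CCU permutation loop kept failing")
  p_perm <- perm_pvalue(diff, drop(pm$diffs))

  comparator_result("ccu", statistic = stat, p_value = p_perm,
                    detail = data.frame(cc1_case = c1$cc1,
                                        cc1_control = c0$cc1,
                                        var_case = v1, var_control = v0),
                    cc1_case = c1$cc1, cc1_control = c0$cc1,
                    var_case = v1, var_control = v0, ridged = ridged,
                    n_perm = plan$n_perm, n_boot = plan$n_boot,
                    seed = plan$seed)
}

#' Moore-Penrose pseudo-inverse with a relative singular-value cut
#'
#' Singular values below `tol * max(singular value)` are dropped.
#'
#' @param M numeric matrix.
#' @param tol relative tolerance (default 1e-10).
#' @return the pseudo-inverse, with the retained rank as attribute `rank`.
#' @export
mp_pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  r <- sum(keep)
  out <- if (r == 0) matrix(0, ncol(M), nrow(M))
         else s$v[, keep, drop = FALSE] %*%
           (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  attr(out, "rank") <- r
  out
}

#' Covariance-difference co-association test
#'
#' Vectorizes the difference `d` of the case and control cross-gene
#' covariance blocks (or of the full joint covariance), estimates the
#' sampling covariance `W` of `d` by stratified bootstrap, and forms the
#' quadratic statistic `d' W^- d` with `W^-` the Moore-Penrose
#' pseudo-inverse -- so rank-deficient `W` (high LD between SNPs) can
#' never abort the test.  The primary p-value comes from label
#' permutation with `W` held fixed; the asymptotic chi-square p-value on
#' the pseudo-rank is reported alongside.
#'
#' @inheritParams snp_logistic_minp
#' @param n_boot bootstrap replicates per stratum for estimating `W`.
#' @param blockwise `"cross_block"` (default: only between-gene
#'   covariances, the gene-pair signal) or `"full_joint"` (all pairwise
#'   covariances of the concatenated blocks).
#' @param w_mode `"per_permutation"` (default) re-estimates `W` by
#'   stratified bootstrap inside every permutation, making the permuted
#'   statistic the same function of the label assignment as the observed
#'   one — the permutation test is then exact under the exchangeable
#'   null.  `"fixed"` reuses the observed `W` for every permutation;
#'   cheaper, but `W` then depends on the observed labeling and the test
#'   is measurably anti-conservative.
#' @return a `comparator_result` with `p_chisq`, `rank`, `d` attached.
#' @export
covariance_test <- function(ds, gene_a, gene_b, n_perm = 1000, seed = 1L,
                            n_boot = 200,
                            blockwise = c("cross_block", "full_joint"),
                            w_mode = c("per_permutation", "fixed")) {
  blockwise <- match.arg(blockwise)
  w_mode <- match.arg(w_mode)
  bl <- get_blocks(ds, gene_a, gene_b)
  if (blockwise == "full_joint") {
    J <- cbind(bl$A, bl$B)
    A <- J; B <- J
  } else {
    A <- bl$A; B <- bl$B
  }
  case <- bl$y == 1L
  d <- cpp_crosscov_vec(A[case, , drop = FALSE], B[case, , drop = FALSE]) -
    cpp_crosscov_vec(A[!case, , drop = FALSE], B[!case, , drop = FALSE])
  d <- drop(d)

  boot_seed <- derive_seed(seed, 1L)
  set.seed(boot_seed)
  r1 <- cpp_cov_boot(A[case, , drop = FALSE], B[case, , drop = FALSE],
                     as.integer(n_boot))
  set.seed(boot_seed)
  r0 <- cpp_cov_boot(A[!case, , drop = FALSE], B[!case, , drop = FALSE],
                     as.integer(n_boot))
  W <- cov(r1) + cov(r0)
  if (w_mode == "per_permutation") {
    # same eigenvalue-cut pseudo-inverse as the permutation engine
    Winv <- cpp_sym_pinv(W, 1e-10)
    rk <- sum(eigen(W, symmetric = TRUE, only.values = TRUE)$values >
                1e-10 * max(eigen(W, symmetric = TRUE,
                                  only.values = TRUE)$values))
    stat <- drop(crossprod(d, Winv %*% d))
    set.seed(derive_seed(seed, 2L))
    perm <- cpp_cov_perm_full(A, B, as.integer(bl$y), as.integer(n_perm),
                              as.integer(n_boot), 1e-10)
  } else {
    Winv <- mp_pinv(W)
    rk <- attr(Winv, "rank")
    stat <- drop(crossprod(d, Winv %*% d))
    set.seed(derive_seed(seed, 2L))
    perm <- cpp_cov_perm(A, B, as.integer(bl$y), as.integer(n_perm), Winv)
  }
  p_perm <- (1 + sum(perm >= stat * (1 - 1e-12))) / (1 + n_perm)
  comparator_result("covariance", statistic = stat, p_value = p_perm,
                    detail = data.frame(statistic = stat, rank = rk,
                                        p_perm = p_perm,
                                        p_chisq = pchisq(stat, df = rk,
                                                         lower.tail = FALSE)),
                    p_chisq = pchisq(stat, df = rk, lower.tail = FALSE),
                    rank = rk, d = d, blockwise = blockwise,
                    w_mode = w_mode,
                    n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                    seed = as.integer(seed))
}
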