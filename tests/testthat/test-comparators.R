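test_that("fit_logistic recovers closed-form maximum-likelihood estimates", {
  y <- c(rep(1, 30), rep(0, 70))
  f <- fit_logistic(matrix(1, 100, 1), y)
  expect_equal(unname(f$coefficients), log(30 / 70), tolerance = 1e-8)

  # 2x2 table (a,b;c,d) = (20,30;10,40): slope = log(ad/bc) = log(8/3)
  x <- c(rep(1, 50), rep(0, 50))
  y2 <- c(rep(1, 20), rep(0, 30), rep(1, 10), rep(0, 40))
  f2 <- fit_logistic(cbind(1, x), y2)
  expect_equal(unname(f2$coefficients[2]), log(8 / 3), tolerance = 1e-8)
  expect_true(f2$converged)
})

test_that("fit_logistic flags separation and names collinear columns", {
  x <- c(rep(0, 20), rep(1, 20))
  f <- fit_logistic(cbind(intercept = 1, sep = x), x)
  expect_false(f$converged)
  expect_error(fit_logistic(cbind(a = x, b = 2 * x), x), "collinear.*b")
  expect_error(fit_logistic(cbind(1, x), rep(1, 40)), "both classes")
})

test_that("the C++ IRLS engine matches glm", {
  set.seed(4)
  n <- 200
  X <- cbind(1, rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  X <- cbind(X, X[, 2] * X[, 3])
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * X[, 2] - 0.2 * X[, 4]))
  cf <- coassoc:::cpp_irls_logistic(X, y)
  gf <- glm.fit(X, y, family = binomial())
  expect_true(cf$converged)
  expect_equal(drop(cf$beta), unname(gf$coefficients), tolerance = 1e-6)
  se_glm <- sqrt(diag(solve(crossprod(X * sqrt(gf$weights)))))
  expect_equal(drop(cf$se), unname(se_glm), tolerance = 1e-6)
})

test_that("min-p scan with one pair agrees with a direct permutation test", {
  ds <- toy_dataset(40, 40, 1, 1, seed = 61)
  res <- snp_logistic_minp(ds, "GA", "GB", n_perm = 400, seed = 5)
  # independent route: permute labels, recompute the single Wald p via glm
  wald_p <- function(y) {
    g <- glm(y ~ ds$dosages[, 1] * ds$dosages[, 2], family = binomial())
    summary(g)$coefficients[4, 4]
  }
  obs <- wald_p(ds$phenotype)
  expect_equal(res$statistic, obs, tolerance = 1e-6)
  set.seed(99)
  perm <- replicate(400, wald_p(sample(ds$phenotype)))
  p_manual <- (1 + sum(perm <= obs)) / 401
  expect_lt(abs(res$p_value - p_manual), 0.1)
})

test_that("duplicated SNPs give identical per-pair p-values", {
  ds <- toy_dataset(40, 40, 2, 2, seed = 17)
  dos <- cbind(ds$dosages, a1dup = ds$dosages[, "a1"])
  gom <- c(ds$gene_of_snp, a1dup = "GA")
  ds2 <- genotype_dataset(dos, gom, ds$phenotype)
  r <- snp_logistic_minp(ds2, "GA", "GB", n_perm = 50, seed = 3)
  expect_equal(r$p_matrix["a1", ], r$p_matrix["a1dup", ], tolerance = 1e-10)
})

test_that("PCA test equals the pairwise logistic test when genes have one SNP", {
  ds <- toy_dataset(50, 50, 1, 1, seed = 23)
  r_pca <- pca_logistic_test(ds, "GA", "GB")
  d <- cbind(1, ds$dosages[, 1], ds$dosages[, 2],
             ds$dosages[, 1] * ds$dosages[, 2])
  r_log <- fit_logistic(d, ds$phenotype)
  # PC1 is an affine map of the single SNP: interaction Wald p unchanged
  expect_equal(r_pca$p_value, unname(r_log$p[4]), tolerance = 1e-7)
})

test_that("PCA test is invariant to flipping a gene's coding", {
  ds <- toy_dataset(40, 40, 3, 2, seed = 29)
  r1 <- pca_logistic_test(ds, "GA", "GB")
  dos <- ds$dosages
  dos[, 1:3] <- 2 - dos[, 1:3]
  r2 <- pca_logistic_test(genotype_dataset(dos, ds$gene_of_snp,
                                           ds$phenotype), "GA", "GB")
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-9)
})

test_that("first canonical correlation: 1-D case and brute-force oracle", {
  ds <- toy_dataset(40, 40, 1, 1, seed = 37)
  r <- ccu_test(ds, "GA", "GB",
                resampling_plan(n_perm = 49, n_boot = 30, seed = 2))
  case <- ds$phenotype == 1
  expect_equal(r$cc1_case, abs(cor(ds$dosages[case, 1],
                                   ds$dosages[case, 2])), tolerance = 1e-9)
  expect_equal(r$cc1_control, abs(cor(ds$dosages[!case, 1],
                                      ds$dosages[!case, 2])),
               tolerance = 1e-9)

  # brute-force maximization of cor(Xa, Yb) over direction vectors
  bl <- random_blocks(300, 5, 4, seed = 51)
  X <- standardize_block(bl$X); Y <- standardize_block(bl$Y)
  cc1 <- coassoc:::cpp_cc1(X, Y)$cc1
  best <- 0
  set.seed(8)
  for (s in 1:6) {
    par0 <- rnorm(9)
    o <- optim(par0, function(par) {
      a <- par[1:5]; b <- par[6:9]
      if (sum(a^2) < 1e-12 || sum(b^2) < 1e-12) return(0)
      -abs(cor(X %*% a, Y %*% b))
    }, method = "BFGS", control = list(maxit = 500))
    best <- max(best, -o$value)
  }
  expect_equal(cc1, best, tolerance = 1e-3)
})

test_that("identical strata zero both the CCU and covariance statistics", {
  base <- toy_dataset(30, 30, 2, 2, seed = 43)
  half <- base$dosages[1:30, ]
  dos <- rbind(half, half)
  rownames(dos) <- paste0("S", 1:60)
  ds <- genotype_dataset(dos, base$gene_of_snp, c(rep(1L, 30), rep(0L, 30)))
  r_ccu <- ccu_test(ds, "GA", "GB",
                    resampling_plan(n_perm = 49, n_boot = 30, seed = 4))
  expect_equal(r_ccu$cc1_case - r_ccu$cc1_control, 0, tolerance = 1e-12)
  r_cov <- covariance_test(ds, "GA", "GB", n_perm = 49, seed = 4)
  expect_equal(r_cov$statistic, 0, tolerance = 1e-10)
  expect_equal(max(abs(r_cov$d)), 0, tolerance = 1e-12)
})

test_that("Moore-Penrose pseudo-inverse: quadratic form and rank cut", {
  d <- c(3, 4)
  W <- diag(2)
  expect_equal(drop(crossprod(d, mp_pinv(W) %*% d)), 25)
  # rank-1 matrix: pseudo-inverse satisfies the Penrose conditions
  M <- tcrossprod(c(1, 2, 3))
  Mi <- mp_pinv(M)
  expect_equal(attr(Mi, "rank"), 1)
  expect_equal(M %*% Mi %*% M, M, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(Mi %*% M %*% Mi, Mi, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("covariance test survives rank-deficient blocks", {
  ds <- toy_dataset(40, 40, 2, 2, seed = 47)
  dos <- cbind(ds$dosages, a1dup = ds$dosages[, "a1"])
  ds2 <- genotype_dataset(dos, c(ds$gene_of_snp, a1dup = "GA"),
                          ds$phenotype)
  r <- covariance_test(ds2, "GA", "GB", n_perm = 49, seed = 6)
  expect_true(is.finite(r$statistic))
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("CCU and PLSPM coincide for single-SNP genes up to the |r| convention", {
  ds <- toy_dataset(40, 40, 1, 1, seed = 53)
  plan <- resampling_plan(n_perm = 49, n_boot = 40, seed = 11)
  r_ccu <- ccu_test(ds, "GA", "GB", plan)
  r_pls <- coassoc_test(ds, "GA", "GB", plan)
  # canonical correlations are |r|; the path coefficient keeps the sign
  expect_equal(r_ccu$cc1_case, abs(r_pls$beta_case), tolerance = 1e-9)
  expect_equal(r_ccu$cc1_control, abs(r_pls$beta_control), tolerance = 1e-9)
})
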