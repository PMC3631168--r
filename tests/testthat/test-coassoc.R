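plan_small <- function(seed = 1, ...) {
  resampling_plan(n_perm = 99, n_boot = 50, seed = seed, ...)
}

test_that("U is the variance-standardized path-coefficient difference", {
  # arithmetic forced by the statistic's definition
  expect_equal(coassoc:::u_statistic(0.5 - 0.2, sqrt(0.01 + 0.03)), 1.5)
  expect_equal(coassoc:::u_statistic(0, 0), 0)
  expect_true(is.infinite(coassoc:::u_statistic(0.2, 0)))

  ds <- toy_dataset(20, 20, 2, 2, seed = 8)
  ct <- coassoc_test(ds, "GA", "GB", plan_small())
  expect_equal(ct$U, (ct$beta_case - ct$beta_control) /
                 sqrt(ct$var_case + ct$var_control), tolerance = 1e-12)
  expect_gte(ct$p_perm, 1 / (1 + ct$n_perm))
  expect_lte(ct$p_perm, 1)
})

test_that("two-replicate bootstrap variance is the half squared difference", {
  ds <- toy_dataset(15, 15, 2, 2, seed = 5)
  A <- ds$dosages[, 1:2]; B <- ds$dosages[, 3:4]
  bv <- bootstrap_path_variance(A, B, n_boot = 2, seed = 31)
  expect_equal(bv$variance, (bv$betas[1] - bv$betas[2])^2 / 2,
               tolerance = 1e-14)
})

test_that("perfectly correlated single-SNP blocks give zero bootstrap variance", {
  set.seed(2)
  g <- rbinom(40, 2, 0.4)
  bv <- bootstrap_path_variance(cbind(a = g), cbind(b = g), n_boot = 30,
                                seed = 7)
  expect_lt(bv$variance, 1e-20)
  expect_equal(bv$betas, rep(1, 30), tolerance = 1e-10)
})

test_that("duplicated strata give U = 0 and a large permutation p", {
  base <- toy_dataset(30, 30, 2, 3, seed = 14)
  half <- base$dosages[1:30, ]
  dos <- rbind(half, half)
  rownames(dos) <- paste0("S", 1:60)
  ds <- genotype_dataset(dos, base$gene_of_snp,
                         c(rep(1L, 30), rep(0L, 30)))
  ct <- coassoc_test(ds, "GA", "GB",
                     resampling_plan(n_perm = 999, n_boot = 50, seed = 2))
  expect_equal(ct$beta_case, ct$beta_control, tolerance = 1e-12)
  expect_equal(ct$U, 0, tolerance = 1e-10)
  expect_gte(ct$p_perm, 0.3)
})

test_that("swapping case/control labels negates U and keeps p", {
  ds <- toy_dataset(25, 20, 3, 3, seed = 19)
  plan <- plan_small(seed = 55)
  r1 <- coassoc_test(ds, "GA", "GB", plan)
  r2 <- coassoc_test(swap_labels(ds), "GA", "GB", plan)
  expect_equal(r2$U, -r1$U, tolerance = 1e-14)
  expect_equal(r2$beta_case, r1$beta_control)
  expect_identical(r2$var_case, r1$var_control)
  expect_identical(r2$var_control, r1$var_case)
  expect_identical(r2$p_perm, r1$p_perm)
})

test_that("the full pipeline is deterministic in the seed", {
  ds <- toy_dataset(20, 20, 2, 2, seed = 33)
  r1 <- coassoc_test(ds, "GA", "GB", plan_small(seed = 9))
  r2 <- coassoc_test(ds, "GA", "GB", plan_small(seed = 9))
  r3 <- coassoc_test(ds, "GA", "GB", plan_small(seed = 10))
  for (f in c("beta_case", "beta_control", "var_case", "var_control", "U",
              "p_perm", "U_perm"))
    expect_identical(r1[[f]], r2[[f]])
  expect_false(identical(r1$var_case, r3$var_case))
})

test_that("bootstrap variance tracks the sampling variance of the path coefficient", {
  # independent oracle: re-simulate fresh datasets from the known
  # generator and compare the Monte-Carlo variance of beta with one
  # dataset's bootstrap estimate
  p <- 6; q <- 4; n <- 300
  gen <- function(seed) {
    set.seed(seed)
    list(A = sapply(rep(0.3, p), function(f) cbind(rbinom(n, 2, f))),
         B = sapply(rep(0.4, q), function(f) cbind(rbinom(n, 2, f))))
  }
  # a common fixed orientation: beta's sign is otherwise arbitrary per
  # dataset under independence, which would inflate the MC variance
  ref <- list(weights_a = rep(1, p) / sqrt(p),
              weights_b = rep(1, q) / sqrt(q))
  mc <- vapply(1:2000, function(i) {
    bl <- gen(10000 + i)
    coassoc:::cpp_plspm_fit(standardize_block(bl$A),
                            standardize_block(bl$B),
                            1e-6, 300, 0L, ref$weights_a,
                            ref$weights_b)$path_coefficient
  }, numeric(1))
  bl <- gen(1)
  bv <- bootstrap_path_variance(bl$A, bl$B, n_boot = 2000, seed = 77,
                                align_to = ref)
  ratio <- bv$variance / var(mc)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("permutation p-values are valid under a label-exchangeable null", {
  # coarse uniformity check on cheap independent-SNP null datasets
  pv <- vapply(1:300, function(i) {
    ds <- toy_dataset(25, 25, 2, 2, seed = 4000 + i)
    coassoc_test(ds, "GA", "GB",
                 resampling_plan(n_perm = 99, n_boot = 20,
                                 seed = 5000 + i))$p_perm
  }, numeric(1))
  expect_lt(max(abs(sort(pv) - seq_along(pv) / length(pv))), 0.08)
  expect_true(all(pv >= 1 / 100))
})

test_that("stratum size and gene-name preconditions are enforced", {
  ds <- toy_dataset(5, 30, 2, 2, seed = 3)
  expect_error(coassoc_test(ds, "GA", "GB", plan_small()), "at least 10")
  ds2 <- toy_dataset(15, 15, 2, 2, seed = 3)
  expect_error(coassoc_test(ds2, "GA", "NOPE", plan_small()),
               "unknown gene")
})

test_that("full-recompute permutation mode agrees with numerator-only", {
  ds <- toy_dataset(30, 30, 2, 2, seed = 91)
  p1 <- coassoc_test(ds, "GA", "GB",
                     plan_small(seed = 3))$p_perm
  p2 <- coassoc_test(ds, "GA", "GB",
                     resampling_plan(n_perm = 99, n_boot = 50, seed = 3,
                                     perm_mode = "full_recompute",
                                     n_boot_full = 30))$p_perm
  expect_lt(abs(p1 - p2), 0.25)
})

test_that("null_calibration rejects alternative models and respects alpha bounds", {
  preset <- scenario_presets("scenario1_8x10")
  panel <- preset_panel(preset, n_haplotypes = 2000, seed = 6)
  expect_error(
    null_calibration(panel, preset_model(preset, or_interaction = 1.3),
                     50, 50, n_datasets = 2),
    "null disease model")
  out <- null_calibration(panel, preset_model(preset), 100, 100,
                          n_datasets = 25,
                          alpha_levels = c(0.01, 0.05, 0.1, 1),
                          plan = resampling_plan(n_perm = 49, n_boot = 20),
                          seed = 12, pool_cases = 1500, pool_controls = 1500)
  expect_equal(out$rejection_rate[out$alpha == 1], 1)
  expect_true(all(diff(out$rejection_rate) >= 0))  # nested rejection regions
  expect_true(all(out$ci_low <= out$rejection_rate &
                    out$rejection_rate <= out$ci_high))
})
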