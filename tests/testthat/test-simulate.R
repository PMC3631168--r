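# bivariate-normal orthant probability P(Z1 < a, Z2 < b | rho) by
# 1-D numerical integration -- the oracle for threshold-model LD
orthant_prob <- function(a, b, rho) {
  integrate(function(z)
    dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2)),
    -Inf, a, rel.tol = 1e-10)$value
}

test_that("identity latent LD gives independent SNPs at the declared MAFs", {
  mafs <- rep(0.3, 6)
  pan <- make_synthetic_panel(mafs, diag(6), 50000, seed = 31)
  expect_true(all(abs(pan$maf_hat - 0.3) < 0.01))
  off <- pan$ld_r[upper.tri(pan$ld_r)]
  expect_lt(max(abs(off)), 0.02)
})

test_that("perfect latent correlation duplicates the allele column", {
  pan <- make_synthetic_panel(c(0.4, 0.4), matrix(1, 2, 2), 2000, seed = 5)
  expect_equal(pan$haplotypes[, 1], pan$haplotypes[, 2],
               ignore_attr = TRUE)
  expect_equal(pan$ld_r[1, 2], 1)
})

test_that("empirical allelic LD matches the tetrachoric attenuation oracle", {
  pan <- make_synthetic_panel(rep(0.45, 4), 0.9, 50000, seed = 77)
  a <- qnorm(0.45)
  p11 <- orthant_prob(a, a, 0.9)
  r_expected <- (p11 - 0.45^2) / (0.45 * 0.55)
  adj <- diag(pan$ld_r[, -1, drop = FALSE])  # adjacent pairs
  expect_lt(max(abs(adj - r_expected)), 0.05)
  # attenuation is real: binary r below the latent rho
  expect_lt(r_expected, 0.9)
})

test_that("non-positive-semi-definite latent LD is rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(make_synthetic_panel(rep(0.3, 3), bad, 100, seed = 1),
               "positive semi-definite")
  expect_error(make_synthetic_panel(c(0.6, 0.3), diag(2), 100, seed = 1),
               "0, 0.5")
})

test_that("controls sit at Hardy-Weinberg proportions under low prevalence", {
  preset <- scenario_presets("scenario2_7x7")
  panel <- preset_panel(preset, n_haplotypes = 8000, seed = 3)
  pop <- build_population(panel, preset_model(preset),
                          pool_cases = 500, pool_controls = 100000,
                          seed = 21)
  ctrl <- pop$components[[1]]$controls
  for (j in c("A1", "A4", "B4")) {
    p <- panel$maf_hat[j]
    exp_freq <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(ctrl[, j] + 1L, 3) / nrow(ctrl)
    expect_lt(max(abs(obs - exp_freq)), 0.01)
  }
})

test_that("a null disease model leaves cases and controls exchangeable", {
  preset <- scenario_presets("scenario1_8x10")
  panel <- preset_panel(preset, n_haplotypes = 8000, seed = 9)
  pop <- build_population(panel, preset_model(preset),
                          pool_cases = 100000, pool_controls = 100000,
                          seed = 13)
  maf_case <- colMeans(pop$components[[1]]$cases) / 2
  maf_ctrl <- colMeans(pop$components[[1]]$controls) / 2
  expect_lt(max(abs(maf_case - maf_ctrl)), 0.01)
})

test_that("population building and dataset draws are deterministic", {
  preset <- scenario_presets("scenario2_7x7")
  panel <- preset_panel(preset, n_haplotypes = 2000, seed = 4)
  panel2 <- preset_panel(preset, n_haplotypes = 2000, seed = 4)
  expect_identical(panel$haplotypes, panel2$haplotypes)
  model <- preset_model(preset, or_marginal_a = 1.3, or_marginal_b = 1.7)
  s1 <- sample_population(panel, model, 100, 100, seed = 6,
                          pool_cases = 2000, pool_controls = 2000)
  s2 <- sample_population(panel, model, 100, 100, seed = 6,
                          pool_cases = 2000, pool_controls = 2000)
  expect_identical(s1$dosages, s2$dosages)
})

test_that("remove_causal drops exactly the causal columns once", {
  preset <- scenario_presets("scenario1_8x10")
  panel <- preset_panel(preset, n_haplotypes = 2000, seed = 4)
  sd <- sample_population(panel, preset_model(preset), 50, 50, seed = 2,
                          pool_cases = 1000, pool_controls = 1000)
  expect_equal(length(sd$snp_ids), 18L)
  out <- remove_causal(sd)
  expect_equal(length(out$snp_ids), 16L)
  expect_false(any(c("A4", "B5") %in% out$snp_ids))
  expect_equal(sum(out$gene_of_snp == "GENEA"), 7L)
  expect_equal(sum(out$gene_of_snp == "GENEB"), 9L)
  # provenance keeps the causal ids and the model
  prov <- attr(out, "provenance")
  expect_equal(prov$causal, c("A4", "B5"))
  expect_s3_class(prov$model, "disease_model")
  expect_warning(again <- remove_causal(out), "already absent")
  expect_equal(again$snp_ids, out$snp_ids)
})

test_that("simulator refits recover the generating log odds ratios", {
  # scaled-down parameter-recovery check (the full-size one runs in the
  # acceptance suite): marginal model, logistic refit on the pool
  preset <- scenario_presets("scenario2_7x7")
  panel <- preset_panel(preset, n_haplotypes = 8000, seed = 15)
  model <- preset_model(preset, or_marginal_a = 1.5, or_marginal_b = 1.0)
  pop <- build_population(panel, model, 20000, 20000, seed = 8)
  g <- rbind(pop$components[[1]]$cases, pop$components[[1]]$controls)
  y <- rep(1:0, each = 20000)
  fit <- glm(y ~ g[, "A4"] + g[, "B4"], family = binomial())
  ci <- suppressMessages(confint.default(fit))["g[, \"A4\"]", ]
  expect_gt(log(1.5), ci[1])
  expect_lt(log(1.5), ci[2])
})

test_that("presets have the documented shapes, MAFs and LD structure", {
  p1 <- scenario_presets("scenario1_8x10")
  expect_equal(length(p1$mafs_a), 8L)
  expect_equal(length(p1$mafs_b), 10L)
  expect_equal(p1$mafs_a[p1$causal_a], 0.43)
  expect_equal(p1$mafs_b[p1$causal_b], 0.44)
  p2 <- scenario_presets("scenario2_7x7")
  expect_equal(c(length(p2$mafs_a), length(p2$mafs_b)), c(7L, 7L))
  expect_equal(p2$mafs_a[p2$causal_a], 0.46)
  expect_equal(p2$mafs_b[p2$causal_b], 0.45)

  # unlinked preset: cross-gene allelic LD ~ 0; linked preset: positive
  # cross-gene LD peaked at the causal pair
  pan1 <- preset_panel(p1, n_haplotypes = 20000, seed = 5)
  expect_lt(max(abs(pan1$ld_r[1:8, 9:18])), 0.03)
  pan2 <- preset_panel(p2, n_haplotypes = 20000, seed = 5)
  expect_gt(pan2$ld_r["A4", "B4"], 0.15)
  expect_gte(pan2$ld_r["A4", "B4"] + 0.02, max(pan2$ld_r[1:7, 8:14]))
  expect_error(scenario_presets("nope"), "unknown preset")
})

test_that("every preset generates a valid dataset end-to-end quickly", {
  for (nm in names(scenario_presets())) {
    t0 <- Sys.time()
    panel <- preset_panel(nm, n_haplotypes = 2000, seed = 1)
    sd <- sample_population(panel, preset_model(nm), 100, 100, seed = 2,
                            pool_cases = 1000, pool_controls = 1000)
    sd <- remove_causal(sd)
    expect_s3_class(sd, "genotype_dataset")
    expect_equal(sum(sd$phenotype), 100L)
    expect_true(all(sd$dosages %in% 0:2))
    expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  }
})

test_that("type3 datasets mix the two mechanisms 1:1", {
  preset <- scenario_presets("scenario3_7x7")
  panel <- preset_panel(preset, n_haplotypes = 2000, seed = 3)
  model <- preset_model(preset, or_interaction = 1.3,
                        or_marginal_a = 1.3, or_marginal_b = 1.7)
  pop <- build_population(panel, model, 1000, 1000, seed = 5)
  expect_length(pop$components, 2L)
  expect_equal(pop$components[[1]]$submodel, "type1")
  expect_equal(pop$components[[2]]$submodel, "type2")
  ds <- draw_case_control(pop, 100, 100, seed = 7)
  expect_equal(sum(ds$phenotype == 1L), 100L)
  expect_equal(nrow(ds$dosages), 200L)
})
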