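## The co-association statistic: U = (beta_case - beta_control) /
## sqrt(var_case + var_control), where the betas are per-stratum PLSPM
## path coefficients and the variances come from stratified bootstrap.
## Significance is assessed by case/control label permutation.

#' Resampling plan for the co-association test
#'
#' @param n_perm number of label permutations (default 1000).
#' @param n_boot number of bootstrap replicates per stratum (default 1000).
#' @param seed master seed; the bootstrap and permutation streams are
#'   derived from it with [derive_seed()] (both strata's bootstraps share
#'   one derived seed so that swapping the case/control labels negates the
#'   statistic exactly).
#' @param perm_mode `"numerator_only"` (default) keeps the bootstrap
#'   denominator fixed at its observed value and re-computes only the
#'   path-coefficient difference for permuted labels; `"full_recompute"`
#'   re-estimates the bootstrap variances inside every permutation with
#'   `n_boot_full` replicates (slow; for sensitivity analysis).
#' @param n_boot_full inner bootstrap size for `perm_mode = "full_recompute"`.
#' @param max_boot_fail largest tolerated fraction of failed (redrawn)
#'   bootstrap replicates before erroring (default 0.10).  Tiny strata
#'   legitimately produce many constant-column resamples; raise this
#'   only when the bootstrap denominator is not the quantity of
#'   interest.
#' @return an object of class `resampling_plan`.
#' @export
resampling_plan <- function(n_perm = 1000, n_boot = 1000, seed = 1L,
                            perm_mode = c("numerator_only", "full_recompute"),
                            n_boot_full = 100, max_boot_fail = 0.10) {
  perm_mode <- match.arg(perm_mode)
  stopifnot(n_perm >= 1, n_boot >= 2, n_boot_full >= 2,
            max_boot_fail > 0, max_boot_fail <= 1)
  structure(list(n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 seed = as.integer(seed), perm_mode = perm_mode,
                 n_boot_full = as.integer(n_boot_full),
                 max_boot_fail = max_boot_fail),
            class = "resampling_plan")
}

#' Bootstrap variance of the path coefficient in one stratum
#'
#' Rows are resampled with replacement jointly across both blocks
#' (preserving the SNP-SNP correlation structure), re-standardized inside
#' each replicate and refit with the shared sign convention.  Replicates
#' whose fit degenerates (a resample turning a column constant) are
#' redrawn; more than 10% failures is an error.
#'
#' @param block_a,block_b raw (unstandardized) dosage matrices of one
#'   stratum, same rows.
#' @param n_boot number of replicates.
#' @param seed integer seed for the resampling stream.
#' @param config a [plspm_config()].
#' @param align_to reference weights (list with `weights_a`, `weights_b`)
#'   every replicate's weights are sign-aligned to; defaults to the
#'   observed fit of the given blocks.  Without a coherent orientation
#'   the replicate path coefficients would mix signs and the variance
#'   would be inflated artifactually.
#' @return list with `variance` (empirical variance of the replicate path
#'   coefficients, divisor `n_boot - 1`), `betas`, `se_loadings_a`,
#'   `se_loadings_b` (bootstrap SE of every loading), `n_redraws`.
#' @export
bootstrap_path_variance <- function(block_a, block_b, n_boot, seed,
                                    config = plspm_config(),
                                    align_to = NULL, max_fail_frac = 0.10) {
  block_a <- as.matrix(block_a); block_b <- as.matrix(block_b)
  if (is.null(align_to))
    align_to <- plspm_two_block(block_a, block_b, config)[
      c("weights_a", "weights_b")]
  set.seed(seed)
  bt <- cpp_boot_paths(block_a, block_b, as.integer(n_boot), config$tol,
                       config$max_iter, init_code(config), max_fail_frac,
                       unname(align_to$weights_a),
                       unname(align_to$weights_b))
  if (isTRUE(bt$error))
    stop("more than ", round(100 * max_fail_frac),
         "% of bootstrap replicates failed (", bt$n_redraws,
         " redraws); consider a larger stratum or SNP filtering")
  betas <- drop(bt$betas)
  list(variance = var(betas), betas = betas,
       se_loadings_a = setNames(apply(bt$loadings_a, 2, sd),
                                colnames(block_a)),
       se_loadings_b = setNames(apply(bt$loadings_b, 2, sd),
                                colnames(block_b)),
       n_redraws = bt$n_redraws)
}

u_statistic <- function(diff, denom) {
  if (denom == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / denom
}

#' Test two genes for co-association
#'
#' Standardizes each stratum's SNP blocks within stratum, fits the
#' two-block PLS path model per stratum (shared deterministic sign
#' convention), forms
#' `U = (beta_case - beta_control) / sqrt(var_case + var_control)` with
#' bootstrap variances, and obtains a p-value by permuting the case/control
#' labels (case/control counts preserved) with the add-one estimator
#' `p = (1 + #{|U*| >= |U|}) / (1 + n_perm)`.
#'
#' @param ds a preprocessed [genotype_dataset()] (no missing dosages, no
#'   monomorphic SNPs).
#' @param gene_a,gene_b gene labels present in `ds`.
#' @param plan a [resampling_plan()].
#' @param config a [plspm_config()].
#' @param min_stratum smallest admissible stratum size (default 10).
#' @return an object of class `coassoc_test`; see Details for fields.
#' @details Fields: `beta_case`, `beta_control`, `var_case`, `var_control`,
#'   `U`, `p_perm`, `n_perm`, `n_boot`, `seed`, `perm_mode`, `loadings`
#'   (per-stratum per-SNP loading tables with bootstrap SEs), `fits`
#'   (the two `plspm_fit` objects), `n_redraws`.
#' @export
coassoc_test <- function(ds, gene_a, gene_b, plan = resampling_plan(),
                         config = plspm_config(), min_stratum = 10) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (anyNA(ds$dosages))
    stop("dataset contains missing dosages; run preprocess_genotypes() first")
  ia <- gene_block(ds, gene_a)
  ib <- gene_block(ds, gene_b)
  A <- ds$dosages[, ia, drop = FALSE]
  B <- ds$dosages[, ib, drop = FALSE]
  case <- ds$phenotype == 1L
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 < min_stratum || n0 < min_stratum)
    stop("each stratum needs at least ", min_stratum, " subjects (",
         n1, " cases, ", n0, " controls)")

  # pooled (label-blind) fit: the common sign reference that makes
  # beta_case and beta_control comparable and the whole statistic
  # equivariant under allele recoding and label swaps
  ref <- plspm_two_block(A, B, config)[c("weights_a", "weights_b")]
  fit_case <- plspm_two_block(A[case, , drop = FALSE],
                              B[case, , drop = FALSE], config,
                              align_to = ref)
  fit_ctrl <- plspm_two_block(A[!case, , drop = FALSE],
                              B[!case, , drop = FALSE], config,
                              align_to = ref)
  beta_case <- fit_case$path_coefficient
  beta_ctrl <- fit_ctrl$path_coefficient

  boot_seed <- derive_seed(plan$seed, 1L)
  bc <- bootstrap_path_variance(A[case, , drop = FALSE],
                                B[case, , drop = FALSE],
                                plan$n_boot, boot_seed, config,
                                align_to = fit_case[c("weights_a",
                                                      "weights_b")],
                                max_fail_frac = plan$max_boot_fail)
  b0 <- bootstrap_path_variance(A[!case, , drop = FALSE],
                                B[!case, , drop = FALSE],
                                plan$n_boot, boot_seed, config,
                                align_to = fit_ctrl[c("weights_a",
                                                      "weights_b")],
                                max_fail_frac = plan$max_boot_fail)
  var_case <- bc$variance; var_ctrl <- b0$variance
  denom <- sqrt(var_case + var_ctrl)
  U <- u_statistic(beta_case - beta_ctrl, denom)

  perm_seed <- derive_seed(plan$seed, 2L)
  set.seed(perm_seed)
  if (plan$perm_mode == "numerator_only") {
    pm <- cpp_perm_beta_diff(A, B, as.integer(ds$phenotype), plan$n_perm,
                             config$tol, config$max_iter, init_code(config),
                             unname(ref$weights_a), unname(ref$weights_b))
    if (isTRUE(pm$error))
      stop("permutation loop kept producing degenerate strata (",
           pm$n_redraws, " redraws)")
    U_perm <- if (denom == 0) drop(pm$diffs) * Inf else drop(pm$diffs) / denom
    # same fixed denominator on both sides: comparing |U*| to |U| is
    # comparing the absolute beta differences
    p_perm <- perm_pvalue(beta_case - beta_ctrl, drop(pm$diffs))
  } else {
    pm <- cpp_perm_U_full(A, B, as.integer(ds$phenotype), plan$n_perm,
                          plan$n_boot_full, config$tol, config$max_iter,
                          init_code(config), plan$max_boot_fail,
                          unname(ref$weights_a), unname(ref$weights_b))
    U_perm <- drop(pm$U)
    p_perm <- perm_pvalue(U, U_perm)
  }

  loadings <- rbind(
    data.frame(stratum = "case", gene = gene_a, snp = names(fit_case$loadings_a),
               loading = unname(fit_case$loadings_a),
               loading_se = unname(bc$se_loadings_a)),
    data.frame(stratum = "case", gene = gene_b, snp = names(fit_case$loadings_b),
               loading = unname(fit_case$loadings_b),
               loading_se = unname(bc$se_loadings_b)),
    data.frame(stratum = "control", gene = gene_a,
               snp = names(fit_ctrl$loadings_a),
               loading = unname(fit_ctrl$loadings_a),
               loading_se = unname(b0$se_loadings_a)),
    data.frame(stratum = "control", gene = gene_b,
               snp = names(fit_ctrl$loadings_b),
               loading = unname(fit_ctrl$loadings_b),
               loading_se = unname(b0$se_loadings_b)))

  structure(list(gene_a = gene_a, gene_b = gene_b,
                 beta_case = beta_case, beta_control = beta_ctrl,
                 var_case = var_case, var_control = var_ctrl,
                 U = U, p_perm = p_perm, U_perm = U_perm,
                 n_perm = plan$n_perm, n_boot = plan$n_boot,
                 seed = plan$seed, perm_mode = plan$perm_mode,
                 loadings = loadings,
                 fits = list(case = fit_case, control = fit_ctrl),
                 n_redraws = c(boot_case = bc$n_redraws,
                               boot_control = b0$n_redraws),
                 n_case = n1, n_control = n0),
            class = "coassoc_test")
}

#' @export
print.coassoc_test <- function(x, ...) {
  cat("PLSPM gene-gene co-association test:", x$gene_a, "-", x$gene_b, "\n")
  cat(sprintf("  beta_case = %.4f  beta_control = %.4f\n",
              x$beta_case, x$beta_control))
  cat(sprintf("  U = %.4f   permutation p = %.4g  (%d permutations, %d bootstraps, %s)\n",
              x$U, x$p_perm, x$n_perm, x$n_boot, x$perm_mode))
  invisible(x)
}

#' @export
summary.coassoc_test <- function(object, ...) {
  print(object)
  cat(sprintf("  var_case = %.3g  var_control = %.3g  (n = %d cases / %d controls)\n",
              object$var_case, object$var_control, object$n_case,
              object$n_control))
  cat("\nLoadings (bootstrap SE):\n")
  print(object$loadings, digits = 3, row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.coassoc_test <- function(x, ...) {
  data.frame(gene_a = x$gene_a, gene_b = x$gene_b, method = "plspm",
             statistic = x$U, p_value = x$p_perm,
             beta_case = x$beta_case, beta_control = x$beta_control,
             var_case = x$var_case, var_control = x$var_control,
             n_perm = x$n_perm, n_boot = x$n_boot, seed = x$seed)
}

#' Type I error calibration of the co-association test
#'
#' Builds one pooled case/control population under a null disease model
#' (all odds ratios 1), repeatedly draws balanced case/control samples
#' from it, runs the permutation test on each, and reports the rejection
#' rate at each nominal level with exact binomial 95% intervals.
#'
#' @param panel a [haplotype_panel()] covering both genes.
#' @param model a [disease_model()] with all ORs equal to 1.
#' @param n_cases,n_controls per-dataset sample sizes.
#' @param n_datasets number of simulated datasets.
#' @param alpha_levels nominal significance levels.
#' @param plan a [resampling_plan()] (its seed drives each dataset's
#'   resampling streams via [derive_seed()]).
#' @param config a [plspm_config()].
#' @param seed master seed for population building and dataset draws.
#' @param pool_cases,pool_controls pooled population sizes.
#' @param drop_causal analyze with the causal SNPs removed (default TRUE,
#'   the indirect-association design).
#' @return data frame `alpha`, `rejection_rate`, `ci_low`, `ci_high`,
#'   `n_datasets`, with the vector of p-values attached as attribute
#'   `p_values`.
#' @export
null_calibration <- function(panel, model, n_cases, n_controls,
                             n_datasets = 1000,
                             alpha_levels = c(0.01, 0.05, 0.1),
                             plan = resampling_plan(),
                             config = plspm_config(), seed = 1L,
                             pool_cases = 20000, pool_controls = 20000,
                             drop_causal = TRUE) {
  stopifnot(inherits(model, "disease_model"))
  if (!is_null_model(model))
    stop("null_calibration requires a null disease model (all ORs = 1)")
  pvals <- replicate_pvalues(panel, model, n_cases, n_controls, n_datasets,
                             plan, config, seed, pool_cases, pool_controls,
                             drop_causal, method = "plspm")
  out <- do.call(rbind, lapply(alpha_levels, function(a) {
    x <- sum(pvals <= a)
    ci <- exact_binom_ci(x, n_datasets)
    data.frame(alpha = a, rejection_rate = x / n_datasets,
               ci_low = ci[1], ci_high = ci[2], n_datasets = n_datasets)
  }))
  attr(out, "p_values") <- pvals
  out
}
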