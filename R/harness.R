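## Experiment harness: gene-pair testing on a dataset, type-I-error
## calibration and power grids over simulated datasets.  Every dataset
## gets its own derived seed, so results are independent of execution
## order and worker count.

run_method <- function(ds, gene_a, gene_b, method, plan, config, seed) {
  switch(method,
    plspm = coassoc_test(ds, gene_a, gene_b,
                         plan = modifyList(plan, list(seed = seed)),
                         config = config)$p_perm,
    ccu = ccu_test(ds, gene_a, gene_b,
                   plan = modifyList(plan, list(seed = seed)),
                   config = config)$p_value,
    pca_logistic = pca_logistic_test(ds, gene_a, gene_b)$p_value,
    snp_logistic = snp_logistic_minp(ds, gene_a, gene_b,
                                     n_perm = plan$n_perm,
                                     seed = seed)$p_value,
    covariance = covariance_test(ds, gene_a, gene_b, n_perm = plan$n_perm,
                                 seed = seed, n_boot = plan$n_boot)$p_value,
    stop("unknown method '", method, "'; valid methods: ",
         paste(valid_methods(), collapse = ", ")))
}

valid_methods <- function() {
  c("plspm", "ccu", "pca_logistic", "snp_logistic", "covariance")
}

# p-values of one method over repeated draws from a pooled population
replicate_pvalues <- function(panel, model, n_cases, n_controls, n_datasets,
                              plan, config, seed, pool_cases, pool_controls,
                              drop_causal = TRUE, method = "plspm",
                              workers = 1L, pop = NULL) {
  if (is.null(pop))
    pop <- build_population(panel, model, pool_cases, pool_controls,
                            seed = derive_seed(seed, 0L))
  genes <- unique(pop$gene_of_snp)
  one <- function(i) {
    dseed <- derive_seed(seed, i)
    ds <- draw_case_control(pop, n_cases, n_controls, seed = dseed)
    if (drop_causal) ds <- remove_causal(ds)
    run_method(ds, genes[1], genes[2], method, plan, config,
               seed = derive_seed(dseed, 3L))
  }
  if (workers > 1L) {
    unlist(parallel::mclapply(seq_len(n_datasets), one,
                              mc.cores = workers, mc.preschedule = TRUE))
  } else {
    vapply(seq_len(n_datasets), one, numeric(1))
  }
}

#' Test every gene pair of a dataset with the requested methods
#'
#' @param ds a preprocessed [genotype_dataset()].
#' @param genes gene labels to pair up (default: all genes in `ds`).
#' @param methods subset of `"plspm"`, `"ccu"`, `"pca_logistic"`,
#'   `"snp_logistic"`, `"covariance"`.
#' @param plan a [resampling_plan()] (per-pair seeds are derived from its
#'   seed).
#' @param config a [plspm_config()].
#' @param out optional path: write the table as a provenance-stamped TSV.
#' @return data frame with one row per unordered gene pair per method:
#'   `gene_a gene_b method statistic p_value` plus, for `snp_logistic`,
#'   the best SNP pair (`snp_a`, `snp_b`, `p_unadj`).
#' @export
test_gene_pairs <- function(ds, genes = NULL, methods = "plspm",
                            plan = resampling_plan(),
                            config = plspm_config(), out = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  genes <- genes %||% unique(ds$gene_of_snp)
  if (length(genes) < 2) stop("need at least two genes")
  bad <- setdiff(methods, valid_methods())
  if (length(bad))
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid methods: ", paste(valid_methods(), collapse = ", "))
  pairs <- utils::combn(genes, 2)
  rows <- list()
  k <- 0L
  for (j in seq_len(ncol(pairs))) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    for (m in methods) {
      k <- k + 1L
      pseed <- derive_seed(plan$seed, k)
      row <- data.frame(gene_a = ga, gene_b = gb, method = m,
                        statistic = NA_real_, p_value = NA_real_,
                        snp_a = NA_character_, snp_b = NA_character_,
                        p_unadj = NA_real_)
      res <- switch(m,
        plspm = coassoc_test(ds, ga, gb,
                             plan = modifyList(plan, list(seed = pseed)),
                             config = config),
        ccu = ccu_test(ds, ga, gb,
                       plan = modifyList(plan, list(seed = pseed)),
                       config = config),
        pca_logistic = pca_logistic_test(ds, ga, gb),
        snp_logistic = snp_logistic_minp(ds, ga, gb, n_perm = plan$n_perm,
                                         seed = pseed),
        covariance = covariance_test(ds, ga, gb, n_perm = plan$n_perm,
                                     seed = pseed, n_boot = plan$n_boot))
      if (inherits(res, "coassoc_test")) {
        row$statistic <- res$U; row$p_value <- res$p_perm
      } else {
        row$statistic <- res$statistic; row$p_value <- res$p_value
        if (m == "snp_logistic") {
          row$snp_a <- res$detail$snp_a; row$snp_b <- res$detail$snp_b
          row$p_unadj <- res$detail$p_unadj
        }
      }
      rows[[k]] <- row
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out))
    write_results_tsv(df, out, seed = plan$seed,
                      config = list(plan = unclass(plan),
                                    config = unclass(config),
                                    methods = methods, genes = genes))
  df
}

#' Type-I-error calibration over a sample-size grid
#'
#' Runs [null_calibration()] for each sample size of a preset's null
#' model and stacks the results.
#'
#' @param preset a [scenario_presets()] object or name.
#' @param n_grid total sample sizes N (balanced: N/2 cases + N/2
#'   controls).
#' @param alphas nominal levels.
#' @param n_datasets simulated datasets per N.
#' @param plan,config resampling plan and fitter configuration.
#' @param seed master seed.
#' @param n_haplotypes panel size.
#' @param pool_cases,pool_controls pooled population quotas.
#' @param workers parallel workers (results are worker-count invariant).
#' @param out optional TSV path.
#' @return data frame `scenario N alpha rejection_rate ci_low ci_high
#'   n_datasets`.
#' @export
calibrate_type1 <- function(preset, n_grid = c(1000, 2000),
                            alphas = c(0.01, 0.05, 0.1), n_datasets = 500,
                            plan = resampling_plan(n_perm = 500,
                                                   n_boot = 200),
                            config = plspm_config(), seed = 1L,
                            n_haplotypes = 10000, pool_cases = 20000,
                            pool_controls = 20000, workers = 1L,
                            out = NULL) {
  if (is.character(preset)) preset <- scenario_presets(preset)
  model <- preset_model(preset)   # all ORs 1
  if (!is_null_model(model))
    stop("calibration requires the null model (all ORs = 1)")
  panel <- preset_panel(preset, n_haplotypes, seed = derive_seed(seed, 99L))
  pop <- build_population(panel, model, pool_cases, pool_controls,
                          seed = derive_seed(seed, 0L))
  rows <- list()
  for (N in n_grid) {
    pv <- replicate_pvalues(panel, model, N %/% 2, N - N %/% 2, n_datasets,
                            plan, config, derive_seed(seed, N),
                            pool_cases, pool_controls, drop_causal = TRUE,
                            method = "plspm", workers = workers, pop = pop)
    for (a in alphas) {
      x <- sum(pv <= a)
      ci <- exact_binom_ci(x, n_datasets)
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = preset$name, N = N, alpha = a,
                   rejection_rate = x / n_datasets, ci_low = ci[1],
                   ci_high = ci[2], n_datasets = n_datasets)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out))
    write_results_tsv(df, out, seed = seed,
                      config = list(preset = preset$name, n_grid = n_grid,
                                    alphas = alphas,
                                    n_datasets = n_datasets,
                                    plan = unclass(plan)))
  df
}

#' Power of the five tests over sample-size and odds-ratio grids
#'
#' For every grid point, builds the pooled population once, draws
#' `n_datasets` balanced samples, removes the causal SNPs, and reports
#' each method's rejection rate at level `alpha` with exact binomial 95%
#' intervals.
#'
#' @param preset a [scenario_presets()] object or name.
#' @param methods methods to run (see [test_gene_pairs()]).
#' @param n_grid total sample sizes.
#' @param or_grid data frame of odds-ratio settings with any of the
#'   columns `or_interaction`, `or_marginal_a`, `or_marginal_b` (one row
#'   per co-association level), or a numeric vector of interaction ORs.
#' @param n_datasets datasets per grid point.
#' @param alpha nominal level for the power count.
#' @inheritParams calibrate_type1
#' @return data frame `scenario N method alpha power ci_low ci_high
#'   n_datasets` plus the OR columns.
#' @export
power_grid <- function(preset, methods = c("plspm", "ccu"),
                       n_grid = 2000, or_grid,
                       n_datasets = 300, alpha = 0.05,
                       plan = resampling_plan(n_perm = 200, n_boot = 200),
                       config = plspm_config(), seed = 1L,
                       n_haplotypes = 10000, pool_cases = 20000,
                       pool_controls = 20000, workers = 1L, out = NULL) {
  if (is.character(preset)) preset <- scenario_presets(preset)
  bad <- setdiff(methods, valid_methods())
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (is.numeric(or_grid))
    or_grid <- data.frame(or_interaction = or_grid)
  panel <- preset_panel(preset, n_haplotypes, seed = derive_seed(seed, 99L))
  rows <- list()
  for (r in seq_len(nrow(or_grid))) {
    ors <- or_grid[r, , drop = FALSE]
    model <- preset_model(preset,
                          or_interaction = ors$or_interaction %||% 1.0,
                          or_marginal_a = ors$or_marginal_a %||% 1.0,
                          or_marginal_b = ors$or_marginal_b %||% 1.0)
    pop <- build_population(panel, model, pool_cases, pool_controls,
                            seed = derive_seed(seed, 7000L + r))
    for (N in n_grid) {
      for (m in methods) {
        pv <- replicate_pvalues(panel, model, N %/% 2, N - N %/% 2,
                                n_datasets, plan, config,
                                derive_seed(seed, 13L * N + r),
                                pool_cases, pool_controls,
                                drop_causal = TRUE, method = m,
                                workers = workers, pop = pop)
        x <- sum(pv <= alpha)
        ci <- exact_binom_ci(x, n_datasets)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(scenario = preset$name, N = N, method = m,
                           alpha = alpha, power = x / n_datasets,
                           ci_low = ci[1], ci_high = ci[2],
                           n_datasets = n_datasets),
                ors, row.names = NULL)
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out))
    write_results_tsv(df, out, seed = seed,
                      config = list(preset = preset$name, n_grid = n_grid,
                                    or_grid = or_grid, alpha = alpha,
                                    n_datasets = n_datasets,
                                    plan = unclass(plan)))
  df
}

#' Line plot of a power table
#'
#' @param df output of [power_grid()].
#' @param x which grid axis to put on the x axis (a column of `df`).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the reshaped power matrix.
#' @export
plot_power <- function(df, x = "N", ...) {
  methods <- unique(df$method)
  xs <- sort(unique(df[[x]]))
  mat <- sapply(methods, function(m)
    sapply(xs, function(v) mean(df$power[df$method == m & df[[x]] == v])))
  graphics::matplot(xs, mat, type = "b", pch = seq_along(methods),
                    xlab = x, ylab = "power", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = methods, lty = seq_along(methods),
                   col = seq_along(methods), pch = seq_along(methods),
                   bty = "n")
  invisible(mat)
}
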