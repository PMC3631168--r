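## Case-control genotype simulation: a latent-Gaussian-threshold synthetic
## haplotype panel with controllable LD, a logistic disease model over one
## or two causal SNPs, and pooled-population sampling.  Three scenario
## presets cover: interaction between independent genes (type1),
## correlation-only co-association between linked genes (type2), and both
## mixed 1:1 (type3).

#' Generate a synthetic LD-structured haplotype panel
#'
#' Latent-Gaussian threshold model: each haplotype draws
#' `z ~ N(0, ld_target)` and carries the minor allele at SNP j iff
#' `z_j < qnorm(maf_j)`.  The latent correlation is attenuated on the
#' binary scale (tetrachoric attenuation); the empirical allelic
#' correlation `ld_r` attached to the panel is the contract, the latent
#' matrix is only the dial (kept as attribute `latent_ld`).
#'
#' @param mafs per-SNP minor-allele frequencies in (0, 0.5].
#' @param ld_target latent correlation: an m x m positive semi-definite
#'   matrix, or a single AR(1) coefficient `rho` giving
#'   `rho^|i-j|`.
#' @param n_haplotypes number of haplotypes H.
#' @param seed integer seed.
#' @inheritParams haplotype_panel
#' @return a [haplotype_panel()] with empirical MAFs and LD attached.
#' @export
make_synthetic_panel <- function(mafs, ld_target, n_haplotypes, seed,
                                 snp_ids = NULL, gene_of_snp = NULL,
                                 ld_groups = NULL) {
  m <- length(mafs)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("mafs must lie in (0, 0.5]")
  if (length(ld_target) == 1) {
    rho <- as.numeric(ld_target)
    ld_target <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  }
  ld_target <- as.matrix(ld_target)
  if (!isTRUE(all.equal(dim(ld_target), c(m, m))))
    stop("ld_target must be ", m, " x ", m)
  e <- eigen((ld_target + t(ld_target)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("ld_target is not positive semi-definite (eigenvalue ",
         signif(min(e$values), 4), ")")
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), m)
  set.seed(seed)
  z <- matrix(rnorm(n_haplotypes * m), n_haplotypes, m) %*% t(L)
  hap <- matrix(0L, n_haplotypes, m)
  thr <- qnorm(mafs)
  for (j in seq_len(m)) hap[, j] <- as.integer(z[, j] < thr[j])
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  colnames(hap) <- snp_ids
  panel <- haplotype_panel(hap, snp_ids, gene_of_snp, mafs = mafs,
                           ld_groups = ld_groups)
  attr(panel, "latent_ld") <- ld_target
  attr(panel, "seed") <- as.integer(seed)
  panel
}

#' Specify the logistic disease model for simulation
#'
#' One causal SNP per gene.  Scenario `type1` (interaction between
#' independent genes): `logit = b0 + log(or_main_a) g_a + log(or_main_b)
#' g_b + log(or_interaction) g_a g_b`.  Scenario `type2`
#' (correlation-only): `logit = b0 + log(or_marginal_a) g_a +
#' log(or_marginal_b) g_b`.  Scenario `type3` mixes a type1 and a type2
#' population 1:1 on the same (correlated) panel.  The intercept `b0` is
#' root-found so the population prevalence matches `prevalence`.
#'
#' @param scenario `"type1"`, `"type2"` or `"type3"`.
#' @param causal_a,causal_b SNP ids of the causal variants (one per gene).
#' @param or_interaction interaction odds ratio (type1/type3).
#' @param or_marginal_a,or_marginal_b marginal odds ratios (type2/type3).
#' @param or_main_a,or_main_b main-effect odds ratios of the type1 model
#'   (default 1).
#' @param prevalence population disease prevalence fixing the intercept.
#' @return an object of class `disease_model`.
#' @export
disease_model <- function(scenario = c("type1", "type2", "type3"),
                          causal_a, causal_b,
                          or_interaction = 1.0,
                          or_marginal_a = 1.0, or_marginal_b = 1.0,
                          or_main_a = 1.0, or_main_b = 1.0,
                          prevalence = 0.1) {
  scenario <- match.arg(scenario)
  stopifnot(prevalence > 0, prevalence < 1,
            or_interaction > 0, or_marginal_a > 0, or_marginal_b > 0)
  structure(list(scenario = scenario, causal_a = causal_a,
                 causal_b = causal_b, or_interaction = or_interaction,
                 or_marginal_a = or_marginal_a,
                 or_marginal_b = or_marginal_b,
                 or_main_a = or_main_a, or_main_b = or_main_b,
                 prevalence = prevalence),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Disease model (", x$scenario, "): causal ", x$causal_a, " x ",
      x$causal_b, "\n", sep = "")
  cat(sprintf("  OR interaction %.2f, marginal (%.2f, %.2f), main (%.2f, %.2f), prevalence %.2f\n",
              x$or_interaction, x$or_marginal_a, x$or_marginal_b,
              x$or_main_a, x$or_main_b, x$prevalence))
  invisible(x)
}

is_null_model <- function(model) {
  all(abs(c(model$or_interaction, model$or_marginal_a, model$or_marginal_b,
            model$or_main_a, model$or_main_b) - 1) < 1e-12)
}

# genotypes by drawing two haplotypes with replacement per individual;
# SNP groups in panel$ld_groups are drawn independently (unlinked regions)
draw_genotypes <- function(panel, n) {
  H <- nrow(panel$haplotypes)
  g <- matrix(0L, n, ncol(panel$haplotypes))
  for (grp in panel$ld_groups) {
    i1 <- sample.int(H, n, replace = TRUE)
    i2 <- sample.int(H, n, replace = TRUE)
    g[, grp] <- panel$haplotypes[i1, grp, drop = FALSE] +
      panel$haplotypes[i2, grp, drop = FALSE]
  }
  colnames(g) <- panel$snp_ids
  g
}

# linear predictor without intercept for one sub-model
linpred <- function(model, ga, gb, submodel = model$scenario) {
  if (submodel == "type1") {
    log(model$or_main_a) * ga + log(model$or_main_b) * gb +
      log(model$or_interaction) * ga * gb
  } else {
    log(model$or_marginal_a) * ga + log(model$or_marginal_b) * gb
  }
}

# root-find the intercept so the population prevalence matches
calibrate_intercept <- function(panel, model, submodel, n_mc = 200000) {
  g <- draw_genotypes(panel, n_mc)
  lin <- linpred(model, g[, model$causal_a], g[, model$causal_b], submodel)
  f <- function(b0) mean(plogis(b0 + lin)) - model$prevalence
  uniroot(f, c(-30, 10), tol = 1e-10)$root
}

build_one_population <- function(panel, model, submodel, pool_cases,
                                 pool_controls, max_draw_factor = 50) {
  b0 <- calibrate_intercept(panel, model, submodel)
  prev <- model$prevalence
  m <- ncol(panel$haplotypes)
  cases <- matrix(0L, 0, m); controls <- matrix(0L, 0, m)
  total_drawn <- 0
  max_draws <- max_draw_factor * (pool_cases / prev +
                                  pool_controls / (1 - prev))
  while (nrow(cases) < pool_cases || nrow(controls) < pool_controls) {
    need_c <- pool_cases - nrow(cases)
    need_0 <- pool_controls - nrow(controls)
    batch <- min(500000,
                 ceiling(1.3 * max(need_c / prev, need_0 / (1 - prev))) + 100)
    g <- draw_genotypes(panel, batch)
    pr <- plogis(b0 + linpred(model, g[, model$causal_a],
                              g[, model$causal_b], submodel))
    y <- rbinom(batch, 1, pr)
    if (need_c > 0) {
      idx <- which(y == 1L)
      cases <- rbind(cases, g[idx[seq_len(min(need_c, length(idx)))], ,
                              drop = FALSE])
    }
    if (need_0 > 0) {
      idx <- which(y == 0L)
      controls <- rbind(controls, g[idx[seq_len(min(need_0, length(idx)))], ,
                                    drop = FALSE])
    }
    total_drawn <- total_drawn + batch
    if (total_drawn > max_draws)
      stop("population quotas unreachable after ", total_drawn,
           " draws (achieved ", nrow(cases), " cases, ", nrow(controls),
           " controls); check prevalence/OR settings")
  }
  list(cases = cases, controls = controls, b0 = b0, submodel = submodel)
}

#' Build a pooled case/control population
#'
#' Individuals are formed by drawing two panel haplotypes with
#' replacement (genotype = allele sum) and disease status from the
#' scenario's logistic model; draws continue until both pool quotas are
#' filled.  For `type3`, two sub-populations (type1 and type2 models on
#' the same panel) are built and later sampled 1:1.
#'
#' @param panel a [haplotype_panel()] covering both genes.
#' @param model a [disease_model()].
#' @param pool_cases,pool_controls pool quotas (per sub-population for
#'   `type3`).
#' @param seed integer seed.
#' @return an object of class `coassoc_population`.
#' @export
build_population <- function(panel, model, pool_cases = 20000,
                             pool_controls = 20000, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(model, "disease_model"))
  for (sn in c(model$causal_a, model$causal_b))
    if (!(sn %in% panel$snp_ids)) stop("causal SNP not in panel: ", sn)
  set.seed(seed)
  comps <- if (model$scenario == "type3") {
    list(build_one_population(panel, model, "type1", pool_cases,
                              pool_controls),
         build_one_population(panel, model, "type2", pool_cases,
                              pool_controls))
  } else {
    list(build_one_population(panel, model, model$scenario, pool_cases,
                              pool_controls))
  }
  structure(list(components = comps, panel_snp_ids = panel$snp_ids,
                 gene_of_snp = panel$gene_of_snp, model = model,
                 panel_hash = config_hash(panel$haplotypes),
                 pool_cases = pool_cases, pool_controls = pool_controls,
                 seed = as.integer(seed)),
            class = "coassoc_population")
}

#' @export
print.coassoc_population <- function(x, ...) {
  cat("Pooled case/control population (", x$model$scenario, "), ",
      length(x$components), " component(s), ", x$pool_cases, " cases + ",
      x$pool_controls, " controls each\n", sep = "")
  invisible(x)
}

#' Draw one balanced case/control dataset from a pooled population
#'
#' @param pop a [build_population()] object.
#' @param n_cases,n_controls per-dataset quotas; for `type3` populations
#'   each is split 1:1 over the two sub-populations.
#' @param seed optional seed for this draw.
#' @return a `simulated_dataset` (a [genotype_dataset()] carrying
#'   provenance and causal-SNP ids).
#' @export
draw_case_control <- function(pop, n_cases, n_controls, seed = NULL) {
  stopifnot(inherits(pop, "coassoc_population"))
  if (!is.null(seed)) set.seed(seed)
  k <- length(pop$components)
  qc <- diff(round(seq(0, n_cases, length.out = k + 1)))
  q0 <- diff(round(seq(0, n_controls, length.out = k + 1)))
  case_rows <- list(); ctrl_rows <- list()
  for (i in seq_len(k)) {
    comp <- pop$components[[i]]
    if (qc[i] > nrow(comp$cases) || q0[i] > nrow(comp$controls))
      stop("requested sample larger than the pooled population")
    case_rows[[i]] <- comp$cases[sample.int(nrow(comp$cases), qc[i]), ,
                                 drop = FALSE]
    ctrl_rows[[i]] <- comp$controls[sample.int(nrow(comp$controls), q0[i]), ,
                                    drop = FALSE]
  }
  dos <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
  rownames(dos) <- sprintf("S%05d", seq_len(nrow(dos)))
  ds <- genotype_dataset(dos, pop$gene_of_snp,
                         c(rep(1L, n_cases), rep(0L, n_controls)))
  class(ds) <- c("simulated_dataset", class(ds))
  attr(ds, "provenance") <- list(
    panel_hash = pop$panel_hash, model = pop$model,
    causal = c(pop$model$causal_a, pop$model$causal_b),
    pool_cases = pop$pool_cases, pool_controls = pop$pool_controls,
    population_seed = pop$seed, draw_seed = seed)
  ds
}

#' Simulate one case-control dataset
#'
#' Convenience wrapper: [build_population()] then [draw_case_control()].
#' For repeated datasets under one configuration, build the population
#' once and draw from it instead.
#'
#' @inheritParams build_population
#' @inheritParams draw_case_control
#' @return a `simulated_dataset`.
#' @export
sample_population <- function(panel, model, n_cases, n_controls, seed = 1L,
                              pool_cases = 20000, pool_controls = 20000) {
  pop <- build_population(panel, model, pool_cases, pool_controls, seed)
  draw_case_control(pop, n_cases, n_controls,
                    seed = derive_seed(seed, 1L))
}

#' Remove the causal SNPs from a simulated dataset
#'
#' The indirect-association design: the causal variants are dropped so
#' their effect can only be picked up through linked markers.  Causal ids
#' stay in the provenance.
#'
#' @param sd a `simulated_dataset`.
#' @return the dataset without the causal columns.
#' @export
remove_causal <- function(sd) {
  prov <- attr(sd, "provenance")
  if (is.null(prov)) stop("not a simulated dataset (no provenance)")
  causal <- prov$causal
  present <- causal %in% sd$snp_ids
  if (!any(present)) {
    warning("causal SNPs already absent; returning dataset unchanged")
    return(sd)
  }
  keep <- setdiff(sd$snp_ids, causal)
  gom <- sd$gene_of_snp[keep]
  lost <- setdiff(unique(sd$gene_of_snp), unique(gom))
  if (length(lost))
    stop("removing causal SNPs would empty gene(s): ",
         paste(lost, collapse = ", "))
  out <- genotype_dataset(sd$dosages[, keep, drop = FALSE], gom,
                          sd$phenotype, sd$sample_ids)
  class(out) <- class(sd)
  attr(out, "provenance") <- prov
  out
}

## ---------------------------------------------------------------------
## Scenario presets

preset_defs <- function() {
  list(
    scenario1_8x10 = list(
      name = "scenario1_8x10", scenario = "type1",
      genes = c("GENEA", "GENEB"),
      mafs_a = c(0.32, 0.25, 0.38, 0.43, 0.29, 0.47, 0.21, 0.35),
      mafs_b = c(0.27, 0.41, 0.22, 0.36, 0.44, 0.31, 0.48, 0.24, 0.39, 0.28),
      causal_a = 4L, causal_b = 5L,     # MAFs 0.43 / 0.44
      rho_within = 0.8, cross_gene = FALSE),
    scenario2_7x7 = list(
      name = "scenario2_7x7", scenario = "type2",
      genes = c("GENEA", "GENEB"),
      mafs_a = c(0.33, 0.41, 0.27, 0.46, 0.38, 0.23, 0.44),
      mafs_b = c(0.29, 0.42, 0.35, 0.45, 0.26, 0.40, 0.31),
      causal_a = 4L, causal_b = 4L,     # MAFs 0.46 / 0.45
      rho_within = 0.8, cross_gene = TRUE, rho_cross = 0.5),
    scenario3_7x7 = list(
      name = "scenario3_7x7", scenario = "type3",
      genes = c("GENEA", "GENEB"),
      mafs_a = c(0.33, 0.41, 0.27, 0.46, 0.38, 0.23, 0.44),
      mafs_b = c(0.29, 0.42, 0.35, 0.45, 0.26, 0.40, 0.31),
      causal_a = 4L, causal_b = 4L,
      rho_within = 0.8, cross_gene = TRUE, rho_cross = 0.5)
  )
}

#' Scenario presets for the simulation study
#'
#' Three ready-made configurations: `scenario1_8x10` -- interaction
#' between two unlinked genes of 8 and 10 common SNPs (causal MAFs
#' 0.43/0.44); `scenario2_7x7` -- two linked 7-SNP genes with cross-gene
#' LD and marginal effects only (causal MAFs 0.46/0.45); `scenario3_7x7`
#' -- the 1:1 mixture of both mechanisms on the linked panel.  Within-gene
#' LD follows a latent AR(1) with coefficient 0.8; for linked presets the
#' cross-gene latent correlation is anchored at 0.5 between the two
#' causal SNPs and decays AR(1)-style around them (see [preset_panel()]).
#'
#' @param name preset name, or `NULL` to list all presets.
#' @return a preset object (class `coassoc_preset`) or a named list of
#'   them.
#' @export
scenario_presets <- function(name = NULL) {
  defs <- preset_defs()
  if (is.null(name))
    return(lapply(defs, function(d) structure(d, class = "coassoc_preset")))
  if (!name %in% names(defs))
    stop("unknown preset '", name, "'; available: ",
         paste(names(defs), collapse = ", "))
  structure(defs[[name]], class = "coassoc_preset")
}

#' @export
print.coassoc_preset <- function(x, ...) {
  cat("Preset", x$name, ":", length(x$mafs_a), "+", length(x$mafs_b),
      "SNPs,", x$scenario, "\n")
  invisible(x)
}

#' Build the haplotype panel of a preset
#'
#' @param preset a [scenario_presets()] object (or preset name).
#' @param n_haplotypes panel size (default 10000).
#' @param seed integer seed.
#' @return a [haplotype_panel()] with gene labels and (for unlinked
#'   presets) independent per-gene sampling groups.
#' @export
preset_panel <- function(preset, n_haplotypes = 10000, seed = 1L) {
  if (is.character(preset)) preset <- scenario_presets(preset)
  pa <- length(preset$mafs_a); pb <- length(preset$mafs_b)
  snp_ids <- c(paste0("A", seq_len(pa)), paste0("B", seq_len(pb)))
  gom <- setNames(rep(preset$genes, c(pa, pb)), snp_ids)
  mafs <- c(preset$mafs_a, preset$mafs_b)
  if (preset$cross_gene) {
    # within-gene AR(1); cross-gene correlation anchored at the causal
    # pair (latent rho_cross) and decaying AR(1)-style around it:
    # Sigma_AB[i,j] = rho_cross * rho^|i-ca| * rho^|j-cb|.  This is the
    # correlation of a Gaussian vector whose two blocks are conditionally
    # independent AR(1) extensions of a correlated causal anchor pair,
    # hence positive semi-definite by construction.
    u <- preset$rho_within^abs(seq_len(pa) - preset$causal_a)
    v <- preset$rho_within^abs(seq_len(pb) - preset$causal_b)
    ld <- rbind(
      cbind(preset$rho_within^abs(outer(seq_len(pa), seq_len(pa), "-")),
            preset$rho_cross * (u %o% v)),
      cbind(preset$rho_cross * (v %o% u),
            preset$rho_within^abs(outer(seq_len(pb), seq_len(pb), "-"))))
    groups <- NULL
  } else {
    ld <- matrix(0, pa + pb, pa + pb)
    ld[seq_len(pa), seq_len(pa)] <-
      preset$rho_within^abs(outer(seq_len(pa), seq_len(pa), "-"))
    ld[pa + seq_len(pb), pa + seq_len(pb)] <-
      preset$rho_within^abs(outer(seq_len(pb), seq_len(pb), "-"))
    groups <- list(seq_len(pa), pa + seq_len(pb))
  }
  make_synthetic_panel(mafs, ld, n_haplotypes, seed, snp_ids, gom,
                       ld_groups = groups)
}

#' Build the disease model of a preset
#'
#' @param preset a [scenario_presets()] object (or preset name).
#' @param or_interaction,or_marginal_a,or_marginal_b odds ratios (default
#'   1: the null model).
#' @param prevalence population prevalence (default 0.1).
#' @return a [disease_model()] whose causal SNPs are the preset's.
#' @export
preset_model <- function(preset, or_interaction = 1.0, or_marginal_a = 1.0,
                         or_marginal_b = 1.0, prevalence = 0.1) {
  if (is.character(preset)) preset <- scenario_presets(preset)
  disease_model(preset$scenario,
                causal_a = paste0("A", preset$causal_a),
                causal_b = paste0("B", preset$causal_b),
                or_interaction = or_interaction,
                or_marginal_a = or_marginal_a,
                or_marginal_b = or_marginal_b,
                prevalence = prevalence)
}
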