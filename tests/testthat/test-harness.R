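small_plan <- resampling_plan(n_perm = 49, n_boot = 30, seed = 2)

test_that("three genes yield the three unordered pairs", {
  ds <- read_genotypes(fixture_path("synthetic_cad_like.raw"), "plink_raw",
                       gene_map = fixture_path("synthetic_cad_like_genes.tsv"))
  ds <- preprocess_genotypes(ds)
  df <- test_gene_pairs(ds, methods = "plspm", plan = small_plan)
  expect_equal(nrow(df), 3L)
  expect_setequal(paste(df$gene_a, df$gene_b, sep = "-"),
                  c("LRP5L-LRP6L", "LRP5L-PCSK9L", "LRP6L-PCSK9L"))
  expect_true(all(df$p_value > 0 & df$p_value <= 1))
})

test_that("unknown methods are refused with the valid list", {
  ds <- toy_dataset(15, 15, 2, 2, seed = 2)
  expect_error(test_gene_pairs(ds, methods = "magic", plan = small_plan),
               "plspm.*ccu.*pca_logistic")
})

test_that("identical seeds give byte-identical result files", {
  ds <- toy_dataset(20, 20, 2, 2, seed = 12)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  test_gene_pairs(ds, methods = c("plspm", "pca_logistic"),
                  plan = small_plan, out = f1)
  test_gene_pairs(ds, methods = c("plspm", "pca_logistic"),
                  plan = small_plan, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  # provenance header present
  expect_match(readLines(f1)[1], "coassoc")
})

test_that("replicated p-values do not depend on the worker count", {
  preset <- scenario_presets("scenario1_8x10")
  panel <- preset_panel(preset, n_haplotypes = 2000, seed = 3)
  pop <- build_population(panel, preset_model(preset), 1500, 1500, seed = 4)
  args <- list(panel = panel, model = NULL, n_cases = 60, n_controls = 60,
               n_datasets = 8, plan = small_plan, config = plspm_config(),
               seed = 31, pool_cases = 0, pool_controls = 0, pop = pop)
  p1 <- do.call(coassoc:::replicate_pvalues, c(args, workers = 1L))
  p2 <- do.call(coassoc:::replicate_pvalues, c(args, workers = 2L))
  expect_identical(p1, p2)
})

test_that("single-dataset calibration degenerates gracefully", {
  preset <- scenario_presets("scenario1_8x10")
  panel <- preset_panel(preset, n_haplotypes = 2000, seed = 5)
  out <- null_calibration(panel, preset_model(preset), 60, 60,
                          n_datasets = 1, alpha_levels = 0.05,
                          plan = small_plan, seed = 3,
                          pool_cases = 1000, pool_controls = 1000)
  expect_true(out$rejection_rate %in% c(0, 1))
  expect_true(out$ci_low >= 0 && out$ci_high <= 1)
})

test_that("the CLI tests gene pairs on the packaged synthetic dataset", {
  out_dir <- withr::local_tempdir()
  expect_message(
    coassoc_cli(c("test", "--geno", fixture_path("synthetic_cad_like.raw"),
                  "--gene-map", fixture_path("synthetic_cad_like_genes.tsv"),
                  "--method", "plspm,pca_logistic", "--n-perm", "49",
                  "--n-boot", "30", "--seed", "7", "--out", out_dir)),
    "wrote")
  tab <- read.table(file.path(out_dir, "gene_pair_tests.tsv"),
                    header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), 6L)   # 3 pairs x 2 methods
  expect_setequal(unique(tab$method), c("plspm", "pca_logistic"))
})

test_that("CLI usage errors are informative", {
  expect_error(coassoc_cli(c("test", "--geno")), "needs a value")
  expect_error(coassoc_cli(c("frobnicate")), "unknown command")
  out_dir <- withr::local_tempdir()
  expect_error(
    coassoc_cli(c("test", "--geno", fixture_path("synthetic_cad_like.raw"),
                  "--gene-map", fixture_path("synthetic_cad_like_genes.tsv"),
                  "--method", "magic", "--out", out_dir)),
    "valid methods")
  expect_error(
    coassoc_cli(c("calibrate", "--preset", "scenario1_8x10",
                  "--or-interaction", "1.3", "--out", out_dir)),
    "null model only")
})

test_that("CLI simulate writes a readable dataset with provenance", {
  out_dir <- withr::local_tempdir()
  suppressMessages(
    coassoc_cli(c("simulate", "--preset", "scenario2_7x7", "--n", "120",
                  "--or-a", "1.3", "--or-b", "1.7", "--seed", "3",
                  "--out", out_dir)))
  ds <- read_genotypes(file.path(out_dir, "simulated.raw"), "plink_raw",
                       gene_map = file.path(out_dir, "gene_map.tsv"))
  expect_equal(nrow(ds$dosages), 120L)
  expect_equal(sum(ds$phenotype), 60L)
  prov <- readLines(file.path(out_dir, "provenance.json"))
  expect_match(paste(prov, collapse = ""), "\"causal\"")
})

test_that("a tiny power grid runs end to end and is reproducible", {
  df <- power_grid("scenario1_8x10", methods = "pca_logistic",
                   n_grid = 150, or_grid = c(1.0, 1.5), n_datasets = 8,
                   plan = resampling_plan(n_perm = 19, n_boot = 20, seed = 1),
                   seed = 5, n_haplotypes = 1500,
                   pool_cases = 1000, pool_controls = 1000)
  expect_equal(nrow(df), 2L)
  expect_true(all(df$power >= 0 & df$power <= 1))
  df2 <- power_grid("scenario1_8x10", methods = "pca_logistic",
                    n_grid = 150, or_grid = c(1.0, 1.5), n_datasets = 8,
                    plan = resampling_plan(n_perm = 19, n_boot = 20,
                                           seed = 1),
                    seed = 5, n_haplotypes = 1500,
                    pool_cases = 1000, pool_controls = 1000)
  expect_identical(df, df2)
})
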