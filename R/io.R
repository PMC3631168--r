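## Readers, writers and preprocessing for genotype data.
##
## Supported text formats: PLINK "raw" additive dosage tables, VCF v4.x
## (GT field only, biallelic records), a plain TSV dosage table, IMPUTE-
## style .hap/.legend haplotype panels, and TSV haplotype matrices.  All
## readers accept gzip-compressed files (R's connections decompress
## transparently).  Genomic coordinates are never used in computation:
## SNP order comes from the file and gene membership comes solely from a
## gene-map TSV (`snp_id<TAB>gene`).

#' Construct and validate a genotype dataset
#'
#' The container used by every test in the package: an additive-coded
#' dosage matrix (minor-allele counts 0/1/2, `NA` allowed until
#' [preprocess_genotypes()] has run), a SNP-to-gene map and a binary
#' phenotype (0 = control, 1 = case).
#'
#' @param dosages numeric matrix, samples x SNPs; values in \{0, 1, 2, NA\}.
#' @param gene_of_snp named character vector mapping every SNP id (the
#'   column names of `dosages`) to a gene label.
#' @param phenotype integer vector of 0/1, one per sample.
#' @param sample_ids optional sample identifiers (defaults to row names or
#'   `S1..Sn`).
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, gene_of_snp, phenotype,
                             sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(colnames(dosages)))
    stop("dosage matrix must have SNP ids as column names")
  snp_ids <- colnames(dosages)
  if (anyDuplicated(snp_ids))
    stop("duplicated SNP ids: ", paste(unique(snp_ids[duplicated(snp_ids)]),
                                       collapse = ", "))
  if (is.null(sample_ids))
    sample_ids <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  rownames(dosages) <- sample_ids

  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop("dosages must be additive counts in {0,1,2} (or NA); found ",
         paste(unique(dosages[bad])[1:min(3, sum(bad))], collapse = ", "))

  miss <- setdiff(snp_ids, names(gene_of_snp))
  if (length(miss))
    stop("SNPs missing from the gene map: ", paste(miss, collapse = ", "))
  gene_of_snp <- gene_of_snp[snp_ids]

  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(dosages))
    stop("phenotype length (", length(phenotype), ") != number of samples (",
         nrow(dosages), ")")
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be coded 0 = control, 1 = case")
  if (sum(phenotype == 1L) < 1 || sum(phenotype == 0L) < 1)
    stop("phenotype must contain at least one case and one control")

  structure(list(dosages = dosages, snp_ids = snp_ids,
                 gene_of_snp = gene_of_snp, phenotype = phenotype,
                 sample_ids = sample_ids),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  genes <- table(x$gene_of_snp)
  cat("Genotype dataset:", length(x$sample_ids), "samples (",
      sum(x$phenotype == 1L), "cases /", sum(x$phenotype == 0L),
      "controls ),", length(x$snp_ids), "SNPs\n")
  cat("Genes:", paste(sprintf("%s (%d SNPs)", names(genes), genes),
                      collapse = ", "), "\n")
  if (anyNA(x$dosages))
    cat("Contains", sum(is.na(x$dosages)),
        "missing dosages (run preprocess_genotypes())\n")
  invisible(x)
}

#' Column indices of a gene's SNPs
#'
#' @param ds a [genotype_dataset()].
#' @param gene gene label.
#' @return integer vector of column indices into `ds$dosages`
#'   (strictly increasing).
#' @export
gene_block <- function(ds, gene) {
  idx <- which(ds$gene_of_snp == gene)
  if (!length(idx)) stop("unknown gene (or gene with no SNPs left): ", gene)
  unname(idx)
}

#' Read a SNP-to-gene map TSV
#'
#' Two tab-separated columns, `snp_id` and `gene`, with or without header.
#'
#' @param path file path (may be gzipped).
#' @return named character vector (names = SNP ids, values = gene labels).
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("gene map file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("gene map must have two tab-separated columns")
  if (identical(tolower(df[1, 1]), "snp_id")) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]]))
    stop("SNP mapped to more than one gene: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a phenotype TSV
#'
#' Columns `sample_id` and `status`; status coded 0/1 or 1/2 (auto-detected,
#' 1/2 recoded to 0/1).
#'
#' @param path file path.
#' @return named integer vector of 0/1.
#' @export
read_phenotype_tsv <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(df[1, 1]), "sample_id")) df <- df[-1, , drop = FALSE]
  ph <- suppressWarnings(as.integer(df[[2]]))
  if (anyNA(ph)) stop("non-integer phenotype value in ", path)
  setNames(recode_phenotype(ph, path), as.character(df[[1]]))
}

# accept 0/1 or PLINK 1/2 case-control coding
recode_phenotype <- function(ph, what) {
  u <- unique(ph[!is.na(ph)])
  if (all(u %in% c(0L, 1L))) {
    ph
  } else if (all(u %in% c(1L, 2L))) {
    message("phenotype in ", what, " read as 1 = control / 2 = case")
    ph - 1L
  } else {
    stop("unrecognized phenotype coding in ", what,
         " (expected 0/1 or 1/2): values ", paste(u, collapse = ", "))
  }
}

# orient every SNP to count the minor allele, pooled over all samples
orient_minor <- function(dosages) {
  af <- colMeans(dosages, na.rm = TRUE) / 2
  flip <- which(!is.na(af) & af > 0.5)
  if (length(flip)) dosages[, flip] <- 2 - dosages[, flip]
  attr(dosages, "flipped_snps") <- unname(colnames(dosages)[flip])
  dosages
}

#' Read genotypes from standard text formats
#'
#' @param path genotype file. `plink_raw`: whitespace-delimited with header
#'   `FID IID PAT MAT SEX PHENOTYPE` then one column per SNP holding
#'   additive dosages 0/1/2 (`NA` for missing); phenotype 1/2 or 0/1,
#'   auto-detected.  `vcf`: VCF v4.x, biallelic records, GT field.  `tsv`:
#'   header `sample_id` then SNP columns of dosages.
#' @param format one of `"plink_raw"`, `"vcf"`, `"tsv"`.
#' @param gene_map path to a gene-map TSV, or a named character vector as
#'   returned by [read_gene_map()].
#' @param phenotype for `vcf`/`tsv` input: path to a phenotype TSV or a
#'   named 0/1 vector.  Ignored for `plink_raw` (phenotype comes from the
#'   PHENOTYPE column).
#' @return a [genotype_dataset()]; dosages are oriented to count the minor
#'   allele as determined from the pooled sample, so case and control
#'   strata share one coding.
#' @export
read_genotypes <- function(path, format = c("plink_raw", "vcf", "tsv"),
                           gene_map, phenotype = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (is.character(gene_map) && length(gene_map) == 1 && file.exists(gene_map))
    gene_map <- read_gene_map(gene_map)

  parsed <- switch(format,
                   plink_raw = read_plink_raw(path),
                   vcf = read_vcf_dosages(path),
                   tsv = read_tsv_dosages(path))
  dos <- orient_minor(parsed$dosages)
  flipped <- attr(dos, "flipped_snps")
  attr(dos, "flipped_snps") <- NULL

  ph <- parsed$phenotype
  if (is.null(ph)) {
    if (is.null(phenotype))
      stop(format, " input needs a companion phenotype (TSV path or named vector)")
    if (is.character(phenotype) && length(phenotype) == 1)
      phenotype <- read_phenotype_tsv(phenotype)
    miss <- setdiff(rownames(dos), names(phenotype))
    if (length(miss))
      stop("samples without phenotype: ", paste(head(miss, 5), collapse = ", "))
    ph <- unname(phenotype[rownames(dos)])
  }
  ds <- genotype_dataset(dos, gene_map, ph)
  attr(ds, "flipped_snps") <- flipped
  ds
}

read_plink_raw <- function(path) {
  df <- tryCatch(
    read.table(path, header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE, na.strings = c("NA", "-9")),
    error = function(e) stop("malformed plink_raw file ", path, ": ",
                             conditionMessage(e)))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(df) < 7 || !identical(toupper(names(df)[1:6]), fixed))
    stop("plink_raw file ", path,
         " must start with columns FID IID PAT MAT SEX PHENOTYPE")
  dos <- as.matrix(df[, -(1:6), drop = FALSE])
  storage.mode(dos) <- "double"
  bad <- which(matrix(!(dos %in% c(0, 1, 2) | is.na(dos)), nrow(dos)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("plink_raw parse error at data line ", bad[1, 1], ", SNP column '",
         colnames(dos)[bad[1, 2]], "': dosage not in {0,1,2,NA}")
  rownames(dos) <- make.unique(as.character(df$IID))
  ph <- recode_phenotype(as.integer(df$PHENOTYPE), path)
  list(dosages = dos, phenotype = ph)
}

read_tsv_dosages <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(tolower(names(df)[1]), "sample_id"))
    stop("tsv genotype file must have 'sample_id' as its first column")
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  bad <- which(matrix(!(dos %in% c(0, 1, 2) | is.na(dos)), nrow(dos)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("tsv parse error at data line ", bad[1, 1], ", SNP '",
         colnames(dos)[bad[1, 2]], "': dosage not in {0,1,2,NA}")
  rownames(dos) <- as.character(df[[1]])
  list(dosages = dos, phenotype = NULL)
}

# VCF v4.x via vcfR: biallelic records, GT subfield only
read_vcf_dosages <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF ", path, ": ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    stop("multi-allelic VCF record not supported: ", fix[i, "CHROM"], ":",
         fix[i, "POS"], " (", fix[i, "ID"], ") ALT=", fix[i, "ALT"])
  }
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  gt <- vcfR::extract.gt(vcf, element = "GT")  # SNPs x samples
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    if (!all(al %in% c("0", "1")))
      stop("unsupported genotype '", g, "' (only 0/1 alleles handled)")
    sum(al == "1")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  dos <- t(dos)  # -> samples x SNPs
  colnames(dos) <- ids
  list(dosages = dos, phenotype = NULL)
}

#' Write a genotype dataset as a PLINK raw text file
#'
#' @param ds a [genotype_dataset()].
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(ds, path) {
  df <- data.frame(FID = ds$sample_ids, IID = ds$sample_ids, PAT = 0,
                   MAT = 0, SEX = 0, PHENOTYPE = ds$phenotype + 1L,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(ds$dosages, check.names = FALSE))
  write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene map TSV
#'
#' @param gene_of_snp named character vector (SNP id -> gene).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gene_of_snp, path) {
  write.table(data.frame(names(gene_of_snp), unname(gene_of_snp)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate and preprocess a genotype dataset
#'
#' Missing dosages are mean-imputed per SNP (default) or the samples
#' carrying them dropped; monomorphic (zero-variance) SNP columns are then
#' removed with a warning, since every downstream statistic standardizes
#' by the SNP standard deviation.  A gene losing all its SNPs is an error.
#'
#' @param ds a [genotype_dataset()].
#' @param impute `"mean"` or `"drop_sample"`.
#' @return the cleaned `genotype_dataset`, with a `preprocess_report`
#'   attribute (see [preprocess_report()]).
#' @export
preprocess_genotypes <- function(ds, impute = c("mean", "drop_sample")) {
  impute <- match.arg(impute)
  dos <- ds$dosages
  ph <- ds$phenotype
  ids <- ds$sample_ids
  n_missing <- sum(is.na(dos))
  dropped_samples <- character(0)

  if (n_missing > 0) {
    if (impute == "mean") {
      for (j in which(colSums(is.na(dos)) > 0)) {
        m <- mean(dos[, j], na.rm = TRUE)
        dos[is.na(dos[, j]), j] <- m
      }
    } else {
      keep <- complete.cases(dos)
      dropped_samples <- ids[!keep]
      dos <- dos[keep, , drop = FALSE]
      ph <- ph[keep]
      ids <- ids[keep]
    }
  }

  v <- apply(dos, 2, var)
  mono <- colnames(dos)[v < 1e-12]
  if (length(mono)) {
    warning("removing ", length(mono), " monomorphic SNP(s): ",
            paste(mono, collapse = ", "))
    dos <- dos[, !(colnames(dos) %in% mono), drop = FALSE]
  }
  if (ncol(dos) == 0) stop("no polymorphic SNPs left after preprocessing")

  gom <- ds$gene_of_snp
  lost <- setdiff(unique(gom), unique(gom[colnames(dos)]))
  if (length(lost))
    stop("gene(s) left with no SNPs after preprocessing: ",
         paste(lost, collapse = ", "))

  out <- genotype_dataset(dos, gom[colnames(dos)], ph, ids)
  attr(out, "preprocess_report") <- list(
    n_imputed = if (impute == "mean") n_missing else 0L,
    dropped_samples = dropped_samples,
    dropped_snps = mono, impute = impute)
  out
}

#' Retrieve the report attached by [preprocess_genotypes()]
#' @param ds a preprocessed [genotype_dataset()].
#' @return a list with elements `n_imputed`, `dropped_samples`,
#'   `dropped_snps`, `impute` (or `NULL` if not preprocessed).
#' @export
preprocess_report <- function(ds) attr(ds, "preprocess_report")

## ---------------------------------------------------------------------
## Haplotype panels

#' Construct a haplotype panel
#'
#' @param haplotypes H x m matrix of 0/1 alleles (rows are haplotypes).
#' @param snp_ids SNP identifiers (defaults to column names).
#' @param gene_of_snp optional named character vector mapping SNP to gene.
#' @param mafs optional declared minor-allele frequencies; empirical
#'   frequencies are always computed.
#' @param ld_groups optional list of SNP index vectors sampled
#'   independently of each other (used by scenario presets where the two
#'   genes sit on unlinked regions); default: one group of all SNPs.
#' @return an object of class `haplotype_panel` with empirical `maf_hat`
#'   and pairwise allelic correlation `ld_r` attached (`NA` for
#'   zero-variance columns).
#' @export
haplotype_panel <- function(haplotypes, snp_ids = NULL, gene_of_snp = NULL,
                            mafs = NULL, ld_groups = NULL) {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% c(0, 1)))
    stop("haplotype entries must be 0/1")
  storage.mode(haplotypes) <- "integer"
  if (is.null(snp_ids))
    snp_ids <- colnames(haplotypes) %||% paste0("snp", seq_len(ncol(haplotypes)))
  colnames(haplotypes) <- snp_ids
  maf_hat <- colMeans(haplotypes)
  v <- apply(haplotypes, 2, var)
  ld_r <- suppressWarnings(cor(haplotypes))
  ld_r[v < 1e-12, ] <- NA_real_
  ld_r[, v < 1e-12] <- NA_real_
  diag(ld_r) <- 1
  if (is.null(ld_groups)) ld_groups <- list(seq_along(snp_ids))
  structure(list(haplotypes = haplotypes, snp_ids = snp_ids,
                 gene_of_snp = gene_of_snp, mafs = mafs, maf_hat = maf_hat,
                 ld_r = ld_r, ld_groups = ld_groups),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "SNPs\n")
  cat("MAF range:", sprintf("%.3f-%.3f", min(x$maf_hat), max(x$maf_hat)), "\n")
  if (!is.null(x$gene_of_snp)) {
    g <- table(x$gene_of_snp)
    cat("Genes:", paste(sprintf("%s (%d)", names(g), g), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a phased haplotype panel
#'
#' `impute_hap_legend`: IMPUTE-style pair of files, `<path>.hap` (one row
#' per SNP, one 0/1 column per haplotype) and `<path>.legend` (header
#' `id position a0 a1`).  `tsv`: tab-separated matrix with a header row of
#' SNP ids, one row per haplotype.
#'
#' @param path for `impute_hap_legend`, the common prefix of the
#'   `.hap`/`.legend` pair (or the `.hap` file itself); for `tsv`, the file.
#' @param format `"impute_hap_legend"` or `"tsv"`.
#' @param gene_of_snp optional SNP-to-gene map (named vector or TSV path).
#' @return a [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path,
                                 format = c("impute_hap_legend", "tsv"),
                                 gene_of_snp = NULL) {
  format <- match.arg(format)
  if (is.character(gene_of_snp) && length(gene_of_snp) == 1 &&
      file.exists(gene_of_snp))
    gene_of_snp <- read_gene_map(gene_of_snp)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    hap <- as.matrix(df)
    check_binary_panel(hap, path)
    return(haplotype_panel(hap, colnames(hap), gene_of_snp))
  }
  hp <- sub("\\.hap(\\.gz)?$", "", path)
  hap_file <- if (file.exists(paste0(hp, ".hap"))) paste0(hp, ".hap")
              else paste0(hp, ".hap.gz")
  leg_file <- if (file.exists(paste0(hp, ".legend"))) paste0(hp, ".legend")
              else paste0(hp, ".legend.gz")
  if (!file.exists(hap_file) || !file.exists(leg_file))
    stop("need both ", hp, ".hap and ", hp, ".legend")
  leg <- read.table(leg_file, header = TRUE, stringsAsFactors = FALSE)
  m <- as.matrix(read.table(hap_file, header = FALSE))
  if (nrow(m) != nrow(leg))
    stop(".hap has ", nrow(m), " rows but .legend lists ", nrow(leg), " SNPs")
  hap <- t(m)   # -> haplotypes x SNPs
  check_binary_panel(hap, hap_file)
  colnames(hap) <- leg$id
  haplotype_panel(hap, leg$id, gene_of_snp)
}

check_binary_panel <- function(hap, path) {
  bad <- which(matrix(!(hap %in% c(0, 1)), nrow(hap)), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-binary haplotype entry '", hap[bad[1, 1], bad[1, 2]], "' in ",
         path, " at row ", bad[1, 1], ", column ", bad[1, 2])
  invisible(TRUE)
}

#' Write a haplotype panel
#'
#' @param panel a [haplotype_panel()].
#' @param path output prefix (for `impute_hap_legend`, writes
#'   `<path>.hap` + `<path>.legend`) or file (for `tsv`).
#' @param format `"impute_hap_legend"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_haplotype_panel <- function(panel, path,
                                  format = c("impute_hap_legend", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(panel$haplotypes, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(path))
  }
  write.table(t(panel$haplotypes), paste0(path, ".hap"), sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  leg <- data.frame(id = panel$snp_ids,
                    position = seq_along(panel$snp_ids), a0 = "A", a1 = "B")
  write.table(leg, paste0(path, ".legend"), sep = " ", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a results table with provenance comment lines
#'
#' @param df results data frame.
#' @param path output TSV.
#' @param seed master seed used for the run.
#' @param config any R object describing the run configuration; a short
#'   hash of it is recorded.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# coassoc ", as.character(packageVersion("coassoc"))),
    paste0("# seed=", seed),
    paste0("# config_hash=", if (is.null(config)) "NA" else config_hash(config))
  ), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
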