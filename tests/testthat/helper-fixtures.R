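# Small in-code fixtures shared across test files.

# genotype matrix from explicit rows (individuals x loci)
gm <- function(..., ids = NULL) {
  rows <- list(...)
  codes <- do.call(rbind, rows)
  genotype_matrix(codes,
                  individual_ids = ids %||% paste0("I", seq_len(nrow(codes))),
                  locus_ids = paste0("L", seq_len(ncol(codes))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cp <- function(values, ids = paste0("I", seq_along(values))) {
  structure(stats::setNames(as.numeric(values), ids), class = "corrected_pheno")
}

# random genotype fixture under HWE
random_gm <- function(n, m, seed, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  genotype_matrix(matrix(rbinom(n * m, 2, rep(p, each = n)), n, m),
                  individual_ids = sprintf("I%04d", seq_len(n)),
                  locus_ids = sprintf("L%04d", seq_len(m)))
}

# a class-means object built directly from the three means (one locus)
means_fixture <- function(m00, m01, m11, n00 = 10, n01 = 10, n11 = 10,
                          pheno_sd = 1) {
  structure(data.frame(locus = "L1", mean_00 = m00, mean_01 = m01,
                       mean_11 = m11, n_00 = n00, n_01 = n01, n_11 = n11,
                       stringsAsFactors = FALSE),
            class = c("genotype_class_means", "data.frame"),
            pheno_sd = pheno_sd, n_subset = n00 + n01 + n11)
}

write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1|0", "0|0", "1|1", "0|1", sep = "\t"),
    paste("1", "300", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/0", "0/2", "1/2", "0/1", sep = "\t"),  # tri-allelic: skipped
    paste("1", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "500", "rs5", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/1", "0/0", sep = "\t")
  ), path)
  path
}

write_tiny_plink_raw <- function(path) {
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_T rs3_G",
    "F1 I1 0 0 1 -9 0 1 2",
    "F1 I2 0 0 2 -9 1 NA 0",
    "F2 I3 0 0 1 -9 2 2 1"
  ), path)
  path
}

# wide per-fold table: one column per model, rows ordered by replicate/fold
reshape_folds <- function(folds, col) {
  sp <- split(folds, folds$model)
  out <- lapply(sp, function(d) d[order(d$replicate, d$fold), col])
  as.data.frame(out)
}

# synthetic cv_result for bootstrap_compare tests: per model a prediction
# vector with target correlation rho to a shared y (clone = TRUE reuses one
# vector for every model)
fake_cv <- function(model_rho, n, seed, clone = FALSE, replicates = 2) {
  set.seed(seed)
  ids <- sprintf("I%04d", seq_len(n))
  rows <- list()
  for (r in seq_len(replicates)) {
    y <- rnorm(n)
    base <- rnorm(n)
    for (m in names(model_rho)) {
      rho <- model_rho[[m]]
      pred <- if (clone) base
      else rho * y + sqrt(max(0, 1 - rho^2)) * rnorm(n)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, replicate = r, id = ids, pred = pred, y = y,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(predictions = do.call(rbind, rows),
                 folds = data.frame(), models = names(model_rho),
                 k = 1, replicates = replicates, seed = seed,
                 n_nonconverged = 0),
            class = "cv_result")
}
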