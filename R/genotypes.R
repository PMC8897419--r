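#' Construct a genotype matrix object
#'
#' Container for biallelic SNP genotypes coded as counts of the allele whose
#' homozygote is coded 2 (conventionally A2): 0 = A1A1, 1 = A1A2, 2 = A2A2,
#' `NA` = missing.
#'
#' @param codes integer matrix, individuals in rows and loci in columns;
#'   entries in {0, 1, 2, NA}.
#' @param individual_ids character vector of unique individual identifiers
#'   (defaults to rownames of `codes`).
#' @param locus_ids character vector of unique locus identifiers (defaults to
#'   colnames of `codes`).
#' @param allele_labels optional data.frame with columns `a1`, `a2` giving the
#'   allele pair per locus; the code counts copies of `a2`.
#' @return an object of class `genotype_matrix`: a list with elements `codes`
#'   (integer matrix with dimnames) and `alleles`.
#' @export
genotype_matrix <- function(codes, individual_ids = rownames(codes),
                            locus_ids = colnames(codes), allele_labels = NULL) {
  codes <- as.matrix(codes)
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("IND%04d", seq_len(nrow(codes)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- sprintf("LOC%05d", seq_len(ncol(codes)))
  }
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (nrow(codes) < 2L) stop_data("need at least 2 individuals")
  if (ncol(codes) < 1L) stop_data("need at least 1 locus")
  if (anyDuplicated(individual_ids)) stop_data("duplicate individual identifiers")
  if (anyDuplicated(locus_ids)) stop_data("duplicate locus identifiers")
  if (length(individual_ids) != nrow(codes) || length(locus_ids) != ncol(codes)) {
    stop_data("identifier lengths do not match the code matrix")
  }
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop_data("genotype codes must be 0, 1, 2 or NA; found ",
                          paste(unique(codes[bad]), collapse = ", "))
  dimnames(codes) <- list(individual_ids, locus_ids)
  if (!is.null(allele_labels)) {
    allele_labels <- as.data.frame(allele_labels)
    stopifnot(nrow(allele_labels) == ncol(codes))
  }
  structure(list(codes = codes, alleles = allele_labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

individual_ids <- function(g) rownames(g$codes)
locus_ids <- function(g) colnames(g$codes)

#' Read genotypes from file
#'
#' Supported formats: a VCF with GT fields (biallelic SNPs; multi-allelic
#' sites are skipped with a message), a PLINK `.raw` additive-coded text file
#' (columns FID/IID/PAT/MAT/SEX/PHENOTYPE then one 0/1/2/NA column per SNP),
#' or the package's TSV dialect written by [write_genotypes_tsv()] (first
#' column `id`, remaining columns locus IDs, entries 0/1/2/NA).
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"vcf"`, `"plink_raw"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("genotype file not found: ", path)
  g <- switch(format,
    tsv = read_genotypes_tsv(path),
    vcf = read_genotypes_vcf(path),
    plink_raw = read_genotypes_plink_raw(path)
  )
  if (ncol(g$codes) == 0L) stop_data("no usable loci in ", path)
  g
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "id") {
    stop_data("TSV genotype dialect requires an 'id' first column")
  }
  codes <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(codes)) stop_data("non-numeric genotype codes in ", path)
  genotype_matrix(codes, individual_ids = df$id, locus_ids = names(df)[-1])
}

read_genotypes_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
  if (!("IID" %in% meta)) stop_data("PLINK .raw file lacks an IID column")
  snp_cols <- setdiff(names(df), meta)
  if (length(snp_cols) == 0L) stop_data("PLINK .raw file has no SNP columns")
  codes <- as.matrix(df[, snp_cols, drop = FALSE])
  # .raw column names carry the counted allele as a suffix, e.g. "rs1_A"
  loc <- sub("_[ACGT0-9]+$", "", snp_cols)
  a2 <- ifelse(grepl("_[ACGT]$", snp_cols), sub("^.*_", "", snp_cols), NA)
  genotype_matrix(codes, individual_ids = df$IID, locus_ids = loc,
                  allele_labels = data.frame(a1 = NA, a2 = a2))
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_usage("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop_data("VCF has no GT field: ", path)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  multi <- nalt > 1L
  if (any(multi)) {
    message(sum(multi), " multi-allelic site(s) skipped")
    gt <- gt[!multi, , drop = FALSE]
    vcf <- vcf[!multi, ]
  }
  if (nrow(gt) == 0L) stop_data("no biallelic sites in ", path)
  codes <- apply(gt, c(1, 2), gt_to_code)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt1 <- vapply(VariantAnnotation::alt(vcf),
                 function(a) as.character(a)[1], character(1))
  genotype_matrix(t(codes), individual_ids = colnames(gt),
                  locus_ids = rownames(gt),
                  allele_labels = data.frame(a1 = ref, a2 = alt1))
}

gt_to_code <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == "1")
}

#' Write genotypes in the package TSV dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  df <- data.frame(id = individual_ids(g), g$codes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele frequencies of the coded-2 allele
#'
#' `p_i` is the frequency of the allele whose homozygote is coded 2,
#' estimated as half the mean of the non-missing codes at locus i.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector `p` (one entry per locus, in `[0, 1]`);
#'   loci with every genotype missing get `NA` and are flagged in the
#'   `all_missing` attribute.
#' @export
allele_frequencies <- function(g) {
  p <- colMeans(g$codes, na.rm = TRUE) / 2
  all_missing <- !is.finite(p)
  p[all_missing] <- NA_real_
  attr(p, "all_missing") <- all_missing
  p
}

#' Filter loci on minor allele frequency
#'
#' Loci with MAF strictly below `threshold` are removed; a locus whose MAF
#' equals the threshold exactly is kept. Loci with all genotypes missing are
#' removed as well.
#'
#' @param g a [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return the filtered [genotype_matrix()] with attribute `n_removed`.
#' @export
filter_maf <- function(g, threshold = 0.01) {
  if (threshold < 0 || threshold > 0.5) stop_usage("MAF threshold must be in [0, 0.5]")
  p <- allele_frequencies(g)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= threshold
  if (!any(keep)) stop_data("all loci removed by the MAF filter")
  out <- genotype_matrix(g$codes[, keep, drop = FALSE],
                         allele_labels = if (!is.null(g$alleles))
                           g$alleles[keep, , drop = FALSE] else NULL)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Mean-impute missing genotypes
#'
#' Missing entries are replaced with the locus mean code `2 p_i`. Returns a
#' real-valued matrix ready for relationship-matrix construction; dominance
#' class means elsewhere use only the original non-missing codes.
#'
#' @param g a [genotype_matrix()].
#' @param freqs allele frequencies from [allele_frequencies()] (recomputed if
#'   omitted); must align with the loci of `g`.
#' @return numeric n x m matrix.
#' @export
impute_missing <- function(g, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  if (length(freqs) != ncol(g$codes)) {
    stop_data("allele frequencies do not align with the genotype loci")
  }
  z <- g$codes
  storage.mode(z) <- "double"
  miss <- which(is.na(z))
  if (length(miss)) {
    col <- (miss - 1L) %/% nrow(z) + 1L
    z[miss] <- 2 * freqs[col]
  }
  z
}
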