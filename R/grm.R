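# Genomic relationship matrices.
#
# Additive G (VanRaden): centered allele counts, G = MM'/sum(2 p q).
# Dominance D (Vitezica): heterozygosity coefficients (-2p^2, 2pq, -2q^2),
#   D = HH'/sum((2pq)^2).
# Combined G_ad (CADM): the dominance-weighted coded matrix (0 / C_d / 2,
#   homozygotes swapped at flipped loci), centered and scaled exactly like
#   the additive G. The scaling denominator sum(2 p q) is kept as printed,
#   i.e. it does not adapt to the weighted coding variance.
#
# Centering note: we center each column by 2 * (frequency of the allele
# coded 2, after any flip). Centering by the other allele's frequency
# (`centering = "paper_literal"`) is available but breaks the zero-mean
# property that centering exists to provide; see the methods vignette.

new_grm <- function(values, kind, ids, denominator, ridge_added = 0) {
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, denominator = denominator,
            ridge_added = ridge_added, class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d x %d, denominator %.4f, ridge %g\n",
              attr(x, "kind"), nrow(x), ncol(x),
              attr(x, "denominator"), attr(x, "ridge_added")))
  invisible(x)
}

center_scale <- function(z, p, kind, centering = c("coded2", "paper_literal")) {
  centering <- match.arg(centering)
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop_data("zero denominator: all loci are monomorphic")
  ctr <- if (centering == "coded2") 2 * p else 2 * (1 - p)
  m <- sweep(z, 2, ctr, "-")
  new_grm(tcrossprod(m) / denom, kind, rownames(z), denom)
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' `G = M M' / sum(2 p_i (1 - p_i))` where column i of `M` holds the
#' genotype codes 0/1/2 (mean-imputed where missing) centered by `2 p_i`.
#'
#' @param g a [genotype_matrix()].
#' @param freqs allele frequencies of the coded-2 allele (recomputed from all
#'   individuals of `g` if omitted).
#' @param centering `"coded2"` (default) centers by twice the coded-2 allele
#'   frequency; `"paper_literal"` by twice the other allele's frequency.
#' @return a `grm` of kind `G_additive`.
#' @export
build_additive_G <- function(g, freqs = NULL, centering = "coded2") {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  z <- impute_missing(g, freqs)
  center_scale(z, as.numeric(freqs), "G_additive", centering)
}

#' Dominance genomic relationship matrix (Vitezica)
#'
#' `D = H H' / sum((2 p_i q_i)^2)` where the column-i coefficients of `H` are
#' `-2 p_i^2` (code 0), `2 p_i q_i` (code 1) and `-2 q_i^2` (code 2).
#' Missing genotypes take the locus mean heterozygosity coefficient.
#'
#' @inheritParams build_additive_G
#' @return a `grm` of kind `D_dominance`.
#' @export
build_dominance_D <- function(g, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  p <- as.numeric(freqs)
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  if (denom <= 0) stop_data("zero denominator: all loci are monomorphic")
  codes <- g$codes
  n <- nrow(codes)
  h <- matrix(NA_real_, n, ncol(codes), dimnames = dimnames(codes))
  col_of <- function(idx) (idx - 1L) %/% n + 1L
  for (k in 0:2) {
    idx <- which(codes == k)
    coefs <- switch(as.character(k),
                    "0" = -2 * p^2, "1" = 2 * p * q, "2" = -2 * q^2)
    h[idx] <- coefs[col_of(idx)]
  }
  miss <- which(is.na(h))
  if (length(miss)) {
    cm <- colMeans(h, na.rm = TRUE)
    cm[!is.finite(cm)] <- 0
    h[miss] <- cm[col_of(miss)]
  }
  new_grm(tcrossprod(h) / denom, "D_dominance", rownames(codes), denom)
}

#' Combined additive-dominance relationship matrix from a coded matrix
#'
#' `G_ad = M_ad M_ad' / sum(2 p_i (1 - p_i))` where `M_ad` is the
#' dominance-weighted coded matrix ([apply_coding()]) centered by `2 p_i`,
#' with `p_i` the frequency of the allele coded 2 after flipping.
#'
#' @param coded real n x m matrix from [apply_coding()] (post-flip,
#'   post-weighting, missing already filled).
#' @param freqs per-locus frequency of the allele coded 2 after flipping.
#' @param centering see [build_additive_G()].
#' @return a `grm` of kind `G_ad_combined`.
#' @export
build_combined_Gad <- function(coded, freqs, centering = "coded2") {
  if (length(freqs) != ncol(coded)) {
    stop_data("allele frequencies do not align with the coded matrix")
  }
  g <- center_scale(coded, as.numeric(freqs), "G_ad_combined", centering)
  g
}

#' CADM relationship matrix from genotypes and a dominance coding
#'
#' Convenience wrapper: applies the coding, flips the centering frequencies
#' at flipped loci, and builds `G_ad`. Frequencies are computed from the
#' original 0/1/2 codes (allele frequency is a population concept; `C_d` is a
#' phenotype-scale weight), over all individuals of `g` unless supplied.
#'
#' @param g a [genotype_matrix()].
#' @param coding a `dominance_coding` aligned with `g`.
#' @param freqs optional allele frequencies of the coded-2 allele of the
#'   *original* codes.
#' @param centering see [build_additive_G()].
#' @return a `grm` of kind `G_ad_combined`.
#' @export
cadm_grm <- function(g, coding, freqs = NULL, centering = "coded2") {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  p <- as.numeric(freqs)
  p_eff <- ifelse(coding$flip, 1 - p, p)
  build_combined_Gad(apply_coding(g, coding), p_eff, centering)
}

#' Ensure a relationship matrix factorizes
#'
#' Adds the smallest ridge from `{0, ridge_start, 10 ridge_start, ...}` to
#' the diagonal such that a Cholesky factorization succeeds; the ridge is
#' recorded in the `ridge_added` attribute.
#'
#' @param R a `grm` (or plain symmetric matrix).
#' @param ridge_start first nonzero ridge to try (default 1e-8).
#' @param ridge_max error out beyond this ridge (default 1e-2): data are
#'   likely degenerate.
#' @return the (possibly ridged) matrix with `ridge_added` set.
#' @export
ensure_invertible <- function(R, ridge_start = 1e-8, ridge_max = 1e-2) {
  v <- unclass(R)
  ridge <- 0
  repeat {
    ok <- tryCatch({chol(v + diag(ridge, nrow(v))); TRUE},
                   error = function(e) FALSE)
    if (ok) break
    ridge <- if (ridge == 0) ridge_start else ridge * 10
    if (ridge > ridge_max) {
      stop_numerical("relationship matrix not factorizable even with ridge ",
                     ridge_max)
    }
  }
  out <- v + diag(ridge, nrow(v))
  new_grm(out, attr(R, "kind") %||% "unknown",
          rownames(v) %||% as.character(seq_len(nrow(v))),
          attr(R, "denominator") %||% NA_real_, ridge_added = ridge)
}

#' Write a relationship matrix as plain text
#'
#' Header line of individual ids, then the lower triangle (including the
#' diagonal), one row per line — a simple interchange format for external
#' REML software.
#'
#' @param R a `grm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(R, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(R), collapse = "\t"), con)
  for (i in seq_len(nrow(R))) {
    writeLines(paste(format(unclass(R)[i, seq_len(i)], digits = 17),
                     collapse = "\t"), con)
  }
  invisible(path)
}
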