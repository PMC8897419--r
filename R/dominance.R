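# Locus-specific dominance weighting: the core of the CADM method.
#
# Per locus, the degree of dominance is estimated from the corrected
# phenotype means of the three genotype classes,
#     d = 2 * (x_het - x_min) / (x_max - x_min),
# where x_min/x_max are the smaller/larger homozygote means. d is clipped to
# [0, 2] (0 = recessive, 1 = additive, 2 = complete dominance); values
# outside would indicate over/under-dominance and the bounds can be relaxed
# via `bounds`. When the low homozygote mean exceeds the high one, the
# homozygote codes are swapped (flip) so that code 2 always tags the
# better-performing homozygote in the estimation data.

#' Per-locus genotype class means of corrected phenotypes
#'
#' Means and counts of the corrected phenotype within the three genotype
#' classes (codes 0, 1, 2), computed over a subset of individuals only —
#' during cross-validation this is the training set, so validation phenotypes
#' never influence the dominance weights. Mean-imputed genotypes are never
#' used here: only observed integer codes contribute.
#'
#' @param g a [genotype_matrix()].
#' @param y a `corrected_pheno` vector (names = ids).
#' @param subset individual ids to use; defaults to all phenotyped and
#'   genotyped individuals.
#' @return object of class `genotype_class_means`: data.frame with one row
#'   per locus (`locus`, `mean_00`, `mean_01`, `mean_11`, `n_00`, `n_01`,
#'   `n_11`); empty classes have `NaN` means. Carries the phenotype standard
#'   deviation of the subset in attribute `pheno_sd`.
#' @export
genotype_class_means <- function(g, y, subset = NULL) {
  ids <- intersect(individual_ids(g), names(y))
  if (!is.null(subset)) {
    bad <- setdiff(subset, ids)
    if (length(bad)) stop_data(length(bad), " subset id(s) not phenotyped+genotyped")
    ids <- intersect(ids, subset)
  }
  if (length(ids) < 2L) stop_data("need at least 2 individuals to compute class means")
  codes <- g$codes[ids, , drop = FALSE]
  yy <- as.numeric(y[ids])
  out <- data.frame(locus = locus_ids(g), stringsAsFactors = FALSE)
  lab <- c("00", "01", "11")
  for (k in 0:2) {
    ind <- codes == k
    ind[is.na(ind)] <- FALSE
    n <- colSums(ind)
    s <- as.numeric(crossprod(ind, yy))
    out[[paste0("mean_", lab[k + 1])]] <- s / n  # NaN where n == 0
    out[[paste0("n_", lab[k + 1])]] <- n
  }
  structure(out, class = c("genotype_class_means", "data.frame"),
            pheno_sd = stats::sd(yy), n_subset = length(ids))
}

#' Estimate per-locus degree of dominance and heterozygote weights
#'
#' Applies the degree-of-dominance estimator per locus and produces the
#' clipped heterozygote weight `C_d` plus the homozygote flip flag. A locus
#' falls back to plain additive coding (`C_d = 1`, no flip) when any genotype
#' class holds fewer than `min_class_count` individuals or when the two
#' homozygote means are numerically indistinguishable — the estimator is
#' undefined or hopelessly noisy there.
#'
#' @param means a [genotype_class_means()] object.
#' @param min_class_count minimum individuals per genotype class (default 3);
#'   use `Inf` to force additive coding at every locus.
#' @param bounds length-2 clipping bounds for `C_d`, default `c(0, 2)`.
#'   Relaxing them admits overdominance; `bounds[1] <= 1 <= bounds[2]` is
#'   required so the additive fallback is always representable.
#' @param spread_tol homozygote-mean spreads below `spread_tol *
#'   attr(means, "pheno_sd")` trigger the fallback (default 1e-12).
#' @return object of class `dominance_coding`: data.frame with columns
#'   `locus`, `raw_d`, `C_d`, `flip`, `fallback` and the class counts.
#' @export
estimate_dominance <- function(means, min_class_count = 3, bounds = c(0, 2),
                               spread_tol = 1e-12) {
  if (!(bounds[1] <= 1 && bounds[2] >= 1)) {
    stop_usage("C_d bounds must bracket 1 (the additive fallback)")
  }
  m00 <- means$mean_00; m01 <- means$mean_01; m11 <- means$mean_11
  sd_y <- attr(means, "pheno_sd")
  tol <- spread_tol * if (is.finite(sd_y) && sd_y > 0) sd_y else 1
  small <- means$n_00 < min_class_count | means$n_01 < min_class_count |
    means$n_11 < min_class_count
  x_min <- pmin(m00, m11)
  x_max <- pmax(m00, m11)
  degenerate <- !is.na(x_max - x_min) & (x_max - x_min) < tol
  fallback <- small | degenerate | !is.finite(m00 + m01 + m11)
  raw_d <- rep(NA_real_, length(m00))
  ok <- !fallback
  raw_d[ok] <- 2 * (m01[ok] - x_min[ok]) / (x_max[ok] - x_min[ok])
  c_d <- ifelse(fallback, 1, pmin(pmax(raw_d, bounds[1]), bounds[2]))
  flip <- !fallback & (m00 > m11)
  flip[is.na(flip)] <- FALSE
  structure(
    data.frame(locus = means$locus, raw_d = raw_d, C_d = c_d,
               flip = flip, fallback = fallback,
               n_00 = means$n_00, n_01 = means$n_01, n_11 = means$n_11,
               stringsAsFactors = FALSE),
    class = c("dominance_coding", "data.frame"),
    bounds = bounds
  )
}

#' Estimate dominance coding from genotypes and phenotypes
#'
#' Convenience wrapper: class means on a (training) subset, then
#' [estimate_dominance()].
#'
#' @inheritParams genotype_class_means
#' @inheritParams estimate_dominance
#' @return a `dominance_coding` object.
#' @export
dominance_coding <- function(g, y, subset = NULL, min_class_count = 3,
                             bounds = c(0, 2)) {
  estimate_dominance(genotype_class_means(g, y, subset),
                     min_class_count = min_class_count, bounds = bounds)
}

#' Apply the dominance coding to a genotype matrix
#'
#' Produces the real-valued coded matrix used to build the combined
#' relationship matrix: per locus the homozygotes are coded 0 and 2 (swapped
#' when `flip`), the heterozygote is coded `C_d`, and missing entries take
#' the locus mean of the coded column (consistent with mean imputation of
#' raw codes).
#'
#' @param g a [genotype_matrix()].
#' @param coding a `dominance_coding` aligned with the loci of `g`.
#' @return numeric n x m matrix.
#' @export
apply_coding <- function(g, coding) {
  if (nrow(coding) != ncol(g$codes) ||
      !identical(coding$locus, locus_ids(g))) {
    stop_data("dominance coding does not align with the genotype loci")
  }
  z <- g$codes
  storage.mode(z) <- "double"
  n <- nrow(z)
  if (any(coding$flip)) {
    z[, coding$flip] <- 2 - z[, coding$flip]
  }
  het <- which(g$codes == 1L)
  if (length(het)) {
    z[het] <- coding$C_d[(het - 1L) %/% n + 1L]
  }
  miss <- which(is.na(z))
  if (length(miss)) {
    cm <- colMeans(z, na.rm = TRUE)
    z[miss] <- cm[(miss - 1L) %/% n + 1L]
  }
  z
}

#' Write a dominance coding audit table
#'
#' TSV with one row per locus: the raw and clipped degree of dominance, flip
#' and fallback flags, and class counts — the audit trail of which loci drove
#' any CADM gain.
#'
#' @param coding a `dominance_coding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dominance_tsv <- function(coding, path) {
  utils::write.table(as.data.frame(coding), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
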