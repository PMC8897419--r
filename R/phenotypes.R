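#' Construct a phenotype table
#'
#' Standardizes a data.frame to columns `id`, `trait`, then the categorical
#' covariates used for fixed-effect correction.
#'
#' @param df data.frame holding identifiers, one trait and covariates.
#' @param id_col name of the identifier column.
#' @param trait_col name of the trait column.
#' @param covariate_cols character vector of covariate column names (may be
#'   empty).
#' @return a data.frame of class `phenotype_table` with columns `id`,
#'   `trait`, and the covariates (as character).
#' @export
phenotype_table <- function(df, id_col = "id", trait_col = "trait",
                            covariate_cols = character(0)) {
  missing_cols <- setdiff(c(id_col, trait_col, covariate_cols), names(df))
  if (length(missing_cols)) {
    stop_data("phenotype table lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(id = as.character(df[[id_col]]),
                    trait = as.numeric(df[[trait_col]]),
                    stringsAsFactors = FALSE)
  for (cv in covariate_cols) out[[cv]] <- as.character(df[[cv]])
  if (anyDuplicated(out$id)) stop_data("duplicate individual identifiers in phenotypes")
  if (all(is.na(out$trait))) stop_data("no non-missing trait values")
  phen <- !is.na(out$trait)
  for (cv in covariate_cols) {
    if (any(is.na(out[[cv]][phen]) | out[[cv]][phen] == "")) {
      stop_data("covariate '", cv, "' has empty levels for phenotyped individuals")
    }
  }
  structure(out, class = c("phenotype_table", "data.frame"),
            covariates = covariate_cols)
}

#' Read a phenotype table from CSV/TSV
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.csv` = comma, otherwise tab).
#' @inheritParams phenotype_table
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, id_col = "id", trait_col = "trait",
                            covariate_cols = character(0)) {
  if (!file.exists(path)) stop_data("phenotype file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  phenotype_table(df, id_col, trait_col, covariate_cols)
}

#' Correct phenotypes for categorical fixed effects
#'
#' Fits an ordinary least-squares model of the trait on the named categorical
#' covariates (intercept plus treatment contrasts, lexicographically first
#' level as the reference) and returns `y - X %*% beta_hat + mean(y)`:
#' the fixed effects are removed but the grand mean is retained. Records with
#' a missing trait value are dropped.
#'
#' @param ph a [phenotype_table()].
#' @param covariate_names covariates to correct for; defaults to all
#'   covariates in `ph`. May be empty, in which case the values are returned
#'   unchanged (minus records with missing trait).
#' @return a named numeric vector of class `corrected_pheno` (names =
#'   individual ids), in trait units.
#' @export
correct_fixed_effects <- function(ph, covariate_names = attr(ph, "covariates")) {
  covariate_names <- covariate_names %||% character(0)
  missing_cols <- setdiff(covariate_names, names(ph))
  if (length(missing_cols)) {
    stop_data("unknown covariate(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- !is.na(ph$trait)
  y <- ph$trait[keep]
  ids <- ph$id[keep]
  if (length(covariate_names) == 0L) {
    return(structure(stats::setNames(y, ids), class = "corrected_pheno"))
  }
  dat <- data.frame(.y = y)
  for (cv in covariate_names) {
    lev <- sort(unique(ph[[cv]][keep]))  # lexicographic reference level
    dat[[cv]] <- factor(ph[[cv]][keep], levels = lev)
  }
  form <- stats::as.formula(paste(".y ~", paste(covariate_names, collapse = " + ")))
  fit <- stats::lm(form, data = dat,
                   contrasts = NULL)  # default treatment contrasts
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop_data("confounded fixed effects; aliased terms: ",
              paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  corrected <- stats::residuals(fit) + mean(y)
  structure(stats::setNames(as.numeric(corrected), ids),
            class = "corrected_pheno")
}

#' Align a genotype matrix and corrected phenotypes
#'
#' Individuals with genotypes but no phenotype are retained in the genotype
#' matrix (they can still be predicted); phenotyped individuals with no
#' genotype are dropped with a warning.
#'
#' @param g a [genotype_matrix()].
#' @param y a `corrected_pheno` vector.
#' @return list with elements `g` and `y`.
#' @export
align_data <- function(g, y) {
  gids <- individual_ids(g)
  drop <- setdiff(names(y), gids)
  if (length(drop)) {
    warning(length(drop), " phenotyped individual(s) without genotypes dropped")
    y <- y[setdiff(names(y), drop)]
    class(y) <- "corrected_pheno"
  }
  if (length(y) == 0L) stop_data("no phenotyped individuals with genotypes")
  list(g = g, y = y)
}
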