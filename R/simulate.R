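# Synthetic genotypes and traits with locus-specific dominance.
#
# Genotypes: independent biallelic loci in Hardy-Weinberg proportions, with
# per-locus allele frequency drawn uniformly from a MAF range. Traits: a
# subset of loci are QTL; QTL j with additive effect a_j and dominance
# degree delta_j contributes a_j * v where v = 0, delta_j, 2 for the three
# genotype classes — the same 0/C_d/2 scale the CADM coding estimates, so a
# simulated delta is directly comparable to an estimated C_d (delta = 1 is
# additive, 2 complete dominance, 0 recessive). The residual variance is
# solved analytically from the realized genetic variance to hit the target
# broad-sense heritability.

#' Define a simulation scenario
#'
#' @param n_individuals number of individuals.
#' @param n_loci number of genotyped marker loci.
#' @param n_qtl number of QTL (a subset of the markers unless `hidden_qtl`).
#' @param maf_range allele-frequency range, uniform draw within
#'   `(0, 0.5]` bounds.
#' @param qtl_effect_sd standard deviation of the Normal additive QTL
#'   effects a_j (trait units).
#' @param delta per-QTL dominance degrees on the 0/delta/2 genotype-value
#'   scale: a scalar (recycled) or a length-`n_qtl` vector with entries
#'   typically in `[0, 2]`.
#' @param h2 target broad-sense heritability, in (0, 1).
#' @param fixed_effects optional named list of covariates; each element is a
#'   named numeric vector of level effects, e.g.
#'   `list(sex = c(F = 0, M = 5))`. Levels are assigned uniformly at random.
#' @param ld_rho optional first-order correlation between adjacent loci
#'   (default 0 = independent loci); used for robustness checks only.
#' @param hidden_qtl if `TRUE` the QTL are dropped from the marker panel.
#' @param seed RNG seed.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_individuals = 500, n_loci = 1000, n_qtl = 50,
                         maf_range = c(0.05, 0.5), qtl_effect_sd = 1,
                         delta = 1, h2 = 0.5, fixed_effects = NULL,
                         ld_rho = 0, hidden_qtl = FALSE, seed = 1) {
  if (h2 <= 0 || h2 >= 1) stop_usage("h2 must be in (0, 1)")
  if (n_qtl > n_loci) stop_usage("n_qtl cannot exceed n_loci")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_usage("maf_range must lie within (0, 0.5]")
  }
  delta <- rep_len(delta, n_qtl)
  structure(list(n_individuals = n_individuals, n_loci = n_loci,
                 n_qtl = n_qtl, maf_range = maf_range,
                 qtl_effect_sd = qtl_effect_sd, delta = delta, h2 = h2,
                 fixed_effects = fixed_effects, ld_rho = ld_rho,
                 hidden_qtl = hidden_qtl, seed = seed),
            class = "sim_scenario")
}

#' Named scenario presets
#'
#' `"additive"`: all delta = 1, h2 = 0.5. `"mixed_dominance"`: the first
#' `floor(n_qtl/2)` QTL at delta = 2, the rest at delta = 0, h2 = 0.3.
#' `"low_h2_dominant"`: all delta = 2, h2 = 0.15. `"null"`: h2 = 0.01
#' (essentially pure noise).
#'
#' @param n_individuals,n_loci,n_qtl,seed shared sizing parameters applied
#'   to every preset.
#' @return named list of [sim_scenario()] objects.
#' @export
scenario_presets <- function(n_individuals = 500, n_loci = 1000, n_qtl = 50,
                             seed = 1) {
  half <- n_qtl %/% 2
  mix <- c(rep(2, half), rep(0, n_qtl - half))
  list(
    additive = sim_scenario(n_individuals, n_loci, n_qtl, delta = 1,
                            h2 = 0.5, seed = seed),
    mixed_dominance = sim_scenario(n_individuals, n_loci, n_qtl, delta = mix,
                                   h2 = 0.3, seed = seed),
    low_h2_dominant = sim_scenario(n_individuals, n_loci, n_qtl, delta = 2,
                                   h2 = 0.15, seed = seed),
    null = sim_scenario(n_individuals, n_loci, n_qtl, delta = 1,
                        h2 = 0.01, seed = seed)
  )
}

#' Simulate genotypes under Hardy-Weinberg proportions
#'
#' @param scenario a [sim_scenario()].
#' @return a [genotype_matrix()]; attribute `p_true` holds the simulated
#'   allele frequencies.
#' @export
simulate_genotypes <- function(scenario) {
  set.seed(scenario$seed)
  m <- scenario$n_loci; n <- scenario$n_individuals
  p <- stats::runif(m, scenario$maf_range[1], scenario$maf_range[2])
  if (scenario$ld_rho > 0) {
    # first-order dependence between adjacent loci via a latent Gaussian copula
    z <- matrix(stats::rnorm(n * 2 * m), n, 2 * m)
    for (j in seq(2, 2 * m)) {
      z[, j] <- scenario$ld_rho * z[, j - 1] +
        sqrt(1 - scenario$ld_rho^2) * z[, j]
    }
    u1 <- stats::pnorm(z[, seq(1, 2 * m, by = 2)])
    u2 <- stats::pnorm(z[, seq(2, 2 * m, by = 2)])
    codes <- (u1 < rep(p, each = n)) + (u2 < rep(p, each = n))
  } else {
    codes <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
  }
  g <- genotype_matrix(codes,
                       individual_ids = sprintf("IND%05d", seq_len(n)),
                       locus_ids = sprintf("LOC%05d", seq_len(m)))
  attr(g, "p_true") <- p
  g
}

#' Simulate a trait on given genotypes
#'
#' @param g a [genotype_matrix()] (typically from [simulate_genotypes()]).
#' @param scenario the [sim_scenario()] used.
#' @return object of class `sim_dataset`: list with `genotypes` (QTL removed
#'   when `hidden_qtl`), `phenotypes` (a [phenotype_table()]), and `truth`
#'   (list: `qtl` data.frame of locus/a/delta, `genetic_values`,
#'   `var_genetic`, `var_residual`, `h2_realized`).
#' @export
simulate_trait <- function(g, scenario) {
  set.seed(derive_seed(scenario$seed, 1L))
  n <- nrow(g$codes); m <- ncol(g$codes)
  if (scenario$n_qtl > m) stop_usage("n_qtl exceeds the number of loci")
  qtl_idx <- sort(sample.int(m, scenario$n_qtl))
  a <- stats::rnorm(scenario$n_qtl, 0, scenario$qtl_effect_sd)
  delta <- scenario$delta
  v <- g$codes[, qtl_idx, drop = FALSE]
  storage.mode(v) <- "double"
  for (j in seq_along(qtl_idx)) {
    het <- which(v[, j] == 1)
    if (length(het)) v[het, j] <- delta[j]
    miss <- which(is.na(v[, j]))
    if (length(miss)) v[miss, j] <- mean(v[, j], na.rm = TRUE)
  }
  genetic <- as.numeric(v %*% a)
  var_g <- stats::var(genetic)
  if (!is.finite(var_g) || var_g <= 0) {
    stop_data("degenerate scenario: realized genetic variance is zero")
  }
  var_e <- var_g * (1 - scenario$h2) / scenario$h2
  e <- stats::rnorm(n, 0, sqrt(var_e))
  yval <- genetic + e
  ph <- data.frame(id = individual_ids(g), trait = yval,
                   stringsAsFactors = FALSE)
  covs <- character(0)
  if (!is.null(scenario$fixed_effects)) {
    for (cv in names(scenario$fixed_effects)) {
      eff <- scenario$fixed_effects[[cv]]
      lev <- sample(names(eff), n, replace = TRUE)
      ph$trait <- ph$trait + as.numeric(eff[lev])
      ph[[cv]] <- lev
      covs <- c(covs, cv)
    }
  }
  g_out <- g
  if (scenario$hidden_qtl) {
    keep <- setdiff(seq_len(m), qtl_idx)
    g_out <- genotype_matrix(g$codes[, keep, drop = FALSE])
  }
  structure(list(
    genotypes = g_out,
    phenotypes = phenotype_table(ph, covariate_cols = covs),
    truth = list(
      # delta is the coded-scale degree; delta_phen orients it phenotypically
      # (a negative effect turns coded dominance into phenotypic recessivity),
      # which is what the dominance-degree estimator targets
      qtl = data.frame(locus = locus_ids(g)[qtl_idx], a = a, delta = delta,
                       delta_phen = ifelse(a >= 0, delta, 2 - delta),
                       stringsAsFactors = FALSE),
      genetic_values = stats::setNames(genetic, individual_ids(g)),
      var_genetic = var_g, var_residual = var_e,
      h2_realized = var_g / stats::var(yval)
    )
  ), class = "sim_dataset")
}

#' Simulate a full dataset from a scenario
#'
#' @param scenario a [sim_scenario()].
#' @return a `sim_dataset` (see [simulate_trait()]).
#' @export
simulate_dataset <- function(scenario) {
  simulate_trait(simulate_genotypes(scenario), scenario)
}
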