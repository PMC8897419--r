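# k-fold cross-validation of genomic predictive ability.
#
# Per replicate the phenotyped individuals are randomly partitioned into k
# folds of near-equal size; each fold in turn is the validation set whose
# phenotypes are masked. The CADM dominance weights, the coded matrix and
# G_ad are recomputed from the training individuals of every fold —
# validation records never touch the weights. AM/ADM reuse the dataset-level
# G and D (genotypes are never masked, only phenotypes; allele frequencies
# therefore default to the full genotyped set). REML is refit per fold and
# model; validation individuals' total genetic values are predicted and
# scored against their held-out corrected phenotypes:
#   r = Pearson correlation (predictive ability),
#   b = OLS slope of phenotype on prediction (1 = unbiased).

#' Build fold plans for repeated k-fold cross-validation
#'
#' @param ids character vector of (phenotyped) individual ids.
#' @param k number of folds (>= 2).
#' @param replicate_seeds one integer seed per replicate; each seed yields a
#'   uniformly random partition into k folds whose sizes differ by at most 1.
#' @return list of fold plans: each is `list(replicate, seed, folds)` with
#'   `folds` a list of k disjoint id vectors covering `ids`.
#' @export
make_folds <- function(ids, k, replicate_seeds) {
  n <- length(ids)
  if (k < 2L) stop_usage("k must be at least 2")
  if (k > n) stop_usage("k exceeds the number of individuals")
  lapply(seq_along(replicate_seeds), function(r) {
    set.seed(replicate_seeds[r])
    perm <- sample(ids)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    folds <- split(perm, rep(seq_len(k), times = sizes))
    names(folds) <- NULL
    list(replicate = r, seed = replicate_seeds[r], folds = folds)
  })
}

#' Predictive ability: correlation of predictions with corrected phenotypes
#'
#' @param pred numeric vector of predicted total genetic values (or a
#'   `genetic_predictions` object, whose `total` column is used).
#' @param y_val corrected phenotypes of the same individuals (matched by
#'   name when both are named).
#' @return Pearson correlation.
#' @export
predictive_ability <- function(pred, y_val) {
  v <- match_pred(pred, y_val)
  if (length(v$p) < 3L) stop_data("need at least 3 validation individuals")
  if (stats::sd(v$p) == 0) stop_numerical("constant predictions: correlation undefined")
  stats::cor(v$p, v$y)
}

#' Prediction bias: regression of corrected phenotype on prediction
#'
#' @inheritParams predictive_ability
#' @return OLS slope; 1 indicates unbiased dispersion.
#' @export
prediction_bias <- function(pred, y_val) {
  v <- match_pred(pred, y_val)
  if (length(v$p) < 3L) stop_data("need at least 3 validation individuals")
  if (stats::var(v$p) == 0) stop_numerical("zero-variance predictions: slope undefined")
  stats::cov(v$p, v$y) / stats::var(v$p)
}

match_pred <- function(pred, y_val) {
  if (inherits(pred, "genetic_predictions")) {
    pred <- stats::setNames(pred$total, pred$id)
  }
  if (!is.null(names(pred)) && !is.null(names(y_val))) {
    ids <- intersect(names(pred), names(y_val))
    list(p = as.numeric(pred[ids]), y = as.numeric(y_val[ids]))
  } else {
    if (length(pred) != length(y_val)) stop_data("prediction/phenotype length mismatch")
    list(p = as.numeric(pred), y = as.numeric(y_val))
  }
}

#' Run the cross-validation protocol
#'
#' @param g a [genotype_matrix()].
#' @param y a `corrected_pheno` vector.
#' @param models subset of `c("CADM", "AM", "ADM")`.
#' @param k folds (default 5).
#' @param replicates number of CV repetitions (default 10).
#' @param seed master seed; fold and bootstrap seeds are derived from it.
#' @param min_class_count,bounds CADM dominance-coding controls (see
#'   [estimate_dominance()]).
#' @param centering relationship-matrix centering (see [build_additive_G()]).
#' @param freq_scope `"all"` (default: allele frequencies from all genotyped
#'   individuals — genotypes are never masked) or `"train"` (per-fold
#'   training-only frequencies).
#' @param reml_options list passed to [reml_fit()] (`max_iter`, `tol`,
#'   `em_warmup`).
#' @param predict_method passed to [gblup_predict()].
#' @param verbose print per-fold progress.
#' @return object of class `cv_result`: list with `folds` (data.frame:
#'   model, replicate, fold, r, bias, converged, n_val), `predictions`
#'   (data.frame: model, replicate, id, pred, y — pooled over folds within a
#'   replicate), `fold_plans`, `models`, `k`, `replicates`, `seed`,
#'   `n_nonconverged`. Non-converged folds are excluded from aggregates for
#'   every model (listwise).
#' @export
run_cv <- function(g, y, models = c("CADM", "AM", "ADM"), k = 5,
                   replicates = 10, seed = 1, min_class_count = 3,
                   bounds = c(0, 2), centering = "coded2",
                   freq_scope = c("all", "train"), reml_options = list(),
                   predict_method = "direct", verbose = FALSE) {
  models <- match.arg(models, c("CADM", "AM", "ADM"), several.ok = TRUE)
  freq_scope <- match.arg(freq_scope)
  al <- align_data(g, y)
  g <- al$g; y <- al$y
  pheno_ids <- names(y)
  if (length(pheno_ids) < k) stop_data("fewer phenotyped individuals than folds")
  plans <- make_folds(pheno_ids, k, derive_seed(seed, seq_len(replicates)))

  freqs_all <- allele_frequencies(g)
  G <- if (any(models %in% c("AM", "ADM")) && freq_scope == "all") {
    build_additive_G(g, freqs_all, centering)
  } else NULL
  D <- if ("ADM" %in% models && freq_scope == "all") {
    build_dominance_D(g, freqs_all)
  } else NULL

  fit_one <- function(spec, y_train, val_ids) {
    fit <- do.call(reml_fit, c(list(y = y_train, spec = spec), reml_options))
    pred <- gblup_predict(y_train, spec, fit, predict_ids = val_ids,
                          method = predict_method)
    list(fit = fit, pred = stats::setNames(pred$total, pred$id))
  }

  fold_rows <- list()
  pred_rows <- list()
  for (plan in plans) {
    for (f in seq_along(plan$folds)) {
      val_ids <- plan$folds[[f]]
      train_ids <- setdiff(pheno_ids, val_ids)
      y_train <- y[train_ids]; class(y_train) <- "corrected_pheno"
      y_val <- y[val_ids]
      freqs <- if (freq_scope == "train") {
        sub <- genotype_matrix(g$codes[train_ids, , drop = FALSE])
        allele_frequencies(sub)
      } else freqs_all
      Gf <- if (any(models %in% c("AM", "ADM")))
        G %||% build_additive_G(g, freqs, centering) else NULL
      Df <- if ("ADM" %in% models) D %||% build_dominance_D(g, freqs) else NULL
      res <- list()
      for (mod in models) {
        spec <- switch(mod,
          AM = model_spec("AM", list(g = Gf)),
          ADM = model_spec("ADM", list(a = Gf, d = Df)),
          CADM = {
            coding <- dominance_coding(g, y, subset = train_ids,
                                       min_class_count = min_class_count,
                                       bounds = bounds)
            model_spec("CADM", list(g = cadm_grm(g, coding, freqs, centering)))
          })
        res[[mod]] <- fit_one(spec, y_train, val_ids)
      }
      all_conv <- all(vapply(res, function(x) x$fit$converged, logical(1)))
      for (mod in models) {
        pr <- res[[mod]]$pred
        r <- tryCatch(predictive_ability(pr, y_val), error = function(e) NA_real_)
        b <- tryCatch(prediction_bias(pr, y_val), error = function(e) NA_real_)
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          model = mod, replicate = plan$replicate, fold = f,
          r = r, bias = b, converged = all_conv && is.finite(r),
          n_val = length(val_ids), stringsAsFactors = FALSE)
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          model = mod, replicate = plan$replicate, id = val_ids,
          pred = as.numeric(pr[val_ids]), y = as.numeric(y_val),
          stringsAsFactors = FALSE)
      }
      if (verbose) message(sprintf("replicate %d fold %d done", plan$replicate, f))
    }
  }
  folds <- do.call(rbind, fold_rows)
  # listwise exclusion: a fold dropped for one model is dropped for all
  bad <- unique(folds[!folds$converged, c("replicate", "fold")])
  if (nrow(bad)) {
    drop <- interaction(folds$replicate, folds$fold) %in%
      interaction(bad$replicate, bad$fold)
    folds$converged[drop] <- FALSE
  }
  structure(list(folds = folds, predictions = do.call(rbind, pred_rows),
                 fold_plans = plans, models = models, k = k,
                 replicates = replicates, seed = seed,
                 n_nonconverged = nrow(bad)),
            class = "cv_result")
}

#' Aggregate cross-validation results
#'
#' Mean and standard error of the per-fold predictive abilities (SE =
#' sd / sqrt(number of converged folds)) and the mean bias, per model.
#'
#' @param cv a `cv_result`.
#' @return data.frame: model, mean_r, se_r, mean_bias, n_folds.
#' @export
aggregate_cv <- function(cv) {
  ok <- cv$folds[cv$folds$converged, ]
  do.call(rbind, lapply(split(ok, ok$model), function(d) {
    data.frame(model = d$model[1], mean_r = mean(d$r),
               se_r = stats::sd(d$r) / sqrt(nrow(d)),
               mean_bias = mean(d$bias), n_folds = nrow(d),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d replicate(s), models %s\n",
              x$k, x$replicates, paste(x$models, collapse = ", ")))
  print(aggregate_cv(x), row.names = FALSE)
  invisible(x)
}

#' Bootstrap comparison of model predictive abilities
#'
#' For each model pair, validation individuals are resampled with
#' replacement (paired: the same resampled individuals for both models of a
#' pair), the pooled-within-replicate correlation difference is recomputed
#' and averaged across replicates, and a two-sided bootstrap p-value
#' `2 * min(P(diff <= 0), P(diff >= 0))` is formed. P-values are
#' Bonferroni-adjusted across the number of pairs; models then receive
#' compact significance letters (models sharing a letter do not differ at
#' the adjusted alpha).
#'
#' @param cv a `cv_result` from [run_cv()] (all models share fold plans by
#'   construction).
#' @param n_boot bootstrap resamples (default 10000; < 100 warns).
#' @param alpha significance level after adjustment (default 0.01, matching
#'   the P < 0.01 letter convention).
#' @param seed RNG seed for the resampling.
#' @return list with `pairs` (data.frame: model1, model2, diff, p, p_adj),
#'   `letters` (named character vector, best model first), `alpha`.
#' @export
bootstrap_compare <- function(cv, n_boot = 10000, alpha = 0.01, seed = 1) {
  models <- cv$models
  if (length(models) < 2L) stop_usage("need at least 2 models to compare")
  if (n_boot < 100) warning("n_boot < 100: p-values will be unstable")
  preds <- cv$predictions
  reps <- sort(unique(preds$replicate))
  # per replicate, an id-aligned matrix of predictions per model plus y
  aligned <- lapply(reps, function(r) {
    d <- preds[preds$replicate == r, ]
    ids <- sort(unique(d$id))
    pm <- vapply(models, function(m) {
      dm <- d[d$model == m, ]
      as.numeric(dm$pred[match(ids, dm$id)])
    }, numeric(length(ids)))
    yy <- d$y[d$model == models[1]][match(ids, d$id[d$model == models[1]])]
    if (anyNA(pm) || anyNA(yy)) stop_data("mismatched fold plans across models")
    list(pm = pm, y = yy, n = length(ids))
  })
  pairs <- utils::combn(models, 2, simplify = FALSE)
  set.seed(seed)
  pair_rows <- lapply(pairs, function(pr) {
    m1 <- pr[1]; m2 <- pr[2]
    obs <- mean(vapply(aligned, function(a)
      stats::cor(a$pm[, m1], a$y) - stats::cor(a$pm[, m2], a$y), numeric(1)))
    diffs <- vapply(seq_len(n_boot), function(b) {
      mean(vapply(aligned, function(a) {
        idx <- sample.int(a$n, a$n, replace = TRUE)
        p1 <- a$pm[idx, m1]; p2 <- a$pm[idx, m2]; yy <- a$y[idx]
        if (stats::sd(p1) == 0 || stats::sd(p2) == 0 || stats::sd(yy) == 0) return(0)
        stats::cor(p1, yy) - stats::cor(p2, yy)
      }, numeric(1)))
    }, numeric(1))
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    data.frame(model1 = m1, model2 = m2, diff = obs,
               p = min(p, 1), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, pair_rows)
  tab$p_adj <- pmin(tab$p * nrow(tab), 1)
  means <- vapply(models, function(m)
    mean(vapply(aligned, function(a) stats::cor(a$pm[, m], a$y), numeric(1))),
    numeric(1))
  list(pairs = tab, letters = letter_groups(models, tab, means, alpha),
       alpha = alpha)
}

# Compact letter display: models ordered by mean performance; letters are the
# maximal cliques of the "not significantly different" graph (brute force,
# fine for the handful of models compared here).
letter_groups <- function(models, pairs, means, alpha) {
  ord <- names(sort(means, decreasing = TRUE))
  M <- length(ord)
  ns <- matrix(TRUE, M, M, dimnames = list(ord, ord))
  for (i in seq_len(nrow(pairs))) {
    sig <- pairs$p_adj[i] < alpha
    ns[pairs$model1[i], pairs$model2[i]] <- !sig
    ns[pairs$model2[i], pairs$model1[i]] <- !sig
  }
  subsets <- list()
  for (sz in M:1) {
    for (cmb in utils::combn(M, sz, simplify = FALSE)) {
      if (all(ns[cmb, cmb])) subsets[[length(subsets) + 1L]] <- cmb
    }
  }
  # keep maximal cliques only
  cliques <- Filter(function(s) !any(vapply(subsets, function(t)
    length(t) > length(s) && all(s %in% t), logical(1))), subsets)
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  lab <- stats::setNames(rep("", M), ord)
  for (i in seq_along(cliques)) {
    lab[cliques[[i]]] <- paste0(lab[cliques[[i]]], LETTERS[i])
  }
  lab[models]
}
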