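# AI-REML variance estimation and GBLUP prediction

res_only <- function() model_spec("residual_only", list())

test_that("residual-only REML equals the n-1 sample variance", {
  y <- cp(c(1, 2, 3))
  fit <- reml_fit(y, res_only(), min_n = 3)
  expect_equal(unname(fit$components["residual"]), 1.0, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("reml_loglik matches the closed form for the iid model", {
  y <- cp(c(1, 2, 3))
  n <- 3
  ll <- reml_loglik(y, res_only(), components = 1.0)
  expect_equal(ll, -0.5 * ((n - 1) * log(1) + log(n) + 2), tolerance = 1e-12)
  # translation invariance of REML
  y2 <- cp(c(1, 2, 3) + 17.3)
  expect_equal(reml_loglik(y2, res_only(), 1.0), ll, tolerance = 1e-10)
  expect_error(reml_loglik(y, res_only(), c(1, 1)), "length|residual")
})

test_that("the fitted optimum dominates perturbed component vectors", {
  sc <- sim_scenario(n_individuals = 150, n_loci = 300, n_qtl = 30,
                     h2 = 0.5, seed = 101)
  ds <- simulate_dataset(sc)
  y <- correct_fixed_effects(ds$phenotypes)
  spec <- model_spec("AM", list(g = build_additive_G(ds$genotypes)))
  fit <- reml_fit(y, spec)
  ll_opt <- reml_loglik(y, spec, fit$components)
  expect_equal(ll_opt, fit$loglik, tolerance = 1e-6)
  for (f1 in c(0.9, 1.1)) for (f2 in c(0.9, 1.1)) {
    expect_gte(ll_opt, reml_loglik(y, spec, fit$components * c(f1, f2)))
  }
})

test_that("eigen and general likelihood paths agree", {
  sc <- sim_scenario(n_individuals = 80, n_loci = 200, n_qtl = 20,
                     h2 = 0.4, seed = 103)
  ds <- simulate_dataset(sc)
  y <- correct_fixed_effects(ds$phenotypes)
  G <- build_additive_G(ds$genotypes)
  spec <- model_spec("AM", list(g = G))
  fit <- reml_fit(y, spec)               # eigen path (1 component)
  theta <- unname(fit$components)
  expect_equal(reml_loglik(y, spec, theta), fit$loglik, tolerance = 1e-8)
})

test_that("monotone convergence: log-likelihood never decreases", {
  for (seed in c(107, 109)) {
    sc <- sim_scenario(n_individuals = 120, n_loci = 250, n_qtl = 25,
                       h2 = 0.35, seed = seed)
    ds <- simulate_dataset(sc)
    y <- correct_fixed_effects(ds$phenotypes)
    G <- build_additive_G(ds$genotypes)
    D <- build_dominance_D(ds$genotypes)
    for (spec in list(model_spec("AM", list(g = G)),
                      model_spec("ADM", list(a = G, d = D)))) {
      fit <- reml_fit(y, spec)
      expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    }
  }
})

test_that("G = identity with equal true components is flagged as degenerate", {
  set.seed(113)
  n <- 60
  ids <- sprintf("I%03d", 1:n)
  G <- structure(diag(n), dimnames = list(ids, ids), kind = "G_additive",
                 denominator = 1, ridge_added = 0,
                 class = c("grm", "matrix", "array"))
  y <- cp(rnorm(n, 0, sqrt(2)), ids)
  fit <- reml_fit(y, model_spec("AM", list(g = G)))
  # V = (sg + se) I: only the sum is identifiable; the fit must signal a
  # boundary hit or singular average-information matrix, and still place the
  # total variance near var(y)
  expect_true(fit$ai_singular || any(fit$pinned))
  expect_equal(sum(fit$components), var(unclass(y)), tolerance = 0.3)
})

test_that("AI-REML matches a multi-stage grid search of the log-likelihood", {
  # oracle: maximize reml_loglik over a coarse-to-fine grid ending at step
  # 0.001 * V_P per component; the fit must agree within one fine step
  sc <- sim_scenario(n_individuals = 150, n_loci = 300, n_qtl = 30,
                     h2 = 0.5, seed = 127)
  ds <- simulate_dataset(sc)
  y <- correct_fixed_effects(ds$phenotypes)
  spec <- model_spec("AM", list(g = build_additive_G(ds$genotypes)))
  fit <- reml_fit(y, spec)
  VP <- var(unclass(y))
  grid_opt <- grid_search_reml(y, spec, VP, step_frac = 0.001)
  expect_lt(abs(fit$components[1] - grid_opt[1]), 0.001 * VP + 1e-9)
  expect_lt(abs(fit$components[2] - grid_opt[2]), 0.001 * VP + 1e-9)
})

test_that("boundary pinning: pure-noise data pins the genetic component", {
  set.seed(131)
  g <- random_gm(150, 100, seed = 131)
  y <- cp(rnorm(150), rownames(g$codes))
  # anti-signal: phenotype independent of genotype, n >> 0
  fit <- reml_fit(y, model_spec("AM", list(g = build_additive_G(g))))
  expect_lt(fit$proportions["g"], 0.15)
})

test_that("MME and direct BLUP routes agree to 1e-8 on small instances", {
  for (seed in c(137, 139)) {
    sc <- sim_scenario(n_individuals = 40, n_loci = 120, n_qtl = 15,
                       h2 = 0.5, seed = seed)
    ds <- simulate_dataset(sc)
    y_all <- correct_fixed_effects(ds$phenotypes)
    y_train <- y_all[1:30]; class(y_train) <- "corrected_pheno"
    G <- build_additive_G(ds$genotypes)
    D <- build_dominance_D(ds$genotypes)
    for (spec in list(model_spec("AM", list(g = G)),
                      model_spec("ADM", list(a = G, d = D)))) {
      fit <- reml_fit(y_train, spec)
      p1 <- gblup_predict(y_train, spec, fit, method = "direct")
      p2 <- gblup_predict(y_train, spec, fit, method = "mme")
      scale <- max(abs(p1$total), 1)
      expect_lt(max(abs(p1$total - p2$total)) / scale, 1e-8)
    }
  }
})

test_that("direct BLUP equals the explicit V-inverse formula", {
  sc <- sim_scenario(n_individuals = 30, n_loci = 100, n_qtl = 10,
                     h2 = 0.5, seed = 149)
  ds <- simulate_dataset(sc)
  y <- correct_fixed_effects(ds$phenotypes)
  G <- build_additive_G(ds$genotypes)
  spec <- model_spec("AM", list(g = G))
  fit <- reml_fit(y, spec)
  pred <- gblup_predict(y, spec, fit)
  # oracle written out longhand
  sg <- fit$components[["g"]]; se <- fit$components[["residual"]]
  ids <- rownames(G)
  V <- sg * unclass(G) + se * diag(30)
  Vi <- solve(V)
  X <- matrix(1, 30)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% unclass(y)[ids])
  ghat <- sg * unclass(G) %*% Vi %*% (unclass(y)[ids] - as.numeric(beta))
  expect_equal(pred$total, as.numeric(ghat), tolerance = 1e-8)
})

test_that("near-zero genetic variance shrinks predictions to zero", {
  sc <- sim_scenario(n_individuals = 30, n_loci = 80, n_qtl = 10,
                     h2 = 0.5, seed = 151)
  ds <- simulate_dataset(sc)
  y <- correct_fixed_effects(ds$phenotypes)
  spec <- model_spec("AM", list(g = build_additive_G(ds$genotypes)))
  p <- gblup_predict(y, spec, c(1e-12, 1))
  expect_lt(max(abs(p$total)), 1e-6)
  p0 <- gblup_predict(y, spec, c(0, 1), method = "mme")
  expect_equal(p0$total, rep(0, 30))
})

test_that("unphenotyped duplicate receives its twin's prediction", {
  g <- random_gm(20, 60, seed = 157)
  codes <- g$codes
  codes[20, ] <- codes[1, ]  # individual 20 is a genetic copy of 1
  g2 <- genotype_matrix(codes)
  set.seed(157)
  y <- cp(rnorm(19), rownames(codes)[1:19])  # 20 is unphenotyped
  G <- build_additive_G(g2)
  spec <- model_spec("AM", list(g = G))
  fit <- reml_fit(y, spec)
  pred <- gblup_predict(y, spec, fit)
  expect_equal(pred$total[pred$id == rownames(codes)[20]],
               pred$total[pred$id == rownames(codes)[1]], tolerance = 1e-6)
  expect_error(gblup_predict(y, spec, fit, predict_ids = "GHOST"), "not in")
})

test_that("fit report JSON captures components and trace", {
  sc <- sim_scenario(n_individuals = 50, n_loci = 100, n_qtl = 10, seed = 163)
  ds <- simulate_dataset(sc)
  y <- correct_fixed_effects(ds$phenotypes)
  fit <- reml_fit(y, model_spec("AM", list(g = build_additive_G(ds$genotypes))))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$components$residual, fit$components[["residual"]],
               tolerance = 1e-12)
  expect_equal(length(rep$loglik_trace), length(fit$loglik_trace))
})
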