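# AI-REML variance-component estimation for GBLUP models
#   y = 1 mu + sum_k Z g_k + e,   g_k ~ N(0, R_k sigma_k^2),  e ~ N(0, I sigma_e^2)
# with R_k a genomic relationship matrix. One genetic component for the AM
# (R = G) and CADM (R = G_ad) models, two (G then D) for ADM.
#
# The REML log-likelihood (additive constants dropped, identical across
# evaluations so comparisons are valid) is
#   ll = -1/2 [ log|V| + log|X'V^-1 X| + y'Py ],
# V = sum_k sigma_k^2 R_k + sigma_e^2 I, P the REML projection matrix.
# Updates: EM-REML warm-up steps (guaranteed uphill, robust far from the
# optimum), then average-information quasi-Newton steps with step-halving
# whenever the log-likelihood would decrease; components are clamped at a
# small positive lower bound (1e-8 * phenotypic variance) and treated as
# pinned (zero) when the score keeps pushing them below it.
#
# Single-component models use an eigendecomposition of R so every iteration
# costs O(n); the multi-component path is Cholesky-based.

#' Define a GBLUP model shape
#'
#' @param name model label: `"CADM"`, `"AM"`, `"ADM"` or any custom string.
#' @param matrices list of `grm` objects (1 for AM/CADM, 2 = list(G, D) for
#'   ADM), all with identical individual ids in identical order.
#' @param component_names names for the genetic components; defaults to the
#'   list names, else `"g"` for one matrix or `c("a", "d")` for two.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, matrices, component_names = names(matrices)) {
  if (length(matrices) == 0 && !identical(name, "residual_only")) {
    matrices <- list()
  }
  if (length(matrices)) {
    ids <- rownames(matrices[[1]])
    for (m in matrices) {
      if (!identical(rownames(m), ids)) {
        stop_data("relationship matrices must share the same individual ordering")
      }
    }
  } else {
    ids <- NULL
  }
  if (is.null(component_names) || any(!nzchar(component_names))) {
    component_names <- if (length(matrices) == 1) "g"
    else if (length(matrices) == 2) c("a", "d")
    else if (length(matrices)) paste0("g", seq_along(matrices))
    else character(0)
  }
  names(matrices) <- component_names
  structure(list(name = name, matrices = matrices, ids = ids),
            class = "model_spec")
}

# ---- likelihood evaluators ------------------------------------------------
# Each returns list(ok, ll, score, AI, trPR, yPRPy) over the parameter vector
# theta = (genetic components..., residual).

reml_eval_general <- function(theta, Rsub, yv) {
  n <- length(yv)
  K <- length(Rsub)
  V <- diag(theta[K + 1], n)
  for (k in seq_len(K)) V <- V + theta[k] * Rsub[[k]]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(list(ok = FALSE))
  ldV <- 2 * sum(log(diag(cV)))
  Vi <- chol2inv(cV)
  vx <- rowSums(Vi)                      # V^-1 X for X = 1
  xtvix <- sum(vx)
  if (xtvix <= 0) return(list(ok = FALSE))
  Viy <- as.numeric(Vi %*% yv)
  b <- sum(vx * yv) / xtvix
  Py <- Viy - vx * b
  ll <- -0.5 * (ldV + log(xtvix) + sum(yv * Py))
  P <- Vi - tcrossprod(vx) / xtvix
  np <- K + 1
  trPR <- numeric(np); yPRPy <- numeric(np)
  w <- vector("list", np)
  for (k in seq_len(K)) {
    trPR[k] <- sum(P * Rsub[[k]])        # tr(P R_k), both symmetric
    w[[k]] <- as.numeric(Rsub[[k]] %*% Py)
    yPRPy[k] <- sum(Py * w[[k]])
  }
  trPR[np] <- sum(diag(P))
  w[[np]] <- Py
  yPRPy[np] <- sum(Py * Py)
  AI <- matrix(0, np, np)
  for (l in seq_len(np)) {
    Pw <- as.numeric(Vi %*% w[[l]]) - vx * (sum(vx * w[[l]]) / xtvix)
    for (k in seq_len(l)) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(w[[k]] * Pw)
    }
  }
  list(ok = TRUE, ll = ll, score = -0.5 * (trPR - yPRPy), AI = AI,
       trPR = trPR, yPRPy = yPRPy)
}

reml_eval_eigen_factory <- function(R, yv) {
  eig <- eigen(R, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  yt <- as.numeric(crossprod(eig$vectors, yv))
  a <- as.numeric(crossprod(eig$vectors, rep(1, length(yv))))
  function(theta) {
    dv <- theta[1] * lam + theta[2]
    if (any(dv <= 0)) return(list(ok = FALSE))
    xv <- a / dv
    xtvix <- sum(a * xv)
    if (xtvix <= 0) return(list(ok = FALSE))
    b <- sum(xv * yt) / xtvix
    Py <- yt / dv - xv * b
    ll <- -0.5 * (sum(log(dv)) + log(xtvix) + sum(yt * Py))
    trPR <- c(sum(lam / dv) - sum(a^2 * lam / dv^2) / xtvix,
              sum(1 / dv) - sum(a^2 / dv^2) / xtvix)
    w <- list(lam * Py, Py)
    yPRPy <- c(sum(Py * w[[1]]), sum(Py * Py))
    Pw <- lapply(w, function(wk) wk / dv - xv * (sum(a * wk / dv) / xtvix))
    AI <- matrix(0, 2, 2)
    for (l in 1:2) for (k in 1:l) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(w[[k]] * Pw[[l]])
    }
    list(ok = TRUE, ll = ll, score = -0.5 * (trPR - yPRPy), AI = AI,
         trPR = trPR, yPRPy = yPRPy)
  }
}

#' REML log-likelihood at given variance components
#'
#' Evaluates `-1/2 [log|V| + log|X'V^-1 X| + y'Py]` (additive constants such
#' as `-(n-1)/2 log(2 pi)` are omitted; they are identical across
#' evaluations of the same data, so comparisons, grid searches and
#' convergence checks remain valid).
#'
#' @param y `corrected_pheno` vector (or named numeric).
#' @param spec a [model_spec()].
#' @param components variance vector: one value per genetic matrix, then the
#'   residual variance (all non-negative; the implied V must be positive
#'   definite).
#' @return scalar log-likelihood.
#' @export
reml_loglik <- function(y, spec, components) {
  dat <- reml_training_data(y, spec)
  if (length(components) != length(dat$Rsub) + 1L) {
    stop_usage("components must have one entry per genetic matrix plus residual")
  }
  ev <- reml_eval_general(components, dat$Rsub, dat$yv)
  if (!ev$ok) stop_numerical("V is not positive definite at these components")
  ev$ll
}

reml_training_data <- function(y, spec, min_n = 2L) {
  yv0 <- stats::setNames(as.numeric(y), names(y))
  if (length(spec$matrices)) {
    train <- intersect(spec$ids, names(yv0))
    if (length(train) < min_n) stop_data("too few phenotyped individuals in the matrices")
    Rsub <- lapply(spec$matrices, function(m) unclass(m)[train, train, drop = FALSE])
  } else {
    train <- names(yv0)
    Rsub <- list()
  }
  list(train = train, yv = as.numeric(yv0[train]), Rsub = Rsub)
}

#' Fit variance components by AI-REML
#'
#' @param y `corrected_pheno` vector; only individuals present in the model's
#'   relationship matrices are used.
#' @param spec a [model_spec()].
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on the maximum relative parameter change
#'   (default 1e-8); iteration also stops when the log-likelihood changes by
#'   less than 1e-9.
#' @param em_warmup number of initial EM-REML steps (default 3).
#' @param start optional starting variance vector (genetic components then
#'   residual); defaults to an equal split of half the phenotypic variance
#'   across genetic components with the other half residual.
#' @param min_n minimum number of phenotyped individuals (default 10).
#' @param verbose print the likelihood trace.
#' @return object of class `reml_fit` with elements `components` (named,
#'   residual last), `proportions` (components / their sum), `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `pinned` (logical vector),
#'   `gradient`, `ai_singular`, `n`, `V_P` (sum of components), `model`,
#'   `train_ids`.
#' @export
reml_fit <- function(y, spec, max_iter = 200, tol = 1e-8, em_warmup = 3,
                     start = NULL, min_n = 10L, verbose = FALSE) {
  dat <- reml_training_data(y, spec, min_n = min_n)
  yv <- dat$yv
  n <- length(yv)
  K <- length(dat$Rsub)
  VP <- stats::var(yv)
  if (!is.finite(VP) || VP <= 0) stop_data("phenotypes have zero variance")
  lb <- 1e-8 * VP
  evalf <- if (K == 1L) reml_eval_eigen_factory(dat$Rsub[[1]], yv)
  else function(theta) reml_eval_general(theta, dat$Rsub, yv)

  theta <- if (!is.null(start)) as.numeric(start)
  else c(rep(0.5 * VP / max(K, 1), K), 0.5 * VP)
  if (length(theta) != K + 1L) stop_usage("start must have length ", K + 1L)
  theta <- pmax(theta, lb)
  ev <- evalf(theta)
  if (!ev$ok) stop_numerical("starting V is not positive definite")
  trace <- ev$ll
  ai_singular <- FALSE
  converged <- FALSE
  iter <- 0L

  em_step <- function(theta, ev) {
    th <- theta + theta^2 * (ev$yPRPy - ev$trPR) / n
    pmax(th, lb)
  }

  for (iter in seq_len(max_iter)) {
    if (iter <= em_warmup) {
      theta_new <- em_step(theta, ev)
      ev_new <- evalf(theta_new)
      # EM-REML is uphill in exact arithmetic; guard numerically by
      # contracting the move toward the current point if needed
      tries <- 0L
      while ((!ev_new$ok || ev_new$ll < ev$ll - 1e-10) && tries < 30L) {
        theta_new <- (theta + theta_new) / 2
        ev_new <- evalf(theta_new)
        tries <- tries + 1L
      }
    } else {
      free <- which(theta > lb * 1.001 | ev$score > 0)
      if (length(free) == 0L) { converged <- TRUE; break }
      AIf <- ev$AI[free, free, drop = FALSE]
      delta <- tryCatch({
        if (rcond(AIf) < 1e-12) NULL else solve(AIf, ev$score[free])
      }, error = function(e) NULL)
      if (is.null(delta)) {
        ai_singular <- TRUE
        theta_new <- em_step(theta, ev)
        ev_new <- evalf(theta_new)
        tries <- 0L
        while ((!ev_new$ok || ev_new$ll < ev$ll - 1e-10) && tries < 30L) {
          theta_new <- (theta + theta_new) / 2
          ev_new <- evalf(theta_new)
          tries <- tries + 1L
        }
      } else {
        step <- 1
        repeat {
          theta_new <- theta
          theta_new[free] <- theta[free] + step * delta
          theta_new <- pmax(theta_new, lb)
          ev_new <- evalf(theta_new)
          if (ev_new$ok && ev_new$ll >= ev$ll - 1e-12) break
          step <- step / 2
          if (step < 1e-10) {             # AI direction hopeless: EM rescue
            theta_new <- em_step(theta, ev)
            ev_new <- evalf(theta_new)
            tries <- 0L
            while ((!ev_new$ok || ev_new$ll < ev$ll - 1e-10) && tries < 30L) {
              theta_new <- (theta + theta_new) / 2
              ev_new <- evalf(theta_new)
              tries <- tries + 1L
            }
            break
          }
        }
      }
    }
    dll <- ev_new$ll - ev$ll
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), lb))
    theta <- theta_new
    ev <- ev_new
    trace <- c(trace, ev$ll)
    if (verbose) message(sprintf("iter %d  ll %.8f  theta %s", iter, ev$ll,
                                 paste(signif(theta, 6), collapse = " ")))
    if (iter > em_warmup && (rel < tol || abs(dll) < 1e-9)) {
      converged <- TRUE
      break
    }
  }
  pinned <- theta <= lb * 1.001 & ev$score < 0
  # gradient check over free components only: a pinned boundary component
  # legitimately keeps a negative score at the constrained optimum
  gnorm <- if (all(pinned)) 0 else max(abs(ev$score[!pinned])) * VP / n
  comp_names <- c(names(dat$Rsub), "residual")
  components <- stats::setNames(ifelse(theta <= lb * 1.001 & pinned, 0, theta),
                                comp_names)
  structure(list(
    components = components,
    proportions = stats::setNames(components / sum(components), comp_names),
    loglik = ev$ll, loglik_trace = trace, iterations = iter,
    converged = converged && gnorm < 1e-2,
    pinned = stats::setNames(pinned, comp_names),
    gradient = stats::setNames(ev$score, comp_names),
    ai_singular = ai_singular, n = n, V_P = sum(components),
    model = spec$name, train_ids = dat$train, lower_bound = lb,
    theta_raw = stats::setNames(theta, comp_names)
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit [%s]: n = %d, loglik = %.4f, %d iteration(s), %s\n",
              x$model, x$n, x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(variance = round(x$components, 6),
                    proportion = round(x$proportions, 4),
                    pinned = x$pinned)
  print(tab)
  invisible(x)
}

#' Write a machine-readable REML fit report
#'
#' @param fit a `reml_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(list(
    model = fit$model, n = fit$n,
    components = as.list(fit$components),
    proportions = as.list(fit$proportions),
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    iterations = fit$iterations, converged = fit$converged,
    pinned = as.list(fit$pinned), ai_singular = fit$ai_singular
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
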