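# GBLUP prediction of genetic values.
#
# Two algebraically equivalent routes are implemented:
#  - "direct": g_hat_k = sigma_k^2 R_k[pred, train] V^-1 (y - X beta_hat),
#    needing only V^-1 on the training records; works for singular R_k.
#  - "mme": Henderson's mixed-model equations with R_k^-1 (ridged minimally
#    via ensure_invertible() when R_k is singular).
# Tests assert their agreement on small instances; "direct" is the default
# because it avoids inverting R_k.

#' Predict genetic values by GBLUP
#'
#' Solves the mixed model at the REML variance estimates and returns
#' per-component and total genetic values for any individuals covered by the
#' relationship matrices, including unphenotyped ones (predicted through
#' their relationship covariances). For ADM the total is `a_hat + d_hat`;
#' for AM/CADM it is `g_hat`. Components pinned at (effectively) zero
#' variance contribute zero.
#'
#' @param y_train `corrected_pheno` vector of training phenotypes.
#' @param spec a [model_spec()].
#' @param estimates a `reml_fit` (or a bare named variance vector, residual
#'   last).
#' @param predict_ids individuals to predict; default all ids in the
#'   matrices.
#' @param method `"direct"` (default) or `"mme"`.
#' @return object of class `genetic_predictions`: data.frame with `id`, one
#'   column per genetic component, and `total`.
#' @export
gblup_predict <- function(y_train, spec, estimates,
                          predict_ids = NULL, method = c("direct", "mme")) {
  method <- match.arg(method)
  theta <- if (inherits(estimates, "reml_fit")) estimates$components
  else as.numeric(estimates)
  K <- length(spec$matrices)
  if (length(theta) != K + 1L) stop_usage("variance vector has wrong length")
  all_ids <- spec$ids
  predict_ids <- predict_ids %||% all_ids
  missing_ids <- setdiff(predict_ids, all_ids)
  if (length(missing_ids)) {
    stop_data("individual(s) not in the relationship matrices: ",
              paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  train <- intersect(all_ids, names(y_train))
  if (length(train) < 2L) stop_data("too few training phenotypes")
  yv <- as.numeric(y_train[train])
  # a residual pinned at (effectively) zero breaks the MME ratio
  # lambda = sig_e / sig_g and can leave the direct route's V singular;
  # floor it at a negligible fraction of the total variance
  tot <- sum(theta)
  if (tot <= 0) stop_numerical("all variance components are zero")
  sig_e <- max(theta[K + 1L], 1e-8 * tot)
  sig_g <- theta[seq_len(K)]
  comp_names <- names(spec$matrices)

  u <- if (method == "direct") {
    predict_direct(spec, train, yv, sig_g, sig_e, predict_ids)
  } else {
    predict_mme(spec, train, yv, sig_g, sig_e, predict_ids)
  }
  colnames(u) <- comp_names
  out <- data.frame(id = predict_ids, u, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$total <- rowSums(u)
  structure(out, class = c("genetic_predictions", "data.frame"),
            method = method)
}

predict_direct <- function(spec, train, yv, sig_g, sig_e, predict_ids) {
  n_t <- length(yv)
  V <- diag(sig_e, n_t)
  Rsub <- lapply(spec$matrices, function(m) unclass(m)[train, train, drop = FALSE])
  for (k in seq_along(Rsub)) V <- V + sig_g[k] * Rsub[[k]]
  cV <- tryCatch(chol(V), error = function(e)
    stop_numerical("training V is not positive definite"))
  Vi <- chol2inv(cV)
  vx <- rowSums(Vi)
  b <- sum(vx * yv) / sum(vx)
  alpha <- as.numeric(Vi %*% (yv - b))
  u <- matrix(0, length(predict_ids), length(spec$matrices))
  for (k in seq_along(spec$matrices)) {
    if (sig_g[k] <= 0) next
    Rpt <- unclass(spec$matrices[[k]])[predict_ids, train, drop = FALSE]
    u[, k] <- sig_g[k] * as.numeric(Rpt %*% alpha)
  }
  u
}

predict_mme <- function(spec, train, yv, sig_g, sig_e, predict_ids) {
  all_ids <- spec$ids
  n_a <- length(all_ids)
  n_t <- length(yv)
  active <- which(sig_g > 1e-12 * (sum(sig_g) + sig_e))
  u <- matrix(0, length(predict_ids), length(spec$matrices))
  if (length(active) == 0L) return(u)
  ti <- match(train, all_ids)
  zty <- numeric(n_a); zty[ti] <- yv            # Z'y
  ztz <- numeric(n_a); ztz[ti] <- 1             # diag(Z'Z)
  xtz <- ztz                                     # X'Z for X = 1
  Ka <- length(active)
  dim_c <- 1L + Ka * n_a
  C <- matrix(0, dim_c, dim_c)
  rhs <- numeric(dim_c)
  C[1, 1] <- n_t
  rhs[1] <- sum(yv)
  blk <- function(k) 1L + (k - 1L) * n_a + seq_len(n_a)
  ZtZ <- diag(ztz, n_a)
  for (k in seq_len(Ka)) {
    ridged <- ensure_invertible(spec$matrices[[active[k]]])
    Kinv <- chol2inv(chol(unclass(ridged)))
    lam <- sig_e / sig_g[active[k]]
    C[1, blk(k)] <- xtz
    C[blk(k), 1] <- xtz
    C[blk(k), blk(k)] <- ZtZ + lam * Kinv
    rhs[blk(k)] <- zty
    if (k > 1) for (l in seq_len(k - 1)) {
      C[blk(k), blk(l)] <- ZtZ
      C[blk(l), blk(k)] <- ZtZ
    }
  }
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop_numerical("singular mixed-model equations"))
  pi_idx <- match(predict_ids, all_ids)
  for (k in seq_len(Ka)) {
    u[, active[k]] <- sol[blk(k)][pi_idx]
  }
  u
}
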