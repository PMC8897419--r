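# Independent oracles used by unit and acceptance tests.

# Coarse-to-fine grid maximization of reml_loglik over (genetic, residual)
# variance pairs; the final stage uses step_frac * V_P, so agreement "within
# one grid step" means within step_frac * V_P per component.
grid_search_reml <- function(y, spec, VP, step_frac = 0.001) {
  f <- function(th) tryCatch(reml_loglik(y, spec, th), error = function(e) -Inf)
  eval_grid <- function(g1, g2) {
    best <- c(NA, NA); best_ll <- -Inf
    for (a in g1) for (b in g2) {
      ll <- f(c(a, b))
      if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
    }
    best
  }
  steps <- c(0.05, 0.01, step_frac) * VP
  lo <- 1e-8 * VP
  best <- eval_grid(seq(lo, 1.5 * VP, by = steps[1]),
                    seq(lo, 1.5 * VP, by = steps[1]))
  for (s in 2:3) {
    prev <- steps[s - 1]
    g1 <- seq(max(lo, best[1] - 2 * prev), best[1] + 2 * prev, by = steps[s])
    g2 <- seq(max(lo, best[2] - 2 * prev), best[2] + 2 * prev, by = steps[s])
    best <- eval_grid(g1, g2)
  }
  best
}
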