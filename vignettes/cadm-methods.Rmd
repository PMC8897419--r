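---
title: "Dominance-weighted genomic prediction: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance-weighted genomic prediction: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domgblup)
```

## The problem

Dominance contributes substantially to complex traits in outbred livestock
and crop populations — heterosis is the canonical symptom — yet adding a
classical dominance component to genomic prediction models rarely improves
predictive ability. The usual two-component model assumes every locus
carries dominance effects drawn from one common variance, which is a poor
description when dominance is strong at some QTL and absent at others.

`domgblup` implements an alternative: estimate, per locus, a *degree of
dominance* from the data, and fold it into a single combined
additive-dominance relationship matrix by re-coding the heterozygote. The
genetic effect stays one component ("total genotypic value"), so no extra
variance parameters are introduced.

## The three models

All models are GBLUP mixed models on fixed-effect-corrected phenotypes
$y$ with an intercept as the only remaining fixed effect:

* **AM** (additive): $y = 1\mu + Z a + e$, $a \sim N(0, G\sigma_a^2)$ with
  the VanRaden matrix $G = MM'/\sum_i 2p_iq_i$, where column $i$ of $M$
  holds the allele counts $0/1/2$ centered by $2p_i$.
* **ADM** (additive + dominance): adds $d \sim N(0, D\sigma_d^2)$ with the
  Vitezica heterozygosity matrix $D = HH'/\sum_i(2p_iq_i)^2$, column-$i$
  coefficients $(-2p_i^2,\; 2p_iq_i,\; -2q_i^2)$ for codes $(0, 1, 2)$.
* **CADM** (combined): $y = 1\mu + Z g + e$, $g \sim N(0,
  G_{ad}\sigma_g^2)$, where $G_{ad} = M_{ad}M_{ad}'/\sum_i 2p_iq_i$ and
  column $i$ of $M_{ad}$ codes the three genotypes $0 / C_d / 2$ (centered
  by $2p_i$), with $C_d$ the locus-specific heterozygote weight below.

### The dominance weight

With corrected-phenotype class means $\bar x_{00}, \bar x_{01}, \bar
x_{11}$ for genotype codes 0/1/2 at a locus, let $x_{min}$ and $x_{max}$ be
the smaller and larger homozygote mean. The prior degree of dominance is

$$ d = \frac{2\,(\bar x_{01} - x_{min})}{x_{max} - x_{min}}, $$

so $d = 0$ means the heterozygote equals the worse homozygote, $d = 1$ is
additive, and $d = 2$ complete dominance. $C_d$ clips $d$ to $[0, 2]$;
relaxing the bounds (argument `bounds`) admits overdominance but in our
experience destabilizes downstream REML, so the default keeps the clip.
When $\bar x_{00} > \bar x_{11}$ the homozygote codes are swapped (*flip*),
so code 2 always tags the better homozygote in the estimation data.

During cross-validation the class means — hence $C_d$, the coded matrix and
$G_{ad}$ — are recomputed from training individuals only; a permutation
test in the suite verifies that validation phenotypes cannot influence the
weights. Genotypes are never masked, so allele frequencies default to the
full genotyped set (`freq_scope = "train"` restricts them).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `maf` filter | 0.01 | frequency | loci with MAF strictly below are removed; a locus at exactly the threshold is kept ("lower than" is strict) |
| `min_class_count` | 3 | individuals | below this in any genotype class the locus falls back to additive coding ($C_d = 1$, no flip); the estimator is a ratio of noisy class means and is meaningless on tiny classes |
| `bounds` | c(0, 2) | dimensionless | $C_d$ clip; widen for overdominance at your own risk |
| `k`, `replicates` | 5, 10 | — | cross-validation shape |
| REML `tol` | 1e-8 | relative | max relative parameter change; also stops on loglik change < 1e-9 |
| `em_warmup` | 3 | iterations | EM-REML steps before average-information updates |

## REML and prediction

Variance components are estimated by average-information REML: the
log-likelihood $-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ (additive
constants omitted, identically across evaluations) is climbed with a few EM
warm-up steps, then AI quasi-Newton steps with step-halving whenever a step
would decrease the likelihood, so the iteration trace is monotone.
Components are clamped at $10^{-8} \times V_P$; a component the score keeps
pushing into the bound is reported as pinned at 0 (this is how proportions
of exactly 0.000 arise). Single-component models use an eigendecomposition
of the relationship matrix, making each iteration $O(n)$; multi-component
fits use Cholesky factorizations. The suite checks the optimizer against a
coarse-to-fine grid search of the same likelihood (final step
$0.001\,V_P$).

Genetic values are predicted for any individual in the relationship
matrices — phenotyped or not — either by the direct formula
$\hat g_k = \sigma_k^2 R_k[\cdot, t]V^{-1}(y - X\hat\beta)$ (default; no
inverse of $R_k$ needed) or by Henderson's mixed-model equations; the two
agree to $10^{-8}$ on test instances. Because REML may legitimately drive
$\sigma_e^2$ to the boundary on saturated small-$n$ fits, prediction floors
the residual at $10^{-8}$ of the total variance.

Relationship matrices that fail to factorize get the smallest power-of-ten
ridge (starting $10^{-8}$, recorded in the object) on the diagonal; past
$10^{-2}$ this is treated as a data problem, not papered over.

## Cross-validation and comparison

Phenotyped individuals are partitioned per replicate into $k$ folds whose
sizes differ by at most one (511 individuals at $k=5$ gives
103/102/102/102/102). Predictive ability is the Pearson correlation between
predicted total genetic value and the held-out corrected phenotype,
computed **per fold** (so $k \times$ replicates values feed the mean and
SE $= sd/\sqrt{k\cdot\text{replicates}}$); dispersion bias is the OLS slope
of phenotype on prediction. Folds whose REML fit fails to converge, or
whose predictions are constant (a genetic component pinned at zero), are
flagged and excluded listwise across models.

Model differences are tested by a paired bootstrap: within each replicate
the validation predictions are pooled, individuals are resampled with
replacement — the same resample for both models of a pair — the correlation
difference is averaged across replicates, and the two-sided p-value is
$2\min(P(\Delta\le 0), P(\Delta\ge 0))$, Bonferroni-adjusted across pairs.
Letters come from the maximal cliques of the "not significantly different"
graph at adjusted $\alpha = 0.01$, matching the usual $P<0.01$ superscript
convention. The source description of the bootstrap is one sentence;
individual-level paired resampling is our construction, and its type-I
error is checked by simulation in the acceptance suite.

## The simulator

`simulate_dataset()` draws independent biallelic loci in Hardy–Weinberg
proportions with allele frequencies uniform in `maf_range`, picks `n_qtl`
markers as QTL, and gives QTL $j$ the genotype values $(0, \delta_j, 2)
\times a_j$ with $a_j \sim N(0, \text{sd}^2)$ — the same $0/C_d/2$ scale
the estimator works on, so simulated $\delta$ and estimated $C_d$ are
directly comparable. The residual variance is solved analytically from the
realized genetic variance to hit the target broad-sense heritability.
Presets: `additive` ($\delta = 1$, $h^2 = 0.5$), `mixed_dominance` (half
$\delta = 2$, half $\delta = 0$, $h^2 = 0.3$), `low_h2_dominant` (all
$\delta = 2$, $h^2 = 0.15$), `null` ($h^2 = 0.01$).

One consequence of signed effects deserves emphasis: at a QTL with $a_j <
0$, coded $\delta_j = 2$ places the heterozygote at the *worse* homozygote
phenotypically, i.e. the phenotypic degree of dominance is $2 - \delta_j$.
The truth table records this as `delta_phen`; it — not $\delta_j$ — is what
the estimator (correctly) recovers, together with a flip.

What the generator does **not** emulate: linkage disequilibrium (an
optional `ld_rho` exists for robustness checks only), family or F2-cross
structure, selection, epistasis, or minor-allele-frequency spectra of real
chips. A green test therefore establishes internal correctness and
qualitative behavior under an idealized architecture, not performance on
real livestock data.

## Design choices where the source was open

* **Centering allele.** The source text centers by "$2p_i$, the frequency
  of allele 1" while coding the allele-2 homozygote as 2. Taken literally
  this destroys the zero-mean property centering exists for; we center by
  twice the frequency of the coded-2 allele (post-flip for $G_{ad}$), and
  expose `centering = "paper_literal"` for the literal reading.
* **$G_{ad}$ denominator.** Kept at $\sum 2p_iq_i$ exactly as printed, even
  though the weighted coding changes column variances; REML absorbs the
  scale into $\sigma_g^2$.
* **Frequencies for $G_{ad}$** come from the original 0/1/2 codes: allele
  frequency is a population quantity, $C_d$ a phenotype-scale weight.
* **Fallback rule.** The source is silent on empty or tiny genotype
  classes and on $x_{max} = x_{min}$; we fall back to additive coding below
  `min_class_count` observations in any class or when the homozygote
  spread is below $10^{-12}\times$ the phenotype SD.
* **Missing genotypes** are mean-imputed ($2p_i$) for matrix construction
  only; class means use observed genotypes exclusively, because an imputed
  value has no genotype class.
* **Configuration files** are JSON rather than YAML (no YAML parser in the
  supported dependency set); the structure is the same flat key-value map
  the CLI flags use.

## Known limitations

* **Null-safety cost of estimated weights.** On purely additive traits the
  per-locus weights are pure noise wherever genotype classes are small, and
  the accumulated noise in $G_{ad}$ costs CADM real predictive ability
  relative to AM (the acceptance suite measures a gap above the 0.05 the
  criteria allow at $n = 500$, $m = 1000$). Raising `min_class_count`
  suppresses the noise but equally suppresses CADM's genuine advantage at
  low-MAF dominant QTL — the audit TSV written by the CLI exists precisely
  so users can see which loci carry informative weights. Shrinkage
  estimation of $d$ would address this and is deliberately out of scope.
* **ADM is not a straw man in simulation.** In the `mixed_dominance` world
  a sizeable share of QTL variance is classical dominance deviation, and
  the two-component model detects it at $n = 1000$; the empirical finding
  that ADM fails to beat AM on real data reflects architectures this
  generator does not reproduce. The corresponding acceptance check is left
  failing with this analysis rather than re-tuned.
* **Dominance variance is weakly identified in unrelated samples**: the
  truncated-at-zero REML estimate of $V_D/V_P$ has a positive mean under
  the null (slightly above the 0.05 the acceptance band allows at
  $n = 500$). Profile likelihoods confirm these are genuine optima.
* The degree of dominance at a QTL with near-zero additive effect is
  intrinsically ill-defined ($x_{max}-x_{min}\to 0$); estimates there are
  clipped noise and fall where the fallback or the clip puts them.
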