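# domgblup

Genomic prediction with **locus-specific dominance weights**: the CADM
model, which folds additive and dominance genetic effects into a single
combined relationship matrix by re-coding each locus's heterozygote with an
estimated degree of dominance, next to the classical additive-only (AM) and
two-component additive + dominance (ADM) GBLUP models.

**Who it is for:** quantitative geneticists and animal/plant breeders who
want to exploit dominance (the genetic basis of heterosis) in genomic
prediction of *total* genetic values — e.g. for mate allocation or
commercial-population performance — without adding variance components that
real datasets rarely support.

## The method

Per locus, with corrected-phenotype means of the three genotype classes
(codes 0/1/2 counting one allele), the prior degree of dominance is

    d = 2 * (x̄_het − x_min) / (x_max − x_min),

where `x_min`/`x_max` are the smaller/larger homozygote means. `d` is
clipped to `[0, 2]` giving the heterozygote weight `C_d` (0 = recessive,
1 = additive, 2 = complete dominance); when the homozygote means are
reversed the homozygote codes are swapped, so code 2 always marks the
better homozygote. The weighted codes `0 / C_d / 2` are then centered and
scaled exactly like a VanRaden additive matrix:

    G_ad = M_ad M_ad' / Σ 2 p_i q_i ,

and one GBLUP component `g ~ N(0, G_ad σ_g²)` carries additive + dominance
signal jointly. Reference models: AM with VanRaden `G`, ADM with `G` plus
the Vitezica dominance matrix `D = HH'/Σ(2p_i q_i)²`. Variance components
come from an AI-REML engine (EM warm-up, step-halving, boundary pinning);
predictions from Henderson's mixed-model equations or the equivalent direct
V⁻¹ formula. A repeated k-fold cross-validation protocol re-estimates the
dominance weights from training individuals only, scores predictive ability
(correlation with held-out corrected phenotypes) and dispersion bias
(regression slope), and compares models by paired bootstrap with Bonferroni
correction and significance letters.

## Worked example

```r
library(domgblup)

# a dominance-rich synthetic dataset: 600 individuals, 1200 SNPs, 40 QTL,
# half completely dominant / half completely recessive, broad-sense h2 0.3
sc <- scenario_presets(n_individuals = 600, n_loci = 1200, n_qtl = 40,
                       seed = 42)$mixed_dominance
ds <- simulate_dataset(sc)
y  <- correct_fixed_effects(ds$phenotypes)

cod <- dominance_coding(ds$genotypes, y)       # per-locus C_d, flip, fallback
fit <- reml_fit(y, model_spec("CADM", list(g = cadm_grm(ds$genotypes, cod))))
fit
#> reml_fit [CADM]: n = 600, loglik = -1454.4460, 10 iteration(s), converged
#>          variance proportion pinned
#> g        33.68306     0.6684  FALSE
#> residual 16.71021     0.3316  FALSE

cv <- run_cv(ds$genotypes, y, models = c("CADM", "AM", "ADM"),
             k = 5, replicates = 3, seed = 7)
cv
#> cv_result: 5-fold x 3 replicate(s), models CADM, AM, ADM
#>  model    mean_r       se_r mean_bias n_folds
#>    ADM 0.1148114 0.01921789 0.9395156      15
#>     AM 0.1073684 0.02206476 1.1698663      15
#>   CADM 0.1261142 0.02223383 0.2602812      15

bootstrap_compare(cv, n_boot = 2000, seed = 8)$pairs
#>   model1 model2        diff     p p_adj
#> 1   CADM     AM  0.04196081 0.031 0.093
#> 2   CADM    ADM  0.02726394 0.101 0.303
#> 3     AM    ADM -0.01469687 0.105 0.315
```

Reading the output: the CADM proportion 0.668 is the share of phenotypic
variance assigned to the *combined* additive + dominance component (note:
`G_ad` built from noisily estimated weights absorbs some weight noise into
this component, so it is not a clean heritability). In cross-validation
CADM's mean predictive ability (0.126) exceeds AM's (0.107) — the direction
the method is designed to deliver on dominance-rich traits — while ADM's
gain over AM is small; at only 3 replicates and n = 600 none of the
bootstrap differences clears the adjusted P < 0.01 bar, so all models share
letter "A". `mean_bias` is the slope of phenotype on prediction (1 =
dispersion-unbiased; CADM's weight noise makes it over-dispersed here).

## Command line

```sh
./exec/domgblup simulate --preset mixed_dominance --n 1000 --m 2000 \
    --seed 1 --out data/
./exec/domgblup fit --genotypes data/genotypes.tsv \
    --phenotypes data/phenotypes.csv --models cadm,am,adm --out fit/
./exec/domgblup cv  --genotypes data/genotypes.tsv \
    --phenotypes data/phenotypes.csv --k 5 --replicates 10 --seed 1 --out cv/
```

`fit` writes per-model variance tables plus `dominance_coding.tsv`, the
audit table of per-locus weights (raw d, C_d, flip, fallback, class
counts). `cv` writes per-fold results, the aggregate table with
significance letters, pairwise bootstrap p-values, and a reproducibility
manifest. Exit codes: 0 ok, 2 usage, 3 data, 4 numerical. A JSON file via
`--config` supplies defaults; explicit flags win.

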