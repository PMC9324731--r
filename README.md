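# cserecall

Metrology for word-list memory tests: Rasch restitution, entropy-based
construct specification equations (CSE), and residual-contrast
multidimensionality diagnostics for serial position effects (SPE).

## Who this is for

Researchers analysing item-level binary recall data from word-list tests —
the canonical case is the 15-word immediate-recall trial of Rey's Auditory
Verbal Learning Test (RAVLT IR) in memory-clinic cohorts spanning healthy
ageing to dementia — who want interval-scale person and item measures with
uncertainties instead of ordinal raw-score proportions, a causal
(entropy-based) account of *why* each word is hard, and a principled check
of whether serial position effects break the unidimensionality their
measures rely on.

## The model

The dichotomous Rasch model separates person ability θ from item difficulty
δ on a common logit scale:

    ln( P / (1 − P) ) = θ_i − δ_j

Item difficulty is then *explained* by Brillouin-entropy variables — more
ordered tasks carry less entropy and are easier. With M = 1/ln(L) for a
list of length L:

    δ_j = δ_j,Pr + 2·δ_j,Mr + δ_j,Rr + δ_j,freq
    δ_j,Pr = −M·ln(j!)        (primacy)
    δ_j,Rr = −M·ln((L−1−j)!)  (recency, argument clipped at 0)
    δ_j,Mr = +M·ln(⌊L/2⌋!)    (constant mid-range term)

A principal component regression of empirical δ on these variables gives
the CSE `z_R = β0 + β_Pr·Primacy + β_Rr·Recency + β_f·Frequency`. Finally,
PCA of standardized Rasch residuals ("contrasts") diagnoses
SPE-induced multidimensionality, and the loading of item j on a contrast is
predicted theoretically by

    L_p,x ∝ a_p,x · Δδ · ∫ p(θ) · ∂P/∂δ dθ,   ∂P/∂δ = −P(1−P)

with a_p,x the explanatory-variable PCA loadings, Δδ the perceived
difficulty distortion, and p(θ) the cohort ability distribution.

## Worked example

The bundled reference table carries the 15 RAVLT IR items: the four
explanatory variables, empirical difficulties δ with k = 2 uncertainties,
and published CSE fitted values.

```r
library(cserecall)
t1 <- load_table1_fixture()

fit_cse(t1$delta, t1$X, U_delta = t1$U_delta)
#> CSE (PCR, 3 components):
#>   z_R = +5(3) +0.7(4)·primacy +0.8(4)·recency +0.2(6)·frequency
#>   Pearson R(delta, z_R) = 0.80, residual sd = 0.70 logits

pca_explanatory(t1$X)
#> PCA of explanatory variables (covariance mode)
#> Eigenvalues: 19.3, 0.696, 0.336
#>             PC1   PC2  PC3
#> primacy    0.77 -0.51 0.38
#> recency   -0.64 -0.60 0.49
#> frequency  0.02  0.62 0.79
```

Reading: the CSE explains 80% (Pearson R = 0.80) of the spread in recall
difficulty from serial position and word frequency alone; the intercept
(+5(3) logits, uncertainties in parentheses at one significant figure,
k = 2) is interpreted as twice the constant mid-range difficulty; the first
principal component is dominated by the primacy/recency pair (r = −0.94),
frequency contributing almost nothing (+0.02).

A fully synthetic cohort (no clinical data ships with the package) runs the
downstream diagnostics end to end — 225 persons shaped like a
memory-clinic cohort (66 HC / 99 SCD / 27 MCI / 33 AD), with a +2 logit
primacy penalty for the impaired groups:

```r
sim <- simulate_cohort(neuromet_like_preset(seed = 3))
fit <- fit_rasch(sim$responses)
y   <- standardized_residuals(sim$responses, fit)
ctr <- residual_contrasts(y, delta = fit$delta)
vd  <- variance_decomposition(sim$responses, fit, ctr)
linacre_checklist(ctr, vd)
#> Multidimensionality checklist:
#>   1. items-explained 15.4% vs first-contrast unexplained 6.5% (ratio 2.4) -> ok
#>   2. first-contrast eigenvalue 1.50 vs threshold 2.0 -> ok
#>   3. 3 clusters, contrast-1 loading spread 0.58 -> FLAG
```

Reading: the item measures explain about twice the variance of the first
residual contrast and its eigenvalue (1.50 items) stays under the ~2-item
chance threshold, but the loading clusters separate clearly — exactly the
mixed picture expected when part of the cohort experiences the
serial-position benefits differently.

## Command line

```sh
inst/cli/cse-recall entropy-vars --length 15 --out vars.csv
inst/cli/cse-recall simulate --preset neuromet --seed 7 --out resp.csv
inst/cli/cse-recall rasch-fit --responses resp.csv --out items.csv
inst/cli/cse-recall reproduce-table1
```

Subcommands: `simulate`, `rasch-fit`, `ctt`, `entropy-vars`, `cse-fit`,
`pca-residuals`, `predict-loadings`, `spe-curves`, `reproduce-table1`.
Every run writes a JSON log with package version, config hash and seed.

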