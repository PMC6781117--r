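# mhcmate

Statistical analysis of MHC-based mate choice in closed breeding
populations.

In many captive or semi-natural breeding programmes — the motivating case
is a crocodilian conservation colony — adults live in physically separated
breeding pools ("ponds"): mating is free within a pond and impossible
across ponds, and parentage analysis of offspring yields the realised
female × male mating pairs. `mhcmate` is for population geneticists and
conservation biologists who want to ask, rigorously: **are those realised
pairs a random draw from the available within-pond combinations, or do
females prefer males with particular genetic properties?**

## What it computes

The package tests the three classic mate-choice hypotheses with the
statistics standard in this literature, each compared against a
pond-stratified Monte-Carlo random-pairing null:

| Hypothesis | Statistics |
|---|---|
| Good genes | carried-allele frequency score *AF* per MHC locus |
| Heterozygosity advantage | mean *d²*, standardised heterozygosity *SH* (microsatellites); heterozygote proportion *Ho* per MHC locus |
| Compatible genes | allele sharing *Nsa*, amino-acid distance *AAdist*, z-descriptor functional distance *AAfunc.dist* per MHC locus |
| Inbreeding avoidance | Queller–Goodnight relatedness *R*<sub>qg</sub> of pairs |

The pair distances are the four-term inter-partner sums
*AAdist = D(A,B) + D(A,b) + D(a,B) + D(a,b)* over the two partners' allele
copies, with *D* either the amino-acid p-distance or the per-site Euclidean
distance in Sandberg z-descriptor space. The null is materialised directly:
within each pond, as many random female × male pairs are drawn (with
replacement) as there are true pairs, the statistic is averaged over the
pooled random pairs, and this is repeated 9999 times; the observed mean is
flagged significant when it falls outside the null's two-tailed 95%
percentile interval, with an empirical p-value reported alongside.

Around that core the package provides:

* individual diversity indices (*SH*, *HL*, *IR*, mean *d²*) with
  brute-force-verified formulas;
* pairwise relatedness: Queller–Goodnight, Wang (2002), Lynch–Ritland
  (1999);
* a Poisson random-intercept model (`lme4`) of male reproductive success
  versus MHC zygosity, with cluster-bootstrap effect bands;
* a Mendelian trio-consistency audit of assigned parentage;
* a synthetic colony generator (founder pedigree, Mendelian offspring,
  tunable softmax female preference) so every stage is testable against
  known ground truth;
* ggplot2 figures: null histograms with observed/CI cutoffs, zygosity
  effect plots; broom-style `tidy()`/`glance()` methods.

## Worked example

```r
library(mhcmate)

ds <- simulate_alligator_dataset(sim_config(seed = 42,
                                            preference = "heterozygote"))
report <- run_mate_choice_pipeline(
  ds$individuals, ds$loci, ds$pairs, ds$alleles,
  clutches = ds$clutches, trios = ds$trios,
  n_iter = 9999, seed = 1)
print(report)
```

```
Mate-choice analysis report
  parentage audit: 1703/1703 trios Mendelian-consistent
  hypothesis tests (9999 Monte-Carlo replicates):
    af           I1327e3   obs =   1.0073  p = 0.8608  CI [0.9853, 1.0330]
    af           I20e2     obs =   1.3193  p = 0.2934  CI [1.2913, 1.4090]
    d2                     obs =   7.0641  p = 0.8202  CI [6.5173, 7.5031]
    sh                     obs =   1.0288  p = 0.2040  CI [0.9775, 1.0384]
    ho           I1327e3   obs =   0.7381  p = 0.0002  CI [0.5000, 0.6170]  *
    ho           I20e2     obs =   0.3810  p = 0.3234  CI [0.2917, 0.4082]
    nsa          I1327e3   obs =   1.4314  p = 0.0488  CI [1.1765, 1.4216]  *
    aa_dist      I1327e3   obs =   0.2667  p = 0.8470  CI [0.2405, 0.2876]
    aa_func_dist I1327e3   obs =   1.6042  p = 0.8556  CI [1.4469, 1.7143]
    nsa          I20e2     obs =   1.5098  p = 0.5264  CI [1.3627, 1.5784]
    aa_dist      I20e2     obs =   0.0444  p = 1.0000  CI [0.0373, 0.0510]
    aa_func_dist I20e2     obs =   0.2460  p = 1.0000  CI [0.2062, 0.2822]
    r_qg                   obs =  -0.0074  p = 0.9816  CI [-0.0483, 0.0350]
  reproductive success: beta_zyg = -0.0644 (Wald p = 0.3865), sigma_u = 0.0000
```

The simulated colony was generated with a strong female preference for
males heterozygous at the first MHC locus (`preference = "heterozygote"`),
and the report recovers exactly that structure: every offspring trio is
Mendelian-consistent (the generator is error-free by construction); *Ho* at
the preference locus I1327e3 is far above its null interval (obs 0.74
against CI [0.50, 0.62], p = 0.0002) while the genome-wide indices *d²* and
*SH*, the second locus, and pair relatedness all stay inside their
intervals — the signature of MHC-targeted, not genome-wide, mate choice.
(Allele sharing at the preference locus is dragged along slightly, as
expected when heterozygous males are over-chosen at a biallelic locus.)
`autoplot(report)` draws the null histograms with observed values and CI
cutoffs; `tidy(report$glmm)` returns the reproductive-success coefficients.

See `vignettes/mate-choice-methods.Rmd` for the full model description,
estimator definitions, conventions, and known limitations.

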