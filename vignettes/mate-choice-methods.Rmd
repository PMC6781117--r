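---
title: "Testing MHC-based mate-choice hypotheses in closed breeding colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing MHC-based mate-choice hypotheses in closed breeding colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In many captive or semi-natural breeding programmes, adults live in closed
breeding pools (here called *ponds*): mating is unrestricted within a pond
and impossible across ponds. Parentage analysis of offspring then yields a
set of realised female × male mating pairs. The scientific question is
whether those realised pairs are a random draw from the available
within-pond combinations, or whether females prefer males with particular
genetic properties. Three classic hypotheses structure the analysis:

* **good genes** — females prefer males carrying particular (e.g. common or
  rare) MHC alleles;
* **heterozygosity advantage** — females prefer heterozygous males, either
  genome-wide (microsatellite heterozygosity) or specifically at MHC loci;
* **compatible genes** — females prefer males whose MHC alleles are
  *dissimilar from their own*, maximising offspring MHC diversity.

`mhcmate` implements the complete statistical machinery for this design:
per-individual diversity indices, pair-level MHC compatibility measures,
pairwise relatedness, a pond-stratified Monte-Carlo randomisation test, a
Poisson random-intercept model of male reproductive success, a Mendelian
trio audit, and a synthetic colony generator with known ground truth.

## Statistics

### Individual indices (male side)

For an individual typed at $N$ microsatellite loci, with reference allele
frequencies $p_{\ell k}$ estimated by gene counting from all adults:

* **Standardised heterozygosity** $SH = \frac{\text{prop. heterozygous
  loci}}{\overline{H_o}}$, where $\overline{H_o}$ is the mean observed
  heterozygosity, in the reference population, of exactly the loci the
  individual is typed at. Its population mean over fully typed individuals
  is 1 by construction.
* **Heterozygosity by locus** $HL = \frac{\sum_h E_h}{\sum_h E_h + \sum_j
  E_j}$ with $E_\ell = 1 - \sum_k p_{\ell k}^2$ the locus's expected
  heterozygosity, $h$ running over the individual's homozygous and $j$ over
  its heterozygous typed loci. 0 = fully heterozygous, 1 = fully
  homozygous.
* **Internal relatedness** $IR = \frac{2H - \sum_i f_i}{2N - \sum_i f_i}$,
  with $H$ the number of homozygous loci and $f_i$ the reference frequency
  of each of the $2N$ carried allele copies.
* **Mean d²** $= \frac1N \sum_\ell \delta_\ell^2$, the mean squared
  difference between the individual's two allele lengths. By default
  $\delta_\ell$ is expressed in repeat units (base-pair difference divided
  by the locus's motif length); `d2_unit = "bp"` switches to raw base
  pairs. The unit is a genuine convention choice — allele-size differences
  are only comparable across loci after dividing by motif length, which is
  why repeat units are the default — and is recorded in the output.
* **MHC heterozygosity** $H_o$: the proportion of heterozygous males among
  the *unique* breeding males at one MHC locus. Counting each male once
  (rather than once per pair) is the convention used for the observed
  value; the randomisation null uses the same basis (see below).
* **Carried-allele frequency score** $AF$: the sum of the reference
  frequencies of a male's two allele copies at an MHC locus, so a
  homozygote for an allele at frequency $p$ scores $2p$ and the score lies
  in $(0, 2]$. This is the good-gene statistic; note it is a *score*, not a
  frequency, which is why values above 1 are expected for common-allele
  homozygotes and heterozygotes.

### Pair statistics (compatible-gene side)

For a female with alleles $\{A, a\}$ and a male with $\{B, b\}$ at one MHC
locus:

* **Allele sharing** $N_{sa} \in \{0, 1, 2\}$: the size of a maximum
  matching between the two 2-copy multisets.
* **Amino-acid distance** $AA_{dist} = D_{AB} + D_{Ab} + D_{aB} + D_{ab}$,
  the sum of the four inter-partner allele distances, where $D$ is the
  p-distance (proportion of differing aligned residues; a Poisson-corrected
  $-\log(1-p)$ variant is available) between the translated exon fragments.
* **Functional distance** $AA_{func.dist}$: the same four-term sum with $D$
  replaced by the per-site mean Euclidean distance between the residues'
  five z-descriptor vectors (principal-component summaries of amino-acid
  physiochemical properties). The per-site *mean* (rather than sum) puts
  loci with different exon lengths on one scale; `normalize = FALSE`
  recovers the summed variant. Distances are computed per locus — each MHC
  locus is tested separately.

Both distances are symmetric in the partners and zero exactly when every
female allele is identical in sequence to every male allele.

### Pairwise relatedness

Three moment estimators from microsatellite genotypes, all symmetrised over
the choice of focal individual and all using reference frequencies that
include the focal dyad (the common default of coancestry software; a
leave-out correction is deliberately not applied):

* **Queller–Goodnight** (primary): per locus, numerator
  $\tfrac12(I_{ac}+I_{ad}+I_{bc}+I_{bd}) - p_a - p_b$ and denominator
  $1 + I_{ab} - p_a - p_b$; numerators and denominators are summed over
  loci before dividing, and the two focal directions are averaged.
* **Wang (2002)**: the joint-genotype-category moment estimator. Each locus
  contributes an indicator of which similarity category the two genotypes
  fall in (identical; one homozygote sharing an allele; two heterozygotes
  sharing one allele; no sharing). With $a_m = \sum_k p_k^m$, the category
  probabilities are linear in the one- and two-pair IBD coefficients
  $(\phi, \Delta)$ with coefficients
  $b = 2a_2^2 - a_4$, $c = a_2 - b$, $d = 4(a_3 - a_4)$,
  $e = 2(a_2 - 3a_3 + 2a_4)$, $f = 4(a_2 - a_2^2 - 2a_3 + 2a_4)$,
  $g = 1 - 7a_2 + 4a_2^2 + 10a_3 - 8a_4$ — a linear system this package
  re-derived from the IBD conditional distributions and solves by
  least squares after the customary $1/u$ locus weighting
  ($u = 2a_2 - a_3$), giving $\hat r = \hat\phi/2 + \hat\Delta$. The
  least-squares solution is linear in the category indicators, so the
  estimator inherits the moment estimator's unbiasedness; it is validated
  against pedigree simulations (identical ≈ 1, parent–offspring ≈ 0.5,
  unrelated ≈ 0) rather than against the original closed-form expression.
* **Lynch–Ritland (1999)**: the regression estimator with the source's
  locus weights $W_\ell = \big[(1+S_{ab})(p_a+p_b) - 4p_ap_b\big] /
  (2p_ap_b)$, averaged over the two focal directions.

Loci untyped in either member are dropped pairwise; loci monomorphic in the
reference carry no information and are skipped. A dyad with no informative
locus is flagged `NA`, never silently zero.

## The randomisation test

The null hypothesis of random mating is materialised directly: within each
pond, draw as many random female × male pairs — uniformly, with
replacement, from that pond's candidates — as there are true mating pairs;
pool the random pairs across ponds; average the statistic; repeat
`n_iter = 9999` times. The observed mean is compared with this null sample
two ways:

* the **decision rule**: observed significant iff outside the null's
  2.5–97.5 percentile interval (two-tailed 95% CI);
* an **empirical p-value** $p = \min\!\big(1,\, 2\min(n_{\le}+1,
  n_{\ge}+1)/(n_{iter}+1)\big)$, reported alongside (the $+1$ correction
  means $p$ is never exactly zero).

Conventions, each chosen once and applied throughout:

* True pairs are de-duplicated to unique female × male pairs (a pair
  observed in several clutches counts once).
* Male-mode statistics ($AF$, $d^2$, $SH$) are evaluated on the male of
  each pair, observed and null alike, so males are weighted by how many
  distinct partners they had. $H_o$ instead uses the unique-male basis on
  both sides. Using the *same* basis for observed and null is what keeps
  the test exchangeable — and hence calibrated — under random mating.
* Candidates default to all adults of the pond (`candidates =
  "breeding-only"` restricts to adults appearing in the pair table).
* No multiple-testing correction is applied; the suite reports the number
  of tests so readers can apply their own.
* Reproducibility: all replicate indices are drawn in one seeded block
  arranged so that replicate $r$ consumes a contiguous chunk of the
  underlying uniform stream — a single replicate is reproducible from
  `(design, seed, r)` alone, and results do not depend on evaluation
  order. Within a suite each statistic receives its own stream derived
  deterministically from the master seed.

### Calibration, and a known conservatism

With the preference-free generator, the CI decision rule rejects each
*continuous-valued* statistic in very close to 5% of replicate datasets.
For lattice-valued statistics at a biallelic MHC locus — $H_o$ (a
proportion of ~40–55 unique males) and $AF$ (per-male values on a
three-point lattice) — the null sample of means has large atoms, and a rule
that requires the observed value to fall strictly outside an interpolated
percentile interval is conservative: measured rejection rates run around
2–3% rather than 5%. This is a property of the published decision rule
itself under biallelic conditions, not of the Monte-Carlo engine (the
reported empirical p-values are exchangeability-exact up to the same
discreteness). Users comparing borderline $H_o$/$AF$ results should read
the p-value, not only the CI flag.

## Reproductive success

Male reproductive success is the offspring count of each clutch, modelled
as `n_offspring ~ zygosity + (1 | male_id)` with Poisson response and log
link; `zygosity` is 1 for MHC-heterozygous sires and 0 for homozygous, per
locus by default (`locus = NULL` codes heterozygous-at-any-locus). The
marginal likelihood is maximised with the Laplace approximation (lme4;
`nAGQ` raises the quadrature order), and the fixed effect is reported with
its Wald p-value. A constant response makes the mixed fit degenerate and is
handled by the exactly-equivalent $\sigma_u = 0$ GLM path. Uncertainty
bands for the fitted class means come from a cluster bootstrap: males are
resampled with replacement as whole clusters of clutches and the model
refitted (study convention: 10,000 resamples; tests use far fewer).

## The synthetic colony generator

The generator produces datasets with the structure of a closed captive
colony and known ground truth, so that power and calibration are testable
without any real data:

* **Founder base**: `n_founders = 11` founders with genotypes drawn from
  Dirichlet(1) allele frequencies (frequencies are redrawn if a locus
  cannot be realised polymorphic among the founders). Every adult is a
  Mendelian child of two distinct random founders, which produces the
  background relatedness characteristic of a colony descended from few
  wild founders.
* **Colony shape**: 123 females and 59 males in three ponds (41/20, 41/20,
  41/19 — a proportional split, since the real per-pond split is not
  published in the main text); 13 microsatellite loci with 4–10 alleles
  and 2–4 bp motifs; two biallelic MHC loci with 270 bp coding sequences
  whose two alleles differ at each codon with probability 0.10 (so the
  realised amino-acid p-distance is Binomial(90, 0.10)/90).
* **Mating**: 105 clutches; for each, a dam is drawn uniformly and her
  sire from her pond with probability $\propto \exp(\beta\,\text{het}_m +
  \gamma\, AA_{func.dist}(f, m))$ at the preference locus. The log-linear
  (softmax) form makes the null exact at $\beta = \gamma = 0$ and the
  strengths recoverable. Clutch sizes are Poisson(16) (~1684 offspring);
  offspring genotypes are Mendelian, optionally perturbed by a mistyping
  rate for audit tests. Preference defaults are $\beta = 2$
  (heterozygote model) and $\gamma = 5$ (compatibility model) — strong
  preferences, chosen so power studies probe the detection of a clear
  signal.

What the generator does *not* emulate: genotyping error in adults, null
alleles, mutation, linkage between loci, multi-year overlapping
generations, and any phenotypic mate-choice cue. Passing tests therefore
demonstrate that the statistics detect (or correctly fail to detect)
*genetic* preference signals under idealised typing, not that any
particular real dataset contains them.

## Numerical and design choices

* Amino-acid distance model defaults to the p-distance; the choice is
  attached to every distance matrix (`attr(m, "model")`).
* Undefined statistic values (e.g. a pair untyped at a locus) are dropped
  from a replicate's mean and counted in `n_dropped`; `na_policy =
  "abort"` turns them into errors.
* Degenerate denominators (monomorphic reference for $SH$/$IR$, no typed
  loci) yield `NA` flags, never silent zeros.
* A trailing stop codon in an allele's translation is trimmed; an internal
  stop is an error.
* Problem sizes used by the test suite: calibration uses 400 replicate
  colonies at 999 null replicates; power uses 20 replicate colonies per
  preference model; relatedness recovery uses 500 dyads per relationship;
  oracle checks use ≤10-individual hand-built fixtures. These sizes put
  Monte-Carlo error well inside each test's tolerance.

## Worked example

```{r example}
library(mhcmate)

ds <- simulate_alligator_dataset(sim_config(seed = 42,
                                            preference = "heterozygote"))
report <- run_mate_choice_pipeline(
  ds$individuals, ds$loci, ds$pairs, ds$alleles,
  clutches = ds$clutches, trios = ds$trios,
  n_iter = 9999, seed = 1)
print(report)
autoplot(report)
```

## Limitations

* The randomisation engine samples; it does not enumerate exact permutation
  distributions (matching the study design it implements). The exact
  expectation is available via `expected_null_mean()` for verification.
* Wang's estimator uses the re-derived moment equations solved by weighted
  least squares, not the original closed-form solution (see above).
* The Mendelian audit is a consistency check with a mismatch budget; it is
  not a likelihood-based parentage assignment and cannot detect an
  assignment that is wrong but Mendelian-consistent.
* The good-gene score $AF$ is one defensible reading of "male MHC allele
  frequency"; it is configurable precisely because the field's usage is
  not standardised.
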