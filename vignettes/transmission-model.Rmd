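---
title: "A two-locus gametophytic-selection model for T-DNA transmission genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-locus gametophytic-selection model for T-DNA transmission genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametrans)
```

## The problem

T-DNA insertion alleles in *Arabidopsis* carry selectable resistance
markers, so the genotype composition of a progeny population can be read
off selective plates. When a gene is required in the haploid gametophyte
(pollen or embryo sac), its mutant allele is under-transmitted and
seedling ratios depart from Mendelian expectations — segregation
distortion. The motivating case is the pair of mitochondrial Rho-GTPase
genes *MIRO1* and *MIRO2*: *miro1* (BASTA resistance) shows distorted
segregation on its own, *miro2-2* (kanamycin resistance) is silent on its
own, but in a *miro1* background the additional loss of *MIRO2* nearly
abolishes transmission of the double-mutant pollen — unequal genetic
redundancy. `gametrans` implements the generative model behind such
analyses, the estimators and tests applied to the observed counts, and a
forward simulator, so the whole workflow can be exercised and validated
without any external data.

## The generative model

The model tracks two unlinked biallelic loci (the general code handles
any number, but the shipped configuration is the two-locus case). A cross
is processed in four stages:

1. **Gamete formation.** Each parent's gametes are enumerated with
   Mendelian frequencies: a factor of 1 for a homozygous locus and 1/2
   per heterozygous locus, multiplied across loci because the loci sit on
   separate chromosomes. A double heterozygote produces four haplotypes
   at 1/4 each.
2. **Gametophytic selection.** Each haplotype $g$ has a sex-specific
   relative transmission efficiency $\tau^{m}_g$ (pollen) or
   $\tau^{f}_g$ (embryo sac) in $[0,\infty)$, with the all-wild-type
   haplotype pinned at 1 so the parameterisation is identifiable within
   each sex. Gamete frequencies are reweighted and renormalised:
   $p'_g \propto p_g \tau_g$. Net efficiencies are all the model sees;
   pollen competition kinetics are deliberately out of scope.
3. **Female gametophyte failure.** An embryo sac of haplotype $g$ fails
   to mature with probability $s_g \in [0,1]$ and is scored as an
   *unfertilized ovule*. This failure can be incompletely penetrant
   ($0 < s_g < 1$), which is exactly the regime the double-mutant data
   require.
4. **Zygote viability.** Fertilised zygotes matching a lethality
   predicate (here: homozygous *miro1*) are scored *aborted seed*;
   every other zygote lands in a *viable* class keyed by the set of
   resistance markers it carries, because marker resistance is taken as
   fully penetrant and strictly linked to the insertion.

The result is an exact probability distribution over
$\{\text{unfertilized}, \text{aborted}\} \cup \{\text{viable} \times
\text{marker pattern}\}$ that sums to one by construction; the test
suite verifies this to $10^{-12}$ against brute-force enumeration of all
homolog choices for every two-locus cross.

### Expected segregation ratios and their two denominators

Published expected ratios for selfings of a *miro1*(+/−) *miro2-2*(+/−)
plant quote 37.5% ("10:6") dual-resistant progeny. That figure counts
the embryo-lethal *miro1* homozygotes in the denominator of the 16-cell
Punnett enumeration, although what is scored on plates are germinated
seedlings. Both conditionings are first-class in
`expected_resistant_fraction()`:

* `all_zygotes_naive` — lethal zygotes stay in the denominator
  (6/16 = 37.5%); this is the convention needed to reproduce the
  published chi-square tests,
* `viable_seedlings` — conditions on non-aborted, non-unfertilized
  classes (6/12 = 50%); biologically the more defensible choice.

Reports always name the conditioning used. The companion "2:1"
hypothesis — 33.3% *miro2-2* homozygotes *within* dual-resistant
seedlings — is the conditional fraction
`conditional_genotype_fraction()` computes:

```{r}
loci <- miro_loci()
prm  <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
dhet <- cross_spec(genotype(loci, "+/- +/-"))
expected_resistant_fraction(dhet, prm, mode = "all_zygotes_naive")
conditional_genotype_fraction(dhet, prm, target = hom_tdna("MIRO2"),
                              condition = resistant_to(c("BASTA", "kanamycin")))
```

Ratio strings like "3:5" or "2:1" are treated as presentation only;
hypotheses are stored as expected resistant proportions throughout,
which avoids the ambiguity of ratio ordering.

## Estimators and tests

* `chisq_gof()` is the uncorrected Pearson statistic
  $\sum (O-E)^2/E$ with $k-1$ degrees of freedom. No Yates continuity
  correction is applied anywhere: the published benchmark (140/328
  against 3:5 giving $\chi^2 = 11.489$) is only reproduced by the
  uncorrected form (the corrected statistic is about 11.17). The
  denominator is the germinated count $R+S$ (468 here), not the total
  seed count, again pinned by the published statistic.
* `transmission_efficiency()` returns $TE = R/S$ with the
  percent-of-total transform $100\,TE/(1+TE)$ and a Wilson score
  interval on $R/(R+S)$ mapped through $p/(1-p)$. Wilson was chosen
  over Wald because male co-transmission ratios sit near zero
  (TE on the order of 0.1%), where the Wald interval collapses.
* `welch_t_summary()` computes the unpaired t-test from published
  summary triplets (mean, SD, n). Welch's unequal-variance form is the
  default because the reported groups have unequal SDs and sizes; a
  pooled-variance flag reproduces the classical Student form, and both
  give $P < 10^{-4}$ on the phenotype comparisons shipped here.
* `two_proportion_test()` is the pooled-variance z test with per-group
  Wilson intervals, used for karyogamy-defect frequencies whose raw
  counts were reconstructed as `round(p * n)` from published
  percentages; the fixture marks them as reconstructed.

## Maximum-likelihood fitting

`fit_transmission()` turns the generative model into an estimator: free
parameters (any subset of taus and sac-failure probabilities, named like
`"tau_male[miro1:miro2-2]"`) are fitted by maximising the multinomial
likelihood of observed class counts. Because plate scoring never sees
unfertilized ovules — and often not aborted seeds — the likelihood
conditions on the scored classes by renormalising the class
probabilities over `names(observed)`.

Numerical choices worth recording:

* Optimisation is bound-constrained (`L-BFGS-B`; taus on $[0,\infty)$,
  probabilities on $[0,1]$) on the natural scale, so boundary MLEs are
  attainable: a cross with zero resistant seedlings gives
  $\hat\tau = 0$ exactly. One-dimensional fits get a golden-section
  polish pass, which makes the numerical optimum agree with the
  closed form $\hat\tau = R/S$ of the single-tau reciprocal cross to
  about $10^{-6}$ relative error.
* Confidence intervals default to profile likelihood (inverting the
  likelihood-ratio chi-square by root finding), which degenerates
  cleanly to a one-sided interval at a boundary estimate; Wald
  intervals from the observed information are available. The test
  suite checks 95% profile intervals cover a true $\tau = 0.3$ between
  92% and 97% of the time over 500 simulated crosses of $n = 2000$.
* A class whose probability vanishes at a parameter boundary (e.g. the
  unfertilized class at $s = 0$) is treated as probability zero, not
  missing, so profiles can cross boundaries safely.
* Identifiability is checked through the eigenvalues of the observed
  information at an interior optimum; a flat direction (for instance,
  freeing the female tau of a haplotype the mother never produces)
  raises a warning instead of returning an arbitrary number.

## The simulator

The forward simulator generates every input the analysis consumes and
is the oracle for the estimator's calibration tests.

* `simulate_progeny()` draws one multinomial sample of size $n$ from
  the exact class distribution.
* `simulate_siliques()` fills a fixed number of ovule positions per
  silique (default 57, the wild-type seed set scale) with independent
  draws, so fates are randomly dispersed along the silique — the model
  makes no spatial claim and none is tested. Ovules per silique are
  fixed per genotype; a Dirichlet-multinomial overdispersion knob
  (`rho`) exists but defaults off, since no between-silique variance
  is specified for the motivating data.
* `simulate_lengths()` draws pollen-tube or silique lengths from a
  normal distribution truncated at zero via inverse-CDF sampling.
  Truncation only matters when the mean is within about two SDs of
  zero; at the shipped parameter regimes its effect is negligible, and
  it exists to keep small-mean simulations physically meaningful.
* Seeds: every simulation derives a per-operation substream from the
  base seed by hashing the operation label, so adding one simulation
  to a pipeline never shifts the draws of another. All derived seeds
  stay below $2^{31}$.

What the simulator does *not* emulate about real data: germination
failure (89.9–97.1% germination is treated as upstream of the counts
and out of scope — analyses condition on germinated counts as given),
marker silencing, linked loci, cytoplasmic effects, and any
environmental covariance between siliques of one plant. Passing tests
therefore demonstrate internal consistency of model, estimator and
simulator under these assumptions, not robustness to violations of
them.

## Problem sizes and fixtures

The shipped fixtures are the small printed count tables of the
motivating study (a few thousand seedlings and ovule positions) plus
reconstructed TE and karyogamy counts flagged as such; everything
larger is generated in code. The test suite simulates at
$n = 10^5$–$1.6\times10^5$ for frequency-convergence checks, $n = 2000$
with 500 replicates for interval calibration, and $n = 5000$ for point
recovery — sizes chosen so sampling error bounds (3 SE) are tight
enough to be meaningful while the whole suite stays interactive.

## Known limitations

* Loci are strictly unlinked; there is no recombination-fraction
  machinery, because the expectation structure being reproduced relies
  on independent assortment of chromosomes.
* Two alleles per locus; allelic series are out of scope.
* Transmission parameters are net efficiencies; the model cannot
  distinguish pollen germination failure from slow tube growth, only
  their combined effect on transmission.
* The multinomial likelihood assumes independent progeny; family
  structure or plate effects would require an overdispersed likelihood
  the package does not provide.
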