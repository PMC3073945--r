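# gametrans

Transmission genetics of selectable T-DNA insertion alleles in plants:
a two-locus gametophytic-selection model, the estimators and tests of
the classical segregation workflow, and a forward simulator.

## What it is for

When a gene acts in the haploid gametophyte (pollen or embryo sac), its
mutant allele is under-transmitted and seedling ratios on selective
plates depart from Mendelian expectations. The motivating system is the
*Arabidopsis* gene pair *MIRO1*/*MIRO2*: the *miro1* insertion (linked
to BASTA resistance) distorts segregation on its own, *miro2-2*
(kanamycin resistance) is silent on its own, yet the double-mutant
gamete is almost never transmitted through pollen — unequal genetic
redundancy. `gametrans` is for geneticists who need to (a) derive exact
expected progeny-class frequencies for selfings and reciprocal crosses
under gametophytic selection, embryo-sac failure and zygotic lethality,
(b) test observed counts against those expectations, and (c) estimate
transmission parameters from counts by maximum likelihood.

## The model in brief

For each parent, gamete haplotypes $g$ get Mendelian frequencies
(factors of 1/2 per heterozygous locus, multiplied across unlinked
loci), reweighted by sex-specific relative transmission efficiencies
$\tau^{m}_g$, $\tau^{f}_g$ (all-wild-type haplotype pinned at 1) and
renormalised. A female gametophyte of haplotype $g$ fails with
probability $s_g$ (scored as an unfertilized ovule); zygotes matching a
lethality predicate (e.g. *miro1*/*miro1*) are scored as aborted seeds;
surviving zygotes land in viable classes keyed by their resistance
markers. Estimation maximises the multinomial likelihood of observed
class counts under this distribution; the single-tau reciprocal-cross
MLE reduces to the classical transmission efficiency $TE = R/S$.

## Worked example

```r
library(gametrans)
loci <- miro_loci()
prm  <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
dhet <- cross_spec(genotype(loci, "+/- +/-"))
progeny_distribution(dhet, prm)
#> Selfing of MIRO1/miro1 MIRO2/miro2-2
#>                   class probability
#>            aborted_seed      0.2500
#>            viable:BASTA      0.1250
#>  viable:BASTA+kanamycin      0.3750
#>        viable:kanamycin      0.1875
#>             viable:none      0.0625
```

The dual-resistant class is 6/16 = 37.5% of all zygotes (the "10:6"
expectation, embryo-lethal *miro1* homozygotes included in the
denominator) and 50% of viable seedlings; both conditionings are
available in `expected_resistant_fraction()`. Testing observed counts
(140 dual-resistant vs 328 sensitive seedlings) against 37.5%:

```r
chisq_gof(c(140, 328), c(0.375, 0.625))
#> Chi-square goodness of fit (no continuity correction)
#>   X-squared = 11.489, df = 1, p = 0.0007
```

— a significant deficit of dual-resistant progeny. Fitting the male
transmission efficiency of the double-mutant gamete from a reciprocal
cross (wild-type mother, counts 161 resistant / 464 sensitive):

```r
fit <- fit_transmission(
  cross_spec(genotype(loci, "+/+ +/+"), genotype(loci, "+/- -/-")),
  observed = c("viable:BASTA+kanamycin" = 161, "viable:kanamycin" = 464),
  free = "tau_male[miro1:miro2-2]")
summary(fit)
#> Gametophytic transmission fit (maximum likelihood)
#> Cross: MIRO1/MIRO1 MIRO2/MIRO2 (female) x MIRO1/miro1 miro2-2/miro2-2 (male)
#> Observed classes (n = 625 ): viable:BASTA+kanamycin, viable:kanamycin
#> Estimates:
#> tau_male[miro1:miro2-2]
#>                0.346983
#>
#> Profile 95% confidence intervals:
#>                         estimate       se    lower    upper
#> tau_male[miro1:miro2-2] 0.346983 0.031738 0.289245 0.414088
#> log-likelihood: -3.3113
```

The estimate equals $R/S = 161/464 = 0.347$ — a transmission efficiency
of 34.7%, i.e. 25.8% of total seedlings carry the double-mutant
haplotype instead of the Mendelian 50%. `miro_report()` runs the whole
pipeline (segregation tables, genotyped subset, TEs, silique
composition, Welch t-tests, two-proportion comparisons) over the
packaged count tables, and `simulate_progeny()` /
`simulate_siliques()` / `simulate_lengths()` generate synthetic inputs
from any parameterisation. A thin CLI over the same functions ships in
`inst/cli/gametrans` (subcommands `expect`, `gof`, `te`, `ttest`,
`simulate`, `recover`, `report`).

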