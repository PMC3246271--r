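---
title: "Inferring spontaneous mutation rates from synonymous substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring spontaneous mutation rates from synonymous substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synrate)
```

## Why synonymous substitutions

In a long-running evolution experiment, every sequenced clone is the end
of an unbroken chain of cell divisions from the ancestor. Mutations that
do not change any encoded protein — synonymous base substitutions — are
invisible to selection to a first approximation, so the number a clone
carries is simply the number that arose along its lineage. That makes
them a direct mutation counter: the expected count is the per-site
mutation rate times the elapsed generations times the number of sites at
which such a mutation could have occurred *and been observed*. Strongly
selected nonsynonymous changes, by contrast, reflect adaptation as much
as mutation; the per-clone dN/dS screen in `dnds()` exists to verify
that (values well above 1 in adapting populations disqualify
nonsynonymous counts for rate estimation).

## Counting the target sites

Two site counts are offered, matching two uses:

* `simple_synonymous_sites()` — protein-coding length / 3. Every coding
  base admits three changes and roughly one in three is synonymous; this
  coarse count is what makes rates comparable across studies where only
  coding length is known. Positions covered by more than one CDS are
  counted once.
* `synonymous_opportunities()` — the full enumeration. For every coding
  position and each of its three possible changes, the change is
  classified by translating every CDS containing the position
  (strand-aware, bacterial/archaeal code, NCBI table 11); synonymous
  opportunities are tallied by the six strand-collapsed substitution
  types. This per-type table is what the likelihood model and all
  spectrum statistics consume, because the chance that a mutation is
  synonymous depends strongly on which base pair mutates to which.

Classification conventions (all deliberate, all applied identically in
`classify_change()`, the opportunity enumeration and the simulator):

* start codons are translated as ordinary codons — the alternative
  (treating position 1 changes that preserve an initiator as silent)
  touches at most one codon per gene and complicates the invariants;
* a change that creates a stop codon in any containing CDS is
  *nonsense*, never synonymous; a change destroying a stop is
  nonsynonymous (stop-loss); a stop-to-stop change preserves the
  protein and counts as synonymous;
* in overlapping CDSs a change is synonymous only if it is synonymous
  in **every** containing frame (the conservative reading), and
  overlapping coding bases are counted once;
* CDS spans not divisible by three, or shorter than two codons, cannot
  be translated in a single frame and are skipped with a logged count;
* circular genomes are supported, with origin-wrapping features rotated
  before translation.

The enumeration is verified in the test suite against an independent
brute-force oracle that mutates the genome string and re-translates
whole CDSs with `Biostrings::translate()`, exactly, on every genome it
is given.

## The blocked Poisson likelihood

With per-clone, per-type counts $m_{g,c}$, generations $t_g$ and sites
$S_{g,c}$, the model is $m_{g,c} \sim
\mathrm{Poisson}(\mu_c\,t_g\,S_{g,c})$. Clones from one population are
not independent replicates — they share the portion of their lineage
before their lines of descent split — so clone log-likelihoods are
averaged within population blocks:

$$\ell(\mu) = \sum_p \frac{1}{n_p} \sum_{g \in p} \sum_c
  \left[ m_{g,c}\ln(\mu_c t_g S_{g,c}) - \mu_c t_g S_{g,c} - \ln m_{g,c}! \right].$$

This down-weights each clone by its population's clone count, so
duplicating every clone of a block leaves both the likelihood and the
estimates unchanged (a property the tests assert). The maximum has a
closed form — block-weighted counts over block-weighted exposures,
per type — which `fit_blocked_ml()` uses directly; the test suite
confirms on random instances that numerically maximizing $\ell$
reproduces it to six significant figures. Types never observed get rate
0 plus a one-sided 95% upper bound from the profile likelihood
($-\ln 0.05 / \text{exposure}$).

Zero-count clones are included: a clone that carries no synonymous
mutation still contributes $-\mu_c t_g S_{g,c}$ terms, and dropping that
information would bias rates upward.

The per-type rates are expressed per ancestral base pair of the matching
type per generation, so the overall rate is their composition-weighted
combination
$\mu = f_{AT}(\mu_{AT>GC}+\mu_{AT>CG}+\mu_{AT>TA}) +
f_{GC}(\mu_{GC>AT}+\mu_{GC>TA}+\mu_{GC>CG})$, with $f_{AT}, f_{GC}$ the
genome-wide base-pair frequencies.

## Confidence limits

* **Simple estimator**: each site-generation is a Bernoulli trial, so
  exact Clopper–Pearson binomial limits apply
  (`binomial_rate_ci()`, via `qbeta`). At the astronomical trial counts
  involved these coincide with exact Poisson limits
  (`poisson_rate_ci()`), which the tests check to four significant
  figures at $10^{11}$ trials.
* **Blocked estimator**: Tukey's jackknife over whole populations.
  Deleting population $i$ gives $\hat\theta_{(-i)}$; pseudo-values
  $\hat\theta_i = n\hat\theta - (n-1)\hat\theta_{(-i)}$ yield a mean,
  a standard error, and a t-interval on $n-1$ degrees of freedom (7,
  for eight populations). The t reference distribution is the standard
  Tukey procedure. The jackknife is applied to the *combined* rate —
  the quantity whose uncertainty is reported — rather than to each
  per-type rate separately. The lower limit is truncated at zero.

The headline analysis of the study this package reimplements also used
per-clone callable-site tables produced by its resequencing pipeline
(masking deletions, low-coverage and repetitive regions per clone).
Those tables were never published, so `build_clone_observations()`
accepts such a table as an optional input but the estimator is validated
by simulation instead of by reproducing that exact interval.

## Spectrum statistics

Raw type counts confound mutation pressure with opportunity: GC>AT
changes are observed often partly because many sites offer them
synonymously. All ratios therefore normalize counts by per-type
opportunities $S_c$:

* `corrected_ts_tv()` — $(\sum_{tv} c/S) / (\sum_{ts} c/S)$, reported in
  the 1:x convention where 1:2 is the value expected under a uniform
  per-opportunity rate (two transversion categories per transition
  category);
* `fold_bias()` — per-opportunity rate ratio of two types, by default
  GC>AT versus AT>GC, the AT-ward mutation pressure;
* `two_tailed_binomial_test()` — the exact two-tailed p-value by the
  minimum-likelihood rule: the summed probability of all outcomes whose
  point probability does not exceed the observed one. Ties are matched
  with a $1+10^{-7}$ relative tolerance (the same convention as
  `stats::binom.test`, which the tests use as an independent
  cross-check alongside a brute-force enumerator).

`spectrum_report()` frames the two tests with opportunity-implied nulls
and records them in the output for auditability: the transition share
under a uniform per-opportunity rate is $\sum_{ts} S_c / \sum_c S_c$
(the "uniform probability of all six types" convention), and the
two-type GC>AT vs AT>GC null is $S_{GC>AT}/(S_{GC>AT}+S_{AT>GC})$. The
exact null behind the originally published p-values was not fully
specified, so the report documents its convention rather than asserting
equality with those p-values.

## dN/dS

`count_sites_ng()` uses unweighted fractional site counts: a coding
position where $k$ of its three changes are synonymous contributes
$k/3$ synonymous and $1-k/3$ nonsynonymous sites. `dnds()` is then
$\big(N_{obs}/N_{sites}\big) / \big(S_{obs}/S_{sites}\big)$, with
nonsense changes counted as nonsynonymous and no multiple-hit
correction — appropriate when clones carry far fewer than one
substitution per gene, where corrected and uncorrected estimators
coincide. The original study used Comeron's method from an external
library; exact numerical agreement with that implementation is not
claimed, and the neutral calibration (uniformly placed coding changes
give mean dN/dS within sampling error of 1) is the governing check.
When a clone has no synonymous change, dS is 0 and the ratio is
reported as undefined, not infinite.

## The synthetic-data generator

`simulate_genome()` + `simulate_mutations()` emulate the experimental
design the estimator targets:

* replicate populations propagated independently; several clones per
  population; star-like within-population genealogy — every clone
  spends a fraction `shared_fraction` of its generations on the
  population's common lineage and the rest on a private branch. A full
  coalescent is unnecessary: a single shared prefix already induces the
  pseudo-replication the blocked likelihood corrects;
* per-type Poisson mutation arrival on every branch with mean
  $\mu_c \times \text{branch length} \times$ (genomic sites carrying
  the type's ancestral pair), uniform placement over those sites,
  infinite-sites resampling of within-population collisions (with a
  warning if more than 1% of placements collide), and classification of
  every placed change against the annotation;
* neutrality throughout: no fitness effects, no mutators, no
  sequencing-error model — deliberately, because selective neutrality
  of synonymous changes is the estimator's core assumption and the
  generator defines the regime in which the estimator is *supposed* to
  work. Passing recovery tests therefore demonstrate correctness of the
  inference machinery, not robustness to selection on synonymous sites,
  rate heterogeneity along the genome, or variant-calling error in real
  data.

Default study conditions (chosen once, as the conditions the emulated
experiment defines): 8 populations × 2 clones sampled at 40,000
generations; `shared_fraction = 0.6`, matched to the packaged mutation
table itself, where 15 of 35 events are carried by more than one clone —
with two clones per population the expected shared fraction is
$\alpha/(2-\alpha)$, and $\alpha = 0.6$ gives the observed ≈ 0.43;
relative per-type rates follow the observed event spectrum
(18 : 1 : 6 : 4 : 6 for GC>AT : AT>GC : GC>TA : AT>TA : AT>CG, with a
0.5 floor for the unobserved GC>CG class so no type has a degenerate
zero truth), scaled by `ltee_like_rates()` so one dataset expects ~35
synonymous events — the yield of the emulated study. The default
synthetic genome is 30 kb with GC 0.5 and coding fraction 0.85
(coding-dense, like a bacterial chromosome); a genome three orders of
magnitude smaller than real, with correspondingly scaled-up rates, gives
the same count statistics while keeping a 200-replicate recovery
experiment (the size used by the validation tests) comfortably fast.
Composition checks use 100 kb, where the generator guarantees realized
GC within one percentage point of target: interior codons are drawn from
a base distribution solved (by `uniroot`) so that conditioning on
"not a stop codon" still yields the target GC.

## Numerical choices and degenerate inputs

* The blocked MLE is computed in closed form; no iterative optimizer is
  in the production path (the optimizer appears only as a test
  cross-check). $0\ln 0 = 0$; a zero rate facing a nonzero count gives
  $\ell = -\infty$, not an error.
* `binomial_rate_ci()` returns a lower limit of exactly 0 at $m = 0$.
* Jackknife lower limits are truncated at 0; identical blocks give a
  zero-width interval.
* Genomes are validated at load: only A/C/G/T (ambiguity codes
  rejected), features within bounds (wrapping only on circular
  molecules), untranslatable spans skipped and counted.
* Event collapse keys on (population, position, ref, alt): the same
  position mutated in two populations is two events; two different
  alternate bases at one position are two events.
* All simulators take explicit integer seeds and are bit-reproducible;
  `recovery_experiment()` derives per-replicate seeds from one stream.

## Limitations

* No spliced CDSs, selenocysteine recoding or programmed frameshifts;
  GenBank `join()` locations are skipped with a warning.
* No context-dependent (neighbour-aware) rates, no rate heterogeneity
  along the genome, no codon-usage or GC-equilibrium modelling.
* The spectrum p-values depend on the documented null convention; other
  reasonable conventions give slightly different p-values (the ratios
  themselves do not change).
* The packaged mutation table records one historical dataset; its
  designated-clone subset tallies 24 synonymous mutations where the
  original publication's comparison table quotes 25 (the extra record
  appears only in that study's unpublished supplement). The table is
  shipped verbatim rather than "corrected".
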