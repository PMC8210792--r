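---
title: "Detecting translocated wrasse: models and design choices in hybridscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting translocated wrasse: models and design choices in hybridscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

## The problem

Corkwing wrasse (*Symphodus melops*) are shipped in large numbers from
Skagerrak–Kattegat to salmon farms in western and mid-western Norway, where
they work as cleaner fish. The exporting and importing coasts hold strongly
diverged wild populations (multilocus Weir–Cockerham $\theta \approx 0.5$
across a panel of discriminant SNPs). Fish escaping the cages can therefore
be recognized genetically, and so can their offspring for roughly two
generations. `hybridscan` packages the full workflow: genotype QC,
diversity and divergence statistics, discriminant-panel design,
Mendelian simulation of hybrid classes, six-class genotype-frequency
classification with calibrated power, admixture clustering, and
geographic-cline analysis.

Everything operates on a `genotype_matrix`: individuals × biallelic loci
coded as reference-allele counts 0/1/2 with `NA` for missing, plus
population and geographic-group labels. The reference allele is whatever
allele the input file lists first (VCF `REF`; allele code 1 in Genepop);
only consistency matters, none of the statistics depend on the
orientation.

## Quality control

Three filters mirror standard SNP-array QC for this kind of panel, in this
order: site filters (missingness > 10%, heterozygote fraction > 0.5 — an
excess of heterozygotes at a "locus" is the signature of lumped paralogs),
then individual missingness (> 20%), then technical-replicate concordance
(a locus with more than 2 discordant replicate pairs is dropped, and one
member of each pair is retained — the one with fewer missing calls, ties
broken by sample id, a rule the package fixes because any deterministic
choice is defensible). The site-missingness filter is applied globally, not
per population; with strongly unbalanced sampling a per-population variant
could behave differently, which is why the removed-locus report is attached
to the result for auditing.

## Diversity and divergence

Per population and locus the package reports observed heterozygosity,
the unbiased expected heterozygosity $\hat H_e = 2\hat p(1-\hat p)\,
2n/(2n-1)$, $F_{IS} = 1 - H_o/\hat H_e$ (the single-population reduction of
the Weir–Cockerham within-population component; the multi-population $f$
is available through the F-statistics machinery), and allelic richness by
rarefaction to $g$ gene copies, with $g$ defaulting per locus to twice the
smallest per-population sample size.

Hardy–Weinberg deviation uses the exact conditional (Levene) distribution
of the heterozygote count given the allele counts, with the two-sided
p-value summed by complete enumeration over all compatible configurations —
no chi-square approximation, so small samples are handled exactly. The test
is verified in the suite against brute-force enumeration of all allele
pairings for $n \le 10$.

Differentiation is Weir & Cockerham's (1984) $\theta$, computed from the
per-locus $a, b, c$ variance components; multilocus values are always the
ratio of summed components, never a mean of per-locus ratios. Pairwise
significance is Monte-Carlo: either a label-permutation test on the
multilocus $\theta$ (default) or a per-locus contingency-table exact test
(genotype counts, simulated p-values) combined across loci by Fisher's
method. Both are seeded; Bonferroni flags are computed over all pairs. The
choice exists because the field's habitual software names an "exact
G-test with Monte-Carlo replicates" without an unambiguous computational
object; both routes agree on every strongly structured dataset we
simulate.

AMOVA partitions squared-Euclidean distances between 0/1/2 genotype
vectors (missing calls imputed at the population mean) into between-group,
between-population-within-group and within-population strata via the
standard nested moments equations with unequal-size coefficients.
Permutation p-values permute whole populations among groups, individuals
among populations within groups, and individuals among all populations,
respectively. Negative components are reported as-is and percentages are
then computed over the positive components with a flag — truncation hides
information, and the flag is what a reader should react to. No suitable
AMOVA implementation exists among this package's dependencies, which is
why the moments equations are implemented here and checked against direct
nested sums of squares on toy hierarchies.

## The synthetic reference generator

`simulate_reference_pops()` draws the study conditions the power analysis
rests on: ancestral frequencies uniform on $[0.05, 0.95]$ (avoiding loci
that are ancestrally monomorphic), population frequencies from the
Balding–Nichols beta model
$p_{pop} \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$,
genotypes binomial. The divergence parameter defaults to the package's
wrasse-inspired condition $F = 0.5$, which realizes a multilocus
$\theta$ of 0.49–0.51 at 84–10 000 loci — matching the printed
west-vs-south-east coastal divergence. Reference sample sizes default to
40 per population, the size of the genotyped reference collections.

`simulate_hybrid_classes()` then draws the six classes by explicit gamete
simulation: pures are two gametes from one pool, an F1 one from each, an
F2 one gamete from each of two independently simulated F1 parents (each F1
gamete carries its A- or B-derived allele with probability ½), and each
backcross one F1 gamete plus one pure gamete. Loci segregate independently
(the real panel spans ~270 contigs, so linkage is negligible at this
scale). When a real two-population reference matrix is supplied instead of
a synthetic panel, its allele frequencies enter as point estimates; no
resampling of frequency uncertainty is attempted.

What the generator does *not* emulate: linkage, genotyping error,
null alleles, population substructure within each reference pool, and the
fact that a designed assay panel is *selected* for extreme per-locus
divergence rather than drawn from a stationary divergence model. The last
point matters for interpreting the power study (below).

## Six-class classification

The classifier is the two-gene-pool genotype-frequency model: an
individual of class $z$ carries, at each locus, 2, 1 or 0 gene copies of
A-pool origin with probabilities $\phi_z = (1,0,0)$, $(0,0,1)$, $(0,1,0)$,
$(\tfrac14,\tfrac12,\tfrac14)$, $(\tfrac12,\tfrac12,0)$,
$(0,\tfrac12,\tfrac12)$ for PureA, PureB, F1, F2, BCA, BCB, and each copy
is the reference allele with its pool's frequency. Two inference routes
share this model:

* `classify_ml()` holds the pool frequencies fixed (known simulation
  truth, or estimates from reference samples) — a fast, deterministic
  path used as the oracle in tests;
* `classify_gibbs()` treats frequencies and labels as unknown and Gibbs
  samples: class labels from their conditionals, then allele origins, then
  pool frequencies from Beta posteriors under uniform priors, with a
  uniform prior over the six classes. Missing genotypes contribute
  likelihood 1.

The sampler is compiled code with its own small seeded RNG
(xoshiro256++), because a desk-scale calibration run needs on the order of
$10^6$ sweeps over hundreds of individuals. Defaults are burn-in 5 000 and
30 000 retained sweeps — enough for between-chain posterior-mean
discrepancies below 0.01 on strongly diverged data — with the full-scale
50 000 / 300 000 setting available by argument. Two independent chains are
always run; chain two is aligned to chain one (the A/B labelling of a
mixture is arbitrary), the maximum per-individual discrepancy is reported,
and a discrepancy above 0.1 triggers an automatic rerun with fresh derived
seeds (at most twice). The final posterior averages the chains.

Orientation deserves a note. The fitted model cannot know which inferred
pool is "population A", so `classify_gibbs()` orients clusters by a fixed
rule (cluster A gets the higher mean reference-allele frequency) and
returns its posterior-mean frequencies. With symmetric synthetic panels
that statistic sits near zero, so the power study re-orients each fitted
posterior against the generating reference frequencies by correlation —
a deterministic alignment whose flip probability is negligible at
$\theta \approx 0.5$. `assign_classes()` thresholds the posterior (strictly
greater than the threshold, labels below it become `"unassigned"`), and
pooling sums posteriors *before* thresholding, which is exactly why a
borderline hybrid that no single hybrid class claims can still be called
a hybrid.

## Power, efficiency, accuracy

For class $c$: efficiency $E$ = correctly assigned over truly-$c$
(recall); accuracy $A$ = correctly assigned over assigned-to-$c$
(precision); power $P = E \times A$, reported on the 0–100 scale.
Unassigned individuals hurt efficiency, never accuracy; a class nothing is
assigned to has undefined accuracy, reported missing rather than zero.
`run_power_study()` runs the calibration design — 3 replicates × 3 datasets
of 288 individuals, 48 per class — and scores every class and the pooled
hybrid group at thresholds 0.5–0.9, reporting per-run values plus minima
and means.

At the synthetic study conditions ($F = 0.5$, Gibbs 5 000 / 30 000), the
106-locus design yields minima over classes and runs of roughly 87%
efficiency, 90% accuracy and power 82 at the 0.5 threshold, and the
84-locus design roughly 56% efficiency / 85% accuracy / power 56 when the
minimum is also taken over thresholds up to 0.9 (F2 at the 0.9 threshold
is always the binding cell); pooling the four hybrid classes lifts the
84-locus metrics above 96% across all thresholds. These are the numbers
the test suite and the acceptance script recompute. A published panel of
the same size does better on the single-class minima, and the reason is
instructive: an assay panel is selected for extreme per-locus divergence,
while Balding–Nichols loci at the same multilocus $\theta$ include many
weakly informative sites. The gap is an information ceiling, not a sampler
artefact — the fixed-true-frequency ML oracle, which no sampler can beat,
shows the same minima (within a few points) on the same synthetic panels.

## Panel design

`rank_loci()` ranks per-locus $\theta$ for each pairwise comparison of the
focal (import-region) population against the export-region populations,
descending, with ties and undefined values broken lexicographically by
locus id so the ranking is reproducible and input-order invariant.
`select_panel()` intersects the top-$K$ lists (default $K = 500$) and then
applies the absolute threshold ($\theta \ge 0.4$ in *every* comparison —
whether the published threshold was per-comparison is not stated, so the
stricter reading is implemented). Validation uses spiked-locus recovery:
strongly diverged loci planted among weak background loci must be
recovered by the selector — conditioning on spikes whose realized
frequency differential is material, because a Balding–Nichols locus at
high $F$ can fix the same allele in both populations and then carries no
signal any method could find.

## Admixture and PCA

`admixture_em()` is a maximum-likelihood EM admixture model: each of an
individual's allele copies comes from cluster $k$ with probability
$q_{ik}$ and is the reference allele with frequency $f_{kl}$. This is a
deliberate, documented simplification of the field's Bayesian MCMC
clustering: the downstream uses here (q thresholds, ΔK over replicate
runs, flagging of intermediate individuals) depend only on point estimates
of $q$, which EM provides deterministically per seed; the price is no
correlated-allele-frequency prior and no $\alpha$ hyperparameter. The
likelihood is non-decreasing at every iteration (asserted in the suite);
supervised initialization from sampling location is available as the
analogue of location-prior clustering. ΔK is the standard second-difference
statistic over replicate runs, undefined at the edge K and wherever the
replicate spread is zero. PCA is done on the genotype matrix with columns
centred, unscaled, and missing values at the column mean, so missing data
fall on the centroid and carry no signal.

## Geographic clines

`fit_cline()` fits $p(x) = p_{min} + (p_{max}-p_{min})/(1 +
e^{-4(x-c)/w})$ to per-site binomial allele counts along the coastal
transect by maximum likelihood (seeded multi-start L-BFGS-B on transformed
parameters), in two variants: asymptotes pinned at 0/1 (2 parameters) or
free (4 parameters). Model choice is by AIC with ties to the simpler
model. Only the no-tail family is implemented: the downstream use is
centre-displacement testing, which the no-tail shapes support; exponential
tails would add parameters the 13-site transect cannot constrain. Sites
with fewer than 10 individuals are dropped by default, matching the
workflow's site filter. The two-log-likelihood support interval of the
centre comes from the profile likelihood over $c$ (re-optimizing the other
parameters on a grid, interpolating the crossing), and two clines are
"displaced" only when their support intervals are disjoint — open-ended
profiles are conservatively called concordant and flagged. A reference
cline can be fitted to per-site mean admixture proportions by treating
$\bar q$ as an allele frequency with $2n$ effective copies; the likelihood
unit for such a cline is not uniquely defined, and this choice keeps the
binomial machinery uniform.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full calibration design
(nine datasets of 288 individuals per panel, 35 000 total sweeps per
chain, two chains per dataset) for both the 106- and 84-locus panels;
property checks use 10 000-locus frequency recovery, 20 seeded cline
recoveries, and exhaustive enumerations at $n \le 10$. Degenerate inputs
are handled explicitly rather than by NaN propagation: monomorphic loci
have undefined $F_{IS}$ and per-locus $\theta$ (reported `NA`, ranked
last), a flat cline flags an unidentifiable width, an all-missing
individual gets the prior as posterior with a flag, and AMOVA on identical
individuals reports undefined percentages. Likelihood evaluations clamp
probabilities at $10^{-300}$ before logging; EM clamps frequencies to
$[10^{-9}, 1-10^{-9}]$.

## Known limitations

Biallelic, diploid, two-source-pool problems only; no F3 or
double-backcross classes; no linkage or genotyping-error model in the
simulator; EM admixture is not a drop-in replacement for Bayesian
clustering when posterior uncertainty of $q$ itself is the quantity of
interest; cline tails and spatial autocorrelation are out of scope. Power
numbers calibrated on synthetic Balding–Nichols references transfer to a
real selected panel only as lower bounds on single-class performance, for
the reason discussed above.
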