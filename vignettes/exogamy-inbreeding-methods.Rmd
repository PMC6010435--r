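---
title: "Methods: quantifying geographical exogamy and genetic inbreeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying geographical exogamy and genetic inbreeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(steppekin)
```

# Scope

`steppekin` implements a joint analysis of marital dispersal and genomic
inbreeding for SNP-array cohorts that come with ethno-demographic survey
data (birthplaces of each individual, their spouse and their parents). The
question it serves is whether geographical exogamy — marrying a spouse born
far away — actually reduces inbreeding, or whether spouses chosen at a
distance are nonetheless relatives (kinship endogamy). Because real
genotype-plus-survey datasets of this kind are access-restricted, the
package ships a synthetic-data generator with exact ground truth, and every
analysis stage is validated against it.

# The synthetic cohort generator

`simulate_cohort()` produces genotypes, phased haplotypes, a survey table
and a truth table for a multi-population cohort.

**Pedigrees and gene dropping.** Each individual's parental mating type is
drawn from a mixture over `OUT` (parents effectively unrelated), `2C`
(second cousins, expected inbreeding coefficient F = 1/64), `1C` (first
cousins, 1/16), `2x1C` (double first cousins, 1/8) and `AV` (avuncular,
1/8); a full-sib pedigree (`SIB`, 1/4) is available for power studies.
Founder haplotypes are drawn site-wise from the panel's allele frequencies
(linkage equilibrium by default; a first-order copying knob can induce
short-range LD but is a free parameter, not a claim of realism). Meioses
recombine with a Poisson crossover process on the cM scale, without
interference and with a sex-averaged map — the standard neutral choice when
the map's sex-specificity is unknown. The focal individual's autozygous
track is computed exactly from the transmitted founder-segment labels, so
the generator provides, per individual, the realised autozygous genome
fraction `f_true` and the exact segment list. No mutation or genotyping
error is added at generation time; `add_genotype_errors()` applies an
optional symmetric flip process afterwards (default rate 0.001) so that the
HMM's error parameter is exercised. Separating signal from noise this way
keeps the ground truth exact.

**Default mating-type mixture.** The default is 64% `OUT`, 29% `2C`, 6%
`1C`, 1% `2x1C`, 0% `AV` — i.e. roughly a third of individuals inbred,
mostly through second cousins and with double-first-cousin matings rare and
avuncular ones absent, which is the regime reported for Inner Asian
populations.

**Geography.** Couple distances are bimodal: an endogamous component
(probability 0.5 by default; exactly 0 km for half of those couples —
spouses born in the same village — and exponential with mean 1 km
otherwise) plus a lognormal exogamous component (median 30 km, log-sd 1,
giving a tail past 1,000 km). Birthplaces are placed in the 40–50°N
latitude band and the partner's birthplace is set due east at the drawn
distance on the same sphere used by `haversine_km()`, so that great-circle
inversion recovers the drawn distance to well under 1%. Planting *kinship
endogamy* — the phenomenon of interest — is done with `band_mixture`: a
different mating-type mixture applied to parental couples whose distance
falls in a chosen band (default 4–40 km).

**Default panel.** 22 chromosomes, 3,500 cM, 5,000 SNPs at a uniform
1 cM/Mb, allele frequencies uniform on [0.1, 0.9]. This desk scale keeps a
full cohort analysis in minutes; all sizes are arguments. ROH work needs a
denser map (see below).

# Geographical exogamy

Distances are great-circle (haversine, Earth radius 6,371.0088 km); whether
the original field studies used great-circle distances is typically
unstated, so the metric is recorded in the output attributes.

The endogamy/exogamy limit is not fixed a priori: per population, a
Gaussian kernel density of log10(distance) is computed with bandwidth 0.2
(interpreted as the kernel SD on the log10 scale, R's `bw` convention), and
the threshold is the antimode — the lowest local minimum strictly between
the two highest substantial modes (a mode must reach 5% of the main peak,
which keeps sampling wiggles from masquerading as a second mode). The
per-population antimodes are averaged. Zero distances cannot enter a
log-scale density; they are moved to 0.1 km for density estimation only
(well below any plausible antimode), while rates and counts always use the
true distances. The evaluation grid spans [0.1, 2000] km padded by four
bandwidths so the density integrates to one; the antimode search is
restricted to the nominal window. On the default geography this procedure
lands near 4 km.

Exogamy rates count couples strictly beyond the threshold. The
distance-class labels used in the individual-scale comparison are `<4`
(closed at 4 km), `4-20`, `20-40` and `>40` — left-closed boundaries, so a
couple at exactly 40 km is in `20-40`.

# Inbreeding from genotypes

**The IBD hidden Markov model.** Two hidden states per marker: autozygous
(IBD) and not. The stationary probability of IBD is `f` (the inbreeding
coefficient being estimated); over a genetic distance `d` cM the chain
transitions with P(IBD→IBD) = exp(−a·d) + (1 − exp(−a·d))·f and
P(nonIBD→IBD) = (1 − exp(−a·d))·f, so `a` (per cM) governs IBD segment
turnover: descendants of short inbreeding loops (avuncular, 5 meioses)
carry longer segments and fit smaller `a` than descendants of long loops
(second cousins, 8 meioses). Chains restart at stationarity on each
chromosome. Emissions: Hardy–Weinberg genotype probabilities in the
non-IBD state; {p, 0, 1−p} for hom-alt/het/hom-ref in the IBD state; both
mixed with a genotyping-error mass ε (default 0.001, fixed rather than
estimated — at desk scale ε is poorly identified jointly with `f`).
Missing calls emit 1 in both states. The forward pass is implemented in
C++ and verified against exhaustive hidden-path enumeration.

**Estimation.** `fit_festim()` maximises the likelihood over
f ∈ [1e−6, 0.5] and a ∈ [1e−3, 1]/cM from a 3×3 grid of starts, refining
the best starts with a bounded Nelder–Mead direct search in a
log-logistic-transformed parameter space (derivative-free search is robust
here because the profile surface is flat in `a` whenever f̂ ≈ 0; the
returned optimum is never below the best grid value, which is asserted in
tests). `f_median()` repeats the fit on 100 (by default) random sparse
submaps — random start, then greedy left-to-right acceptance of the next
marker more than 0.5 cM away — and reports the medians F-Median and
A-Median, which are robust to occasional degenerate submap fits.

**Allele frequencies.** Emission frequencies are estimated
leave-one-out within the individual's population (clamped away from 0/1).
With realistic population sizes (~25+ individuals) the residual noise
inflates F-Median by a few thousandths; harnesses that probe the
*statistical calibration* of downstream tests therefore may pass the known
generator frequencies instead.

**Inbred/outbred test.** A likelihood-ratio test on the consensus submap
(the one whose f̂ equals the per-submap median — deterministic and cheap):
stat = 2(logL₁ − logL₀) with logL₀ the f = 0 likelihood on the same
submap, referred to the boundary mixture ½χ²₀ + ½χ²₁. Because `a` is
unidentified under f = 0, the alternative effectively maximises over a
nuisance range, so this reference distribution is mildly
anti-conservative — a property of the test as formulated, not of the
optimiser (the forward likelihood is exact against enumeration). We report
rather than recalibrate: the test suite measures the empirical size over
200 outbred replicates, and `scripts/acceptance.R` writes the measured
type-I error for its own seed.

**Mating-type classification.** Reference clouds of (F-Median, A-Median)
are simulated per mating type with the generator. An individual flagged
outbred by the LRT is `OUT` directly (mirroring the two-step logic of the
field's pipelines); otherwise the point (F-Median, log10 A-Median) is
scored against a product-Gaussian kernel density of each inbred cloud and
the posterior is the normalised density under a uniform prior over
{AV, 2x1C, 1C, 2C}. `AV` and `2x1C` share the same expected F and differ
only through segment length, so confusion between them is expected;
validation therefore counts errors into adjacent types
(OUT↔2C↔1C↔{2x1C, AV}) separately from gross errors.

# Runs of homozygosity

`call_rohs()` is a sliding-window scanner in the PLINK style with the
scanner's widely used defaults: 50-SNP windows with at most 1 heterozygote
and 5 missing calls, a SNP is ROH material when more than 5% of covering
windows pass, and maximal runs qualify at ≥50 SNPs, ≥500 kb, at least one
SNP per 50 kb, and no gap above 1,000 kb. The original analyses name only
the calling program, so all parameters are exposed and recorded. ROH
analyses need marker spacing well below 50 kb; the test harnesses use a
6,000-SNP, 120-Mb panel (~20 kb spacing) rather than the default array
panel.

Two classifications are computed. *Fixed*: intermediate = 500–1,500 kb
(closed), long > 1,500 kb — the classical literature thresholds.
*Population-specific*: a three-component Gaussian mixture on log10 length
(unequal variances, EM to tolerance 1e−6, best of ten seeded restarts;
the EM log-likelihood trace is returned and its monotonicity asserted),
components ranked by mean define classes A/B/C, and boundaries are the
crossing points of adjacent weighted component densities located by
bisection between the means. Classes are closed on the upper class at a
boundary. A degenerate component (weight < 0.01) triggers a flagged
two-component refit. When the fitted boundaries are forced to the fixed
thresholds, both classifications agree segment by segment (a consistency
check in the tests).

The genomic excess of homozygosity is (O_hom − E_hom)/N over an
individual's non-missing sites, with E_hom summing
1 − 2p(1−p)·2n/(2n − 1), p the within-population alt frequency and 2n the
non-missing allele count at the site (the small-sample correction makes
the site-wise expected heterozygosity unbiased). Negative values mean
fewer homozygotes than panmixia predicts.

# Diversity statistics

Allele-sharing dissimilarity between two individuals is
1 − (shared alleles)/(2 × overlapping sites) with 2 − |g₁ − g₂| shared
alleles per site and pairwise-complete handling of missing data. Relative
pairs are excluded with a method-of-moments kinship estimate (centred
genotype products scaled by total heterozygosity — the simplest auditable
choice; no IBS0 refinement) and greedy removal of the individual in the
most over-threshold pairs (first-cousin kinship 1/16 plus a 0.02 noise
allowance by default; ties broken by sample id). Haplotypic
heterozygosity is the unbiased estimator n/(n−1)(1 − Σp²ₕ) over distinct
block haplotypes within maximal runs of ≥5 consecutive SNPs whose local
recombination rate is below 0.5 cM/Mb, averaged per autosome and then
across autosomes. The exact block rule and estimator of the original
ascertainment-bias-robust statistic are not fully specified in the
literature this mirrors, so both are parameters; and because the statistic
needs phase, it is defined on simulator haplotypes — real-data phasing is
out of scope, which is the main caveat when transferring conclusions to
real data.

# Comparison layer

`mwu()` computes the Mann–Whitney U test with an exact, tie-aware
permutation distribution of the rank sum whenever n_x·n_y ≤ 400 (dynamic
programming over doubled average ranks; doubling makes tied rank sums
integer) and a tie-corrected normal approximation with continuity
correction otherwise. `spearman()` uses average ranks, exact permutation
p-values for n ≤ 8 and the t approximation beyond. `chi2_yates()` wraps
the standard Yates-corrected 2×2 test. All exact paths are tested against
brute-force enumeration. Raw p-values are reported throughout (a
Benjamini–Hochberg column can be added by the user; it never gates
conclusions here). One-tailed directions are always explicit arguments,
never inferred from the data.

`exogamy_inbreeding_report()` joins inbreeding measures (F-Median and,
when supplied, class-C ROH count and total length) to parental couple
distances, bins individuals into the four distance classes, compares each
exogamous class to the endogamous `<4` class with the Mann–Whitney test,
and correlates each measure with log10 distance among exogamous
descendants. "Percent inbred" is reported both as F-Median > 0 and as
LRT-inbred.

# Validation scales and what they show

The acceptance suite runs, per block: exact-likelihood checks (<1 s);
F-Median recovery on 100 simulated offspring per mating type at the
default 5,000-SNP panel with 15 submaps each; LRT size over 200 outbred
replicates and power over 60 sib-mating replicates; classification
confusion over 100 individuals per type against 60-simulation reference
clouds with 12 submaps; ROH/ground-truth agreement over a 60-individual
mixed cohort on a 12,000-SNP, 240-Mb dense panel; mixture recovery on
planted three-lognormal lengths; threshold and rate recovery at 400
couples; and the bell-shape design with 10 planted seeds (100 individuals,
8 submaps) plus 20 cheaper null seeds (60 individuals, 5 submaps — the
null arm checks a rate, so replicate count matters more than per-seed
power). Submap counts below the 100-submap default trade a little
per-individual precision for runtime; medians over cohorts are unaffected
well within the stated tolerances. Passing these simulations shows the
estimators track their own generative model; it does not certify
performance on real arrays, where LD between markers, genotyping batch
effects and population structure (none of which the generator emulates
beyond an optional LD knob) will add bias that must be assessed per
dataset.

# Known limitations

* Phased-haplotype statistics rely on simulator phase; no phasing of real
  data.
* The LRT reference distribution is mildly anti-conservative (see above);
  treat "percent inbred by LRT" as slightly optimistic, the more so the
  smaller the population used for leave-one-out frequencies.
* The five-way classifier cannot separate `AV` from `2x1C` reliably — they
  share expected F and differ only in segment length.
* Only text PED/MAP I/O; binary PLINK, VCF and liftover are out of scope.
* The genome build / genetic map is never assumed: a map is a required
  input.
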