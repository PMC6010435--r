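# steppekin

Tools for asking a simple question with awkward data requirements: **does
marrying someone born far away actually reduce inbreeding?** In many human
populations spouses are chosen across village boundaries (geographical
exogamy), which is usually assumed to work as an inbreeding-avoidance
mechanism. Testing that assumption needs, for the same individuals, (i)
birthplace coordinates for themselves, their spouse and their parents, and
(ii) genome-wide genotypes from which individual inbreeding can be
measured. `steppekin` implements the full analysis pipeline for such
paired survey + SNP-array data, and — because real datasets of this kind
are access-restricted — a pedigree-based simulator with exact ground truth
against which every stage is validated.

## What it computes

* **Geographical exogamy** (`haversine_km`, `couple_distances`,
  `kde_log_distance`, `find_exogamy_threshold`, `exogamy_rate`,
  `distance_class`): great-circle distances between spousal birthplaces,
  a data-driven endogamy/exogamy threshold at the antimode of the
  log-distance kernel density (bandwidth 0.2 on log10 km), per-population
  exogamy rates, and the `<4 / 4-20 / 20-40 / >40` km parental-distance
  classes.
* **Inbreeding coefficients** (`hmm_loglik`, `fit_festim`, `f_median`,
  `lrt_inbred`, `estimate_inbreeding`): a two-state identity-by-descent
  hidden Markov model. `f` is the probability a marker is autozygous; `a`
  (per cM) the IBD-segment turnover rate; transitions over `d` cM are
  P(IBD→IBD) = e^(−a·d) + (1 − e^(−a·d))·f, P(non→IBD) = (1 − e^(−a·d))·f,
  with Hardy–Weinberg vs {p, 0, 1−p} emissions and error rate ε. The fit
  is repeated over 100 sparse submaps (markers > 0.5 cM apart) and the
  medians **F-Median** / **A-Median** are reported, plus a boundary
  likelihood-ratio test for inbred status and a five-way parental
  mating-type classification (AV, 2x1C, 1C, 2C, OUT) against simulated
  reference clouds.
* **Runs of homozygosity** (`call_rohs`, `classify_fixed`,
  `fit_length_mixture`, `classify_population`, `excess_homozygosity`):
  PLINK-style sliding-window ROH calling; classification by the classical
  500–1,500 / >1,500 kb thresholds and by per-population three-component
  Gaussian mixtures on log10 length (classes A/B/C); and the genomic
  excess of homozygosity relative to panmixia.
* **Diversity** (`asd_matrix`, `pairwise_kinship`, `exclude_relatives`,
  `low_recombination_blocks`, `block_haplotype_heterozygosity`):
  allele-sharing dissimilarity, kinship-based relative exclusion and
  haplotypic heterozygosity over low-recombination blocks.
* **Comparisons** (`mwu`, `spearman`, `chi2_yates`,
  `regress_confounders`, `exogamy_inbreeding_report`,
  `population_correlates`): exact-when-small rank tests and the
  distance-binned exogamy-versus-inbreeding report.
* **Synthetic data** (`make_snp_panel`, `simulate_founders`,
  `pedigree_spec`, `gene_drop`, `simulate_cohort`,
  `add_genotype_errors`): gene dropping through canonical consanguineous
  pedigrees with exact autozygous tracks, bimodal spousal-distance
  geography, and optional kinship endogamy planted in a distance band.

I/O: PLINK text PED/MAP (`read_ped_map` / `write_ped_map`), a
whitespace-separated genetic map (`read_genetic_map`), survey CSVs
(`read_survey`).

## Worked example

```r
library(steppekin)

# a 2-population cohort with known ground truth
coh <- simulate_cohort(n_per_pop = 27, populations = 2, seed = 42)

# exogamy: couple distances, threshold, rates
cur <- couple_distances(coh$survey, "current")
th  <- find_exogamy_threshold(kde_log_distance(cur$distance_km))
round(as.numeric(th), 2)
#> [1] 4.57
prof <- exogamy_rate(cur, threshold_km = 4)
round(attr(prof, "overall")$exogamy_rate, 2)
#> [1] 0.54

# per-individual inbreeding (F-Median + LRT)
fits <- estimate_inbreeding(coh$genotypes, coh$truth$population_code,
                            n_submaps = 25, seed = 1)
round(median(fits$F_Median[coh$truth$mating_type == "2C"]), 3)
#> [1] 0.031
round(median(fits$F_Median[coh$truth$mating_type == "OUT"]), 3)
#> [1] 0.013

# distance-binned inbreeding comparison
rep <- exogamy_inbreeding_report(coh$survey, fits, measures = "F_Median")
rep$bin_table[, c("distance_class", "n", "median", "mwu_p_vs_endogamous")]
#>   distance_class  n     median mwu_p_vs_endogamous
#> 1             <4 23 0.01559822                  NA
#> 2           4-20 10 0.01803713           0.4050882
#> 3          20-40 13 0.01738821           0.1721027
#> 4            >40  8 0.01805827           0.1183430
```

The detected threshold lands near 4 km because the simulated distance
distribution is bimodal (an endogamous mass near 0 km and a lognormal
exogamous tail), and the exogamy rate recovers the generator's endogamous
fraction (0.5). The second-cousin median F-Median (0.031) sits above the
outbred median (0.013), both inflated by a constant few thousandths
because allele frequencies are estimated leave-one-out from only 27
individuals per population — at this panel size that noise floor is
expected (see the methods vignette; with larger populations or known
frequencies the outbred median drops below 0.01). With the default
generator, where mating type is independent of distance, no distance class
is significantly more inbred than the endogamous one, as expected.

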