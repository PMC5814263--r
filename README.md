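# clonevo

Mutation dynamics between matched diagnosis and relapse tumor specimens
from targeted deep sequencing. The package is aimed at analysts of paired
tumor cohorts (e.g. primary and first-recurrence glioblastoma) who want to
ask, from variant call tables alone: did treatment leave a footprint in
the clonal composition of the recurrence?

It provides, as one pipeline or as standalone functions:

* the variant-retention filter chain used for high-depth panel data
  (caller p < 0.05, Q ≥ 20, depth > 100, alt reads ≥ 50, VAF ≥ 8%,
  population MAF ≤ 5%, cross-patient artifact exclusion at > 50% of
  patients);
* shared/private partitioning of each patient's diagnosis and relapse
  variant sets, burden summaries, TP53-stratified VAF counts, and Grubbs'
  outlier test;
* pyrimidine-collapsed mutational spectra with dinucleotide context for
  C>T transitions, and temozolomide-hypermutator calling;
* methylation-based tumor purity (LUMP: `purity = min(1, mean(beta)/0.85)`
  over leukocyte-unmethylated CpG sites), MGMT promoter methylation calls,
  a 55% purity gate, and VAF purity adjustment;
* the neutral-evolution test: under neutral growth the cumulative count of
  subclonal mutations is linear in inverse allele frequency,

  M(f) = (μ/β) (1/f − 1/f_max),

  fitted by zero-intercept least squares on purity-adjusted VAFs in the
  window (0.10, 0.25), with R² > 0.98 (strict) declaring neutrality —
  `fit_neutral_model()` returns a classed model object with `print`,
  `summary`, `coef`, `predict`, `plot` and `residuals` methods;
* a branching-process tumor simulator (`simulate_tumor()`,
  `simulate_cohort()`) that generates full paired cohorts — neutral 1/f
  spectra, selection events, treatment bottlenecks, sequencing noise,
  normal-cell contamination, TMZ-signature injection, and methylation
  tables consistent with configured purity — so every stage is testable
  without external data.

## Worked example

Simulate a 10-patient paired cohort (2 untreated controls, one
injection-configured hypermutator) and run the full pipeline:

```r
library(clonevo)

cohort  <- simulate_cohort(cohort_sim_config(n_patients = 10,
                                             fraction_untreated = 0.2,
                                             seed = 17))
summary <- run_pipeline(pipeline_config(cohort))
summary
#> <pipeline_summary> 20 samples, 10 pairs
#>   pooled diagnosis: R² = 0.9948 (neutral), n = 482
#>   pooled relapse: R² = 0.9390 (non_neutral), n = 1828
#>   paired shift: R² decreased in 7 of 10 pairs
```

Read collectively, the diagnosis samples follow the neutral 1/f law
(pooled R² = 0.9948 > 0.98 over 482 subclonal variants), the relapse pool
does not (0.9390), and the per-patient fits shifted downward in 7 of 10
pairs — the signature of treatment-mediated selection that the simulated
treated bottlenecks planted. The injected hypermutator is recovered by its
relapse-specific C>T/CpC+CpT excess:

```r
vapply(summary$hypermutator, `[[`, "", "decision")
#> ...  P10 
#> ... "positive"   # the injection-configured patient, and only that one
```

Single-sample fits behave like ordinary model objects:

```r
tum <- simulate_tumor(simulation_config(seed = 1))
fit <- fit_neutral_model(subclonal_window(
         sample_reads(tum, depth = 1000, purity = 1)$variants$vaf))
fit
#> Neutral-evolution 1/f fit (sample)
#>   n = 62 subclonal variants
#>   slope (mu/beta): 11.8
#>   R-squared: 0.9081
#>   classification: non_neutral (R^2 > 0.98, n >= 2)
```

The slope estimates the effective mutation rate per effective division
(the generator's μ/β is 10 here); the R² of 0.91 on a *truly neutral*
simulated tumor illustrates why single-sample fits in a narrow subclonal
window rarely clear the strict 0.98 rule even under neutrality — only a
handful of lineages span cell fractions 0.2–0.5 — whereas pooled fits
across patients do. See the methods vignette
(`vignettes/clonal-dynamics.Rmd`) for the model and this caveat in full.

Clinical metadata tables are summarised per treatment group; on the
shipped 21-patient cohort table:

```r
md <- read_cohort_metadata(system.file("extdata", "cohort1_clinical.tsv",
                                       package = "clonevo"))
clinical_summary(md)
#>   treatment  n median_time_to_recurrence_months median_survival_months
#> 1   treated 18                                9                  16.15
#> 2 untreated  3                                3                  13.80
```

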