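---
title: "Mutation dynamics in paired primary and recurrent tumors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation dynamics in paired primary and recurrent tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonevo)
```

clonevo analyses targeted deep-sequencing variant calls from matched
diagnosis and relapse tumor specimens. This vignette is the package's
account of the science it implements: the models, the parameters that
matter, what the synthetic cohort generator does and does not emulate, and
the design decisions that were genuinely open.

## The analysis pipeline

The pipeline runs in a fixed order:

1. **Per-variant quality filters** — keep a call iff the caller p-value is
   below 0.05, the Phred quality is at least 20, coverage exceeds 100
   reads, at least 50 reads support the alternate allele, and the VAF is at
   least 8%. Calls with a recorded 1000-genomes minor allele frequency
   above 5% are removed as probable germline polymorphisms; a variant with
   *no* recorded MAF is kept (absence of evidence of commonness is not
   treated as commonness). Each boundary follows the wording it was stated
   with: "at least" is inclusive, "greater than" exclusive.
2. **Cohort-level artifact exclusion** — a variant key
   (chromosome, position, ref, alt) seen in more than 50% of *patients*
   (a patient with the key at both timepoints counts once) is removed
   everywhere as a probable platform artifact. Whether this step runs
   before or after the per-variant filters is not dictated by the method;
   clonevo applies the per-variant filters first so that the patient
   fraction is computed on confidently called variants.
3. **Purity estimation and gate** — tumor purity per sample, either from
   methylation (LUMP, below) or supplied externally; samples below 55%
   purity (equivalently above 45% normal contamination; the boundary is
   inclusive on the purity side) are excluded from the evolution analyses.
4. **VAF purity adjustment** — observed VAFs are divided by purity and
   capped at 1, a copy-neutral heterozygous diploid admixture model. The
   correction formula is an assumption of this package: it ignores
   copy-number change at the variant locus, which is prominently wrong for
   amplified oncogenes; the subclonal window below limits, but does not
   remove, that exposure.
5. **Paired partitioning and burden** — variants are matched between a
   patient's two samples by the position-level key; annotations never
   enter identity. (Matching at amino-acid level would merge distinct
   nucleotide changes with equal protein consequence; the position-level
   key is the stricter, more conservative choice.)
6. **Mutational spectrum and hypermutator calls** on unique-to-relapse
   variants.
7. **Neutral-evolution fits** per sample and pooled per timepoint, then
   the paired diagnosis-to-relapse shift summary.

## The neutral-evolution test

Under neutral exponential growth the cumulative number of subclonal
mutations with allele frequency at least $f$ is linear in inverse
frequency:

$$M(f) \;=\; \frac{\mu}{\beta}\left(\frac{1}{f} - \frac{1}{f_{max}}\right),$$

where $\mu$ is the mutation rate per effective division and $\beta$ the
effective division fraction. clonevo fits $M$ on
$x = 1/f - 1/f_{max}$ by zero-intercept least squares
($\hat{\text{slope}} = \sum xM / \sum x^2$) and reports
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean of $M$, so a
fit worse than a flat line is negative. A sample is classified *neutral*
when $R^2 > 0.98$, strictly; ties at the threshold are non-neutral.

Key parameter choices:

* **Subclonal window** $(f_{min}, f_{max}) = (0.10, 0.25)$ on
  purity-adjusted VAFs, strict on both sides: frequencies at or below 0.10
  are unreliably detected even at high depth, and frequencies at or above
  0.25 approach clonal heterozygous variants (0.5) where ploidy and
  germline leakage confound the spectrum. For sparse external datasets a
  lower-bound-inclusive reading and a minimum of 12 window variants are
  available (`inclusive_lower`, `min_variants = 12`).
* **Evaluation of M(f)** — by default the curve is evaluated on a fixed
  grid of 100 equally spaced $x$ values spanning the window (the canonical
  binned form of the test). Evaluating at the observed frequencies instead
  (`mf_eval = "observed"`) concentrates the regression points on tied
  mutation clusters: mutations born on the same genealogical branch share a
  frequency exactly, so observed-point evaluation is markedly noisier on
  finite tumors. The observed form remains the right choice when a data
  set is constructed to satisfy the law exactly, and is what
  `cumulative_mf()` returns by default for display.
* **Minimum variants** — per-sample fits are reported whatever the count;
  with fewer than 10 variants the fit is refitted dropping each variant in
  turn and flagged if any single removal changes the classification.
* **Pooled (collective) fits** concatenate the window VAFs of many
  samples before fitting. Pooling across patients averages over
  independent genealogies, which is why collective fits routinely clear
  the 0.98 threshold while individual samples — carried by a handful of
  lineages each — rarely do (see "what passing tests show" below).

Degenerate inputs: an empty window, a single variant, or all-tied $x$
values classify as *insufficient*; the slope is clamped at zero from
below; $R^2$ is undefined (NA) when $M$ is constant.

## Purity from methylation, and MGMT

**LUMP** (leukocytes unmethylation for purity): tumor purity is estimated
as `min(1, mean(beta) / 0.85)` over a panel of CpG sites that are
unmethylated in leukocytes, using only panel probes whose detection
p-value is below 0.05. The panel identity is array- and study-specific and
must be supplied for real data; the package ships a 44-probe *synthetic*
placeholder panel (`default_lump_panel()`) used by the simulator and the
test suite. The 0.85 scale constant is the conventional mean beta of the
panel in pure tumor tissue and is configurable.

**MGMT promoter methylation** is called conjunctively: the sentinel probe
cg12981137 must exceed beta 0.2 *and* the mean beta over the promoter
probe set must exceed 0.2 (both strict). A missing sentinel (or an empty
promoter set) yields *indeterminate* rather than a guess. The 12 promoter
probe ids shipped as defaults are synthetic placeholders, like the LUMP
panel.

## The temozolomide signature and hypermutator calls

Substitutions are collapsed to the pyrimidine strand (C>A, C>G, C>T, T>A,
T>C, T>G), so C>T and G>A transitions are one class. For C>T transitions
the dinucleotide context is written 5'→3' with the mutated cytosine first
(CpN): "CpC and CpT" means the base 3' of the mutated C is C or T. For a
variant reported on the purine strand the 5' neighbour is complemented.
The alternative convention (5' neighbour of the pyrimidine) is available
behind `convention = "5prime"`; the CpN reading was chosen because the
four Cp\* contexts are the natural enumeration for this signature.

A patient is called a temozolomide hypermutator when, among
unique-to-relapse SNVs (at least 10, else *insufficient*), the C>T
fraction reaches 0.60 and the CpC/CpT fraction among context-resolved C>T
transitions reaches 0.60. An additional requirement that the patient's
unique-to-relapse count be a Grubbs outlier of the cohort is available
(`require_burden_outlier`) but off by default: when relapse regrowth
passes through a severe treatment bottleneck, baseline unique-to-relapse
counts are heavy-tailed across patients and the outlier test loses power,
rejecting true hypermutators whose signature fractions are unambiguous;
the background C>T fraction (~1/6 under a uniform spectrum) is so far
below 0.60 that the signature fractions alone are highly specific. The
Grubbs test itself (`grubbs_test()`) is the standard two-sided
maximum-studentized-deviation test with the t-distribution critical value;
a one-sided variant is available.

## The synthetic cohort generator

`simulate_tumor()` grows a tumor as a discrete-generation branching
process: each generation every cell divides with probability
`div_prob = 0.5` (non-dividers persist), each daughter dies independently
with probability `death_prob` and acquires Poisson(`mu`) novel mutations.
The Bernoulli division step matters: with deterministic synchronous
division every clade fraction is an exact power of 1/2 and the frequency
spectrum a staircase; randomising division timing produces the continuum
of clade sizes on which the 1/f law rests. Growth stops at `n_final`
cells; a mutation's ground-truth cell fraction is its carrier count over
the final population.

Selection events `(size, s)` mark one random cell's lineage when the
population first reaches `size`; marked cells divide with probability
`min(1, div_prob (1+s))`. For the selection-sensitivity analyses the
trigger size is 20 cells (0.2% of the default `n_final`): growth-ratio
arithmetic shows an `s = 0.5` lineage triggered at that size reaches the
subclonal window by the end of growth, whereas lineages triggered at a few
hundred cells remain below the window and leave no imprint.

`sample_reads()` adds sequencing noise: per site the depth is
Poisson(`depth`, default 1272 to emulate high-depth targeted panels), the
alternate count Binomial(depth, purity × cell fraction / 2), and
undetected sites are simply absent from the call set.

`simulate_paired_case()` creates the matched relapse: survivors of a
bottleneck re-grow to `n_final` with new mutations. The bottleneck
severity is the treatment model: untreated post-surgical regrowth retains
bulk tumor (`bottleneck_fraction = 0.05`), while cytotoxic treatment
leaves few founder cells (`treated_bottleneck_fraction = 0.001`, ~10
founders), biased toward a resistant subclonal lineage that regrows with
advantage `relapse_selection_s = 1`. The few-founder regrowth is what
creates relapse-specific subclonal mutation clusters — the non-neutral
signature — because each founder's private mutation load rides at that
founder's clade frequency. A wide bottleneck merely rescales the diagnosis
spectrum and leaves the relapse effectively neutral, which is exactly what
the untreated control shows.

The designated hypermutator patient (by default the last) receives
`tmz_injection_count = 600` injected C>T mutations with CpC/CpT contexts
at cell fractions uniform on (0.2, 0.6) in the relapse. The count is sized
roughly six-fold above the typical treated baseline of unique-to-relapse
calls so that the injected patient's burden is an unambiguous cohort
outlier, mirroring the order-of-magnitude burden excess of the phenotype.

Cohort defaults emulate the study design the package targets: 21 patients
of whom 3 are untreated, per-sample purity uniform on (0.6, 0.95) so the
55% gate is exercised, methylation betas generated by inverting the LUMP
formula (recovery within ±0.02, with five panel probes failing detection
to exercise the informative-probe filter), and clinical intervals drawn
log-normally with medians near 9 months (treated) and 3 months
(untreated) time to recurrence.

**What the generator does not emulate.** Copy-number alteration (the
simulation is copy-neutral heterozygous diploid throughout), spatial
structure and regional sampling, germline leakage in tumor-only calling,
FFPE artifacts, explicit radiotherapy dose or cell-cycle models
(treatment is the biased-bottleneck + injection abstraction), and
realistic genome coordinates (positions are synthetic identifiers; the
artifact-exclusion step sees disjoint positions across patients).
Population size is also ~10^4 cells rather than ~10^9; relapse regrowth
at this scale produces more detectable relapse-private variants than
targeted sequencing of a real recurrence would show, so shared/unique
*proportions* in simulated cohorts should not be read as calibrated to
real tumors.

**What passing tests show — and do not.** A consequence of finite
single-tumor genealogies deserves emphasis: in the narrow (0.10, 0.25)
window, a tumor's spectrum is carried by roughly half a dozen lineages
(the expected number of clades with cell fraction at least $g$ scales as
$1/g$, independent of final population size). Per-sample $R^2$ for a truly
neutral simulated tumor therefore fluctuates around ~0.90–0.95 and only
rarely exceeds the strict 0.98 threshold, at any mutation rate, depth or
population size we examined — while pooled fits across independent
genealogies clear it comfortably. The package's seeded checks assert what
the model actually guarantees: slope recovery within 30% of $\mu/\beta$,
a strictly decreasing median $R^2$ with increasing selection strength,
a paired diagnosis-to-relapse decrease in at least 8 of 10 treated pairs
with no systematic shift in untreated controls, and pooled-fit neutrality.
A per-sample neutrality *rate* at the strict threshold is not a property
this class of generative model can deliver, and high per-sample $R^2$ on
real data should likewise be interpreted against this baseline.

## Numerical and reproducibility choices

* Problem sizes for the seeded analyses: tumors of $10^4$ cells with
  mutation rate 10 per daughter per division (about 50–60 window variants
  per sample at depth 1000 and purity 1), cohorts of 10–21 patients, and
  20-seed panels for the recovery and sensitivity summaries.
* Every stochastic component takes a seed; identical configuration and
  seed reproduce tumors, cohorts, written TSVs and report bundles
  byte-for-byte. Per-patient streams are derived from the cohort seed, so
  patient k is reproducible without simulating patients 1..k−1.
* Reports store full-precision numbers; display rounding ($R^2$ to 4
  decimals, percentages to whole numbers) is applied only in the
  human-readable table, never before comparison or storage.
* Medians of even-sized groups use the midpoint convention, matching how
  clinical summary medians are conventionally reported.
* The TSV dialect writes numerics with 17 significant digits so that a
  write/read round-trip is bit-exact.

## Known limitations

The VAF purity adjustment assumes copy-neutral diploidy; the LUMP scale
constant and probe panels are configurable stand-ins; the neutral test is
a goodness-of-fit classification, not an inference of selection strength
(no Bayesian or frequency-spectrum alternatives are provided); and the
generator's treatment abstraction collapses radiotherapy and chemotherapy
into one bottleneck-plus-selection event. Mean variant burdens and
shared/unique proportions reported by the paired-comparison module on
simulated cohorts reflect the generator's scaled-down geometry, not
calibrated expectations for real tumors.
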