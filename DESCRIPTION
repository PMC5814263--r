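Package: clonevo
Title: Clonal Evolution Dynamics in Paired Primary and Recurrent Tumors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of mutation dynamics between matched diagnosis and
    relapse tumor specimens profiled by targeted deep sequencing. Provides
    the variant-retention filter chain used for high-depth panel data,
    shared/private burden partitioning of paired samples, pyrimidine-collapsed
    mutational spectra with dinucleotide-context analysis and
    temozolomide-hypermutator calling, methylation-based tumor purity (LUMP)
    and MGMT promoter methylation calls, and a test of neutral tumor
    evolution based on the linearity of the cumulative subclonal mutation
    distribution M(f) against the inverse allele frequency 1/f, fitted as a
    zero-intercept regression and classified by an R-squared threshold. A
    branching-process tumor simulator generates paired cohorts with treatment
    bottlenecks, sequencing noise, normal-cell contamination and
    temozolomide-signature injection so the whole pipeline can be exercised
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
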