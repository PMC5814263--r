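# The branching-process tumor generator, read sampling, paired cases and
# cohort output.

test_that("a zero mutation rate yields a tumor without mutations", {
  tum <- simulate_tumor(simulation_config(n_final = 500, mu = 0, seed = 1))
  expect_equal(nrow(tum$mutations), 0)
  expect_gte(tum$n_cells, 500)
})

test_that("identical configuration and seed reproduce the tumor exactly", {
  cfg <- simulation_config(n_final = 2000, mu = 5, seed = 123)
  t1 <- simulate_tumor(cfg)
  t2 <- simulate_tumor(cfg)
  expect_identical(t1$mutations, t2$mutations)
  expect_identical(t1$n_cells, t2$n_cells)
})

test_that("carrier counts are conserved down the clone tree", {
  tum <- simulate_tumor(simulation_config(n_final = 2000, mu = 3, seed = 7))
  counts <- tum$tree$counts
  parent <- tum$tree$parent
  kids <- which(parent > 0L)
  # every child's carrier count is at most its parent's
  child_sum <- tapply(counts[kids], parent[kids], sum)
  expect_true(all(counts[kids] <= counts[parent[kids]]))
  # cell fractions are fractions of the final population
  expect_true(all(tum$mutations$cell_fraction > 0 &
                    tum$mutations$cell_fraction <= 1))
  # no child clade can exceed its parent clade in total
  expect_true(all(child_sum <= counts[as.integer(names(child_sum))] |
                    counts[as.integer(names(child_sum))] == 0))
})

test_that("read sampling follows the diploid admixture expectation", {
  flat_tumor <- function(cf, n) {
    structure(list(
      mutations = cbind(
        data.frame(id = seq_len(n), node = NA, cell_fraction = cf,
                   origin = "growth", stringsAsFactors = FALSE),
        clonevo:::make_mutation_annotations(n, rep(1 / 6, 6))),
      n_cells = 1000, generations = 1,
      config = simulation_config(n_final = 1000)), class = "simulated_tumor")
  }
  set.seed(5)
  # purity 0.5, cell fraction 0.4 -> expected VAF 0.10
  sc <- sample_reads(flat_tumor(0.4, 4000), depth = 1000, purity = 0.5)
  expect_equal(mean(sc$variants$vaf), 0.10, tolerance = 0.003)
  # clonal heterozygous at purity 1 -> VAF 0.5
  sc2 <- sample_reads(flat_tumor(1, 500), depth = 5000, purity = 1)
  expect_equal(mean(sc2$variants$vaf), 0.5, tolerance = 0.005)
  # zero-depth and zero-alt sites are not reported
  expect_true(all(sc$variants$depth > 0 & sc$variants$alt_reads > 0))
  expect_true(all(sc$variants$alt_reads <= sc$variants$depth))
})

test_that("a full bottleneck with no regrowth reproduces the diagnosis tumor", {
  cfg <- cohort_sim_config(n_patients = 1, fraction_untreated = 1,
                           bottleneck_fraction = 1, n_final = 2000,
                           purity_range = c(0.9, 0.9), depth = 2000, seed = 77)
  sc <- simulate_paired_case(cfg, 1)
  dxv <- sc$case$diagnosis$variants
  relv <- sc$case$relapse$variants
  # confidently detected diagnosis variants persist at comparable VAFs
  strong <- dxv[dxv$vaf >= 0.15, ]
  found <- match(strong$pos, relv$pos)
  expect_gte(mean(!is.na(found)), 0.95)
  expect_gt(cor(strong$vaf[!is.na(found)], relv$vaf[found[!is.na(found)]]),
            0.9)
})

test_that("untreated patients receive no injected mutations and treated hypermutators do", {
  cfg <- cohort_sim_config(n_patients = 2, fraction_untreated = 0.5,
                           hypermutator_patients = 2L, n_final = 3000,
                           seed = 11)
  untr <- simulate_paired_case(cfg, 1)
  expect_length(untr$truth$injected_ids, 0)
  expect_false(untr$truth$treated)

  hyp <- simulate_paired_case(cfg, 2)
  expect_length(hyp$truth$injected_ids, cfg$tmz_injection_count)
  # injection accounting: the detected relapse-unique C>T excess reflects
  # most of the injected mutations
  part <- partition_shared_unique(hyp$case)
  relv <- hyp$case$relapse$variants
  uniq <- relv[variant_keys(hyp$case$relapse) %in% part$unique_relapse, ]
  ct <- spectrum_counts(uniq)$classes[["C>T"]]
  expect_gte(ct, 0.8 * cfg$tmz_injection_count)
  # and injected contexts resolve to CpC/CpT
  inj <- uniq[uniq$pos %in% hyp$truth$injected_pos, ]
  ctx <- dinucleotide_context(inj$ref, inj$alt, inj$context_5p, inj$context_3p)
  expect_true(all(ctx %in% c("CpC", "CpT")))
})

test_that("cohort simulation is reproducible byte-for-byte and writes readable files", {
  cfg <- cohort_sim_config(n_patients = 3, fraction_untreated = 1 / 3,
                           n_final = 1500, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- simulate_cohort(cfg, dir = d1)
  co2 <- simulate_cohort(cfg, dir = d2)
  for (f in c("variants.tsv", "metadata.tsv", "methylation.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # the written dialects read back to the simulated objects
  samples <- read_variant_table(file.path(d1, "variants.tsv"))
  expect_setequal(names(samples), names(co1$samples))
  expect_identical(samples[[1]]$variants[, c("pos", "vaf", "depth")],
                   co1$samples[[names(samples)[1]]]$variants[, c("pos", "vaf", "depth")])
  md <- read_cohort_metadata(file.path(d1, "metadata.tsv"))
  expect_equal(sum(md$treatment == "untreated"), 1)
  profs <- read_methylation_table(file.path(d1, "methylation.tsv"))
  expect_length(profs, 6)
})

test_that("emitted methylation betas recover the configured purity via LUMP", {
  cfg <- cohort_sim_config(n_patients = 2, fraction_untreated = 0,
                           n_final = 1500, purity_range = c(0.70, 0.70),
                           seed = 19)
  co <- simulate_cohort(cfg)
  for (sid in names(co$methylation)) {
    est <- lump_purity(co$methylation[[sid]])
    expect_equal(est$n_probes_used, 39)
    expect_equal(est$purity, 0.70, tolerance = 0.02)
  }
})

test_that("the untreated fraction controls metadata group sizes", {
  cfg <- cohort_sim_config(n_patients = 10, fraction_untreated = 0.2,
                           n_final = 1000, seed = 3)
  co <- simulate_cohort(cfg)
  md <- co$metadata
  untreated <- md$treatment_prior_to_second_surgery == "none"
  expect_equal(sum(untreated), 2)
  expect_equal(nrow(md), 10)
})

test_that("neutral growth recovers the expected 1/f slope within 30 percent", {
  panel <- neutral_panel()
  expect_gte(median(panel[, "n"]), 40)
  target <- expected_slope(simulation_config())
  expect_lt(abs(median(panel[, "slope"]) - target) / target, 0.30)
})

test_that("a strongly selected lineage lowers the median window r-squared", {
  r2_neutral <- selection_median_r2(0)
  r2_selected <- selection_median_r2(1)
  expect_lt(r2_selected, r2_neutral)
})

test_that("an unbiased bottleneck leaves the paired r-squared shift non-systematic", {
  sm <- shift_cohort_summary("control")
  expect_equal(sm$paired_shift$n_pairs, 10)
  expect_gt(sm$paired_shift$sign_test_p, 0.05)
})
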