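# Shared/private partitioning, burden summaries, TP53 stratification,
# Grubbs outliers, validation arithmetic and clinical summaries.

test_that("partition follows set algebra on variant keys", {
  case <- make_pair(pos_sample(c(1, 2, 3))$variants,
                    pos_sample(c(2, 3, 4))$variants)
  p <- partition_shared_unique(case)
  expect_setequal(p$shared, c("chr1:2:C:T", "chr1:3:C:T"))
  expect_setequal(p$unique_diagnosis, "chr1:1:C:T")
  expect_setequal(p$unique_relapse, "chr1:4:C:T")

  same <- make_pair(pos_sample(1:3)$variants, pos_sample(1:3)$variants)
  ps <- partition_shared_unique(same)
  expect_length(ps$shared, 3)
  expect_length(ps$unique_diagnosis, 0)

  disjoint <- make_pair(pos_sample(1:3)$variants, pos_sample(4:6)$variants)
  expect_length(partition_shared_unique(disjoint)$shared, 0)
})

test_that("partition is symmetric under swapping timepoints", {
  set.seed(3)
  for (rep in 1:10) {
    a <- sample(1:30, sample(5:15, 1))
    b <- sample(1:30, sample(5:15, 1))
    fwd <- partition_shared_unique(make_pair(pos_sample(a)$variants,
                                             pos_sample(b)$variants))
    rev <- partition_shared_unique(make_pair(pos_sample(b)$variants,
                                             pos_sample(a)$variants))
    expect_setequal(fwd$shared, rev$shared)
    expect_setequal(fwd$unique_diagnosis, rev$unique_relapse)
    expect_setequal(fwd$unique_relapse, rev$unique_diagnosis)
  }
})

test_that("burden summary counts match hand-computed means and respect restriction", {
  # 5 patients with known partitions; 3 treated, 2 untreated
  sizes <- list(c(2, 1, 1), c(3, 0, 2), c(1, 2, 0), c(4, 1, 1), c(0, 3, 3))
  cohort <- lapply(seq_along(sizes), function(i) {
    sz <- sizes[[i]]
    shared <- seq_len(sz[1]); ud <- 100 + seq_len(sz[2]); ur <- 200 + seq_len(sz[3])
    make_pair(pos_sample(c(shared, ud))$variants,
              pos_sample(c(shared, ur))$variants,
              patient_id = sprintf("P%d", i),
              treatment = if (i <= 3) "treated" else "untreated")
  })
  tab <- burden_summary(cohort)
  expect_equal(tab$n_diagnosis, c(3, 3, 3, 5, 3))
  expect_equal(tab$n_relapse, c(3, 5, 1, 5, 3))
  expect_equal(tab$n_diagnosis, tab$shared + tab$unique_diagnosis)
  expect_equal(tab$n_relapse, tab$shared + tab$unique_relapse)
  means <- attr(tab, "group_means")
  expect_equal(means$n_diagnosis[means$treatment == "treated"], mean(c(3, 3, 3)))
  expect_equal(means$unique_relapse[means$treatment == "untreated"],
               mean(c(1, 3)))

  # consequence restriction drops the synonymous variant from all counts
  dx <- rbind(variant_row(pos = 1, consequence = "nonsynonymous"),
              variant_row(pos = 2, consequence = "synonymous"))
  rel <- variant_row(pos = 1, consequence = "nonsynonymous")
  tab2 <- burden_summary(list(make_pair(dx, rel)),
                         consequence_subset = c("nonsynonymous", "splice_site"))
  expect_equal(tab2$n_diagnosis, 1)
  expect_equal(tab2$shared, 1)
})

test_that("TP53 status requires nonsynonymous plus damaging prediction", {
  hit <- make_sample(variant_row(gene = "TP53", consequence = "nonsynonymous",
                                 damaging_pred = TRUE))
  expect_identical(classify_tp53_status(hit), "mutant")
  syn <- make_sample(variant_row(gene = "TP53", consequence = "synonymous"))
  expect_identical(classify_tp53_status(syn), "wildtype")
  benign <- make_sample(variant_row(gene = "TP53", consequence = "nonsynonymous",
                                    damaging_pred = FALSE))
  expect_identical(classify_tp53_status(benign), "wildtype")
  expect_identical(classify_tp53_status(benign, require_damaging = FALSE),
                   "mutant")
})

test_that("VAF stratification puts the 0.4 boundary in the high bin", {
  dx <- rbind(variant_row(pos = 1, vaf = 0.1, depth = 1000, alt_reads = 100),
              variant_row(pos = 2, vaf = 0.4, depth = 1000, alt_reads = 400),
              variant_row(pos = 3, vaf = 0.9, depth = 1000, alt_reads = 900),
              variant_row(pos = 4, vaf = 0.39, depth = 1000, alt_reads = 390,
                          ref = "AT", alt = "A"))  # indel: not an SNV
  case <- make_pair(dx, variant_row(pos = 1, vaf = 0.39, depth = 1000,
                                    alt_reads = 390))
  tab <- vaf_stratified_counts(case)
  expect_equal(tab$low_vaf[tab$timepoint == "diagnosis"], 1)
  expect_equal(tab$high_vaf[tab$timepoint == "diagnosis"], 2)
  expect_equal(tab$n_snv[tab$timepoint == "diagnosis"], 3)
  expect_equal(tab$low_vaf[tab$timepoint == "relapse"], 1)
  expect_equal(tab$low_vaf + tab$high_vaf, tab$n_snv)
})

test_that("Grubbs test matches the explicit t-quantile formula", {
  g <- grubbs_test(c(10, 11, 12, 10, 11, 50))
  o <- grubbs_oracle(c(10, 11, 12, 10, 11, 50))
  expect_equal(g$statistic, o$G)
  expect_equal(g$critical, o$crit)
  expect_equal(g$outlier_index, 6L)

  # maximal-concentration pattern: G attains (n-1)/sqrt(n) and exceeds the
  # critical value, so the single deviant IS flagged
  g2 <- grubbs_test(c(5, 5, 5, 5, 6))
  o2 <- grubbs_oracle(c(5, 5, 5, 5, 6))
  expect_equal(g2$statistic, o2$G)
  expect_true(o2$outlier)
  expect_equal(g2$outlier_index, 5L)

  expect_error(grubbs_test(c(1, 1, 1)), "zero variance")
  expect_error(grubbs_test(c(1, 2)), "at least 3")
})

test_that("Grubbs agrees with the oracle on 100 random vectors", {
  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(sample(4:25, 1), sd = runif(1, 0.5, 5))
    if (sample(c(TRUE, FALSE), 1)) x[1] <- x[1] + sample(0:20, 1)
    g <- grubbs_test(x)
    o <- grubbs_oracle(x)
    expect_equal(g$statistic, o$G)
    expect_equal(g$critical, o$crit)
    expect_identical(!is.na(g$outlier_index), o$outlier)
  }
})

test_that("validation percentages reproduce pooled and per-class arithmetic", {
  assays <- data.frame(
    class = c(rep("SNV", 36), rep("INDEL", 10)),
    validated = c(rep(TRUE, 34), rep(FALSE, 2), rep(TRUE, 5), rep(FALSE, 5)))
  vs <- validation_summary(assays)
  expect_equal(vs$pooled$pct_whole, 85)
  expect_equal(vs$per_class$pct_whole[vs$per_class$class == "SNV"], 94)
  expect_equal(vs$per_class$pct_whole[vs$per_class$class == "INDEL"], 50)

  expect_equal(fraction_selected(138, 5357)$pct_1dp, 2.6)
  zero <- validation_summary(data.frame(class = rep("SNV", 10),
                                        validated = rep(FALSE, 10)))
  expect_equal(zero$pooled$pct, 0)
  expect_error(fraction_selected(1, 0), "positive")
})

test_that("clinical summary reproduces group sizes and midpoint medians", {
  md <- read_cohort_metadata(clinical_fixture_path())
  cs <- clinical_summary(md)
  expect_equal(cs$n[cs$treatment == "treated"], 18)
  expect_equal(cs$n[cs$treatment == "untreated"], 3)
  expect_equal(cs$median_time_to_recurrence_months[cs$treatment == "treated"], 9)
  expect_equal(cs$median_time_to_recurrence_months[cs$treatment == "untreated"], 3)
  # even-sized group median is the midpoint of the central pair
  surv <- sort(md$survival_months[md$treatment == "treated"])
  expect_equal(cs$median_survival_months[cs$treatment == "treated"],
               mean(surv[9:10]))
  # empty group yields NA, not an error
  cs2 <- clinical_summary(md[md$treatment == "treated", ])
  expect_true(is.na(cs2$median_survival_months[cs2$treatment == "untreated"]))
})
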