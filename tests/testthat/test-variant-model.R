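# Readers, writers and domain containers for variant, clinical and
# methylation tables.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tsv_header <- paste(c("sample_id", "patient_id", "timepoint", "chrom", "pos",
                      "ref", "alt", "vaf", "depth", "alt_reads", "qual",
                      "caller_p", "gene", "consequence", "pop_maf",
                      "context_5p", "context_3p", "damaging_pred"),
                    collapse = "\t")

test_that("a well-formed TSV parses into sample calls with typed records", {
  path <- write_tsv_lines(c(
    "# comment line",
    tsv_header,
    "S1\tP1\tdiagnosis\tchr1\t100\tC\tT\t0.25\t500\t125\t60\t0.001\tTP53\tnonsynonymous\t\tA\tG\tTRUE",
    "S1\tP1\tdiagnosis\tchr2\t200\tG\tA\t0.10\t800\t80\t50\t0.002\t\tsynonymous\t0.01\t\t\t",
    "S1\tP1\tdiagnosis\tchr3\t300\tA\tC\t0.50\t400\t200\t70\t0.0005\tPTEN\tintronic\t\tT\tT\tFALSE"
  ))
  out <- read_variant_table(path)
  expect_named(out, "S1")
  v <- out$S1$variants
  expect_equal(nrow(v), 3)
  expect_equal(v$pos, c(100, 200, 300))
  expect_equal(v$vaf, c(0.25, 0.10, 0.50))
  expect_true(is.na(v$pop_maf[1]))
  expect_equal(v$pop_maf[2], 0.01)
  expect_identical(v$damaging_pred, c(TRUE, NA, FALSE))
  expect_identical(v$context_5p, c("A", NA, "T"))
})

test_that("rows violating alt_reads <= depth are rejected with the line number", {
  path <- write_tsv_lines(c(
    tsv_header,
    "S1\tP1\tdiagnosis\tchr1\t100\tC\tT\t0.25\t100\t120\t60\t0.001\t\t\t\t\t\t"
  ))
  expect_error(read_variant_table(path), "line 2.*alt_reads \\(120\\) exceeds depth \\(100\\)")
})

test_that("malformed numeric fields and bad timepoints are rejected by line", {
  path <- write_tsv_lines(c(
    tsv_header,
    "S1\tP1\tdiagnosis\tchr1\t100\tC\tT\tnot_a_number\t500\t125\t60\t0.001\t\t\t\t\t\t"
  ))
  expect_error(read_variant_table(path), "line 2.*vaf")
  path2 <- write_tsv_lines(c(
    tsv_header,
    "S1\tP1\tprogression\tchr1\t100\tC\tT\t0.2\t500\t100\t60\t0.001\t\t\t\t\t\t"
  ))
  expect_error(read_variant_table(path2), "timepoint")
})

test_that("unknown consequence strings map to 'other' with a warning", {
  v <- variant_row(consequence = "missense_variant")
  expect_warning(s <- make_sample(v), "unknown consequence")
  expect_identical(s$variants$consequence, "other")
})

test_that("TSV round-trip reproduces every field exactly and parsing is order-independent", {
  set.seed(11)
  v <- do.call(rbind, lapply(1:25, function(i) {
    variant_row(pos = i, ref = sample(c("A", "C", "G", "T"), 1),
                alt = "N", vaf = runif(1), depth = rpois(1, 900),
                alt_reads = 0, qual = runif(1, 20, 99),
                caller_p = runif(1, 0, 0.05),
                gene = sample(c("", "TP53", "EGFR"), 1),
                consequence = sample(c("nonsynonymous", "intronic"), 1),
                pop_maf = sample(c(NA, runif(1, 0, 0.05)), 1),
                context_5p = sample(c(NA, "A", "C"), 1),
                damaging_pred = sample(c(NA, TRUE, FALSE), 1))
  }))
  v$alt <- vapply(v$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  v$alt_reads <- pmin(v$depth, round(v$vaf * v$depth))
  v$vaf <- v$alt_reads / v$depth
  s <- make_sample(v, sample_id = "SX", patient_id = "PX")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(s, path)
  back <- read_variant_table(path)$SX
  expect_identical(back$variants, s$variants)
  expect_identical(back$patient_id, "PX")

  # permuting data rows yields set-equal records
  lines <- readLines(path)
  perm <- c(lines[1:2], sample(lines[-(1:2)]))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(perm, path2)
  back2 <- read_variant_table(path2)$SX
  reord <- function(v) { v <- v[order(v$pos), ]; rownames(v) <- NULL; v }
  expect_identical(reord(back2$variants), reord(back$variants))
})

test_that("duplicate variant keys within one sample are rejected", {
  v <- rbind(variant_row(pos = 5), variant_row(pos = 5))
  expect_error(make_sample(v), "duplicated variant key")
})

test_that("VCF dialect extracts AF/DP/AO per sample, matching an independent text parse", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"consequence\">",
    "##INFO=<ID=PMAF,Number=1,Type=Float,Description=\"population MAF\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=AO,Number=1,Type=Integer,Description=\"alt reads\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP7_diagnosis\tP7_relapse",
    "chr1\t1042\t.\tC\tT\t88\tPASS\tGENE=TP53;CSQ=nonsynonymous;PMAF=0.01\tDP:AO:AF\t500:60:0.12\t.:.:.",
    "chr2\t77\t.\tG\tA\t99\tPASS\tGENE=PTEN;CSQ=synonymous\tDP:AO:AF\t900:90:0.1\t800:200:0.25"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  out <- read_variant_table(path, dialect = "vcf")
  expect_setequal(names(out), c("P7_diagnosis", "P7_relapse"))

  # independent parse of the fixture text
  rec1 <- strsplit(vcf[9], "\t")[[1]]
  gt <- as.numeric(strsplit(rec1[10], ":")[[1]])
  v <- out$P7_diagnosis$variants
  expect_equal(nrow(v), 2)
  expect_equal(v$vaf[1], gt[3])
  expect_equal(v$depth[1], gt[1])
  expect_equal(v$alt_reads[1], gt[2])
  expect_identical(v$gene[1], "TP53")
  expect_equal(v$pop_maf[1], 0.01)
  # relapse sample only carries the record with non-missing AF
  expect_equal(nrow(out$P7_relapse$variants), 1)
  expect_equal(out$P7_relapse$variants$pos, 77)
  expect_identical(out$P7_relapse$timepoint, "relapse")
})

test_that("cohort metadata parses group assignment from the treatment detail", {
  md <- read_cohort_metadata(clinical_fixture_path())
  expect_equal(nrow(md), 21)
  expect_equal(sum(md$treatment == "untreated"), 3)
  expect_identical(md$treatment[md$treatment_prior_to_second_surgery == "none"],
                   rep("untreated", 3))
})

test_that("empty metadata gives an empty table and duplicate patients error", {
  path <- write_tsv_lines(paste(c("patient_id", "treatment_prior_to_second_surgery",
                                  "time_to_recurrence_months", "survival_months"),
                                collapse = "\t"))
  expect_equal(nrow(read_cohort_metadata(path)), 0)
  path2 <- write_tsv_lines(c(
    "patient_id\ttreatment_prior_to_second_surgery\ttime_to_recurrence_months\tsurvival_months",
    "1\tnone\t3\t10", "1\tnone\t4\t12"))
  expect_error(read_cohort_metadata(path2), "duplicate patient_id")
})

test_that("methylation tables parse with the documented detection-p default", {
  probes <- sprintf("cg%08d", 1:44)
  path <- write_tsv_lines(c("probe\tbeta",
                            paste(probes, round(runif(44), 4), sep = "\t")))
  prof <- read_methylation_table(path, sample_id = "M1")
  expect_s3_class(prof, "methylation_profile")
  expect_equal(nrow(prof$probes), 44)
  expect_true(all(prof$probes$detection_p == 0))

  bad <- write_tsv_lines(c("probe\tbeta", "cg1\t1.2"))
  expect_error(read_methylation_table(bad), "beta values")
})
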