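# Builders for in-code fixtures and a cache for the heavier seeded
# simulations shared between property and acceptance tests.

variant_row <- function(chrom = "chr1", pos = 1, ref = "C", alt = "T",
                        vaf = 0.3, depth = 500, alt_reads = round(vaf * depth),
                        qual = 99, caller_p = 1e-4, gene = "",
                        consequence = "other", pop_maf = NA_real_,
                        context_5p = NA_character_, context_3p = NA_character_,
                        damaging_pred = NA) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, vaf = vaf,
             depth = depth, alt_reads = alt_reads, qual = qual,
             caller_p = caller_p, gene = gene, consequence = consequence,
             pop_maf = pop_maf, context_5p = context_5p,
             context_3p = context_3p, damaging_pred = damaging_pred,
             stringsAsFactors = FALSE)
}

# n passing variants at distinct positions
variant_block <- function(n, pos0 = 1, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) variant_row(pos = pos0 + i - 1, ...)))
}

make_sample <- function(variants, sample_id = "S1", patient_id = "P1",
                        timepoint = "diagnosis", ...) {
  sample_call(sample_id, patient_id, timepoint, variants, ...)
}

make_pair <- function(dx_variants, rel_variants, patient_id = "P1",
                      treatment = "treated") {
  paired_case(
    patient_id,
    sample_call(paste0(patient_id, "_d"), patient_id, "diagnosis", dx_variants),
    sample_call(paste0(patient_id, "_r"), patient_id, "relapse", rel_variants),
    treatment = treatment
  )
}

# sample whose variant keys are the positions `pos`
pos_sample <- function(pos, patient_id = "P1", timepoint = "diagnosis",
                       sample_id = paste0(patient_id, "_", timepoint), ...) {
  v <- do.call(rbind, lapply(pos, function(p) variant_row(pos = p, ...)))
  if (is.null(v)) v <- clonevo::empty_variants()
  sample_call(sample_id, patient_id, timepoint, v)
}

clinical_fixture_path <- function() {
  system.file("extdata", "cohort1_clinical.tsv", package = "clonevo")
}

# independent Grubbs oracle (explicit formula, written separately from the
# implementation)
grubbs_oracle <- function(x, alpha = 0.05) {
  n <- length(x)
  G <- max(abs(x - mean(x))) / sd(x)
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(G = G, crit = crit, outlier = G > crit,
       idx = which.max(abs(x - mean(x))))
}

# cache for seeded heavy simulations (helpers are loaded once per test run,
# so results are shared across test files)
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# 20 neutral tumors at generator defaults, read-sampled at depth 1000 and
# purity 1, fitted in the subclonal window (seeds 1..20)
neutral_panel <- function() {
  cached("neutral_panel", {
    t(vapply(1:20, function(i) {
      tum <- simulate_tumor(simulation_config(seed = i))
      f <- fit_neutral_model(subclonal_window(
        sample_reads(tum, depth = 1000, purity = 1)$variants$vaf))
      c(slope = f$slope, r2 = f$r_squared, n = f$n_variants)
    }, numeric(3)))
  })
}

# median window r2 across seeds 1..20 for a selection coefficient, with the
# selective lineage arising at population size 20
selection_median_r2 <- function(s) {
  cached(paste0("sel_r2_", s), {
    ev <- if (s > 0) list(list(size = 20, s = s)) else list()
    median(vapply(1:20, function(i) {
      tum <- simulate_tumor(simulation_config(selection_events = ev, seed = i))
      fit_neutral_model(subclonal_window(
        sample_reads(tum, depth = 1000, purity = 1)$variants$vaf))$r_squared
    }, numeric(1)))
  })
}

# pipeline runs over seeded 10-pair cohorts: all-treated with selective
# bottlenecks, and the untreated neutral control
shift_cohort_summary <- function(kind = c("treated", "control"), seed = 42) {
  kind <- match.arg(kind)
  cached(paste0("shift_", kind, "_", seed), {
    cfg <- cohort_sim_config(
      n_patients = 10,
      fraction_untreated = if (kind == "treated") 0 else 1,
      hypermutator_patients = integer(0),
      purity_range = c(0.75, 0.95), seed = seed)
    run_pipeline(pipeline_config(simulate_cohort(cfg)))
  })
}

hypermutator_cohort_summary <- function() {
  cached("hyper_cohort", {
    cfg <- cohort_sim_config(n_patients = 10, fraction_untreated = 0.2,
                             seed = 17)
    run_pipeline(pipeline_config(simulate_cohort(cfg)))
  })
}

# small pipeline cohort for orchestration tests
small_cohort <- function() {
  cached("small_cohort", {
    simulate_cohort(cohort_sim_config(n_patients = 5, fraction_untreated = 0.2,
                                      n_final = 3000, seed = 9))
  })
}
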