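# End-to-end orchestration: simulate-or-read -> quality filters -> cohort
# artifact exclusion -> purity gate -> VAF adjustment -> paired partition ->
# spectra and hypermutator calls -> neutral fits (per sample and pooled) ->
# paired shift -> report bundle. Stage order is fixed and logged so a run is
# auditable against its thresholds.

#' Pipeline configuration
#'
#' @param input One of: a [simulate_cohort()] result, a
#'   [cohort_sim_config()] (the cohort is simulated at run time), or a named
#'   list of paths `list(variants =, metadata =, methylation =)` in the
#'   package's TSV dialects.
#' @param filter A [filter_config()].
#' @param hyper A [hypermutator_config()].
#' @param f_min,f_max Subclonal window bounds (defaults 0.10, 0.25; strict).
#' @param inclusive_lower Public-data window reading, see
#'   [subclonal_window()].
#' @param r2_threshold Strict neutrality threshold (default 0.98).
#' @param min_variants Minimum subclonal variants for per-sample
#'   classification (default 2; use 12 for sparse public-data mode).
#' @param purity_source `"lump"` (estimate from methylation) or
#'   `"external"` (use the purity carried by each sample).
#' @param lump_panel LUMP probe panel for `purity_source = "lump"`.
#' @param min_purity Purity gate threshold (default 0.55, inclusive).
#' @param vaf_cutoff Low/high VAF bin boundary (default 0.4).
#' @param outdir Optional directory for the report bundle.
#' @param seed Optional seed applied before a simulated input is generated.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, filter = filter_config(),
                            hyper = hypermutator_config(),
                            f_min = 0.10, f_max = 0.25,
                            inclusive_lower = FALSE,
                            r2_threshold = 0.98, min_variants = 2L,
                            purity_source = c("lump", "external"),
                            lump_panel = default_lump_panel(),
                            min_purity = 0.55, vaf_cutoff = 0.4,
                            outdir = NULL, seed = NULL) {
  purity_source <- match.arg(purity_source)
  stopifnot(inherits(filter, "filter_config"),
            inherits(hyper, "hypermutator_config"))
  structure(list(input = input, filter = filter, hyper = hyper,
                 f_min = f_min, f_max = f_max,
                 inclusive_lower = inclusive_lower,
                 r2_threshold = r2_threshold,
                 min_variants = as.integer(min_variants),
                 purity_source = purity_source, lump_panel = lump_panel,
                 min_purity = min_purity, vaf_cutoff = vaf_cutoff,
                 outdir = outdir, seed = seed),
            class = "pipeline_config")
}

#' @noRd
resolve_input <- function(cfg) {
  input <- cfg$input
  if (inherits(input, "cohort_sim_config")) {
    if (!is.null(cfg$seed)) input$seed <- input$seed %||% cfg$seed
    input <- simulate_cohort(input)
  }
  if (inherits(input, "clonevo_cohort")) {
    md <- input$metadata
    if (!is.null(md) && !"treatment" %in% names(md)) {
      md$treatment <- ifelse(
        trimws(tolower(md$treatment_prior_to_second_surgery)) == "none",
        "untreated", "treated")
    }
    return(list(samples = input$samples, metadata = md,
                methylation = input$methylation))
  }
  if (is.list(input) && !is.null(input$variants)) {
    samples <- read_variant_table(input$variants)
    metadata <- if (!is.null(input$metadata))
      read_cohort_metadata(input$metadata) else NULL
    methylation <- if (!is.null(input$methylation)) {
      m <- read_methylation_table(input$methylation)
      if (inherits(m, "methylation_profile")) {
        stats::setNames(list(m), m$sample_id)
      } else m
    } else list()
    return(list(samples = samples, metadata = metadata,
                methylation = methylation))
  }
  stop("unrecognised pipeline input", call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages run in a fixed order: per-variant quality filters, cohort-level
#' artifact exclusion, purity estimation and gate, VAF purity adjustment,
#' paired shared/private partitioning and burden summary, mutational
#' spectra and hypermutator calls on unique-to-relapse variants, per-sample
#' and pooled neutral 1/f fits on gated samples, the paired R^2 shift
#' summary, and the clinical summary. Identical configuration and seed give
#' an identical summary.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `pipeline_summary` (a nested list of plain
#'   tables and values; see [write_report()]).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  inp <- resolve_input(cfg)
  samples <- inp$samples
  log <- c(sprintf("thresholds: caller_p<%g qual>=%g depth>%g alt_reads>=%g vaf>=%g pop_maf<=%g patient_fraction<=%g",
                   cfg$filter$max_caller_p, cfg$filter$min_qual,
                   cfg$filter$min_depth, cfg$filter$min_alt_reads,
                   cfg$filter$min_vaf, cfg$filter$max_pop_maf,
                   cfg$filter$max_patient_fraction),
           sprintf("window: (%g, %g) %s; R2 threshold %g; min variants %d; purity gate >= %g",
                   cfg$f_min, cfg$f_max,
                   if (cfg$inclusive_lower) "inclusive-lower" else "strict",
                   cfg$r2_threshold, cfg$min_variants, cfg$min_purity))

  # 1. per-variant quality filters
  filtered <- lapply(samples, apply_quality_filters, cfg = cfg$filter)
  reports <- lapply(filtered, `[[`, "report")
  samples <- lapply(filtered, `[[`, "sample")
  log <- c(log, sprintf("quality filters: kept %d of %d variants",
                        sum(vapply(reports, `[[`, numeric(1), "kept")),
                        sum(vapply(reports, `[[`, numeric(1), "input"))))

  # 2. cohort artifact exclusion
  removed_keys <- character(0)
  if (length(samples)) {
    art <- exclude_recurrent_artifacts(samples, cfg$filter)
    samples <- art$cohort
    removed_keys <- art$removed_keys
    log <- c(log, sprintf("artifact exclusion: removed %d recurrent keys",
                          length(removed_keys)))
  }

  # 3. purity and gate; 4. VAF adjustment; MGMT calls
  purity_tab <- do.call(rbind, lapply(names(samples), function(sid) {
    s <- samples[[sid]]
    est <- if (cfg$purity_source == "lump") {
      prof <- inp$methylation[[sid]]
      if (is.null(prof)) NA_real_
      else tryCatch(lump_purity(prof, cfg$lump_panel)$purity,
                    error = function(e) NA_real_)
    } else s$purity
    mgmt <- if (!is.null(inp$methylation[[sid]]))
      mgmt_methylation_call(inp$methylation[[sid]]) else "indeterminate"
    data.frame(sample_id = sid, patient_id = s$patient_id,
               timepoint = s$timepoint, purity = est,
               gate = if (is.na(est)) "exclude" else
                 purity_gate(est, cfg$min_purity),
               mgmt = mgmt, stringsAsFactors = FALSE)
  }))
  included <- purity_tab$sample_id[purity_tab$gate == "include"]
  for (sid in included) {
    s <- samples[[sid]]
    pur <- purity_tab$purity[purity_tab$sample_id == sid]
    samples[[sid]]$purity <- pur
    samples[[sid]]$variants$adjusted_vaf <- adjust_vaf(s$variants$vaf, pur)
  }
  if (!is.null(purity_tab)) {
    log <- c(log, sprintf("purity gate: %d of %d samples included",
                          length(included), nrow(purity_tab)))
  }

  # 5. assemble pairs
  metadata <- inp$metadata
  cases <- list()
  if (!is.null(metadata) && nrow(metadata)) {
    by_pt <- split(samples, vapply(samples, `[[`, character(1), "patient_id"))
    for (pid in metadata$patient_id) {
      grp <- by_pt[[pid]]
      if (is.null(grp)) next
      tps <- vapply(grp, `[[`, character(1), "timepoint")
      if (!all(c("diagnosis", "relapse") %in% tps)) next
      row <- metadata[metadata$patient_id == pid, ]
      cases[[pid]] <- paired_case(
        pid, grp[[which(tps == "diagnosis")[1]]],
        grp[[which(tps == "relapse")[1]]],
        treatment = row$treatment,
        treatment_detail = row$treatment_prior_to_second_surgery,
        time_to_recurrence_months = row$time_to_recurrence_months,
        survival_months = row$survival_months)
    }
  }

  # 6. burden, partitions, outlier detection, spectra, hypermutator
  burden <- NULL; outlier_patient <- NA_character_; grubbs <- NULL
  spectra <- list(); hyper_calls <- list(); vaf_strata <- NULL
  if (length(cases)) {
    burden0 <- burden_summary(cases)
    counts <- stats::setNames(burden0$unique_relapse, burden0$patient_id)
    if (length(counts) >= 3 && stats::sd(counts) > 0) {
      grubbs <- grubbs_test(counts, alpha = cfg$hyper$grubbs_alpha)
      if (!is.na(grubbs$outlier_index)) {
        outlier_patient <- names(counts)[grubbs$outlier_index]
      }
    }
    burden <- burden_summary(cases, exclude_patients =
                               outlier_patient[!is.na(outlier_patient)])
    vaf_strata <- do.call(rbind, lapply(cases, vaf_stratified_counts,
                                        vaf_cutoff = cfg$vaf_cutoff))
    rownames(vaf_strata) <- NULL
    for (pid in names(cases)) {
      part <- partition_shared_unique(cases[[pid]])
      vr <- cases[[pid]]$relapse$variants
      uniq <- vr[variant_keys(vr) %in% part$unique_relapse, , drop = FALSE]
      spectra[[pid]] <- spectrum_counts(uniq)
      hyper_calls[[pid]] <- call_hypermutator(cases[[pid]], counts, cfg$hyper)
    }
  }

  # 7. neutral fits per included sample and pooled per timepoint
  fits <- list(); windows <- list()
  for (sid in included) {
    v <- samples[[sid]]$variants
    win <- subclonal_window(v$adjusted_vaf, cfg$f_min, cfg$f_max,
                            inclusive_lower = cfg$inclusive_lower,
                            source = sid)
    windows[[sid]] <- win
    fits[[sid]] <- fit_neutral_model(win, r2_threshold = cfg$r2_threshold,
                                     min_variants = cfg$min_variants)
  }
  pooled <- list()
  for (tp in TIMEPOINTS) {
    sel <- included[vapply(included, function(sid)
      samples[[sid]]$timepoint == tp, logical(1))]
    if (length(sel)) {
      pooled[[tp]] <- fit_neutral_model(
        structure(list(vafs = unlist(lapply(windows[sel], `[[`, "vafs"),
                                     use.names = FALSE),
                       f_min = cfg$f_min, f_max = cfg$f_max,
                       source = paste0("pooled_", tp)),
                  class = "subclonal_set"),
        r2_threshold = cfg$r2_threshold, min_variants = cfg$min_variants)
    }
  }

  # 8. paired shift over pairs with both samples gated
  shift <- NULL
  if (length(cases)) {
    rows <- list()
    for (pid in names(cases)) {
      sd_id <- cases[[pid]]$diagnosis$sample_id
      sr_id <- cases[[pid]]$relapse$sample_id
      if (all(c(sd_id, sr_id) %in% included) &&
          !is.na(fits[[sd_id]]$r_squared) && !is.na(fits[[sr_id]]$r_squared)) {
        rows[[pid]] <- data.frame(
          patient_id = pid,
          r2_diagnosis = fits[[sd_id]]$r_squared,
          r2_relapse = fits[[sr_id]]$r_squared, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) shift <- paired_shift_summary(do.call(rbind, rows))
  }

  clinical <- if (!is.null(metadata) && nrow(metadata))
    clinical_summary(metadata) else NULL

  fit_tab <- function(f) list(slope = f$slope, r_squared = f$r_squared,
                              n_variants = f$n_variants,
                              classification = f$classification)
  summary <- structure(list(
    n_samples = length(samples), n_pairs = length(cases),
    filter_reports = lapply(reports, function(r)
      list(sample_id = r$sample_id, input = r$input, kept = r$kept,
           removed = as.list(r$removed))),
    removed_artifact_keys = removed_keys,
    purity = purity_tab,
    burden = burden,
    burden_group_means = if (!is.null(burden)) attr(burden, "group_means"),
    outlier_patient = outlier_patient,
    vaf_strata = vaf_strata,
    spectra = lapply(spectra, function(s)
      list(classes = as.list(s$classes), ct_context = as.list(s$ct_context),
           n_snv = s$n_snv)),
    hypermutator = lapply(hyper_calls, function(h)
      list(decision = h$decision, ct_fraction = h$ct_fraction,
           cpc_cpt_fraction = h$cpc_cpt_fraction,
           n_unique_relapse_snvs = h$n_unique_relapse_snvs)),
    fits = lapply(fits, fit_tab),
    pooled_fits = lapply(pooled, fit_tab),
    paired_shift = if (!is.null(shift))
      list(table = shift$table, n_pairs = shift$n_pairs,
           n_decreased = shift$n_decreased,
           sign_test_p = shift$sign_test_p)
      else list(table = NULL, n_pairs = 0L, n_decreased = 0L,
                sign_test_p = NA_real_),
    clinical = clinical,
    log = log,
    schema_version = "1.0"
  ), class = "pipeline_summary")
  if (!is.null(cfg$outdir)) write_report(summary, cfg$outdir)
  summary
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(sprintf("<pipeline_summary> %d samples, %d pairs\n",
              x$n_samples, x$n_pairs))
  for (tp in names(x$pooled_fits)) {
    f <- x$pooled_fits[[tp]]
    cat(sprintf("  pooled %s: R² = %s (%s), n = %d\n", tp,
                display_r2(f$r_squared), f$classification, f$n_variants))
  }
  if (x$paired_shift$n_pairs > 0) {
    cat(sprintf("  paired shift: R² decreased in %d of %d pairs\n",
                x$paired_shift$n_decreased, x$paired_shift$n_pairs))
  }
  invisible(x)
}

#' Write the report bundle
#'
#' Writes `summary.json` (full precision; schema version recorded in the
#' file) and `summary.txt` (display rounding: R^2 to 4 decimals,
#' percentages to whole numbers). Serialization is deterministic, so equal
#' summaries produce byte-identical bundles; the JSON reloads to the same
#' values.
#'
#' @param summary A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the path of the JSON file.
#' @export
write_report <- function(summary, outdir) {
  stopifnot(inherits(summary, "pipeline_summary"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  txt <- c(sprintf("samples: %d  pairs: %d", summary$n_samples,
                   summary$n_pairs))
  for (tp in names(summary$pooled_fits)) {
    f <- summary$pooled_fits[[tp]]
    txt <- c(txt, sprintf("pooled %s: R^2 = %s (%s), slope = %.4g, n = %d",
                          tp, display_r2(f$r_squared), f$classification,
                          f$slope, f$n_variants))
  }
  if (summary$paired_shift$n_pairs > 0) {
    txt <- c(txt, sprintf("paired R^2 decreased: %d of %d",
                          summary$paired_shift$n_decreased,
                          summary$paired_shift$n_pairs))
  }
  if (!is.null(summary$burden_group_means)) {
    m <- summary$burden_group_means
    for (i in seq_len(nrow(m))) {
      txt <- c(txt, sprintf(
        "%s (n=%d): mean diagnosis %.1f, relapse %.1f, shared %.1f, unique dx %.1f, unique rel %.1f",
        m$treatment[i], m$n_patients[i], m$n_diagnosis[i], m$n_relapse[i],
        m$shared[i], m$unique_diagnosis[i], m$unique_relapse[i]))
    }
  }
  txt <- c(txt, summary$log)
  writeLines(txt, file.path(outdir, "summary.txt"))
  invisible(json_path)
}
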