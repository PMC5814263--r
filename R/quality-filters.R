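# Variant-retention filter chain and cohort-level artifact exclusion.
#
# Boundary semantics follow the wording the thresholds were stated with:
# "at least" is inclusive, "greater than" exclusive, and common variants are
# excluded only when their recorded population MAF exceeds the cutoff (a
# variant with no recorded MAF is not treated as a known common variant).

#' Filter configuration
#'
#' Defaults reproduce the retention rule used for high-depth targeted panel
#' data: keep a variant iff `caller_p < 0.05`, `qual >= 20` (Q20),
#' `depth > 100`, `alt_reads >= 50`, `vaf >= 0.08`, and the 1000-genomes MAF
#' is either unrecorded or `<= 0.05`. `max_patient_fraction` drives the
#' cohort-level artifact exclusion: a variant key seen in more than that
#' fraction of patients is removed everywhere.
#'
#' @param max_caller_p Caller p-value bound (exclusive; keep `p <` this).
#' @param min_qual Minimum Phred quality (inclusive).
#' @param min_depth Depth bound (exclusive; keep `depth >` this).
#' @param min_alt_reads Minimum alternate-read count (inclusive).
#' @param min_vaf Minimum variant allele fraction (inclusive).
#' @param max_pop_maf Population-MAF bound (keep `maf <=` this or missing).
#' @param max_patient_fraction Recurrence bound for artifact exclusion
#'   (remove when patient fraction `>` this).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_caller_p = 0.05, min_qual = 20, min_depth = 100,
                          min_alt_reads = 50, min_vaf = 0.08,
                          max_pop_maf = 0.05, max_patient_fraction = 0.50) {
  stopifnot(max_caller_p >= 0, max_caller_p <= 1, min_qual >= 0,
            min_depth >= 0, min_alt_reads >= 0,
            min_vaf >= 0, min_vaf <= 1,
            max_pop_maf >= 0, max_pop_maf <= 1,
            max_patient_fraction >= 0, max_patient_fraction <= 1)
  structure(list(max_caller_p = max_caller_p, min_qual = min_qual,
                 min_depth = min_depth, min_alt_reads = min_alt_reads,
                 min_vaf = min_vaf, max_pop_maf = max_pop_maf,
                 max_patient_fraction = max_patient_fraction),
            class = "filter_config")
}

# Rule order determines first-failing-rule attribution in the report.
FILTER_RULES <- c("caller_p", "qual", "depth", "alt_reads", "vaf", "pop_maf")

#' Apply the per-variant quality filter chain
#'
#' Keeps variants satisfying every rule of the configuration; the report
#' attributes each removal to the first failing rule in the order
#' caller_p, qual, depth, alt_reads, vaf, pop_maf.
#'
#' @param sample A [sample_call()] whose variants all carry `caller_p`,
#'   `qual`, `depth`, `alt_reads` and `vaf`.
#' @param cfg A [filter_config()].
#' @return A list with elements `sample` (the filtered [sample_call()]) and
#'   `report` (class `filter_report`: per-rule removal counts plus kept and
#'   input totals).
#' @export
apply_quality_filters <- function(sample, cfg = filter_config()) {
  stopifnot(inherits(sample, "sample_call"), inherits(cfg, "filter_config"))
  v <- sample$variants
  required <- c("caller_p", "qual", "depth", "alt_reads", "vaf")
  for (col in required) {
    bad <- which(is.na(v[[col]]))
    if (length(bad)) {
      stop(sprintf("missing %s for variant %s in sample %s", col,
                   variant_key_of(v[bad[1], ]), sample$sample_id),
           call. = FALSE)
    }
  }
  fails <- cbind(
    caller_p  = !(v$caller_p < cfg$max_caller_p),
    qual      = !(v$qual >= cfg$min_qual),
    depth     = !(v$depth > cfg$min_depth),
    alt_reads = !(v$alt_reads >= cfg$min_alt_reads),
    vaf       = !(v$vaf >= cfg$min_vaf),
    pop_maf   = !(is.na(v$pop_maf) | v$pop_maf <= cfg$max_pop_maf)
  )
  if (!nrow(v)) fails <- matrix(FALSE, 0, length(FILTER_RULES),
                                dimnames = list(NULL, FILTER_RULES))
  keep <- !apply(fails, 1L, any)
  first_fail <- apply(fails, 1L, function(f) which(f)[1])
  removed <- vapply(seq_along(FILTER_RULES), function(i)
    sum(!keep & first_fail == i, na.rm = TRUE), integer(1))
  names(removed) <- FILTER_RULES
  out <- sample
  out$variants <- v[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  report <- structure(
    list(removed = removed, kept = sum(keep), input = nrow(v),
         sample_id = sample$sample_id),
    class = "filter_report")
  list(sample = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: kept %d of %d\n",
              x$sample_id, x$kept, x$input))
  rem <- x$removed[x$removed > 0]
  if (length(rem)) {
    cat("  removed (first failing rule):\n")
    for (r in names(rem)) cat(sprintf("    %-10s %d\n", r, rem[[r]]))
  }
  invisible(x)
}

#' Cohort-level recurrent-artifact exclusion
#'
#' A variant key is removed from every sample exactly when the fraction of
#' distinct patients carrying it (at either timepoint, counted once per
#' patient) exceeds `cfg$max_patient_fraction`. Intended to run after the
#' per-variant quality filters.
#'
#' @param cohort A list of [sample_call()] objects.
#' @param cfg A [filter_config()].
#' @param min_cohort_size Below this many patients the fraction is too coarse
#'   to be meaningful and a warning is emitted (the rule is still applied).
#' @return A list with elements `cohort` (filtered samples, same order/names)
#'   and `removed_keys` (character vector of excluded variant keys).
#' @export
exclude_recurrent_artifacts <- function(cohort, cfg = filter_config(),
                                        min_cohort_size = 5L) {
  stopifnot(length(cohort) >= 1L)
  patients <- vapply(cohort, function(s) s$patient_id, character(1))
  n_patients <- length(unique(patients))
  if (n_patients < min_cohort_size) {
    warning(sprintf(paste0("artifact exclusion on only %d patient(s): the ",
                           "patient-fraction rule is unreliable in small cohorts"),
                    n_patients), call. = FALSE)
  }
  key_patient <- unique(do.call(rbind, lapply(cohort, function(s) {
    if (!nrow(s$variants)) return(NULL)
    data.frame(key = variant_keys(s), patient = s$patient_id,
               stringsAsFactors = FALSE)
  })))
  if (is.null(key_patient) || !nrow(key_patient)) {
    return(list(cohort = cohort, removed_keys = character(0)))
  }
  counts <- table(key_patient$key)
  removed_keys <- names(counts)[counts / n_patients > cfg$max_patient_fraction]
  out <- lapply(cohort, function(s) {
    keep <- !variant_keys(s) %in% removed_keys
    s$variants <- s$variants[keep, , drop = FALSE]
    rownames(s$variants) <- NULL
    s
  })
  names(out) <- names(cohort)
  list(cohort = out, removed_keys = removed_keys)
}
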