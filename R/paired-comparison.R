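# Shared/unique partitioning of matched diagnosis and relapse samples,
# burden summaries, TP53-stratified VAF counts, the Grubbs outlier test and
# small reporting utilities.

#' Partition variants of a pair into shared and private sets
#'
#' Variant identity is the `(chrom, pos, ref, alt)` key; annotations play no
#' role. The three sets are pairwise disjoint and their union is the union of
#' both samples' keys.
#'
#' @param case A [paired_case()].
#' @return An object of class `partition_result` with character-vector fields
#'   `shared`, `unique_diagnosis` and `unique_relapse`.
#' @export
partition_shared_unique <- function(case) {
  stopifnot(inherits(case, "paired_case"))
  kd <- variant_keys(case$diagnosis)
  kr <- variant_keys(case$relapse)
  structure(list(shared = intersect(kd, kr),
                 unique_diagnosis = setdiff(kd, kr),
                 unique_relapse = setdiff(kr, kd)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> shared %d | unique to diagnosis %d | unique to relapse %d\n",
              length(x$shared), length(x$unique_diagnosis),
              length(x$unique_relapse)))
  invisible(x)
}

#' @noRd
restrict_consequence <- function(case, consequence_subset) {
  if (is.null(consequence_subset)) return(case)
  for (tp in c("diagnosis", "relapse")) {
    v <- case[[tp]]$variants
    case[[tp]]$variants <- v[v$consequence %in% consequence_subset, ,
                             drop = FALSE]
  }
  case
}

#' Per-patient and per-group variant burden summary
#'
#' Counts total, shared and private variants for every pair, optionally
#' restricted to a consequence subset (e.g. `c("nonsynonymous",
#' "splice_site")` for coding/splice burden) and optionally excluding
#' designated outlier patients from the group means.
#'
#' @param cohort A list of [paired_case()] objects.
#' @param consequence_subset Optional character vector of consequence classes
#'   to retain before counting.
#' @param exclude_patients Patient ids dropped from the group means (they stay
#'   in the per-patient table, flagged in column `excluded_from_means`).
#' @return A data frame (one row per patient) with counts
#'   `n_diagnosis`, `n_relapse`, `shared`, `unique_diagnosis`,
#'   `unique_relapse`; per-treatment-group means are attached as attribute
#'   `group_means`.
#' @export
burden_summary <- function(cohort, consequence_subset = NULL,
                           exclude_patients = character(0)) {
  stopifnot(length(cohort) >= 1L)
  rows <- lapply(cohort, function(case) {
    case <- restrict_consequence(case, consequence_subset)
    p <- partition_shared_unique(case)
    data.frame(
      patient_id = case$patient_id, treatment = case$treatment,
      n_diagnosis = length(p$shared) + length(p$unique_diagnosis),
      n_relapse = length(p$shared) + length(p$unique_relapse),
      shared = length(p$shared),
      unique_diagnosis = length(p$unique_diagnosis),
      unique_relapse = length(p$unique_relapse),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$excluded_from_means <- tab$patient_id %in% exclude_patients
  used <- tab[!tab$excluded_from_means, , drop = FALSE]
  count_cols <- c("n_diagnosis", "n_relapse", "shared",
                  "unique_diagnosis", "unique_relapse")
  means <- do.call(rbind, lapply(split(used, used$treatment), function(g) {
    cbind(data.frame(treatment = g$treatment[1], n_patients = nrow(g)),
          as.data.frame(as.list(colMeans(g[, count_cols]))))
  }))
  rownames(means) <- NULL
  attr(tab, "group_means") <- means
  tab
}

#' Classify TP53 mutation status of one sample
#'
#' A sample is `"mutant"` when it carries at least one nonsynonymous TP53
#' variant; by default the variant must additionally be predicted
#' damaging/deleterious (SIFT/PROVEAN-style annotation).
#'
#' @param sample A [sample_call()].
#' @param require_damaging Require `damaging_pred` to be `TRUE` as well.
#' @return `"mutant"` or `"wildtype"`.
#' @export
classify_tp53_status <- function(sample, require_damaging = TRUE) {
  v <- sample$variants
  hit <- v$gene == "TP53" & v$consequence == "nonsynonymous"
  if (require_damaging) hit <- hit & !is.na(v$damaging_pred) & v$damaging_pred
  if (any(hit, na.rm = TRUE)) "mutant" else "wildtype"
}

#' Low/high-VAF SNV counts per timepoint, tagged by TP53 status
#'
#' Single-nucleotide variants are binned at the VAF cutoff; the boundary value
#' itself falls in the high bin (low is `< cutoff`, high is `>= cutoff`).
#'
#' @param case A [paired_case()].
#' @param vaf_cutoff Bin boundary (default 0.4).
#' @param require_damaging Passed to [classify_tp53_status()].
#' @return A data frame with one row per timepoint and columns `tp53_status`,
#'   `low_vaf`, `high_vaf`, `n_snv`.
#' @export
vaf_stratified_counts <- function(case, vaf_cutoff = 0.4,
                                  require_damaging = TRUE) {
  stopifnot(inherits(case, "paired_case"))
  one <- function(sample) {
    v <- sample$variants
    snv <- v[nchar(v$ref) == 1L & nchar(v$alt) == 1L &
               v$ref %in% BASES & v$alt %in% BASES, , drop = FALSE]
    data.frame(
      patient_id = case$patient_id, timepoint = sample$timepoint,
      tp53_status = classify_tp53_status(sample, require_damaging),
      low_vaf = sum(snv$vaf < vaf_cutoff),
      high_vaf = sum(snv$vaf >= vaf_cutoff),
      n_snv = nrow(snv), stringsAsFactors = FALSE
    )
  }
  out <- rbind(one(case$diagnosis), one(case$relapse))
  rownames(out) <- NULL
  out
}

#' Grubbs' test for a single outlier
#'
#' Computes the maximum studentized deviation `G = max|x - mean(x)| / sd(x)`
#' and compares it with the critical value derived from the t-distribution,
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n-2)` for the two-sided test (`alpha/n` for the
#' one-sided variant). The most deviant observation is flagged as an outlier
#' exactly when `G > G_crit`.
#'
#' @param values Numeric vector, `n >= 3`, non-zero standard deviation.
#' @param alpha Significance level (default 0.05).
#' @param two_sided Use the two-sided critical value (default); set `FALSE`
#'   for the one-sided test.
#' @return An object of class `grubbs_result` with fields `statistic`,
#'   `critical`, `outlier_index` (`NA` when none), `p_bound`, `alpha`,
#'   `two_sided` and `n`.
#' @export
grubbs_test <- function(values, alpha = 0.05, two_sided = TRUE) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("Grubbs' test needs at least 3 observations", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("Grubbs' test is undefined for constant data (zero variance)",
         call. = FALSE)
  }
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  q <- if (two_sided) 1 - alpha / (2 * n) else 1 - alpha / n
  tcrit <- stats::qt(q, df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  # upper bound on the p-value by inverting the critical-value formula
  denom <- (n - 1)^2 / n - G^2
  p_bound <- if (denom <= 0) 0 else {
    ts <- sqrt(G^2 * (n - 2) / denom)
    mult <- if (two_sided) 2 * n else n
    min(1, mult * stats::pt(ts, df = n - 2, lower.tail = FALSE))
  }
  structure(list(statistic = G, critical = crit,
                 outlier_index = if (G > crit) which.max(dev) else NA_integer_,
                 p_bound = p_bound, alpha = alpha, two_sided = two_sided,
                 n = n),
            class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("<grubbs_result> G = %.4f, critical = %.4f (alpha = %g, %s)\n",
              x$statistic, x$critical, x$alpha,
              if (x$two_sided) "two-sided" else "one-sided"))
  if (!is.na(x$outlier_index)) {
    cat(sprintf("  outlier at index %d (p <= %.4g)\n",
                x$outlier_index, x$p_bound))
  } else {
    cat("  no outlier detected\n")
  }
  invisible(x)
}

#' Validation-assay summary percentages
#'
#' Summarises orthogonal validation assays (e.g. Sanger re-sequencing of
#' selected calls) per variant class and pooled. Percentages are `100 *
#' validated / assayed`, reported at full precision plus one-decimal and
#' nearest-whole roundings.
#'
#' @param assays Data frame with columns `class` (`"SNV"`/`"INDEL"`) and
#'   `validated` (logical).
#' @return A list with `per_class` (data frame) and `pooled` (one-row data
#'   frame), each carrying `n`, `n_validated`, `pct`, `pct_1dp`, `pct_whole`.
#' @export
validation_summary <- function(assays) {
  stopifnot(is.data.frame(assays),
            all(c("class", "validated") %in% names(assays)))
  if (!nrow(assays)) stop("no assays supplied", call. = FALSE)
  summarise <- function(d, label) {
    n <- nrow(d); v <- sum(d$validated)
    pct <- 100 * v / n
    data.frame(class = label, n = n, n_validated = v, pct = pct,
               pct_1dp = round(pct, 1), pct_whole = round(pct),
               stringsAsFactors = FALSE)
  }
  per_class <- do.call(rbind, lapply(split(assays, assays$class),
                                     function(d) summarise(d, d$class[1])))
  rownames(per_class) <- NULL
  list(per_class = per_class, pooled = summarise(assays, "pooled"))
}

#' Fraction of variants selected for validation
#'
#' @param selected Number of variants assayed.
#' @param total Total variants detected (must be positive).
#' @return A list with `pct` (full precision) and `pct_1dp` (one decimal).
#' @export
fraction_selected <- function(selected, total) {
  stopifnot(selected >= 0)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  pct <- 100 * selected / total
  list(pct = pct, pct_1dp = round(pct, 1))
}

#' Clinical summary of a cohort metadata table
#'
#' Group sizes and median clinical intervals per treatment group. Medians use
#' the midpoint convention for even group sizes ([stats::median()]); an empty
#' group yields `NA` rather than an error.
#'
#' @param metadata Data frame from [read_cohort_metadata()].
#' @return A data frame with one row per treatment group: `n`,
#'   `median_time_to_recurrence_months`, `median_survival_months`.
#' @export
clinical_summary <- function(metadata) {
  stopifnot(is.data.frame(metadata), "treatment" %in% names(metadata))
  groups <- c("treated", "untreated")
  out <- do.call(rbind, lapply(groups, function(g) {
    d <- metadata[metadata$treatment == g, , drop = FALSE]
    data.frame(
      treatment = g, n = nrow(d),
      median_time_to_recurrence_months =
        if (nrow(d)) stats::median(d$time_to_recurrence_months, na.rm = TRUE)
        else NA_real_,
      median_survival_months =
        if (nrow(d)) stats::median(d$survival_months, na.rm = TRUE)
        else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
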