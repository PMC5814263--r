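# Pyrimidine-collapsed substitution classification, dinucleotide-context
# analysis for C>T transitions, and temozolomide-hypermutator calling.
#
# Context convention: the dinucleotide is written 5'->3' with the mutated
# cytosine FIRST (CpN), so "CpC and CpT" means the base 3' of the mutated C
# is C or T. For a variant reported on the purine strand (G>A) the 5'
# neighbour is complemented to recover the 3' neighbour on the
# pyrimidine-containing strand. The alternative 5'-neighbour (NpC)
# convention is available via `convention = "5prime"`.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
CT_CONTEXTS <- c("CpA", "CpC", "CpG", "CpT")

#' @noRd
revcomp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Collapse a single-base substitution to its pyrimidine representative
#'
#' Purine-reference substitutions are reverse-complemented so that every SNV
#' maps to one of the six classes C>A, C>G, C>T, T>A, T>C, T>G; in particular
#' C>T and G>A transitions are one class.
#'
#' @param ref,alt Single reference/alternate bases (vectorised).
#' @return Character vector of six-class labels.
#' @export
collapse_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) stop("ref and alt lengths differ",
                                       call. = FALSE)
  ok <- ref %in% BASES & alt %in% BASES & ref != alt
  if (!all(ok)) {
    stop(sprintf("not a single-base substitution: %s>%s",
                 ref[!ok][1], alt[!ok][1]), call. = FALSE)
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- revcomp_base(ref[purine])
  alt[purine] <- revcomp_base(alt[purine])
  paste0(ref, ">", alt)
}

#' Dinucleotide context of a C>T transition
#'
#' Returns the context `Cp{A,C,G,T}` of the mutated pyrimidine, or `NA` when
#' the needed flanking base is missing ("unresolved").
#'
#' @param ref,alt Single bases; the substitution must collapse to C>T.
#' @param context_5p,context_3p Flanking reference bases (as reported on the
#'   same strand as `ref`), `NA` when unknown.
#' @param convention `"3prime"` (default; mutated base written first, CpN) or
#'   `"5prime"` (NpC, using the 5' neighbour of the pyrimidine).
#' @return Character vector of contexts (`"CpA"`..`"CpT"`) or `NA`.
#' @export
dinucleotide_context <- function(ref, alt, context_5p = NA, context_3p = NA,
                                 convention = c("3prime", "5prime")) {
  convention <- match.arg(convention)
  cls <- collapse_substitution(ref, alt)
  if (any(cls != "C>T")) {
    stop("dinucleotide context is defined for C>T (G>A) transitions only",
         call. = FALSE)
  }
  ref <- toupper(as.character(ref))
  c5 <- toupper(as.character(context_5p))
  c3 <- toupper(as.character(context_3p))
  n <- length(ref)
  if (length(c5) == 1L) c5 <- rep(c5, n)
  if (length(c3) == 1L) c3 <- rep(c3, n)
  # neighbour of the mutated pyrimidine on the pyrimidine-containing strand
  neighbour <- ifelse(
    ref == "C",
    if (convention == "3prime") c3 else c5,
    # reported on the purine strand: complement the opposite flank
    revcomp_base(if (convention == "3prime") c5 else c3)
  )
  out <- ifelse(is.na(neighbour) | !neighbour %in% BASES,
                NA_character_, paste0("Cp", neighbour))
  out
}

#' Mutational spectrum counts
#'
#' Classifies SNVs into the six pyrimidine-collapsed classes and, for the
#' C>T class, tallies the dinucleotide context. Non-SNV records (indels,
#' MNVs) are skipped and counted in `n_skipped`.
#'
#' @param variants Variant data frame (see [empty_variants()]).
#' @param convention Context convention, see [dinucleotide_context()].
#' @return An object of class `spectrum_counts`: `classes` (named count
#'   vector over the six classes), `ct_context` (named counts over
#'   CpA/CpC/CpG/CpT), `n_snv`, `n_skipped`, `n_ct_unresolved`.
#' @export
spectrum_counts <- function(variants, convention = "3prime") {
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    toupper(variants$ref) %in% BASES & toupper(variants$alt) %in% BASES &
    toupper(variants$ref) != toupper(variants$alt)
  snv <- variants[which(is_snv), , drop = FALSE]
  classes <- stats::setNames(integer(length(SUB_CLASSES)), SUB_CLASSES)
  ctx <- stats::setNames(integer(length(CT_CONTEXTS)), CT_CONTEXTS)
  n_unres <- 0L
  if (nrow(snv)) {
    cls <- collapse_substitution(snv$ref, snv$alt)
    tab <- table(factor(cls, levels = SUB_CLASSES))
    classes[] <- as.integer(tab)
    ct <- snv[cls == "C>T", , drop = FALSE]
    if (nrow(ct)) {
      cc <- dinucleotide_context(ct$ref, ct$alt, ct$context_5p, ct$context_3p,
                                 convention = convention)
      n_unres <- sum(is.na(cc))
      ctab <- table(factor(cc, levels = CT_CONTEXTS))
      ctx[] <- as.integer(ctab)
    }
  }
  structure(list(classes = classes, ct_context = ctx,
                 n_snv = nrow(snv),
                 n_skipped = nrow(variants) - nrow(snv),
                 n_ct_unresolved = n_unres),
            class = "spectrum_counts")
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat(sprintf("<spectrum_counts> %d SNVs (%d non-SNV records skipped)\n",
              x$n_snv, x$n_skipped))
  print(x$classes)
  if (x$classes[["C>T"]] > 0) {
    cat(sprintf("C>T dinucleotide context (%d unresolved):\n",
                x$n_ct_unresolved))
    print(x$ct_context)
  }
  invisible(x)
}

#' Hypermutator-calling configuration
#'
#' Thresholds operationalising the temozolomide-hypermutator phenotype: a
#' relapse-specific excess of C>T transitions concentrated at CpC/CpT
#' dinucleotides, optionally gated on the patient's unique-to-relapse
#' burden being a cohort outlier.
#'
#' @param min_ct_fraction Minimum fraction of unique-to-relapse SNVs in class
#'   C>T (default 0.60).
#' @param min_cpc_cpt_fraction Minimum fraction of context-resolved C>T
#'   transitions at CpC or CpT (default 0.60).
#' @param require_burden_outlier Additionally require the patient's
#'   unique-to-relapse count to be a Grubbs outlier in the cohort (off by
#'   default: when relapse regrowth passes through a severe bottleneck the
#'   baseline unique-to-relapse burden is heavy-tailed and the outlier test
#'   loses power; the dinucleotide signature is the discriminative
#'   evidence).
#' @param grubbs_alpha Significance level for the outlier test.
#' @param min_unique_snvs Below this many unique-to-relapse SNVs the decision
#'   is `"insufficient"` (default 10).
#' @return An object of class `hypermutator_config`.
#' @export
hypermutator_config <- function(min_ct_fraction = 0.60,
                                min_cpc_cpt_fraction = 0.60,
                                require_burden_outlier = FALSE,
                                grubbs_alpha = 0.05,
                                min_unique_snvs = 10L) {
  stopifnot(min_ct_fraction >= 0, min_ct_fraction <= 1,
            min_cpc_cpt_fraction >= 0, min_cpc_cpt_fraction <= 1)
  structure(list(min_ct_fraction = min_ct_fraction,
                 min_cpc_cpt_fraction = min_cpc_cpt_fraction,
                 require_burden_outlier = require_burden_outlier,
                 grubbs_alpha = grubbs_alpha,
                 min_unique_snvs = as.integer(min_unique_snvs)),
            class = "hypermutator_config")
}

#' Call the temozolomide-hypermutator phenotype for one pair
#'
#' Positive exactly when (i) the fraction of unique-to-relapse SNVs in class
#' C>T reaches `min_ct_fraction`, (ii) among those with resolved context the
#' CpC/CpT fraction reaches `min_cpc_cpt_fraction`, and (iii) when required,
#' the patient's unique-to-relapse count is the Grubbs outlier of the cohort
#' counts. With fewer than `min_unique_snvs` unique-to-relapse SNVs the
#' decision is `"insufficient"`.
#'
#' @param case A [paired_case()] (already filtered).
#' @param cohort_unique_relapse_counts Named numeric vector of
#'   unique-to-relapse variant counts per patient, including this patient.
#' @param cfg A [hypermutator_config()].
#' @return A list: `decision` (`"positive"`/`"negative"`/`"insufficient"`),
#'   `ct_fraction`, `cpc_cpt_fraction`, `n_unique_relapse_snvs`, `grubbs`
#'   (a `grubbs_result` or `NULL`), `is_outlier`.
#' @export
call_hypermutator <- function(case, cohort_unique_relapse_counts = NULL,
                              cfg = hypermutator_config()) {
  stopifnot(inherits(case, "paired_case"))
  part <- partition_shared_unique(case)
  vr <- case$relapse$variants
  uniq <- vr[variant_key_of(vr) %in% part$unique_relapse, , drop = FALSE]
  spec <- spectrum_counts(uniq)
  n <- spec$n_snv
  if (n < cfg$min_unique_snvs) {
    return(list(decision = "insufficient", ct_fraction = NA_real_,
                cpc_cpt_fraction = NA_real_, n_unique_relapse_snvs = n,
                grubbs = NULL, is_outlier = NA))
  }
  ct <- spec$classes[["C>T"]]
  ct_fraction <- ct / n
  resolved <- sum(spec$ct_context)
  cpc_cpt_fraction <- if (resolved > 0) {
    (spec$ct_context[["CpC"]] + spec$ct_context[["CpT"]]) / resolved
  } else NA_real_
  gr <- NULL; is_outlier <- NA
  if (cfg$require_burden_outlier) {
    if (is.null(cohort_unique_relapse_counts) ||
        is.null(names(cohort_unique_relapse_counts)) ||
        !case$patient_id %in% names(cohort_unique_relapse_counts)) {
      stop("cohort_unique_relapse_counts must be named and include this patient",
           call. = FALSE)
    }
    gr <- grubbs_test(cohort_unique_relapse_counts, alpha = cfg$grubbs_alpha)
    is_outlier <- !is.na(gr$outlier_index) &&
      names(cohort_unique_relapse_counts)[gr$outlier_index] == case$patient_id
  }
  positive <- ct_fraction >= cfg$min_ct_fraction &&
    !is.na(cpc_cpt_fraction) &&
    cpc_cpt_fraction >= cfg$min_cpc_cpt_fraction &&
    (!cfg$require_burden_outlier || isTRUE(is_outlier))
  list(decision = if (positive) "positive" else "negative",
       ct_fraction = ct_fraction, cpc_cpt_fraction = cpc_cpt_fraction,
       n_unique_relapse_snvs = n, grubbs = gr, is_outlier = is_outlier)
}
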