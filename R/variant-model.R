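# Domain containers and readers/writers for variant tables, cohort metadata
# and methylation beta tables.
#
# Coordinates are 1-based and fully closed, matching VCF convention. Variant
# identity is the tuple (chrom, pos, ref, alt); annotations are carried but
# never take part in identity.

VARIANT_CORE_COLUMNS <- c(
  "sample_id", "patient_id", "timepoint", "chrom", "pos", "ref", "alt",
  "vaf", "depth", "alt_reads", "qual", "caller_p"
)
VARIANT_OPTIONAL_COLUMNS <- c(
  "gene", "consequence", "pop_maf", "context_5p", "context_3p", "damaging_pred"
)
VARIANT_TSV_COLUMNS <- c(VARIANT_CORE_COLUMNS, VARIANT_OPTIONAL_COLUMNS)

CONSEQUENCE_LEVELS <- c("nonsynonymous", "synonymous", "splice_site",
                        "intronic", "other")
TIMEPOINTS <- c("diagnosis", "relapse")
BASES <- c("A", "C", "G", "T")

#' Empty variant table
#'
#' Returns a zero-row data frame with the canonical variant columns. One row
#' per called variant in one sample; `vaf` is the variant allele fraction,
#' `depth`/`alt_reads` the total and alternate-supporting read counts at the
#' site, `qual` a Phred-scaled quality, `caller_p` the caller p-value,
#' `pop_maf` the 1000-genomes minor allele frequency (NA when the variant has
#' no recorded population frequency) and `context_5p`/`context_3p` the
#' reference bases flanking the site.
#'
#' @return A data frame with zero rows and the canonical variant columns.
#' @export
empty_variants <- function() {
  data.frame(
    chrom = character(), pos = numeric(), ref = character(), alt = character(),
    vaf = numeric(), depth = numeric(), alt_reads = numeric(),
    qual = numeric(), caller_p = numeric(), gene = character(),
    consequence = character(), pop_maf = numeric(), context_5p = character(),
    context_3p = character(), damaging_pred = logical(),
    stringsAsFactors = FALSE
  )
}

#' Validate and normalise a variant table
#'
#' Fills absent optional columns with missing values, maps unknown consequence
#' strings to `"other"` with a warning, and enforces the record invariants
#' (`0 <= vaf <= 1`, `alt_reads <= depth`, `ref != alt`, unique variant keys).
#'
#' @param variants A data frame of variant records.
#' @param where Label used in error messages (e.g. a sample id).
#' @return The normalised data frame.
#' @export
validate_variants <- function(variants, where = "variants") {
  tmpl <- empty_variants()
  if (nrow(variants) == 0L && ncol(variants) == 0L) return(tmpl)
  for (col in names(tmpl)) {
    if (!col %in% names(variants)) {
      variants[[col]] <- tmpl[[col]][rep(NA_integer_, nrow(variants))]
    }
  }
  variants <- variants[, names(tmpl), drop = FALSE]
  for (col in c("pos", "vaf", "depth", "alt_reads", "qual", "caller_p",
                "pop_maf")) {
    variants[[col]] <- as.numeric(variants[[col]])
  }
  variants$chrom <- as.character(variants$chrom)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  variants$gene <- ifelse(is.na(variants$gene), "", as.character(variants$gene))
  variants$consequence <- as.character(variants$consequence)
  variants$consequence[is.na(variants$consequence) |
                         !nzchar(variants$consequence)] <- "other"
  unknown <- !variants$consequence %in% CONSEQUENCE_LEVELS
  if (any(unknown)) {
    warning(sprintf("%s: %d unknown consequence value(s) mapped to 'other' (e.g. '%s')",
                    where, sum(unknown), variants$consequence[unknown][1]),
            call. = FALSE)
    variants$consequence[unknown] <- "other"
  }

  bad <- which(!is.na(variants$vaf) & (variants$vaf < 0 | variants$vaf > 1))
  if (length(bad)) {
    stop(sprintf("%s: vaf outside [0,1] for %s", where,
                 variant_key_of(variants[bad[1], ])), call. = FALSE)
  }
  bad <- which(!is.na(variants$alt_reads) & !is.na(variants$depth) &
                 variants$alt_reads > variants$depth)
  if (length(bad)) {
    stop(sprintf("%s: alt_reads (%g) exceeds depth (%g) for %s", where,
                 variants$alt_reads[bad[1]], variants$depth[bad[1]],
                 variant_key_of(variants[bad[1], ])), call. = FALSE)
  }
  bad <- which(variants$ref == variants$alt)
  if (length(bad)) {
    stop(sprintf("%s: ref equals alt for %s", where,
                 variant_key_of(variants[bad[1], ])), call. = FALSE)
  }
  keys <- variant_key_of(variants)
  if (anyDuplicated(keys)) {
    stop(sprintf("%s: duplicated variant key %s", where,
                 keys[duplicated(keys)][1]), call. = FALSE)
  }
  rownames(variants) <- NULL
  variants
}

#' @noRd
variant_key_of <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' One sample's variant calls
#'
#' A `sample_call` bundles the variants called in one specimen with its
#' identifiers, an optional tumor-purity estimate and an MGMT promoter
#' methylation status.
#'
#' @param sample_id Sample identifier.
#' @param patient_id Patient identifier.
#' @param timepoint Either `"diagnosis"` or `"relapse"`.
#' @param variants Variant data frame (see [empty_variants()]).
#' @param purity Tumor purity in `[0, 1]`, or `NA` when unknown.
#' @param mgmt_status `"methylated"`, `"unmethylated"` or `"unknown"`.
#' @return An object of class `sample_call`.
#' @export
sample_call <- function(sample_id, patient_id, timepoint,
                        variants = empty_variants(), purity = NA_real_,
                        mgmt_status = "unknown") {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  mgmt_status <- match.arg(mgmt_status,
                           c("unknown", "methylated", "unmethylated"))
  if (!is.na(purity) && (purity < 0 || purity > 1)) {
    stop("purity must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         timepoint = timepoint,
         variants = validate_variants(variants, where = sample_id),
         purity = purity, mgmt_status = mgmt_status),
    class = "sample_call"
  )
}

#' @export
print.sample_call <- function(x, ...) {
  cat(sprintf("<sample_call> %s (patient %s, %s): %d variants",
              x$sample_id, x$patient_id, x$timepoint, nrow(x$variants)))
  if (!is.na(x$purity)) cat(sprintf(", purity %.2f", x$purity))
  cat("\n")
  invisible(x)
}

#' Variant keys of a sample
#'
#' @param x A `sample_call` or a variant data frame.
#' @return Character vector of `chrom:pos:ref:alt` keys.
#' @export
variant_keys <- function(x) {
  if (inherits(x, "sample_call")) x <- x$variants
  variant_key_of(x)
}

#' A matched diagnosis/relapse pair for one patient
#'
#' @param patient_id Patient identifier shared by both samples.
#' @param diagnosis,relapse `sample_call` objects with matching timepoints.
#' @param treatment `"untreated"` or `"treated"`.
#' @param treatment_detail Free-text treatment description.
#' @param time_to_recurrence_months,survival_months Clinical intervals.
#' @return An object of class `paired_case`.
#' @export
paired_case <- function(patient_id, diagnosis, relapse,
                        treatment = c("treated", "untreated"),
                        treatment_detail = "",
                        time_to_recurrence_months = NA_real_,
                        survival_months = NA_real_) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(diagnosis, "sample_call"), inherits(relapse, "sample_call"))
  if (diagnosis$timepoint != "diagnosis" || relapse$timepoint != "relapse") {
    stop("diagnosis/relapse sample timepoints do not match their roles",
         call. = FALSE)
  }
  if (diagnosis$patient_id != patient_id || relapse$patient_id != patient_id) {
    stop("both samples of a paired_case must share patient_id", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id), diagnosis = diagnosis,
         relapse = relapse, treatment = treatment,
         treatment_detail = treatment_detail,
         time_to_recurrence_months = time_to_recurrence_months,
         survival_months = survival_months),
    class = "paired_case"
  )
}

#' @export
print.paired_case <- function(x, ...) {
  cat(sprintf("<paired_case> patient %s (%s): %d diagnosis / %d relapse variants\n",
              x$patient_id, x$treatment, nrow(x$diagnosis$variants),
              nrow(x$relapse$variants)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# TSV dialect
# ---------------------------------------------------------------------------

#' Read a variant table
#'
#' The required TSV dialect is a tab-separated table with header
#' `sample_id patient_id timepoint chrom pos ref alt vaf depth alt_reads qual
#' caller_p gene consequence pop_maf context_5p context_3p damaging_pred`;
#' lines starting with `#` are comments and empty fields are missing values.
#' Optional columns may be absent entirely. Coordinates are 1-based, fully
#' closed.
#'
#' The optional VCF dialect (requires the `vcfR` package) reads standard
#' VCF 4.x with per-sample FORMAT keys `DP` (depth), `AO` (alternate reads)
#' and `AF` (variant allele fraction), optional FORMAT `PV` (caller p-value),
#' and optional INFO keys `GENE`, `CSQ`, `PMAF`, `C5P`, `C3P`, `DMG` for the
#' annotations. Sample names must follow `<patient>_<timepoint>`. A record is
#' attributed to a sample when its `AF` genotype field is non-missing.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @return A named list of [sample_call()] objects, one per sample.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(read_variant_vcf(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  content <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (!length(content)) stop("no content in ", path, call. = FALSE)
  header <- strsplit(lines[content[1]], "\t", fixed = TRUE)[[1]]
  if (!all(VARIANT_CORE_COLUMNS %in% header)) {
    stop("variant table header is missing required column(s): ",
         paste(setdiff(VARIANT_CORE_COLUMNS, header), collapse = ", "),
         call. = FALSE)
  }
  if (!all(header %in% VARIANT_TSV_COLUMNS)) {
    stop("unknown column(s) in variant table: ",
         paste(setdiff(header, VARIANT_TSV_COLUMNS), collapse = ", "),
         call. = FALSE)
  }
  rows <- content[-1]
  if (!length(rows)) return(list())
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty fields are dropped by strsplit; pad them back
  fields[nf < length(header)] <- lapply(fields[nf < length(header)], function(f)
    c(f, rep("", length(header) - length(f))))
  bad <- which(nf > length(header))
  if (length(bad)) {
    stop(sprintf("line %d: expected %d fields, found %d",
                 rows[bad[1]], length(header), nf[bad[1]]), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  get <- function(col) if (col %in% header) mat[, col] else rep("", nrow(mat))

  df <- data.frame(
    sample_id = mat[, "sample_id"], patient_id = mat[, "patient_id"],
    timepoint = mat[, "timepoint"], chrom = mat[, "chrom"],
    pos = parse_num(mat[, "pos"], rows, "pos"),
    ref = mat[, "ref"], alt = mat[, "alt"],
    vaf = parse_num(mat[, "vaf"], rows, "vaf"),
    depth = parse_num(mat[, "depth"], rows, "depth"),
    alt_reads = parse_num(mat[, "alt_reads"], rows, "alt_reads"),
    qual = parse_num(mat[, "qual"], rows, "qual"),
    caller_p = parse_num(mat[, "caller_p"], rows, "caller_p"),
    gene = get("gene"),
    consequence = get("consequence"),
    pop_maf = parse_num(get("pop_maf"), rows, "pop_maf"),
    context_5p = get("context_5p"),
    context_3p = get("context_3p"),
    damaging_pred = parse_lgl(get("damaging_pred"), rows, "damaging_pred"),
    stringsAsFactors = FALSE
  )
  df$context_5p[!nzchar(df$context_5p)] <- NA_character_
  df$context_3p[!nzchar(df$context_3p)] <- NA_character_
  bad <- which(!df$timepoint %in% TIMEPOINTS)
  if (length(bad)) {
    stop(sprintf("line %d: timepoint must be one of %s (found '%s')",
                 rows[bad[1]], paste(TIMEPOINTS, collapse = "/"),
                 df$timepoint[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.na(df$alt_reads) & !is.na(df$depth) & df$alt_reads > df$depth)
  if (length(bad)) {
    stop(sprintf("line %d: alt_reads (%g) exceeds depth (%g) for %s",
                 rows[bad[1]], df$alt_reads[bad[1]], df$depth[bad[1]],
                 variant_key_of(df[bad[1], ])), call. = FALSE)
  }

  out <- list()
  for (sid in unique(df$sample_id)) {
    sub <- df[df$sample_id == sid, , drop = FALSE]
    if (length(unique(sub$patient_id)) > 1L ||
        length(unique(sub$timepoint)) > 1L) {
      stop(sprintf("sample %s has inconsistent patient_id/timepoint", sid),
           call. = FALSE)
    }
    out[[sid]] <- sample_call(
      sample_id = sid, patient_id = sub$patient_id[1],
      timepoint = sub$timepoint[1],
      variants = sub[, setdiff(names(sub),
                               c("sample_id", "patient_id", "timepoint"))]
    )
  }
  out
}

#' Write sample calls in the TSV dialect
#'
#' The written file reads back bit-exactly with [read_variant_table()].
#'
#' @param samples A `sample_call` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_table <- function(samples, path) {
  if (inherits(samples, "sample_call")) samples <- list(samples)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# variant table; coordinates are 1-based, fully closed", con)
  writeLines(paste(VARIANT_TSV_COLUMNS, collapse = "\t"), con)
  for (s in samples) {
    v <- s$variants
    if (!nrow(v)) next
    cols <- cbind(
      s$sample_id, s$patient_id, s$timepoint,
      do.call(cbind, lapply(v[, setdiff(VARIANT_TSV_COLUMNS,
                                        c("sample_id", "patient_id", "timepoint"))],
                            fmt_field))
    )
    writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' @noRd
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the VCF dialect requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  af <- vcfR::extract.gt(v, "AF", as.numeric = TRUE)
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ao <- vcfR::extract.gt(v, "AO", as.numeric = TRUE)
  pv <- tryCatch(vcfR::extract.gt(v, "PV", as.numeric = TRUE),
                 error = function(e) NULL)
  info_get <- function(key) {
    val <- tryCatch(vcfR::extract.info(v, key), error = function(e) NULL)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_get("GENE"); csq <- info_get("CSQ"); pmaf <- info_get("PMAF")
  c5 <- info_get("C5P"); c3 <- info_get("C3P"); dmg <- info_get("DMG")
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  out <- list()
  for (sid in colnames(af)) {
    idx <- which(!is.na(af[, sid]))
    parts <- strsplit(sid, "_", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !parts[length(parts)] %in% TIMEPOINTS) {
      stop(sprintf("VCF sample name '%s' does not follow <patient>_<timepoint>",
                   sid), call. = FALSE)
    }
    tp <- parts[length(parts)]
    pid <- paste(parts[-length(parts)], collapse = "_")
    variants <- data.frame(
      chrom = fix[idx, "CHROM"],
      pos = as.numeric(fix[idx, "POS"]),
      ref = fix[idx, "REF"], alt = fix[idx, "ALT"],
      vaf = af[idx, sid], depth = dp[idx, sid], alt_reads = ao[idx, sid],
      qual = qual[idx],
      caller_p = if (is.null(pv)) NA_real_ else pv[idx, sid],
      gene = ifelse(is.na(gene[idx]), "", gene[idx]),
      consequence = ifelse(is.na(csq[idx]), "other", csq[idx]),
      pop_maf = suppressWarnings(as.numeric(pmaf[idx])),
      context_5p = c5[idx], context_3p = c3[idx],
      damaging_pred = ifelse(is.na(dmg[idx]), NA, dmg[idx] %in% c("1", "TRUE")),
      stringsAsFactors = FALSE
    )
    out[[sid]] <- sample_call(sid, pid, tp, variants)
  }
  out
}

# ---------------------------------------------------------------------------
# Cohort metadata
# ---------------------------------------------------------------------------

#' Read a cohort clinical metadata table
#'
#' Expects a tab-separated table with columns `patient_id`, `gender`,
#' `age_at_diagnosis`, `primary_diagnosis`, `diagnosis_of_recurrence`,
#' `treatment_prior_to_second_surgery`, `time_to_recurrence_months`,
#' `survival_months` (`#` comments allowed). A patient is classified
#' `untreated` exactly when the treatment detail equals `"none"`.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per patient and an added `treatment`
#'   column (`"treated"`/`"untreated"`).
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("patient_id", "treatment_prior_to_second_surgery",
                "time_to_recurrence_months", "survival_months")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in cohort metadata: ",
         df$patient_id[duplicated(df$patient_id)][1], call. = FALSE)
  }
  df$treatment <- ifelse(
    trimws(tolower(df$treatment_prior_to_second_surgery)) == "none",
    "untreated", "treated")
  df
}

# ---------------------------------------------------------------------------
# Methylation profiles
# ---------------------------------------------------------------------------

#' Methylation profile container
#'
#' @param sample_id Sample identifier.
#' @param probes Data frame with columns `probe`, `beta` and `detection_p`.
#' @return An object of class `methylation_profile`.
#' @export
methylation_profile <- function(sample_id, probes) {
  stopifnot(all(c("probe", "beta") %in% names(probes)))
  if (!"detection_p" %in% names(probes)) probes$detection_p <- 0
  if (any(probes$beta < 0 | probes$beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (any(probes$detection_p < 0 | probes$detection_p > 1, na.rm = TRUE)) {
    stop("detection p-values must lie in [0, 1]", call. = FALSE)
  }
  probes$probe <- as.character(probes$probe)
  rownames(probes) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 probes = probes[, c("probe", "beta", "detection_p")]),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("<methylation_profile> %s: %d probes\n",
              x$sample_id, nrow(x$probes)))
  invisible(x)
}

#' Read a methylation beta-value table
#'
#' Two-to-three-column TSV (`probe`, `beta`, optional `detection_p`; a missing
#' `detection_p` column defaults to 0, i.e. all probes detected). When the file
#' carries an additional `sample_id` column with several samples, a named list
#' of profiles is returned.
#'
#' @param path Path to the TSV file.
#' @param sample_id Identifier to attach when the file has no `sample_id`
#'   column (defaults to the file name).
#' @return A [methylation_profile()], or a named list of them.
#' @export
read_methylation_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("probe", "beta") %in% names(df))) {
    stop("methylation table must have columns 'probe' and 'beta'",
         call. = FALSE)
  }
  if (!"detection_p" %in% names(df)) df$detection_p <- 0
  if ("sample_id" %in% names(df)) {
    ids <- unique(df$sample_id)
    profs <- lapply(ids, function(id)
      methylation_profile(id, df[df$sample_id == id,
                                 c("probe", "beta", "detection_p")]))
    names(profs) <- ids
    if (length(profs) == 1L) return(profs[[1]])
    return(profs)
  }
  methylation_profile(sample_id %||% basename(path), df)
}
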