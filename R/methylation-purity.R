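# LUMP purity from methylation betas, MGMT promoter methylation calls,
# the purity inclusion gate, and VAF purity adjustment.

#' Synthetic LUMP probe panel
#'
#' The LUMP estimator averages beta values over a panel of CpG sites that are
#' unmethylated in leukocytes; the panel identity is array- and
#' study-specific and must normally be supplied by the user. This helper
#' returns a 44-probe synthetic placeholder panel (ids `lump_syn_001` ...)
#' used by the simulator and the test suite; it is NOT a published panel.
#'
#' @return Character vector of 44 synthetic probe ids.
#' @export
default_lump_panel <- function() {
  sprintf("lump_syn_%03d", seq_len(44))
}

#' Synthetic MGMT promoter probe set
#'
#' Twelve synthetic placeholder probe ids standing in for the MGMT promoter
#' region probes of a methylation array (the true ids are array-specific and
#' should be supplied by the user for real data).
#'
#' @return Character vector of 12 synthetic probe ids.
#' @export
default_mgmt_promoter_probes <- function() {
  sprintf("mgmt_prom_syn_%02d", seq_len(12))
}

#' LUMP tumor-purity estimate
#'
#' Leukocytes-unmethylation-for-purity: tumor purity is the mean beta value
#' over the informative panel probes divided by a scale constant (default
#' 0.85) and capped at 1. A panel probe is informative when it is present in
#' the profile and its detection p-value is below the threshold; probes
#' failing detection are dropped from the average.
#'
#' @param profile A [methylation_profile()].
#' @param probe_panel Character vector of panel probe ids (see
#'   [default_lump_panel()] for the synthetic test panel).
#' @param detection_p_threshold Keep probes with `detection_p <` this
#'   (default 0.05).
#' @param scale Scale constant dividing the mean beta (default 0.85).
#' @return An object of class `purity_estimate`: `purity`, `n_probes_used`,
#'   `method = "LUMP"`, `sample_id`.
#' @export
lump_purity <- function(profile, probe_panel = default_lump_panel(),
                        detection_p_threshold = 0.05, scale = 0.85) {
  stopifnot(inherits(profile, "methylation_profile"),
            length(probe_panel) >= 1L, scale > 0)
  p <- profile$probes
  inf <- p[p$probe %in% probe_panel &
             p$detection_p < detection_p_threshold, , drop = FALSE]
  if (!nrow(inf)) {
    stop(sprintf("no informative LUMP probes for sample %s",
                 profile$sample_id), call. = FALSE)
  }
  structure(list(purity = min(1, mean(inf$beta) / scale),
                 n_probes_used = nrow(inf), method = "LUMP",
                 sample_id = profile$sample_id),
            class = "purity_estimate")
}

#' Wrap an externally determined purity value
#'
#' Purity values inferred by other means (e.g. sequencing-based estimators)
#' enter the pipeline through the same container as LUMP estimates; the gate
#' and the VAF adjustment are agnostic to the source.
#'
#' @param purity Fraction in `[0, 1]`.
#' @param sample_id Optional sample identifier.
#' @return An object of class `purity_estimate` with `method = "external"`.
#' @export
external_purity <- function(purity, sample_id = NA_character_) {
  stopifnot(purity >= 0, purity <= 1)
  structure(list(purity = purity, n_probes_used = NA_integer_,
                 method = "external", sample_id = sample_id),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("<purity_estimate> %s: %.3f (%s", x$sample_id, x$purity,
              x$method))
  if (!is.na(x$n_probes_used)) cat(sprintf(", %d probes", x$n_probes_used))
  cat(")\n")
  invisible(x)
}

#' MGMT promoter methylation call
#'
#' A sample is `"methylated"` when the sentinel probe's beta value is
#' strictly above the threshold AND the mean beta over the available promoter
#' probes is strictly above the threshold; `"unmethylated"` when the sentinel
#' is present but either condition fails; `"indeterminate"` when the sentinel
#' probe (or every promoter probe) is missing.
#'
#' @param profile A [methylation_profile()].
#' @param sentinel_probe Sentinel CpG probe id (default `"cg12981137"`).
#' @param promoter_probes Promoter-region probe ids (default the synthetic
#'   placeholder set, see [default_mgmt_promoter_probes()]).
#' @param beta_threshold Beta threshold, strict (default 0.2).
#' @return `"methylated"`, `"unmethylated"` or `"indeterminate"`.
#' @export
mgmt_methylation_call <- function(profile,
                                  sentinel_probe = "cg12981137",
                                  promoter_probes = default_mgmt_promoter_probes(),
                                  beta_threshold = 0.2) {
  stopifnot(inherits(profile, "methylation_profile"))
  p <- profile$probes
  sent <- p$beta[p$probe == sentinel_probe]
  prom <- p$beta[p$probe %in% promoter_probes]
  if (!length(sent) || !length(prom)) {
    message(sprintf("sample %s: MGMT probes missing (sentinel %s, %d/%d promoter); call is indeterminate",
                    profile$sample_id,
                    if (length(sent)) "present" else "absent",
                    length(prom), length(promoter_probes)))
    return("indeterminate")
  }
  if (sent[1] > beta_threshold && mean(prom) > beta_threshold) {
    "methylated"
  } else {
    "unmethylated"
  }
}

#' Purity inclusion gate
#'
#' Include a sample exactly when its purity is at least `min_purity`
#' (equivalently, normal contamination at most `1 - min_purity`); the
#' boundary is inclusive.
#'
#' @param estimate A [lump_purity()]/[external_purity()] result, or a bare
#'   numeric purity.
#' @param min_purity Inclusion threshold (default 0.55).
#' @return `"include"` or `"exclude"`.
#' @export
purity_gate <- function(estimate, min_purity = 0.55) {
  purity <- if (inherits(estimate, "purity_estimate")) estimate$purity
            else as.numeric(estimate)
  stopifnot(is_scalar_number(purity))
  if (purity >= min_purity) "include" else "exclude"
}

#' Purity-adjust variant allele fractions
#'
#' Rescales observed VAFs to the tumor-cell fraction of reads under a
#' copy-neutral diploid admixture model: `adjusted = min(1, vaf / purity)`.
#' Note the admixture model is an assumption; it ignores copy-number
#' alterations at the variant locus.
#'
#' @param vaf Numeric vector of VAFs in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @return Adjusted VAFs (capped at 1).
#' @export
adjust_vaf <- function(vaf, purity) {
  if (!is_scalar_number(purity) || purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]", call. = FALSE)
  }
  stopifnot(all(vaf >= 0 & vaf <= 1, na.rm = TRUE))
  pmin(1, vaf / purity)
}
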