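# Synthetic clonal-growth cohorts: a discrete-generation branching process
# generates the neutral 1/f subclonal spectrum, selection events distort it,
# a treatment bottleneck creates shared/private structure between paired
# samples, and binomial read sampling adds sequencing noise with normal-cell
# contamination. Temozolomide-signature mutations can be injected into a
# designated hypermutator patient's relapse.

#' Tumor-growth simulation configuration
#'
#' Discrete-generation branching process: each generation, every cell
#' divides with probability `div_prob` (non-dividing cells persist); each
#' daughter independently dies with probability `death_prob` and acquires
#' `Poisson(mu)` novel mutations. The Bernoulli division step
#' desynchronizes lineages (cell-cycle heterogeneity) so clade sizes form a
#' continuum and the neutral 1/f subclonal spectrum emerges; with
#' deterministic synchronous division every clade fraction would be an
#' exact power of 1/2 and the spectrum a staircase. Growth stops at the
#' first generation with at least `n_final` cells. A selection event
#' `(size, s)` marks one random cell's lineage when the population first
#' reaches `size`; marked cells divide with probability
#' `min(1, div_prob * (1 + s))`.
#'
#' @param n_final Target population size (>= 10).
#' @param mu Mean novel mutations per daughter cell per division.
#' @param death_prob Per-daughter death probability in `[0, 0.5)`.
#' @param div_prob Per-generation division probability in `(0, 1]`
#'   (default 0.5).
#' @param selection_events List of `list(size =, s =)` events.
#' @param depth Mean sequencing depth for read sampling (default 1272).
#' @param purity Default tumor purity for read sampling.
#' @param background_spectrum Probabilities over the six substitution
#'   classes used to annotate growth mutations (default uniform).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param max_retries Retries on population extinction before erroring.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_final = 1e4, mu = 10, death_prob = 0,
                              div_prob = 0.5, selection_events = list(),
                              depth = 1272, purity = 1,
                              background_spectrum = NULL,
                              seed = NULL, max_retries = 100L) {
  stopifnot(n_final >= 10, mu >= 0, death_prob >= 0, death_prob < 0.5,
            div_prob > 0, div_prob <= 1, depth >= 1, purity > 0, purity <= 1)
  background_spectrum <- background_spectrum %||%
    stats::setNames(rep(1 / 6, 6), SUB_CLASSES)
  stopifnot(length(background_spectrum) == 6)
  for (ev in selection_events) {
    stopifnot(ev$size >= 1, ev$s >= 0)
  }
  structure(list(n_final = n_final, mu = mu, death_prob = death_prob,
                 div_prob = div_prob, selection_events = selection_events,
                 depth = depth, purity = purity,
                 background_spectrum = background_spectrum,
                 seed = seed, max_retries = as.integer(max_retries)),
            class = "simulation_config")
}

#' Expected M(f) slope of a neutral simulation
#'
#' Under neutral growth the fitted slope of M against `1/f - 1/f_max`
#' (with f the diploid VAF at purity 1) estimates the effective mutation
#' rate per effective division, `mu / beta` with `beta = 1 - 2 * death_prob`.
#'
#' @param cfg A [simulation_config()].
#' @return The expected slope in model units.
#' @export
expected_slope <- function(cfg) {
  cfg$mu / (1 - 2 * cfg$death_prob)
}

# ---------------------------------------------------------------------------
# Growth engine
# ---------------------------------------------------------------------------

# Grows a population from `n_founders` cells (founders may carry selection
# coefficients) until it reaches cfg$n_final cells or goes extinct. Nodes are
# numbered in creation order so every parent id precedes its children.
# Returns NULL on extinction.
#' @noRd
gw_grow <- function(n_founders, founder_s, cfg) {
  parent <- list(rep(0L, n_founders))
  nmut <- list(rep(0L, n_founders))
  founder <- list(seq_len(n_founders))
  gen_of <- list(rep(0L, n_founders))
  n_nodes <- n_founders
  alive <- seq_len(n_founders)
  alive_sel <- rep_len(founder_s, n_founders)
  alive_founder <- seq_len(n_founders)
  pending <- cfg$selection_events
  triggered <- rep(FALSE, length(pending))
  gen <- 0L
  while (length(alive) > 0L && length(alive) < cfg$n_final) {
    gen <- gen + 1L
    P <- length(alive)
    p_div <- pmin(1, cfg$div_prob * (1 + alive_sel))
    divides <- stats::runif(P) < p_div
    # dividing cells are replaced by their two daughters; others persist
    par_idx <- rep(alive[divides], each = 2L)
    d_sel <- rep(alive_sel[divides], each = 2L)
    d_founder <- rep(alive_founder[divides], each = 2L)
    surv <- stats::runif(length(par_idx)) >= cfg$death_prob
    par_idx <- par_idx[surv]; d_sel <- d_sel[surv]
    d_founder <- d_founder[surv]
    nd <- length(par_idx)
    if (nd == 0L && !any(!divides)) { alive <- integer(0); break }
    d_nmut <- stats::rpois(nd, cfg$mu)
    ids <- n_nodes + seq_len(nd)
    n_nodes <- n_nodes + nd

    i <- length(parent) + 1L
    parent[[i]] <- par_idx
    nmut[[i]] <- d_nmut
    founder[[i]] <- d_founder
    gen_of[[i]] <- rep.int(gen, nd)

    alive <- c(alive[!divides], ids)
    alive_sel <- c(alive_sel[!divides], d_sel)
    alive_founder <- c(alive_founder[!divides], d_founder)

    for (j in seq_along(pending)) {
      if (!triggered[j] && length(alive) >= pending[[j]]$size) {
        triggered[j] <- TRUE
        pick <- sample.int(length(alive), 1L)
        alive_sel[pick] <- pending[[j]]$s
      }
    }
  }
  if (!length(alive)) return(NULL)
  parent <- unlist(parent, use.names = FALSE)
  nmut <- unlist(nmut, use.names = FALSE)
  founder <- unlist(founder, use.names = FALSE)
  gen_of <- unlist(gen_of, use.names = FALSE)
  counts <- integer(n_nodes)
  counts[alive] <- 1L
  for (i in n_nodes:1) {
    if (counts[i] > 0L && parent[i] > 0L) {
      counts[parent[i]] <- counts[parent[i]] + counts[i]
    }
  }
  list(parent = parent, nmut = nmut, founder = founder, gen = gen_of,
       counts = counts, alive = alive, n_cells = length(alive),
       generations = gen,
       founder_counts = tabulate(founder[alive], nbins = n_founders))
}

#' @noRd
grow_with_retries <- function(n_founders, founder_s, cfg) {
  for (i in seq_len(cfg$max_retries)) {
    res <- gw_grow(n_founders, founder_s, cfg)
    if (!is.null(res)) return(res)
  }
  stop(sprintf("population went extinct in all %d attempts", cfg$max_retries),
       call. = FALSE)
}

# Random substitution annotations for n mutations.
#' @noRd
make_mutation_annotations <- function(n, spectrum) {
  if (n == 0L) {
    return(data.frame(class = character(), ref = character(),
                      alt = character(), context_5p = character(),
                      context_3p = character(), gene = character(),
                      consequence = character(), damaging_pred = logical(),
                      stringsAsFactors = FALSE))
  }
  cls <- sample(SUB_CLASSES, n, replace = TRUE, prob = spectrum)
  pyr_ref <- substr(cls, 1, 1)
  pyr_alt <- substr(cls, 3, 3)
  on_purine <- stats::runif(n) < 0.5
  ref <- ifelse(on_purine, revcomp_base(pyr_ref), pyr_ref)
  alt <- ifelse(on_purine, revcomp_base(pyr_alt), pyr_alt)
  consequence <- sample(CONSEQUENCE_LEVELS, n, replace = TRUE,
                        prob = c(0.45, 0.15, 0.05, 0.25, 0.10))
  damaging <- ifelse(consequence == "nonsynonymous",
                     stats::runif(n) < 0.5, NA)
  data.frame(
    class = cls, ref = ref, alt = alt,
    context_5p = sample(BASES, n, replace = TRUE),
    context_3p = sample(BASES, n, replace = TRUE),
    gene = sprintf("G%03d", sample.int(409L, n, replace = TRUE)),
    consequence = consequence, damaging_pred = damaging,
    stringsAsFactors = FALSE
  )
}

#' Simulate a tumor by branching growth
#'
#' Runs the Galton-Watson growth of [simulation_config()] and reports every
#' surviving mutation with its ground-truth cell fraction (carrier cells /
#' final population). Mutations are annotated with a substitution class
#' drawn from the background spectrum, flanking context bases, and a gene /
#' consequence / damaging annotation so the downstream readers and filters
#' see realistic columns.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `simulated_tumor`: `mutations` (data frame
#'   with `id`, `node`, `cell_fraction`, `origin` and annotation columns),
#'   `tree` (parent links, generation, per-node carrier counts), `n_cells`,
#'   `generations`, `config`.
#' @export
simulate_tumor <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- grow_with_retries(1L, 0, cfg)
  keep <- which(res$nmut > 0L & res$counts > 0L)
  mut_node <- rep.int(keep, res$nmut[keep])
  n <- length(mut_node)
  ann <- make_mutation_annotations(n, cfg$background_spectrum)
  mutations <- cbind(
    data.frame(id = seq_len(n), node = mut_node,
               cell_fraction = res$counts[mut_node] / res$n_cells,
               origin = rep.int("growth", n), stringsAsFactors = FALSE),
    ann
  )
  structure(
    list(mutations = mutations,
         tree = list(parent = res$parent, gen = res$gen,
                     counts = res$counts, alive = res$alive,
                     founder = res$founder),
         n_cells = res$n_cells, generations = res$generations,
         config = cfg),
    class = "simulated_tumor")
}

#' @export
print.simulated_tumor <- function(x, ...) {
  cat(sprintf("<simulated_tumor> %d cells, %d generations, %d mutations\n",
              x$n_cells, x$generations, nrow(x$mutations)))
  invisible(x)
}

#' Sample sequencing reads from a simulated tumor
#'
#' Per mutation the site depth is `Poisson(depth)` and the alternate read
#' count `Binomial(site depth, purity * cell_fraction / 2)` (heterozygous,
#' copy-neutral diploid admixture). Sites with zero depth or zero alternate
#' reads are not reported — undetected mutations simply do not appear in
#' the call set. Quality and caller p-value are filled with passing
#' defaults; substitution and context annotations are copied through.
#'
#' @param tumor A [simulate_tumor()] result (or any object with a
#'   compatible `mutations` data frame).
#' @param depth Mean sequencing depth.
#' @param purity Tumor purity in `(0, 1]`.
#' @param sample_id,patient_id,timepoint Identifiers for the resulting call
#'   set.
#' @param pos_offset Offset added to mutation ids to form genomic positions
#'   (keeps keys distinct between patients).
#' @param seed Optional seed.
#' @return A [sample_call()].
#' @export
sample_reads <- function(tumor, depth = NULL, purity = NULL,
                         sample_id = "S1", patient_id = "P1",
                         timepoint = "diagnosis", pos_offset = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depth <- depth %||% tumor$config$depth
  purity <- purity %||% tumor$config$purity
  stopifnot(depth >= 1, purity > 0, purity <= 1)
  m <- tumor$mutations
  n <- nrow(m)
  dp <- stats::rpois(n, depth)
  evaf <- pmin(1, purity * m$cell_fraction / 2)
  alt <- stats::rbinom(n, dp, evaf)
  det <- which(dp > 0L & alt > 0L)
  variants <- data.frame(
    chrom = "chr1", pos = pos_offset + m$id[det],
    ref = m$ref[det], alt = m$alt[det],
    vaf = alt[det] / dp[det], depth = dp[det], alt_reads = alt[det],
    qual = 99, caller_p = 1e-6,
    gene = m$gene[det], consequence = m$consequence[det],
    pop_maf = NA_real_,
    context_5p = m$context_5p[det], context_3p = m$context_3p[det],
    damaging_pred = m$damaging_pred[det],
    stringsAsFactors = FALSE
  )
  sample_call(sample_id, patient_id, timepoint, variants, purity = purity)
}

# ---------------------------------------------------------------------------
# Paired cases and cohorts
# ---------------------------------------------------------------------------

#' Cohort simulation configuration
#'
#' Defaults emulate a 21-patient paired glioblastoma cohort: 3 of 21
#' patients untreated, targeted sequencing at mean depth 1272x, and one
#' treated patient (the last) whose relapse receives an injected
#' temozolomide signature. Treatment is modelled as a population bottleneck
#' at relapse, biased toward a resistant subclonal lineage that regrows with
#' fitness advantage `relapse_selection_s`; untreated patients regrow from
#' an unbiased bottleneck with no advantage.
#'
#' @param n_patients Number of paired patients.
#' @param fraction_untreated Fraction of patients left untreated (assigned
#'   to the first patients).
#' @param relapse_selection_s Fitness advantage of the resistant lineage in
#'   treated relapses (0 disables selection).
#' @param bottleneck_fraction Fraction of cells surviving the relapse
#'   bottleneck in untreated patients (post-surgical regrowth retains bulk
#'   tumor; default 0.05).
#' @param treated_bottleneck_fraction Fraction surviving the cytotoxic
#'   treatment bottleneck in treated patients (default 0.001, i.e. ~10
#'   founder cells at the default `n_final`); the few-founder regrowth is
#'   what produces relapse-specific subclonal clusters.
#' @param tmz_injection_count Temozolomide-signature mutations injected into
#'   each hypermutator patient's relapse (C>T at CpC/CpT contexts).
#' @param hypermutator_patients Indices of injection-configured patients;
#'   default the last patient (`integer(0)` for none).
#' @param n_final,mu,death_prob,depth As in [simulation_config()].
#' @param purity_range Per-sample purity drawn uniformly from this range.
#' @param mgmt_methylated_fraction Fraction of patients simulated as MGMT
#'   promoter methylated.
#' @param seed Integer seed (per-patient streams are derived from it), or
#'   `NULL` for the current RNG stream.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 21L, fraction_untreated = 3 / 21,
                              relapse_selection_s = 1.0,
                              bottleneck_fraction = 0.05,
                              treated_bottleneck_fraction = 0.001,
                              tmz_injection_count = 600L,
                              hypermutator_patients = NULL,
                              n_final = 1e4, mu = 10, death_prob = 0,
                              depth = 1272, purity_range = c(0.6, 0.95),
                              mgmt_methylated_fraction = 0.3, seed = NULL) {
  stopifnot(n_patients >= 1, fraction_untreated >= 0, fraction_untreated <= 1,
            relapse_selection_s >= 0, bottleneck_fraction > 0,
            bottleneck_fraction <= 1, treated_bottleneck_fraction > 0,
            treated_bottleneck_fraction <= 1, tmz_injection_count >= 0,
            length(purity_range) == 2, purity_range[1] <= purity_range[2])
  hypermutator_patients <- hypermutator_patients %||% n_patients
  structure(list(
    n_patients = as.integer(n_patients),
    fraction_untreated = fraction_untreated,
    relapse_selection_s = relapse_selection_s,
    bottleneck_fraction = bottleneck_fraction,
    treated_bottleneck_fraction = treated_bottleneck_fraction,
    tmz_injection_count = as.integer(tmz_injection_count),
    hypermutator_patients = as.integer(hypermutator_patients),
    n_final = n_final, mu = mu, death_prob = death_prob, depth = depth,
    purity_range = purity_range,
    mgmt_methylated_fraction = mgmt_methylated_fraction, seed = seed),
    class = "cohort_sim_config")
}

#' @noRd
n_untreated_of <- function(cfg) round(cfg$fraction_untreated * cfg$n_patients)

# Marks all descendants of `node` (including itself) in a grown tree.
#' @noRd
mark_descendants <- function(parent, node) {
  mark <- logical(length(parent))
  if (is.null(node) || is.na(node)) return(mark)
  mark[node] <- TRUE
  idx <- which(seq_along(parent) > node & parent > 0L)
  for (i in idx) if (mark[parent[i]]) mark[i] <- TRUE
  mark
}

#' Simulate one patient's matched diagnosis/relapse pair
#'
#' The diagnosis sample is read-sampled from a grown tumor; the relapse
#' regrows from a bottleneck of surviving cells (unbiased for untreated
#' patients, biased toward a resistant subclonal lineage with advantage
#' `relapse_selection_s` for treated patients), accumulating new mutations
#' during regrowth. Injection-configured treated patients additionally
#' receive `tmz_injection_count` C>T mutations at CpC/CpT contexts and
#' subclonal-to-intermediate cell fractions in the relapse.
#'
#' @param cfg A [cohort_sim_config()].
#' @param patient_index Index in `1:n_patients`; the first
#'   `round(fraction_untreated * n_patients)` patients are untreated.
#' @return An object of class `simulated_case`: `case` (a [paired_case()]),
#'   `methylation` (profiles for both samples), `metadata_row`, and `truth`
#'   (treated/hypermutator flags, purities, injected ids).
#' @export
simulate_paired_case <- function(cfg, patient_index) {
  stopifnot(inherits(cfg, "cohort_sim_config"),
            patient_index >= 1, patient_index <= cfg$n_patients)
  if (!is.null(cfg$seed)) {
    set.seed((cfg$seed + patient_index * 7919L) %% .Machine$integer.max)
  }
  treated <- patient_index > n_untreated_of(cfg)
  hyper <- treated && patient_index %in% cfg$hypermutator_patients
  s <- if (treated) cfg$relapse_selection_s else 0
  pid <- sprintf("P%02d", patient_index)
  pos_offset <- patient_index * 1e7

  sim_cfg <- simulation_config(n_final = cfg$n_final, mu = cfg$mu,
                               death_prob = cfg$death_prob,
                               depth = cfg$depth, seed = NULL)
  t1 <- simulate_tumor(sim_cfg)
  purity_d <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
  purity_r <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
  diagnosis <- sample_reads(t1, depth = cfg$depth, purity = purity_d,
                            sample_id = paste0(pid, "_diagnosis"),
                            patient_id = pid, timepoint = "diagnosis",
                            pos_offset = pos_offset)

  # bottleneck: survivors among the final cells; the treatment bottleneck
  # is far more severe than untreated post-surgical regrowth
  bf <- if (treated) cfg$treated_bottleneck_fraction else cfg$bottleneck_fraction
  k <- max(1L, round(bf * t1$n_cells))
  resistant <- rep(FALSE, length(t1$tree$alive))
  if (treated && s > 0) {
    cf <- t1$mutations$cell_fraction
    cand <- t1$mutations$node[cf >= 0.1 & cf <= 0.6]
    if (length(cand)) {
      rnode <- cand[sample.int(length(cand), 1L)]
      resistant <- mark_descendants(t1$tree$parent, rnode)[t1$tree$alive]
    }
  }
  w <- ifelse(resistant, 1 + s, 1)
  pick <- sample.int(length(t1$tree$alive), size = min(k, length(t1$tree$alive)),
                     prob = w)
  survivors <- t1$tree$alive[pick]
  founder_s <- if (treated) ifelse(resistant[pick], s, 0) else rep(0, length(pick))

  res2 <- grow_with_retries(length(survivors), founder_s, sim_cfg)

  # old mutations: weight each tumor-1 cell by its relapse descendant count
  w1 <- numeric(length(t1$tree$parent))
  w1[survivors] <- res2$founder_counts
  for (i in length(w1):1) {
    if (w1[i] > 0 && t1$tree$parent[i] > 0L) {
      w1[t1$tree$parent[i]] <- w1[t1$tree$parent[i]] + w1[i]
    }
  }
  old <- t1$mutations
  old$cell_fraction <- w1[old$node] / res2$n_cells
  old <- old[old$cell_fraction > 0, , drop = FALSE]

  # novel regrowth mutations
  keep <- which(res2$nmut > 0L & res2$counts > 0L)
  new_node <- rep.int(keep, res2$nmut[keep])
  n_new <- length(new_node)
  id0 <- if (nrow(t1$mutations)) max(t1$mutations$id) else 0L
  new <- cbind(
    data.frame(id = id0 + seq_len(n_new), node = new_node,
               cell_fraction = res2$counts[new_node] / res2$n_cells,
               origin = rep.int("growth", n_new), stringsAsFactors = FALSE),
    make_mutation_annotations(n_new, sim_cfg$background_spectrum)
  )

  injected_ids <- integer(0)
  inj <- NULL
  if (hyper && cfg$tmz_injection_count > 0L) {
    n_inj <- cfg$tmz_injection_count
    ann <- make_mutation_annotations(n_inj, sim_cfg$background_spectrum)
    on_purine <- stats::runif(n_inj) < 0.5
    ann$class <- "C>T"
    ann$ref <- ifelse(on_purine, "G", "C")
    ann$alt <- ifelse(on_purine, "A", "T")
    pyr_3p <- sample(c("C", "T"), n_inj, replace = TRUE)  # CpC / CpT 50:50
    ann$context_3p <- ifelse(on_purine, sample(BASES, n_inj, TRUE), pyr_3p)
    ann$context_5p <- ifelse(on_purine, revcomp_base(pyr_3p),
                             sample(BASES, n_inj, TRUE))
    injected_ids <- id0 + n_new + seq_len(n_inj)
    inj <- cbind(
      data.frame(id = injected_ids, node = NA_integer_,
                 cell_fraction = stats::runif(n_inj, 0.2, 0.6),
                 origin = "injected_tmz", stringsAsFactors = FALSE),
      ann
    )
  }
  t2 <- structure(
    list(mutations = rbind(old, new, inj), n_cells = res2$n_cells,
         generations = res2$generations, config = sim_cfg),
    class = "simulated_tumor")
  relapse <- sample_reads(t2, depth = cfg$depth, purity = purity_r,
                          sample_id = paste0(pid, "_relapse"),
                          patient_id = pid, timepoint = "relapse",
                          pos_offset = pos_offset)

  mgmt <- stats::runif(1) < cfg$mgmt_methylated_fraction
  ttr <- max(1, round(stats::rlnorm(1, log(if (treated) 9 else 3), 0.45)))
  surv <- ttr + max(1, round(stats::rlnorm(1, log(7), 0.4)))
  detail <- if (treated) "concomitant RT/TMZ and adjuvant TMZ" else "none"
  case <- paired_case(pid, diagnosis, relapse,
                      treatment = if (treated) "treated" else "untreated",
                      treatment_detail = detail,
                      time_to_recurrence_months = ttr,
                      survival_months = surv)
  methylation <- list(
    diagnosis = simulate_methylation(paste0(pid, "_diagnosis"), purity_d, mgmt),
    relapse = simulate_methylation(paste0(pid, "_relapse"), purity_r, mgmt)
  )
  structure(
    list(case = case, methylation = methylation,
         metadata_row = data.frame(
           patient_id = pid, gender = sample(c("F", "M"), 1),
           age_at_diagnosis = round(stats::runif(1, 30, 75)),
           primary_diagnosis = "GBM", diagnosis_of_recurrence = "GBM",
           treatment_prior_to_second_surgery = detail,
           time_to_recurrence_months = ttr, survival_months = surv,
           stringsAsFactors = FALSE),
         truth = list(treated = treated, hypermutator = hyper,
                      purity_diagnosis = purity_d, purity_relapse = purity_r,
                      injected_ids = injected_ids,
                      injected_pos = pos_offset + injected_ids,
                      mgmt_methylated = mgmt)),
    class = "simulated_case")
}

# Methylation betas consistent with a configured purity: the LUMP panel
# betas centre on purity * 0.85 so that lump_purity() recovers the purity;
# five fixed panel probes fail detection to exercise the informative-probe
# filter. MGMT probes centre on 0.4 (methylated) or 0.05 (unmethylated).
#' @noRd
simulate_methylation <- function(sample_id, purity, mgmt_methylated,
                                 panel = default_lump_panel()) {
  clamp <- function(x) pmin(1, pmax(0, x))
  lump_beta <- clamp(stats::rnorm(length(panel), purity * 0.85, 0.01))
  det_p <- rep(0.01, length(panel))
  det_p[seq(length(panel) - 4L, length(panel))] <- 0.5  # 5 failing probes
  mgmt_probes <- c("cg12981137", default_mgmt_promoter_probes())
  mgmt_mu <- if (mgmt_methylated) 0.4 else 0.05
  mgmt_beta <- clamp(stats::rnorm(length(mgmt_probes), mgmt_mu, 0.03))
  methylation_profile(sample_id, data.frame(
    probe = c(panel, mgmt_probes),
    beta = c(lump_beta, mgmt_beta),
    detection_p = c(det_p, rep(0.01, length(mgmt_probes))),
    stringsAsFactors = FALSE
  ))
}

#' Simulate a full paired cohort
#'
#' Generates every patient of the configuration and assembles the three
#' pipeline inputs: the per-sample variant calls, the clinical metadata
#' table and per-sample methylation profiles whose LUMP betas recover each
#' sample's configured purity. Fully reproducible from `cfg$seed`; with
#' `dir` given, the three TSV files are written in the package's dialects
#' and identical runs produce byte-identical files.
#'
#' @param cfg A [cohort_sim_config()].
#' @param dir Optional output directory for `variants.tsv`, `metadata.tsv`
#'   and `methylation.tsv`.
#' @return An object of class `clonevo_cohort`: `samples` (named list of
#'   [sample_call()]), `cases` (named list of [paired_case()]), `metadata`,
#'   `methylation` (named list of profiles), `truth`, `config`, and `files`
#'   when written.
#' @export
simulate_cohort <- function(cfg = cohort_sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  sims <- lapply(seq_len(cfg$n_patients), function(i)
    simulate_paired_case(cfg, i))
  cases <- lapply(sims, function(s) s$case)
  names(cases) <- vapply(cases, function(c) c$patient_id, character(1))
  samples <- list()
  methylation <- list()
  for (s in sims) {
    samples[[s$case$diagnosis$sample_id]] <- s$case$diagnosis
    samples[[s$case$relapse$sample_id]] <- s$case$relapse
    methylation[[s$case$diagnosis$sample_id]] <- s$methylation$diagnosis
    methylation[[s$case$relapse$sample_id]] <- s$methylation$relapse
  }
  metadata <- do.call(rbind, lapply(sims, function(s) s$metadata_row))
  truth <- lapply(sims, function(s) s$truth)
  names(truth) <- names(cases)
  out <- structure(
    list(samples = samples, cases = cases, metadata = metadata,
         methylation = methylation, truth = truth, config = cfg),
    class = "clonevo_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(variants = file.path(dir, "variants.tsv"),
               metadata = file.path(dir, "metadata.tsv"),
               methylation = file.path(dir, "methylation.tsv"))
    write_variant_table(samples, files[["variants"]])
    write_metadata_table(metadata, files[["metadata"]])
    write_methylation_table(methylation, files[["methylation"]])
    out$files <- files
  }
  out
}

#' @export
print.clonevo_cohort <- function(x, ...) {
  cat(sprintf("<clonevo_cohort> %d patients (%d untreated), %d samples\n",
              x$config$n_patients, n_untreated_of(x$config),
              length(x$samples)))
  invisible(x)
}

#' @noRd
write_metadata_table <- function(metadata, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(metadata), collapse = "\t"), con)
  rows <- apply(do.call(cbind, lapply(metadata, fmt_field)), 1L,
                paste, collapse = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' @noRd
write_methylation_table <- function(methylation, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("sample_id\tprobe\tbeta\tdetection_p", con)
  for (sid in names(methylation)) {
    p <- methylation[[sid]]$probes
    writeLines(paste(sid, p$probe, fmt_field(p$beta),
                     fmt_field(p$detection_p), sep = "\t"), con)
  }
  invisible(path)
}
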