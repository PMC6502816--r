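#' Catalog of condition-effect scenarios
#'
#' Machine-readable taxonomy of the ten hypothetical case-vs-control
#' effect patterns a paired-fraction experiment can exhibit: no change;
#' concordant abundance change in both fractions (up / down, leaving the
#' enrichment score unchanged); change in one fraction only (each
#' direction); moderate opposite-direction changes (cytosol-to-organelle
#' redistribution and its reverse), which move the enrichment score
#' while the lysate change stays sub-threshold; and a combined
#' induction-plus-enrichment pattern. The numbering is this package's
#' own declaration: the two pure redistribution scenarios sit at
#' positions 6 and 10.
#'
#' Effect codes refer to the configured effect sizes: `main` is the full
#' condition effect, `mod` the moderate (redistribution) effect, both in
#' log2 units.
#'
#' @return data.frame with columns `scenario`, `name`, `lysate`, `mito`
#'   (effect codes) and `mtfe_direction` (sign of the implied mtFE
#'   effect).
#' @export
scenario_catalog <- function() {
  cat <- data.frame(
    scenario = 1:10,
    name = c("none", "up_both", "down_both", "up_mito_only",
             "down_lysate_only", "redist_to_mito", "down_mito_only",
             "up_lysate_only", "up_both_enriched", "redist_to_cytosol"),
    lysate = c("0", "+main", "-main", "0", "-main", "-mod", "0",
               "+main", "+mod", "+mod"),
    mito = c("0", "+main", "-main", "+main", "0", "+mod", "-main",
             "0", "+main", "-mod"),
    stringsAsFactors = FALSE
  )
  code_val <- function(code, main, mod)
    switch(code, "0" = 0, "+main" = main, "-main" = -main,
           "+mod" = mod, "-mod" = -mod)
  l <- vapply(cat$lysate, code_val, numeric(1L), main = 1, mod = 0.5)
  m <- vapply(cat$mito, code_val, numeric(1L), main = 1, mod = 0.5)
  cat$mtfe_direction <- sign(m - l)
  cat
}

# numeric effects (log2) for each scenario given the configured sizes
.scenario_effects <- function(effect_main, effect_moderate) {
  cat <- scenario_catalog()
  code_val <- function(code)
    switch(code, "0" = 0, "+main" = effect_main, "-main" = -effect_main,
           "+mod" = effect_moderate, "-mod" = -effect_moderate)
  data.frame(
    scenario = cat$scenario, name = cat$name,
    lysate_effect = vapply(cat$lysate, code_val, numeric(1L)),
    mito_effect = vapply(cat$mito, code_val, numeric(1L)),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults state the world the generator emulates: a processed
#' DIA/SWATH two-fraction liver cohort of ~2,500 proteins across four
#' genotype-by-condition groups (8/8/6/6 mice), with organelle-dependent
#' fraction offsets matching the graded marker-panel enrichment means
#' (mitochondrion 1.62 ... spliceosome -1.27 log2 units), technical
#' noise calibrated to a replicate CV median near 8%, between-animal
#' biological variation shared by both fractions (and therefore
#' cancelling in the enrichment score), and a genotype confounder that
#' dominates abundances but, for most affected proteins, not the
#' enrichment score.
#'
#' @param n_proteins Number of simulated proteins.
#' @param class_props Named organelle class proportions (must sum to 1).
#' @param class_offsets Named log2 fraction offsets per organelle class.
#' @param baseline_mean,baseline_sd Log2 baseline abundance distribution.
#' @param scenario_counts Integer vector of length 10: planted proteins
#'   per scenario of [scenario_catalog()]; entry 1 (no change) is
#'   ignored and absorbs the remainder.
#' @param effect_main Log2 size of a full condition effect.
#' @param effect_moderate Log2 size of a moderate (redistribution)
#'   effect; default one technical noise sd, which keeps the per-fraction
#'   change sub-threshold at the default group sizes.
#' @param genotype_effect Log2 size of the genotype confounder.
#' @param genotype_frac Fraction of proteins carrying the genotype
#'   effect.
#' @param genotype_unequal_frac Fraction *of the affected proteins*
#'   whose genotype effect hits only the organelle fraction (and hence
#'   leaks into the enrichment score).
#' @param noise_sd Technical (replicate) noise sd, log2 units, per
#'   fraction; 0.12 gives a linear-scale replicate CV of ~8%.
#' @param bio_sd Between-subject biological sd, log2 units, shared by
#'   both fractions of a sample.
#' @param group_sizes Named sizes of the `condition.genotype` groups.
#' @param pairing `"grouped"` (independent groups) or `"paired"`
#'   (tumor/adjacent pairs from the same subject).
#' @param n_pairs Number of subjects in `"paired"` mode.
#' @param missing_rate Completely-at-random missingness per cell.
#'   Default 0: processed DIA matrices with requantification enabled are
#'   essentially complete; raise it to emulate sparser pipelines.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2500L,
                       class_props = c(mitochondrion = 0.24, peroxisome = 0.03,
                                       er = 0.10, cytosol = 0.38,
                                       nucleus = 0.17, spliceosome = 0.08),
                       class_offsets = c(mitochondrion = 1.62, peroxisome = 0.82,
                                         er = 0.27, cytosol = -1.03,
                                         nucleus = -1.12, spliceosome = -1.27),
                       baseline_mean = 14, baseline_sd = 2,
                       scenario_counts = c(0L, rep(40L, 9L)),
                       effect_main = 1.0, effect_moderate = NULL,
                       genotype_effect = 0.8, genotype_frac = 0.30,
                       genotype_unequal_frac = 0.05,
                       noise_sd = 0.12, bio_sd = 0.30,
                       group_sizes = c(Ctrl.WT = 8L, DEN.WT = 8L,
                                       Ctrl.KO = 6L, DEN.KO = 6L),
                       pairing = c("grouped", "paired"), n_pairs = 5L,
                       missing_rate = 0) {
  pairing <- match.arg(pairing)
  if (is.null(effect_moderate)) effect_moderate <- noise_sd
  cfg <- list(n_proteins = as.integer(n_proteins), class_props = class_props,
              class_offsets = class_offsets, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              scenario_counts = as.integer(scenario_counts),
              effect_main = effect_main, effect_moderate = effect_moderate,
              genotype_effect = genotype_effect, genotype_frac = genotype_frac,
              genotype_unequal_frac = genotype_unequal_frac,
              noise_sd = noise_sd, bio_sd = bio_sd, group_sizes = group_sizes,
              pairing = pairing, n_pairs = as.integer(n_pairs),
              missing_rate = missing_rate)
  if (abs(sum(cfg$class_props) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (!setequal(names(cfg$class_props), names(cfg$class_offsets)))
    stop("class_props and class_offsets must name the same classes")
  if (length(cfg$scenario_counts) != 10L)
    stop("scenario_counts must have length 10")
  if (sum(cfg$scenario_counts[-1L]) > cfg$n_proteins)
    stop("planted scenario counts exceed the protein count")
  if (any(c(cfg$baseline_sd, cfg$noise_sd, cfg$bio_sd) < 0))
    stop("standard deviations must be >= 0")
  if (cfg$pairing == "grouped" && any(cfg$group_sizes < 2L))
    stop("group sizes must be >= 2")
  if (cfg$pairing == "paired" && cfg$n_pairs < 2L)
    stop("need >= 2 pairs")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

.sim_samples <- function(cfg) {
  if (cfg$pairing == "grouped") {
    grp <- rep(names(cfg$group_sizes), cfg$group_sizes)
    parts <- strsplit(grp, ".", fixed = TRUE)
    condition <- vapply(parts, `[`, character(1L), 1L)
    genotype <- vapply(parts, `[`, character(1L), 2L)
    n <- length(grp)
    sid <- sprintf("s%02d", seq_len(n))
    data.frame(sample_id = sid, subject_id = sprintf("m%02d", seq_len(n)),
               genotype = genotype, condition = condition,
               cohort = "sim", pair_id = "", replicate = 0L,
               stringsAsFactors = FALSE)
  } else {
    subj <- sprintf("m%02d", seq_len(cfg$n_pairs))
    data.frame(sample_id = c(paste0(subj, "_N"), paste0(subj, "_T")),
               subject_id = rep(subj, 2L), genotype = "WT",
               condition = rep(c("Adjacent", "Tumor"), each = cfg$n_pairs),
               cohort = "sim", pair_id = rep(subj, 2L), replicate = 0L,
               stringsAsFactors = FALSE)
  }
}

#' Generate a paired two-fraction cohort with known ground truth
#'
#' Simulates matched lysate and organelle-fraction log2 abundance
#' matrices under the additive model
#' `lysate = baseline + bio + genotype + condition_lysate + noise` and
#' `mito = baseline + bio + class_offset + genotype(mito) +
#' condition_mito + noise`, where `bio` is a per-(protein, subject)
#' biological deviation shared between fractions, effects are additive
#' on log2 scale, and the two noise draws are independent. Condition
#' effects follow the scenario taxonomy of [scenario_catalog()];
#' genotype effects hit both fractions equally (cancelling in the
#' enrichment score) except for a configurable minority hitting only
#' the organelle fraction. Missing cells are injected completely at
#' random. Fully reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer random seed.
#' @return List of class `sim_cohort`: `mito` and `lysate`
#'   ([quant_matrix]), `meta` (`sample_metadata`), `truth` (per-protein
#'   data.frame with organelle class, scenario, per-fraction condition
#'   effects, implied mtFE effect, genotype effect and baseline),
#'   `config`, `seed`.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, .generate_cohort_impl(config, seed))
}

.generate_cohort_impl <- function(config, seed) {
  cfg <- config
  np <- cfg$n_proteins
  prot <- sprintf("P%04d", seq_len(np))
  classes <- names(cfg$class_props)
  organelle <- sample(classes, np, replace = TRUE, prob = cfg$class_props)
  offset <- unname(cfg$class_offsets[organelle])

  scenario <- rep(1L, np)
  planted_total <- sum(cfg$scenario_counts[-1L])
  planted_idx <- sample(np, planted_total)
  scenario[planted_idx] <- rep(2:10, cfg$scenario_counts[-1L])
  eff <- .scenario_effects(cfg$effect_main, cfg$effect_moderate)
  lys_eff <- eff$lysate_effect[scenario]
  mit_eff <- eff$mito_effect[scenario]

  n_gen <- round(cfg$genotype_frac * np)
  gen_idx <- sample(np, n_gen)
  gen_eff <- numeric(np)
  gen_eff[gen_idx] <- sample(c(-1, 1), n_gen, replace = TRUE) * cfg$genotype_effect
  unequal <- rep(FALSE, np)
  if (n_gen > 0L && cfg$genotype_unequal_frac > 0) {
    n_un <- round(cfg$genotype_unequal_frac * n_gen)
    if (n_un > 0L) unequal[sample(gen_idx, n_un)] <- TRUE
  }

  meta <- .sim_samples(cfg)
  ns <- nrow(meta)
  is_ko <- meta$genotype == "KO"
  is_case <- meta$condition %in% c("DEN", "Tumor")
  baseline <- stats::rnorm(np, cfg$baseline_mean, cfg$baseline_sd)

  subj <- unique(meta$subject_id)
  bio_subj <- matrix(stats::rnorm(np * length(subj), 0, cfg$bio_sd),
                     nrow = np, dimnames = list(prot, subj))
  bio <- bio_subj[, meta$subject_id, drop = FALSE]

  case_row <- matrix(as.numeric(is_case), nrow = np, ncol = ns, byrow = TRUE)
  ko_row <- matrix(as.numeric(is_ko), nrow = np, ncol = ns, byrow = TRUE)

  gen_lys <- ifelse(unequal, 0, gen_eff)
  gen_mit <- gen_eff
  sys_lys <- baseline + bio + outer(gen_lys, as.numeric(is_ko)) +
    outer(lys_eff, as.numeric(is_case))
  sys_mit <- baseline + offset + bio + outer(gen_mit, as.numeric(is_ko)) +
    outer(mit_eff, as.numeric(is_case))

  lys <- sys_lys + matrix(stats::rnorm(np * ns, 0, cfg$noise_sd), np, ns)
  mit <- sys_mit + matrix(stats::rnorm(np * ns, 0, cfg$noise_sd), np, ns)
  dimnames(lys) <- dimnames(mit) <- list(prot, meta$sample_id)
  if (cfg$missing_rate > 0) {
    lys[matrix(stats::runif(np * ns) < cfg$missing_rate, np, ns)] <- NA
    mit[matrix(stats::runif(np * ns) < cfg$missing_rate, np, ns)] <- NA
  }

  truth <- data.frame(
    protein_id = prot, organelle = organelle, scenario = scenario,
    scenario_name = scenario_catalog()$name[scenario],
    lysate_effect = lys_eff, mito_effect = mit_eff,
    mtfe_effect = mit_eff - lys_eff,
    genotype_effect = gen_eff, genotype_unequal = unequal,
    baseline = baseline, class_offset = offset,
    stringsAsFactors = FALSE
  )
  structure(list(mito = quant_matrix(mit, "mito"),
                 lysate = quant_matrix(lys, "lysate"),
                 meta = sample_metadata(meta), truth = truth,
                 config = cfg, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d proteins x %d samples (%s design), seed %d\n",
              nrow(x$mito), ncol(x$mito), x$config$pairing, x$seed))
  cat("  planted scenarios:\n")
  tb <- table(x$truth$scenario_name[x$truth$scenario != 1L])
  for (nm in names(tb)) cat(sprintf("    %-18s %d\n", nm, tb[[nm]]))
  invisible(x)
}

#' Generate a technical-replicate experiment
#'
#' Repeated fractionations of a single tissue piece: the biological
#' component is fixed, only technical noise varies between replicates.
#' This is the design used to calibrate replicate CVs.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicate preparations.
#' @param seed Integer random seed.
#' @return List: `mito`, `lysate` ([quant_matrix] of replicates), `meta`.
#' @export
generate_replicates <- function(config, n_reps = 5L, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 2L)
  .with_seed(seed, .generate_replicates_impl(config, n_reps))
}

.generate_replicates_impl <- function(config, n_reps) {
  cfg <- config
  np <- cfg$n_proteins
  prot <- sprintf("P%04d", seq_len(np))
  organelle <- sample(names(cfg$class_props), np, replace = TRUE,
                      prob = cfg$class_props)
  offset <- unname(cfg$class_offsets[organelle])
  baseline <- stats::rnorm(np, cfg$baseline_mean, cfg$baseline_sd)
  bio <- stats::rnorm(np, 0, cfg$bio_sd)   # one tissue: fixed across reps
  sid <- sprintf("rep%d", seq_len(n_reps))
  lys <- baseline + bio +
    matrix(stats::rnorm(np * n_reps, 0, cfg$noise_sd), np, n_reps)
  mit <- baseline + bio + offset +
    matrix(stats::rnorm(np * n_reps, 0, cfg$noise_sd), np, n_reps)
  dimnames(lys) <- dimnames(mit) <- list(prot, sid)
  meta <- sample_metadata(data.frame(
    sample_id = sid, subject_id = "rep_tissue", genotype = "WT",
    condition = "Ctrl", cohort = "replicates", pair_id = "",
    replicate = 1L, stringsAsFactors = FALSE))
  list(mito = quant_matrix(mit, "mito"),
       lysate = quant_matrix(lys, "lysate"),
       meta = meta, organelle = stats::setNames(organelle, prot))
}

#' Detection and false-positive rates against simulation truth
#'
#' Per-scenario, per-data-type fraction of planted proteins called
#' significant, plus the type-I error rate, computed over fully-null
#' proteins (no condition scenario and no genotype effect; a
#' genotype-affected "none"-scenario protein is true signal for the
#' genotype comparisons). Per-scenario rates count detection through any
#' comparison, so in confounded cohorts they include genuine genotype
#' detections. The detection criterion is configurable: raw ANOVA
#' p below alpha (default, the test's operating characteristic),
#' BH-adjusted p below alpha, or the full per-comparison flag
#' (adjusted ANOVA and Tukey p both below alpha for at least one
#' comparison).
#'
#' @param truth The `truth` component of a `sim_cohort`.
#' @param tables Named list of `differential_table`s, one per data type,
#'   computed on the same cohort (identical protein universe required).
#' @param alpha Significance level.
#' @param criterion `"raw"`, `"bh"` or `"flag"`.
#' @return List: `rates` (data.frame scenario x data type) and `type1`
#'   (named vector per data type).
#' @export
evaluate_recovery <- function(truth, tables, alpha = 0.05,
                              criterion = c("raw", "bh", "flag")) {
  criterion <- match.arg(criterion)
  stopifnot(!is.null(names(tables)))
  for (nm in names(tables)) {
    if (!setequal(tables[[nm]]$protein_id, truth$protein_id))
      stop("protein universe of table '", nm, "' does not match the truth")
  }
  detect <- function(tab) {
    tab <- tab[match(truth$protein_id, tab$protein_id), , drop = FALSE]
    switch(criterion,
           raw = !is.na(tab$p_value) & tab$p_value < alpha,
           bh = !is.na(tab$p_adj) & tab$p_adj < alpha,
           flag = {
             sig_cols <- grep("^sig_", colnames(tab), value = TRUE)
             rowSums(as.matrix(tab[, sig_cols, drop = FALSE])) > 0
           })
  }
  det <- vapply(tables, detect, logical(nrow(truth)))
  scen <- scenario_catalog()
  rates <- do.call(rbind, lapply(scen$scenario, function(s) {
    idx <- truth$scenario == s
    if (!any(idx)) return(NULL)
    cbind(data.frame(scenario = s, name = scen$name[s], n = sum(idx),
                     stringsAsFactors = FALSE),
          as.data.frame(t(colMeans(det[idx, , drop = FALSE]))))
  }))
  rownames(rates) <- NULL
  # type-I error only over fully-null proteins: no condition scenario AND
  # no genotype effect (genotype-affected "none" proteins are true signal
  # for the genotype comparisons, not false positives)
  null_idx <- truth$scenario == 1L
  if (!is.null(truth$genotype_effect))
    null_idx <- null_idx & truth$genotype_effect == 0
  type1 <- if (any(null_idx))
    colMeans(det[null_idx, , drop = FALSE])
  else stats::setNames(rep(NA_real_, ncol(det)), colnames(det))
  list(rates = rates, type1 = type1, criterion = criterion, alpha = alpha)
}
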