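#' Run the full discovery workflow and summarize it
#'
#' Chains alignment, enrichment scoring, optional QC, four-group
#' differential analysis of the three data types (lysate, mito, mtFE),
#' significant-set accounting and overlap, hierarchical clustering of
#' each significant subset with partition-agreement statistics, and
#' single-feature classifier ranking, into one machine-readable summary.
#'
#' @param mito,lysate [quant_matrix] objects for the two fractions.
#' @param meta `sample_metadata` covering all samples.
#' @param panels Optional list of `marker_panel`s for QC panel means.
#' @param alpha Significance level for the differential stage.
#' @param k Cluster count for the partition-agreement stage.
#' @param scheme,folds,seed Classifier cross-validation settings.
#' @param restrict_to Optional `marker_panel`/character vector
#'   restricting classifier input (e.g. organelle-annotated proteins);
#'   applied on top of the per-type significant union.
#' @param case,control Condition labels of the classification contrast;
#'   defaults to the two condition levels (second sorted = case).
#' @param top_k Depth of the consensus ranking lists.
#' @return List of class `mtfe_report`: `counts`, `panel_means`,
#'   `differential` (tables), `sets`, `overlap`, `clustering`,
#'   `ranking`, `consensus`, `provenance`.
#' @export
run_report <- function(mito, lysate, meta, panels = NULL, alpha = 0.05,
                       k = 2L, scheme = "kfold", folds = 5L, seed = 1L,
                       restrict_to = NULL, case = NULL, control = NULL,
                       top_k = 10L) {
  pair <- align_fractions(mito, lysate, meta)
  E <- compute_mtfe(pair)
  mats <- list(lysate = unclass(pair$lysate), mito = unclass(pair$mito),
               mtfe = unclass(E))

  design <- fourgroup_design(meta, samples = colnames(E))
  tables <- lapply(mats, function(x)
    anova_tukey(x, design$groups, alpha = alpha,
                comparisons = design$comparisons))
  sets <- significant_sets(tables, alpha = alpha)
  unions <- lapply(sets, `[[`, "union")
  overlap <- set_overlap(unions)

  df <- as.data.frame(meta)
  conds <- sort(unique(df$condition[match(colnames(E), df$sample_id)]))
  if (is.null(control)) control <- conds[1L]
  if (is.null(case)) case <- setdiff(conds, control)[1L]
  labels <- stats::setNames(
    df$condition[match(colnames(E), df$sample_id)] == case, colnames(E))
  genos <- stats::setNames(
    df$genotype[match(colnames(E), df$sample_id)], colnames(E))

  clustering <- lapply(names(mats), function(nm) {
    sub <- mats[[nm]][intersect(unions[[nm]], rownames(mats[[nm]])), ,
                      drop = FALSE]
    if (nrow(sub) < 2L) return(NULL)
    cr <- hclust_manhattan(sub)
    list(result = cr,
         ari_condition = partition_agreement(cr, k, labels)$ari,
         ari_genotype = partition_agreement(cr, k, genos)$ari)
  })
  names(clustering) <- names(mats)

  ranking <- lapply(names(mats), function(nm) {
    keep <- unions[[nm]]
    if (!is.null(restrict_to)) {
      members <- if (inherits(restrict_to, "marker_panel"))
        restrict_to$members else as.character(restrict_to)
      keep <- intersect(keep, members)
    }
    if (length(keep) < 1L) return(NULL)
    per_model <- lapply(c("lr", "nb"), function(mod)
      rank_features(mats[[nm]][keep, , drop = FALSE], labels,
                    models = mod, scheme = scheme, folds = folds,
                    seed = seed))
    names(per_model) <- c("lr", "nb")
    per_model
  })
  names(ranking) <- names(mats)
  consensus <- lapply(ranking, function(r) {
    if (is.null(r)) return(NULL)
    kk <- min(top_k, nrow(r$lr))
    consensus_top_k(r$lr, r$nb, k = kk)
  })

  panel_means <- NULL
  if (length(panels)) {
    ps <- lapply(panels, function(p) panel_stats(E, p))
    panel_means <- data.frame(
      panel = vapply(ps, `[[`, character(1L), "name"),
      organelle = vapply(ps, `[[`, character(1L), "organelle"),
      n_present = vapply(ps, function(x) length(x$per_protein), integer(1L)),
      mean_mtfe = vapply(ps, `[[`, numeric(1L), "panel_mean"),
      stringsAsFactors = FALSE)
  }

  counts <- list(
    shared_proteins = nrow(E),
    exclusive_to_mito = length(pair$exclusive_to_mito),
    exclusive_to_lysate = length(pair$exclusive_to_lysate),
    n_samples = ncol(E),
    significant = vapply(unions, length, integer(1L)),
    overlap_all = overlap$count[overlap$region ==
                                  paste(names(unions), collapse = "&")],
    consensus_overlap = vapply(consensus, function(x)
      if (is.null(x)) NA_integer_ else attr(x, "overlap"), integer(1L))
  )
  structure(list(counts = counts, panel_means = panel_means,
                 differential = tables, sets = sets, overlap = overlap,
                 clustering = clustering, ranking = ranking,
                 consensus = consensus,
                 provenance = list(alpha = alpha, k = k, scheme = scheme,
                                   folds = folds, seed = seed,
                                   case = case, control = control,
                                   top_k = top_k)),
            class = "mtfe_report")
}

#' @export
print.mtfe_report <- function(x, ...) {
  cat("mtfe_report\n")
  cat(sprintf("  shared proteins: %d (%d mito-only, %d lysate-only), samples: %d\n",
              x$counts$shared_proteins, x$counts$exclusive_to_mito,
              x$counts$exclusive_to_lysate, x$counts$n_samples))
  cat("  significant proteins (union of comparisons): ",
      paste(sprintf("%s=%d", names(x$counts$significant),
                    x$counts$significant), collapse = ", "), "\n", sep = "")
  cat(sprintf("  shared by all data types: %d\n", x$counts$overlap_all))
  for (nm in names(x$clustering)) {
    cl <- x$clustering[[nm]]
    if (is.null(cl)) next
    cat(sprintf("  clustering %-6s ARI condition %.2f, ARI genotype %.2f\n",
                nm, cl$ari_condition, cl$ari_genotype))
  }
  invisible(x)
}

#' Serialize a report summary to JSON (and TSVs)
#'
#' Writes `summary.json` with all counts, panel means, agreement
#' statistics and consensus rankings, plus per-data-type differential
#' TSVs, into `out_dir`. The emitted JSON embeds the resolved settings
#' and seed, so a run is reproducible from its own record.
#'
#' @param report An `mtfe_report`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the JSON file, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$differential))
    utils::write.table(report$differential[[nm]],
                       file.path(out_dir, paste0("diff_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- report$counts
  counts$significant <- as.list(counts$significant)   # keep names in JSON
  counts$consensus_overlap <- as.list(counts$consensus_overlap)
  summ <- list(
    counts = counts,
    panel_means = report$panel_means,
    overlap = report$overlap,
    clustering = lapply(report$clustering, function(cl)
      if (is.null(cl)) NULL else cl[c("ari_condition", "ari_genotype")]),
    consensus = lapply(report$consensus, function(x)
      if (is.null(x)) NULL else as.list(x)),
    provenance = report$provenance
  )
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
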