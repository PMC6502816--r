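#' Compute organelle fold-enrichment (mtFE) scores
#'
#' The score for protein p in sample s is
#' `log2(mito abundance) - log2(lysate abundance)`, i.e. the log2 fold
#' enrichment of the protein in the organelle fraction relative to total
#' lysate. It responds to genuine abundance change in either fraction and
#' to redistribution of the protein between compartments, which makes it
#' sensitive to moderate opposite-direction shifts invisible to
#' whole-lysate analysis.
#'
#' A value is missing wherever either fraction is missing. Proteins
#' quantified in only one fraction are excluded by construction
#' ([align_fractions()]) and surfaced in the `summary` attribute rather
#' than imputed.
#'
#' @param pair An `aligned_pair` from [align_fractions()].
#' @return A matrix of class `mtfe_matrix` with attributes `summary`
#'   (exclusive-protein and missing-cell counts).
#' @export
compute_mtfe <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  v <- unclass(pair$mito) - unclass(pair$lysate)
  summ <- list(
    n_exclusive_to_mito = length(pair$exclusive_to_mito),
    n_exclusive_to_lysate = length(pair$exclusive_to_lysate),
    n_missing_cells = sum(is.na(v))
  )
  structure(v, fraction = "mtfe", summary = summ,
            class = c("mtfe_matrix", "matrix", "array"))
}

#' @export
print.mtfe_matrix <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("mtfe_matrix: %d proteins x %d samples, %d missing cells\n",
              nrow(x), ncol(x), s$n_missing_cells))
  cat(sprintf("  excluded: %d proteins exclusive to mito, %d to lysate\n",
              s$n_exclusive_to_mito, s$n_exclusive_to_lysate))
  invisible(x)
}

#' Marker-panel enrichment statistics
#'
#' Per-protein mean mtFE over non-missing samples, then the panel mean as
#' the mean of the per-protein means. Averaging protein-first keeps
#' proteins with many observations from dominating the panel summary.
#'
#' @param E An `mtfe_matrix` (or any matrix with protein rownames).
#' @param panel A `marker_panel`.
#' @return List with `per_protein` (named vector), `panel_mean`, `absent`
#'   (members not present in `E`), `name`, `organelle`.
#' @export
panel_stats <- function(E, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  present <- intersect(panel$members, rownames(E))
  if (!length(present))
    stop("no member of panel '", panel$name, "' is present in the matrix")
  per_protein <- rowMeans(E[present, , drop = FALSE], na.rm = TRUE)
  per_protein <- per_protein[is.finite(per_protein)]
  list(name = panel$name, organelle = panel$organelle,
       per_protein = per_protein,
       panel_mean = mean(per_protein),
       absent = sort(setdiff(panel$members, present)))
}

#' Per-protein coefficient of variation across replicate samples
#'
#' CV is computed on linear-scale values (`2^x` of the stored log2
#' abundances or mtFE scores), as is standard for reproducibility QC:
#' `CV% = 100 * sd / mean`. Proteins observed in fewer than two of the
#' replicate samples get `NA`.
#'
#' @param m A `quant_matrix` or `mtfe_matrix` (log2 scale).
#' @param replicate_sample_ids At least two sample identifiers designating
#'   technical replicates.
#' @return Named numeric vector of CV percentages per protein.
#' @export
replicate_cv <- function(m, replicate_sample_ids) {
  if (length(replicate_sample_ids) < 2L)
    stop("need at least two replicate samples")
  absent <- setdiff(replicate_sample_ids, colnames(m))
  if (length(absent))
    stop("replicate sample(s) not in matrix: ", paste(absent, collapse = ", "))
  lin <- 2^unclass(m)[, replicate_sample_ids, drop = FALSE]
  n_obs <- rowSums(!is.na(lin))
  sds <- apply(lin, 1L, stats::sd, na.rm = TRUE)
  mus <- rowMeans(lin, na.rm = TRUE)
  cv <- 100 * sds / mus
  cv[n_obs < 2L] <- NA_real_
  cv
}

#' Spearman correlations among sample vectors across data types
#'
#' Builds the full symmetric Spearman rank-correlation matrix over all
#' sample vectors of the supplied matrices (e.g. lysate, mito and mtFE of
#' the same replicate set), on their shared proteins. Ties receive
#' average ranks. Pairs with fewer than `min_overlap` jointly observed
#' proteins are reported as `NA`.
#'
#' @param ... Named matrices sharing (a subset of) protein rownames.
#' @param min_overlap Minimum jointly non-missing proteins per pair.
#' @return Symmetric correlation matrix with unit diagonal; dimnames are
#'   `"<type>:<sample>"`.
#' @export
cross_dataset_correlation <- function(..., min_overlap = 3L) {
  mats <- list(...)
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    stop("all matrices must be named, e.g. lysate = , mito = , mtfe = ")
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < min_overlap)
    stop("fewer than ", min_overlap, " proteins shared by all matrices")
  cols <- do.call(cbind, lapply(names(mats), function(nm) {
    x <- unclass(mats[[nm]])[shared, , drop = FALSE]
    colnames(x) <- paste0(nm, ":", colnames(x))
    x
  }))
  k <- ncol(cols)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(cols), colnames(cols))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(cols[, i]) & !is.na(cols[, j])
      if (sum(ok) < min_overlap) {
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <-
          stats::cor(rank(cols[ok, i]), rank(cols[ok, j]))
      }
    }
  }
  out
}

#' Quality-control report for a replicate experiment
#'
#' Bundles the standard QC of the paired-fraction workflow: per-protein
#' replicate CVs for lysate, mito and mtFE; marker-panel mean mtFE per
#' panel; and the Spearman correlation matrix among all replicate sample
#' vectors of the three data types.
#'
#' @param pair An `aligned_pair` whose samples are technical replicates.
#' @param panels List of `marker_panel` objects (may be empty).
#' @param replicate_sample_ids Sample ids to treat as replicates; default
#'   all shared samples.
#' @return List of class `qc_report` with elements `cv` (data.frame),
#'   `panel_means` (data.frame), `panel_details` (list), `spearman`
#'   (matrix).
#' @export
qc_report <- function(pair, panels = list(), replicate_sample_ids = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  if (is.null(replicate_sample_ids)) replicate_sample_ids <- colnames(pair$mito)
  E <- compute_mtfe(pair)
  cv <- data.frame(
    protein_id = rownames(pair$mito),
    cv_lysate = replicate_cv(pair$lysate, replicate_sample_ids),
    cv_mito = replicate_cv(pair$mito, replicate_sample_ids),
    cv_mtfe = replicate_cv(E, replicate_sample_ids),
    row.names = NULL, stringsAsFactors = FALSE
  )
  panel_details <- lapply(panels, function(p) panel_stats(E, p))
  panel_means <- data.frame(
    panel = vapply(panel_details, `[[`, character(1L), "name"),
    organelle = vapply(panel_details, `[[`, character(1L), "organelle"),
    n_present = vapply(panel_details, function(x) length(x$per_protein), integer(1L)),
    mean_mtfe = vapply(panel_details, `[[`, numeric(1L), "panel_mean"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  sp <- cross_dataset_correlation(lysate = pair$lysate, mito = pair$mito, mtfe = E)
  structure(list(cv = cv, panel_means = panel_means,
                 panel_details = panel_details, spearman = sp),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  cat(sprintf("  median replicate CV%%: lysate %.1f, mito %.1f, mtFE %.1f\n",
              stats::median(x$cv$cv_lysate, na.rm = TRUE),
              stats::median(x$cv$cv_mito, na.rm = TRUE),
              stats::median(x$cv$cv_mtfe, na.rm = TRUE)))
  if (nrow(x$panel_means)) {
    cat("  panel mean mtFE:\n")
    for (i in seq_len(nrow(x$panel_means)))
      cat(sprintf("    %-14s (%s, n=%d): %+.2f\n", x$panel_means$panel[i],
                  x$panel_means$organelle[i], x$panel_means$n_present[i],
                  x$panel_means$mean_mtfe[i]))
  }
  invisible(x)
}
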