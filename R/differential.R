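#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' input order is preserved. `NA` entries propagate and do not count
#' toward the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
    out[ok] <- adj
  }
  out
}

# Resolve a sample->group mapping against matrix columns.
.resolve_groups <- function(m, groups) {
  if (!is.null(names(groups))) {
    absent <- setdiff(colnames(m), names(groups))
    if (length(absent))
      stop("sample(s) without group label: ", paste(absent, collapse = ", "))
    groups <- groups[colnames(m)]
  } else if (length(groups) != ncol(m)) {
    stop("`groups` must be named by sample or match the column count")
  }
  as.character(groups)
}

#' One-way ANOVA with Tukey-Kramer post-hoc tests, per protein
#'
#' Classical fixed-effects one-way ANOVA F-test for each protein row,
#' followed by Tukey HSD pairwise comparisons in the Tukey-Kramer form
#' (studentized range with unequal group sizes). ANOVA p-values are
#' adjusted across proteins with [bh_adjust()] (or the method named in
#' `adjust`). A protein/comparison is flagged significant when both its
#' adjusted ANOVA p and the comparison's Tukey p fall below `alpha`.
#'
#' Missing values: each protein is tested on its available observations.
#' Groups with fewer than two non-missing values for a protein are
#' dropped from that protein's model; proteins retaining fewer than two
#' groups are skipped and listed in `attr(,"skipped")`.
#'
#' @param m Numeric matrix, proteins x samples (e.g. a `quant_matrix` or
#'   `mtfe_matrix`).
#' @param groups Group label per sample: a vector named by sample id, or
#'   an unnamed vector in column order.
#' @param alpha Significance level in (0, 1).
#' @param comparisons Named list of group pairs `c(A, B)`; the reported
#'   difference is `mean(A) - mean(B)`. Default: all pairs of sorted
#'   group levels, named `"A_vs_B"`.
#' @param adjust Multiple-testing method across proteins: `"BH"`
#'   (default), `"bonferroni"` or `"holm"`.
#' @return A `differential_table` data.frame with group means, `F`,
#'   `p_value`, `p_adj`, and per comparison `diff_*`, `tukey_p_*`,
#'   `sig_*` columns.
#' @export
anova_tukey <- function(m, groups, alpha = 0.05, comparisons = NULL,
                        adjust = c("BH", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  g <- .resolve_groups(m, groups)
  levs <- sort(unique(g))
  if (length(levs) < 2L) stop("need at least two groups")
  x <- unclass(m)
  obs <- !is.na(x)
  if (any(vapply(levs, function(l) sum(obs[, g == l]) == 0L, logical(1L))) &&
      nrow(x) > 0L)
    stop("group(s) entirely missing for all proteins: ",
         paste(levs[vapply(levs, function(l) sum(obs[, g == l]) == 0L,
                           logical(1L))], collapse = ", "))
  if (is.null(comparisons)) {
    comparisons <- list()
    for (i in seq_len(length(levs) - 1L))
      for (j in (i + 1L):length(levs))
        comparisons[[paste0(levs[j], "_vs_", levs[i])]] <- c(levs[j], levs[i])
  }
  for (cmp in comparisons)
    if (!all(cmp %in% levs))
      stop("comparison refers to unknown group(s): ", paste(cmp, collapse = ", "))

  # per-group row statistics (NA treated as 0 after masking)
  x0 <- x; x0[!obs] <- 0
  G <- length(levs)
  ind <- vapply(levs, function(l) as.numeric(g == l), numeric(length(g)))
  n_g <- obs %*% ind                      # proteins x groups counts
  s_g <- x0 %*% ind                       # sums
  q_g <- (x0^2) %*% ind                   # sums of squares
  colnames(n_g) <- colnames(s_g) <- colnames(q_g) <- levs

  inc <- n_g >= 2                          # group enters the protein's model
  k <- rowSums(inc)
  tested <- k >= 2
  Ninc <- rowSums(n_g * inc)
  Sinc <- rowSums(s_g * inc)
  mean_g <- s_g / n_g                      # NaN where n_g == 0
  grand <- Sinc / Ninc
  ssb <- rowSums(inc * n_g * (mean_g - grand)^2, na.rm = TRUE)
  ssw <- rowSums(inc * (q_g - s_g^2 / pmax(n_g, 1)), na.rm = TRUE)
  dfb <- k - 1
  dfw <- Ninc - k
  msw <- ssw / dfw
  Fs <- (ssb / dfb) / msw
  # degenerate variance: all residuals zero
  zero_w <- tested & ssw <= 0
  Fs[zero_w & ssb <= 1e-12] <- 0
  p <- stats::pf(Fs, dfb, dfw, lower.tail = FALSE)
  p[zero_w & ssb <= 1e-12] <- 1
  p[zero_w & ssb > 1e-12] <- 0
  Fs[!tested] <- NA_real_
  p[!tested] <- NA_real_

  p_adj <- switch(adjust,
                  BH = bh_adjust(p),
                  bonferroni = pmin(1, p * sum(!is.na(p))),
                  holm = stats::p.adjust(p, "holm"))

  out <- data.frame(protein_id = rownames(x), row.names = NULL,
                    stringsAsFactors = FALSE)
  for (l in levs) out[[paste0("mean_", l)]] <- mean_g[, l]
  out$F <- Fs
  out$p_value <- p
  out$p_adj <- p_adj

  for (nm in names(comparisons)) {
    a <- comparisons[[nm]][1L]; b <- comparisons[[nm]][2L]
    valid <- tested & inc[, a] & inc[, b]
    dif <- mean_g[, a] - mean_g[, b]
    se2 <- (msw / 2) * (1 / n_g[, a] + 1 / n_g[, b])
    qstat <- abs(dif) / sqrt(se2)
    tp <- rep(NA_real_, nrow(x))
    fin <- valid & is.finite(qstat)
    tp[fin] <- stats::ptukey(qstat[fin], nmeans = k[fin], df = dfw[fin],
                             lower.tail = FALSE)
    # zero within-group variance: identical means -> p 1, else p -> 0
    degen <- valid & !is.finite(qstat)
    tp[degen] <- ifelse(abs(dif[degen]) <= 1e-12, 1, 0)
    tp[valid & abs(dif) <= 1e-15 & is.nan(qstat)] <- 1
    dif[!valid] <- NA_real_
    out[[paste0("diff_", nm)]] <- dif
    out[[paste0("tukey_p_", nm)]] <- tp
    out[[paste0("sig_", nm)]] <- !is.na(p_adj) & !is.na(tp) &
      p_adj < alpha & tp < alpha
  }
  attr(out, "skipped") <- rownames(x)[!tested]
  attr(out, "comparisons") <- comparisons
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Four-group design helper
#'
#' Builds the `condition.genotype` group labels and the four
#' within-stratum comparisons used in a two-condition x two-genotype
#' cohort: genotype contrasts within each condition and condition
#' contrasts within each genotype.
#'
#' @param meta A `sample_metadata` data.frame.
#' @param samples Optional sample ids to restrict to (default all
#'   non-replicate samples).
#' @return List with `groups` (named vector sample -> group) and
#'   `comparisons` (named list of group pairs, names
#'   `"A_vs_B.within_S"`).
#' @export
fourgroup_design <- function(meta, samples = NULL) {
  df <- as.data.frame(meta)
  if (is.null(samples)) samples <- df$sample_id[df$replicate == 0L]
  df <- df[match(samples, df$sample_id), , drop = FALSE]
  conds <- sort(unique(df$condition))
  genos <- sort(unique(df$genotype))
  if (length(conds) != 2L || length(genos) != 2L)
    stop("fourgroup design needs exactly two conditions and two genotypes")
  groups <- paste(df$condition, df$genotype, sep = ".")
  names(groups) <- df$sample_id
  comparisons <- list()
  for (cd in conds)
    comparisons[[paste0(genos[2L], "_vs_", genos[1L], ".within_", cd)]] <-
      c(paste(cd, genos[2L], sep = "."), paste(cd, genos[1L], sep = "."))
  for (gn in genos)
    comparisons[[paste0(conds[2L], "_vs_", conds[1L], ".within_", gn)]] <-
      c(paste(conds[2L], gn, sep = "."), paste(conds[1L], gn, sep = "."))
  list(groups = groups, comparisons = comparisons)
}

#' Per-comparison significant protein sets and per-data-type unions
#'
#' @param tables Named list of `differential_table`s (one per data type,
#'   e.g. lysate / mito / mtfe). If the tables' protein universes differ,
#'   the intersection is used (with a message).
#' @param alpha Significance level; default the tables' own alpha.
#' @return List of class `significant_sets`: per data type a list of
#'   sorted per-comparison sets plus `union`.
#' @export
significant_sets <- function(tables, alpha = NULL) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  universe <- Reduce(intersect, lapply(tables, `[[`, "protein_id"))
  if (any(vapply(tables, nrow, integer(1L)) != length(universe)))
    message("protein universes differ; restricting to ", length(universe),
            " shared proteins")
  out <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    tab <- tab[tab$protein_id %in% universe, , drop = FALSE]
    a <- if (is.null(alpha)) attr(tab, "alpha") else alpha
    if (!is.null(alpha)) {
      cmps <- names(attr(tab, "comparisons"))
      for (cmp in cmps)
        tab[[paste0("sig_", cmp)]] <- !is.na(tab$p_adj) &
          !is.na(tab[[paste0("tukey_p_", cmp)]]) &
          tab$p_adj < a & tab[[paste0("tukey_p_", cmp)]] < a
    }
    sig_cols <- grep("^sig_", colnames(tab), value = TRUE)
    sets <- lapply(sig_cols, function(cl) sort(tab$protein_id[tab[[cl]]]))
    names(sets) <- sub("^sig_", "", sig_cols)
    sets$union <- sort(unique(unlist(sets)))
    out[[nm]] <- sets
  }
  structure(out, class = "significant_sets", universe = universe)
}

#' Venn-region cardinalities for named sets
#'
#' Counts every region of the inclusion-exclusion partition of two or
#' more sets; region counts sum to the size of the union.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return data.frame with one row per non-empty combination label
#'   (`"A"`, `"A&B"`, ...) and its exclusive count; attribute `total`
#'   holds the union size.
#' @export
set_overlap <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop("need >= 2 named sets")
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  counts <- table(key)
  # enumerate all regions, including empty ones, in canonical order
  nms <- names(sets)
  regions <- character(0)
  for (sz in seq_along(nms))
    regions <- c(regions, apply(utils::combn(nms, sz), 2L,
                                paste, collapse = "&"))
  out <- data.frame(region = regions,
                    count = as.integer(counts[regions]),
                    stringsAsFactors = FALSE)
  out$count[is.na(out$count)] <- 0L
  attr(out, "total") <- length(universe)
  out
}

#' Paired t-test per protein
#'
#' Two-tailed paired t-test on per-pair differences (case minus control),
#' as used to verify candidate markers in tumor vs matched adjacent
#' tissue. Proteins with fewer than two complete pairs are reported `NA`
#' and listed in `attr(,"skipped")`.
#'
#' Degenerate variance: all differences exactly zero gives `t = 0`,
#' `p = 1`; zero variance with non-zero mean gives a p-value at the
#' numeric underflow floor with `degenerate = TRUE`.
#'
#' @param m Numeric matrix, proteins x samples.
#' @param meta `sample_metadata` with `pair_id` filled for the paired
#'   samples.
#' @param case,control Condition labels of the case and control member of
#'   each pair.
#' @param adjust Logical: add a BH-adjusted column across proteins.
#' @return A `paired_test_table` data.frame: `protein_id`, `mean_diff`,
#'   `t`, `p_value`, `n_pairs`, `degenerate`, optionally `p_adj`.
#' @export
paired_ttest <- function(m, meta, case, control, adjust = TRUE) {
  df <- as.data.frame(meta)
  df <- df[nzchar(df$pair_id), , drop = FALSE]
  pids <- unique(df$pair_id)
  if (!length(pids)) stop("metadata contains no pairs")
  case_s <- control_s <- character(0)
  for (p in pids) {
    two <- df[df$pair_id == p, ]
    ca <- two$sample_id[two$condition == case]
    co <- two$sample_id[two$condition == control]
    if (length(ca) == 1L && length(co) == 1L) {
      case_s <- c(case_s, ca); control_s <- c(control_s, co)
    }
  }
  if (length(case_s) < 2L) stop("fewer than two usable pairs for ",
                                case, " vs ", control)
  keep <- case_s %in% colnames(m) & control_s %in% colnames(m)
  case_s <- case_s[keep]; control_s <- control_s[keep]
  d <- unclass(m)[, case_s, drop = FALSE] - unclass(m)[, control_s, drop = FALSE]
  n <- rowSums(!is.na(d))
  mu <- rowMeans(d, na.rm = TRUE)
  sdd <- apply(d, 1L, stats::sd, na.rm = TRUE)
  tested <- n >= 2L
  tt <- mu / (sdd / sqrt(n))
  pv <- 2 * stats::pt(-abs(tt), df = n - 1)
  degen <- tested & sdd <= 0
  zero <- degen & abs(mu) <= 1e-15
  tt[zero] <- 0; pv[zero] <- 1
  floor_case <- degen & abs(mu) > 1e-15
  tt[floor_case] <- sign(mu[floor_case]) * Inf
  pv[floor_case] <- .Machine$double.xmin
  tt[!tested] <- NA_real_; pv[!tested] <- NA_real_; mu[!tested] <- NA_real_
  out <- data.frame(protein_id = rownames(m), mean_diff = mu, t = tt,
                    p_value = pv, n_pairs = n, degenerate = degen & tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- bh_adjust(out$p_value)
  attr(out, "skipped") <- rownames(m)[!tested]
  attr(out, "pairs") <- data.frame(case = case_s, control = control_s,
                                   stringsAsFactors = FALSE)
  class(out) <- c("paired_test_table", "data.frame")
  out
}

#' Two-sample Student t-test per protein (pooled variance)
#'
#' Two-tailed equal-variance t-test between two groups, the classical
#' form used for independent validation cohorts. Proteins with fewer
#' than two observations in either group are reported `NA` and listed in
#' `attr(,"skipped")`.
#'
#' @param m Numeric matrix, proteins x samples.
#' @param groups Two-level label per sample (named by sample id or in
#'   column order).
#' @param case,control Which level is case / control; the reported
#'   difference is `mean(case) - mean(control)`. Default: sorted levels,
#'   second as case.
#' @param adjust Logical: add a BH-adjusted column.
#' @return data.frame: `protein_id`, `mean_diff`, `t`, `p_value`,
#'   `n_case`, `n_control`, optionally `p_adj`.
#' @export
two_sample_ttest <- function(m, groups, case = NULL, control = NULL,
                             adjust = TRUE) {
  g <- .resolve_groups(m, groups)
  levs <- sort(unique(g))
  if (length(levs) != 2L) stop("`groups` must have exactly two levels")
  if (is.null(control)) control <- levs[1L]
  if (is.null(case)) case <- setdiff(levs, control)
  stopifnot(case %in% levs, control %in% levs, case != control)
  x <- unclass(m)
  xa <- x[, g == case, drop = FALSE]
  xb <- x[, g == control, drop = FALSE]
  n1 <- rowSums(!is.na(xa)); n2 <- rowSums(!is.na(xb))
  m1 <- rowMeans(xa, na.rm = TRUE); m2 <- rowMeans(xb, na.rm = TRUE)
  v1 <- apply(xa, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(xb, 1L, stats::var, na.rm = TRUE)
  tested <- n1 >= 2L & n2 >= 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  pv <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  zero <- tested & sp2 <= 0 & abs(m1 - m2) <= 1e-15
  tt[zero] <- 0; pv[zero] <- 1
  floor_case <- tested & sp2 <= 0 & abs(m1 - m2) > 1e-15
  tt[floor_case] <- sign(m1 - m2)[floor_case] * Inf
  pv[floor_case] <- .Machine$double.xmin
  tt[!tested] <- NA_real_; pv[!tested] <- NA_real_
  out <- data.frame(protein_id = rownames(m), mean_diff = m1 - m2, t = tt,
                    p_value = pv, n_case = n1, n_control = n2,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- bh_adjust(out$p_value)
  attr(out, "skipped") <- rownames(m)[!tested]
  attr(out, "case") <- case
  attr(out, "control") <- control
  out
}
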