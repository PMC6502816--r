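#' ROC curve and AUC by the Mann-Whitney identity
#'
#' AUC is the probability that a randomly chosen positive scores higher
#' than a randomly chosen negative, with ties counted one half
#' (equivalently U / (n1 * n0)). The curve is built by a threshold sweep
#' over the unique scores, so it starts at (0,0), ends at (1,1) and its
#' trapezoidal area equals the Mann-Whitney AUC.
#'
#' @param scores Numeric score per sample (higher = more case-like).
#' @param labels Binary labels (logical, 0/1, or two-level factor /
#'   character; the higher level is the positive class unless `positive`
#'   is given).
#' @param positive Label value of the positive class.
#' @return List of class `roc_result`: `points` (data.frame `fpr`,
#'   `tpr`), `auc`, `positive`, `flipped` (always `FALSE` here; see
#'   [evaluate_markers()] for orientation handling).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  y <- .as_binary(labels, positive)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                      # average ranks handle ties
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # threshold sweep, descending unique scores; ties move together
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_last <- !duplicated(ss, fromLast = TRUE)[seq_along(ss)]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  keep <- which(grp_last)
  pts <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  structure(list(points = pts, auc = auc,
                 positive = attr(y, "positive"), flipped = FALSE),
            class = "roc_result")
}

.as_binary <- function(labels, positive = NULL) {
  if (is.logical(labels)) {
    y <- labels; pos <- "TRUE"
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    y <- labels == 1; pos <- "1"
  } else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) stop("labels must be binary")
    pos <- if (is.null(positive)) lv[2L] else as.character(positive)
    if (!pos %in% lv) stop("positive label '", pos, "' not found")
    y <- as.character(labels) == pos
  }
  if (!is.null(positive) && is.logical(labels))
    y <- labels == as.logical(positive)
  structure(y, positive = pos)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (positive class '%s'%s), %d curve points\n",
              x$auc, x$positive, if (x$flipped) ", scores sign-flipped" else "",
              nrow(x$points)))
  invisible(x)
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic stratified fold assignment
.make_folds <- function(y, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

.fit_predict_lr <- function(xtr, ytr, xte) {
  mu <- mean(xtr); s <- stats::sd(xtr)
  if (!is.finite(s) || s <= 0) return(rep(0.5, length(xte)))
  ztr <- (xtr - mu) / s; zte <- (xte - mu) / s
  fit <- suppressWarnings(
    stats::glm(ytr ~ ztr, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)))
  eta <- fit$coefficients[1L] + fit$coefficients[2L] * zte
  eta <- pmin(pmax(eta, -30), 30)        # cap the linear predictor
  1 / (1 + exp(-eta))
}

.fit_predict_nb <- function(xtr, ytr, xte) {
  if (stats::sd(xtr) <= 0) return(rep(0.5, length(xte)))
  m1 <- mean(xtr[ytr]); m0 <- mean(xtr[!ytr])
  v1 <- stats::var(xtr[ytr]); v0 <- stats::var(xtr[!ytr])
  vfloor <- 1e-9 * max(stats::var(xtr), 1e-12)
  v1 <- max(v1, vfloor, na.rm = TRUE); v0 <- max(v0, vfloor, na.rm = TRUE)
  p1 <- mean(ytr)
  l1 <- stats::dnorm(xte, m1, sqrt(v1), log = TRUE) + log(p1)
  l0 <- stats::dnorm(xte, m0, sqrt(v0), log = TRUE) + log(1 - p1)
  1 / (1 + exp(pmin(pmax(l0 - l1, -700), 700)))
}

#' Cross-validated out-of-fold probabilities for a single feature
#'
#' Trains a one-feature classifier (logistic regression on the
#' standardized feature, or Gaussian naive Bayes) under stratified k-fold
#' or leave-one-out cross-validation, returning one out-of-fold
#' case-probability per sample. Standardization parameters are estimated
#' on the training folds only. Fold assignment is deterministic given
#' `seed`; LOO is seed-independent.
#'
#' @param values Numeric feature vector, one value per sample.
#' @param labels Binary labels (see [roc_auc()]).
#' @param model `"lr"` or `"nb"`.
#' @param scheme `"kfold"` (stratified, `folds` folds) or `"loo"`.
#' @param folds Number of folds for `"kfold"`.
#' @param seed Integer seed controlling fold assignment.
#' @param positive Positive class label (see [roc_auc()]).
#' @return Numeric vector of out-of-fold probabilities with attributes
#'   `model`, `scheme`, `seed`, `flagged_constant` (folds where the
#'   training feature was constant).
#' @export
crossval_single_feature <- function(values, labels, model = c("lr", "nb"),
                                    scheme = c("kfold", "loo"), folds = 5L,
                                    seed = 1L, positive = NULL) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  ok <- !is.na(values) & !is.na(labels)
  y <- .as_binary(labels[ok], positive)
  x <- values[ok]
  n <- length(x)
  if (sum(y) == 0L || sum(!y) == 0L) stop("both classes must be present")
  if (scheme == "loo") {
    fold <- seq_len(n)
    k <- n
  } else {
    k <- min(folds, n)
    fold <- .make_folds(y, k, seed)
    # guard: every training set must contain both classes
    tries <- 0L
    while (tries < 10L) {
      bad <- any(vapply(seq_len(k), function(f) {
        tr <- fold != f
        sum(y[tr]) == 0L || sum(!y[tr]) == 0L
      }, logical(1L)))
      if (!bad) break
      tries <- tries + 1L
      fold <- .make_folds(y, k, seed + 1000L * tries)
    }
  }
  prob <- rep(NA_real_, n)
  flagged <- integer(0)
  fitfun <- if (model == "lr") .fit_predict_lr else .fit_predict_nb
  for (f in seq_len(k)) {
    te <- fold == f
    if (!any(te)) next
    xtr <- x[!te]; ytr <- y[!te]
    if (stats::sd(xtr) <= 0 || sum(ytr) == 0L || sum(!ytr) == 0L) {
      prob[te] <- 0.5
      flagged <- c(flagged, f)
      next
    }
    prob[te] <- fitfun(xtr, ytr, x[te])
  }
  out <- rep(NA_real_, length(values))
  out[ok] <- prob
  structure(out, model = model, scheme = scheme, seed = seed,
            folds = k, flagged_constant = flagged,
            labels_used = as.logical(y), positive = attr(y, "positive"))
}

#' Rank proteins by single-feature cross-validated AUC
#'
#' Runs [crossval_single_feature()] for every protein and model,
#' computes the pooled out-of-fold AUC and 0.5-threshold accuracy, and
#' ranks proteins by the average AUC across models (descending), with
#' ties broken by average accuracy (descending) then protein id
#' (ascending).
#'
#' @param m Numeric matrix, proteins x samples.
#' @param labels Binary labels per sample (named by sample id or in
#'   column order).
#' @param models Character subset of `c("lr", "nb")`.
#' @param scheme,folds,seed Cross-validation scheme (see
#'   [crossval_single_feature()]).
#' @param restrict_to Optional `marker_panel` (or character vector)
#'   restricting the ranked proteins.
#' @param positive Positive class label.
#' @return A `classifier_ranking` data.frame with per-model `auc_*` /
#'   `acc_*` columns, `avg_auc`, `avg_acc` and `rank`.
#' @export
rank_features <- function(m, labels, models = c("lr", "nb"),
                          scheme = c("kfold", "loo"), folds = 5L, seed = 1L,
                          restrict_to = NULL, positive = NULL) {
  scheme <- match.arg(scheme)
  models <- match.arg(models, several.ok = TRUE)
  if (!is.null(names(labels))) {
    absent <- setdiff(colnames(m), names(labels))
    if (length(absent)) stop("sample(s) without label: ",
                             paste(absent, collapse = ", "))
    labels <- labels[colnames(m)]
  }
  x <- unclass(m)
  if (!is.null(restrict_to)) {
    members <- if (inherits(restrict_to, "marker_panel"))
      restrict_to$members else as.character(restrict_to)
    keep <- intersect(rownames(x), members)
    if (!length(keep)) stop("restriction panel shares no protein with the matrix")
    x <- x[keep, , drop = FALSE]
  }
  prots <- rownames(x)
  res <- data.frame(protein_id = prots, stringsAsFactors = FALSE)
  for (mod in models) {
    aucs <- accs <- rep(NA_real_, length(prots))
    for (i in seq_along(prots)) {
      pr <- crossval_single_feature(x[i, ], labels, model = mod,
                                    scheme = scheme, folds = folds,
                                    seed = seed, positive = positive)
      ok <- !is.na(pr)
      y <- .as_binary(labels[ok], positive)
      if (sum(y) == 0L || sum(!y) == 0L) next
      aucs[i] <- roc_auc(pr[ok], as.logical(y))$auc
      accs[i] <- mean((pr[ok] > 0.5) == as.logical(y))
    }
    res[[paste0("auc_", mod)]] <- aucs
    res[[paste0("acc_", mod)]] <- accs
  }
  auc_cols <- paste0("auc_", models)
  acc_cols <- paste0("acc_", models)
  res$avg_auc <- rowMeans(res[, auc_cols, drop = FALSE])
  res$avg_acc <- rowMeans(res[, acc_cols, drop = FALSE])
  o <- order(-res$avg_auc, -res$avg_acc, res$protein_id)
  res <- res[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "models") <- models
  attr(res, "scheme") <- scheme
  attr(res, "folds") <- folds
  attr(res, "seed") <- seed
  class(res) <- c("classifier_ranking", "data.frame")
  res
}

#' Consensus of two top-k ranking lists
#'
#' Intersection of the two top-k sets, ordered by the average of the two
#' ranks (ties by identifier).
#'
#' @param ranking_a,ranking_b `classifier_ranking` tables (or data.frames
#'   with `protein_id` and `rank`).
#' @param k Depth of each list.
#' @return data.frame `protein_id`, `rank_a`, `rank_b`, `avg_rank`,
#'   ordered by `avg_rank`; attribute `overlap` holds the overlap size.
#' @export
consensus_top_k <- function(ranking_a, ranking_b, k = 10L) {
  if (k > nrow(ranking_a) || k > nrow(ranking_b))
    stop("k exceeds a ranking's length")
  top_a <- ranking_a$protein_id[ranking_a$rank <= k]
  top_b <- ranking_b$protein_id[ranking_b$rank <= k]
  common <- intersect(top_a, top_b)
  ra <- ranking_a$rank[match(common, ranking_a$protein_id)]
  rb <- ranking_b$rank[match(common, ranking_b$protein_id)]
  out <- data.frame(protein_id = common, rank_a = ra, rank_b = rb,
                    avg_rank = (ra + rb) / 2, stringsAsFactors = FALSE)
  out <- out[order(out$avg_rank, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overlap") <- length(common)
  out
}

#' Validate candidate markers by direct-value test and ROC
#'
#' For each marker: the appropriate differential test (paired t-test
#' when `meta` provides tumor/adjacent pairs, two-sample pooled-variance
#' t-test otherwise) plus a ROC computed directly on the marker's values
#' without refitting any model. Orientation is chosen so the case
#' group's mean maps to positive scores; when the case mean is lower the
#' scores are sign-flipped and this is recorded.
#'
#' @param m Numeric matrix, proteins x samples (validation cohort).
#' @param meta `sample_metadata` for the cohort.
#' @param markers Character vector of candidate protein ids.
#' @param design `"paired"` or `"twosample"`.
#' @param case,control Condition labels.
#' @return data.frame per present marker: `protein_id`, `mean_diff`,
#'   `p_value`, `auc`, `flipped`; attribute `skipped` lists absent
#'   markers, attribute `roc` the per-marker `roc_result`s.
#' @export
evaluate_markers <- function(m, meta, markers,
                             design = c("paired", "twosample"),
                             case, control) {
  design <- match.arg(design)
  present <- intersect(markers, rownames(m))
  skipped <- setdiff(markers, present)
  if (!length(present)) stop("no marker present in the matrix")
  sub <- unclass(m)[present, , drop = FALSE]
  df <- as.data.frame(meta)
  if (design == "paired") {
    tab <- paired_ttest(sub, meta, case = case, control = control,
                        adjust = FALSE)
  } else {
    g <- df$condition[match(colnames(sub), df$sample_id)]
    names(g) <- colnames(sub)
    g <- g[g %in% c(case, control)]
    tab <- two_sample_ttest(sub[, names(g), drop = FALSE], g,
                            case = case, control = control, adjust = FALSE)
  }
  case_samples <- df$sample_id[df$condition == case]
  is_case <- colnames(sub) %in% case_samples
  rocs <- list()
  auc <- flip <- rep(NA, length(present))
  for (i in seq_along(present)) {
    v <- sub[i, ]
    ok <- !is.na(v)
    lab <- is_case[ok]
    if (!any(lab) || all(lab)) next
    flip[i] <- mean(v[ok][lab]) < mean(v[ok][!lab])
    sc <- if (isTRUE(flip[i])) -v[ok] else v[ok]
    r <- roc_auc(sc, lab)
    r$flipped <- isTRUE(flip[i])
    rocs[[present[i]]] <- r
    auc[i] <- r$auc
  }
  out <- data.frame(protein_id = present,
                    mean_diff = tab$mean_diff[match(present, tab$protein_id)],
                    p_value = tab$p_value[match(present, tab$protein_id)],
                    auc = as.numeric(auc), flipped = as.logical(flip),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "roc") <- rocs
  attr(out, "design") <- design
  out
}
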