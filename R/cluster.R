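#' Z-scale matrix rows
#'
#' Centers each row to mean 0 and scales to unit sample sd, the usual
#' preprocessing before sample clustering of a centered heat map.
#' Constant rows map to all-zeros and are listed in
#' `attr(,"constant_rows")`. Idempotent (up to floating-point error).
#'
#' @param m Numeric matrix with >= 2 non-missing values per row.
#' @return Scaled matrix with the same dimnames.
#' @export
scale_rows <- function(m) {
  x <- unclass(m)
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1L, stats::sd, na.rm = TRUE)
  const <- !is.finite(s) | s <= 0
  s[const] <- 1
  out <- (x - mu) / s
  out[const, ] <- 0
  out[is.na(x)] <- NA
  attr(out, "constant_rows") <- rownames(x)[const]
  out
}

# Manhattan distance between columns with pairwise-complete handling:
# the mean absolute difference over shared coordinates is rescaled by
# the total row count, so distances stay comparable across pairs with
# different missingness.
.manhattan_cols <- function(x) {
  n <- ncol(x); p <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      ns <- sum(ok)
      if (ns == 0L) stop("samples '", colnames(x)[i], "' and '",
                         colnames(x)[j], "' share no observed protein")
      d[i, j] <- d[j, i] <- sum(abs(x[ok, i] - x[ok, j])) * p / ns
    }
  }
  stats::as.dist(d)
}

#' Hierarchical clustering of samples on Manhattan distance
#'
#' Agglomerative clustering of the matrix columns (samples) using
#' Manhattan (city-block) distance, after optional row z-scaling.
#' Missing entries are handled pairwise-complete with rescaling by the
#' shared-coordinate count. Columns are processed in lexicographic
#' order, which makes merge-order tie-breaking deterministic across
#' platforms (at equal heights the pair containing the lexicographically
#' smallest ids merges first).
#'
#' @param m Numeric matrix, proteins x samples.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @param scale Logical: z-scale rows first (default `TRUE`).
#' @return List of class `clustering_result`: `hclust` (the tree),
#'   `merge`, `height`, `leaf_order` (sample ids), `metric`, `linkage`,
#'   `scaled`.
#' @export
hclust_manhattan <- function(m, linkage = "complete", scale = TRUE) {
  x <- unclass(m)
  if (ncol(x) < 2L) stop("need at least two samples")
  x <- x[, order(colnames(x)), drop = FALSE]
  if (scale) x <- scale_rows(x)
  d <- .manhattan_cols(x)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 leaf_order = hc$labels[hc$order],
                 metric = "manhattan", linkage = linkage, scaled = scale),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d samples, %s distance, %s linkage%s\n",
              length(x$leaf_order), x$metric, x$linkage,
              if (x$scaled) ", row-scaled" else ""))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement (Hubert-Arabie form). 1 for identical
#' partitions, ~0 for independent ones; 0 exactly when one side is a
#' single cluster.
#'
#' @param a,b Cluster/label assignments of the same length.
#' @return The ARI, a single number `<= 1`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(0)
  (sij - expected) / (maxidx - expected)
}

#' Agreement between a tree cut and external sample labels
#'
#' Cuts the clustering tree into `k` clusters and quantifies how well
#' the partition follows the labels: adjusted Rand index plus the purity
#' of each cluster (fraction of its members carrying its majority
#' label).
#'
#' @param result A `clustering_result`.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param labels Label per sample, named by sample id or in leaf order
#'   of the clustered samples.
#' @return List: `ari`, `purity` (per cluster), `assignment` (named
#'   cluster vector).
#' @export
partition_agreement <- function(result, k, labels) {
  stopifnot(inherits(result, "clustering_result"))
  n <- length(result$leaf_order)
  if (k < 2L || k > n) stop("k must lie in [2, n]")
  cl <- stats::cutree(result$hclust, k = k)
  if (!is.null(names(labels))) {
    absent <- setdiff(names(cl), names(labels))
    if (length(absent)) stop("sample(s) without label: ",
                             paste(absent, collapse = ", "))
    labels <- labels[names(cl)]
  } else if (length(labels) != n) {
    stop("`labels` must be named or match the sample count")
  }
  purity <- vapply(split(as.character(labels), cl),
                   function(l) max(table(l)) / length(l), numeric(1L))
  list(ari = adjusted_rand_index(cl, as.character(labels)),
       purity = purity, assignment = cl)
}
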