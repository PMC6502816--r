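# Independent brute-force oracles used to pin expected values.
# These deliberately use naive arithmetic (explicit sums, pair counting)
# rather than the package's vectorized code paths.

oracle_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  levs <- unique(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0; n <- 0
  for (l in levs) {
    x <- values[groups == l]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
    n <- n + length(x)
  }
  k <- length(levs)
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = stats::pf(F, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1, df2 = n - k)
}

oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

oracle_paired_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  # step-up: p[i] * m / rank, then cumulative minimum from the largest rank
  run <- 1
  for (r in m:1) {
    run <- min(run, p[o[r]] * m / r)
    adj[o[r]] <- run
  }
  pmin(adj, 1)
}

# concordant-pair probability with ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# adjusted Rand index by explicit pair counting
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / np
  maxidx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxidx == expected) return(0)
  (s11 - expected) / (maxidx - expected)
}

rand_quant <- function(np = 6, ns = 4, fraction = "mito", missing = 0,
                       prefix = "P") {
  v <- matrix(rnorm(np * ns, 12, 1), np, ns,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(np)),
                              sprintf("s%02d", seq_len(ns))))
  if (missing > 0) v[matrix(runif(np * ns) < missing, np, ns)] <- NA
  quant_matrix(v, fraction)
}

fourgroup_meta <- function(sizes = c(Ctrl.WT = 4, DEN.WT = 4,
                                     Ctrl.KO = 3, DEN.KO = 3)) {
  grp <- rep(names(sizes), sizes)
  parts <- strsplit(grp, ".", fixed = TRUE)
  sample_metadata(data.frame(
    sample_id = sprintf("s%02d", seq_along(grp)),
    subject_id = sprintf("m%02d", seq_along(grp)),
    genotype = vapply(parts, `[`, character(1), 2),
    condition = vapply(parts, `[`, character(1), 1),
    cohort = "test", pair_id = "", replicate = 0L,
    stringsAsFactors = FALSE))
}
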