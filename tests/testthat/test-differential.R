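test_that("BH adjustment matches the step-up oracle and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(20)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
  # NA propagation: non-NA entries adjusted among themselves
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

as_mat <- function(rows) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sprintf("P%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  m
}

test_that("ANOVA F matches explicit sums-of-squares arithmetic", {
  g <- rep(c("a", "b", "c", "d"), each = 3)
  x <- c(1, 2, 3, 2, 3, 4, 3, 4, 5, 10, 11, 12)
  tab <- anova_tukey(as_mat(list(x)), g)
  orc <- oracle_anova_F(x, g)
  expect_equal(tab$F, orc$F, tolerance = 1e-10)
  expect_equal(tab$p_value, orc$p, tolerance = 1e-10)

  const <- anova_tukey(as_mat(list(rep(7, 12))), g)
  expect_equal(const$F, 0)
  expect_equal(const$p_value, 1)
})

test_that("ANOVA/Tukey agree with reference implementations on random instances", {
  set.seed(21)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    sizes <- sample(3:6, k, replace = TRUE)
    g <- rep(letters[1:k], sizes)
    x <- rnorm(length(g), mean = sample(0:2, 1))
    tab <- anova_tukey(as_mat(list(x)), g)
    orc <- oracle_anova_F(x, g)
    expect_equal(tab$F, orc$F, tolerance = 1e-8)
    ref <- summary(aov(x ~ factor(g)))[[1]]
    expect_equal(tab$F, ref[["F value"]][1], tolerance = 1e-8)
    expect_equal(tab$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
    thsd <- TukeyHSD(aov(x ~ factor(g)))[[1]]
    for (cmp in rownames(thsd)) {
      ab <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      col_p <- paste0("tukey_p_", ab[1], "_vs_", ab[2])
      col_d <- paste0("diff_", ab[1], "_vs_", ab[2])
      expect_equal(tab[[col_p]], thsd[cmp, "p adj"], tolerance = 1e-6)
      expect_equal(tab[[col_d]], thsd[cmp, "diff"], tolerance = 1e-10)
    }
  }
})

test_that("F is location invariant and scale invariant", {
  set.seed(22)
  g <- rep(c("a", "b", "c"), each = 4)
  x <- rnorm(12)
  f0 <- anova_tukey(as_mat(list(x)), g)$F
  expect_equal(anova_tukey(as_mat(list(x + 100)), g)$F, f0, tolerance = 1e-9)
  expect_equal(anova_tukey(as_mat(list(x * 3.7)), g)$F, f0, tolerance = 1e-9)
})

test_that("Tukey p decreases as |mean difference| grows (equal n)", {
  g <- rep(c("a", "b", "c"), each = 4)
  base <- c(0.1, -0.2, 0.15, -0.05)
  ps <- vapply(c(0.5, 1, 2, 4), function(d) {
    x <- c(base, base + d, base + 10)   # third group far away, fixed
    anova_tukey(as_mat(list(x)), g)$tukey_p_b_vs_a
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("missing-data rules: sparse groups are dropped, proteins skipped", {
  g <- rep(c("a", "b", "c"), each = 3)
  full <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  sparse <- c(1, 2, 3, 4, 5, 6, 7, NA, NA)   # group c has 1 obs -> dropped
  gone <- c(1, 2, 3, NA, NA, NA, NA, NA, NA)  # only one group left -> skipped
  m <- as_mat(list(full, sparse, gone))
  tab <- anova_tukey(m, g)
  expect_identical(attr(tab, "skipped"), "P03")
  expect_true(is.na(tab$F[3]))
  # sparse row equals a two-group ANOVA on groups a, b
  orc <- oracle_anova_F(sparse[1:7][-7], g[1:6])
  expect_equal(tab$F[2], orc$F, tolerance = 1e-10)
  expect_true(is.na(tab$tukey_p_c_vs_a[2]))
  expect_error(anova_tukey(m, g, alpha = 1.5), "alpha")
})

test_that("significance flags require both adjusted ANOVA p and Tukey p below alpha", {
  set.seed(23)
  g <- rep(c("a", "b"), each = 5)
  rows <- c(replicate(30, rnorm(10), simplify = FALSE),
            replicate(10, c(rnorm(5), rnorm(5, 4)), simplify = FALSE))
  tab <- anova_tukey(as_mat(rows), g, alpha = 0.05)
  expect_identical(tab$sig_b_vs_a,
                   !is.na(tab$p_adj) & tab$p_adj < 0.05 &
                     !is.na(tab$tukey_p_b_vs_a) & tab$tukey_p_b_vs_a < 0.05)
  expect_true(all(tab$p_adj >= tab$p_value - 1e-15))
})

test_that("fourgroup design builds the four within-stratum comparisons", {
  meta <- fourgroup_meta()
  d <- fourgroup_design(meta)
  expect_length(d$groups, 14)
  expect_setequal(names(d$comparisons),
                  c("WT_vs_KO.within_Ctrl", "WT_vs_KO.within_DEN",
                    "DEN_vs_Ctrl.within_WT", "DEN_vs_Ctrl.within_KO"))
  expect_identical(d$comparisons$DEN_vs_Ctrl.within_WT, c("DEN.WT", "Ctrl.WT"))
})

test_that("significant sets and Venn accounting are consistent", {
  sets <- list(a = c("A", "B"), b = c("B", "C"))
  ov <- set_overlap(sets)
  expect_identical(ov$count[ov$region == "a"], 1L)
  expect_identical(ov$count[ov$region == "b"], 1L)
  expect_identical(ov$count[ov$region == "a&b"], 1L)
  expect_identical(attr(ov, "total"), 3L)

  tri <- set_overlap(list(x = letters[1:5], y = letters[1:5], z = letters[1:5]))
  expect_identical(tri$count[tri$region == "x&y&z"], 5L)
  expect_identical(sum(tri$count), 5L)

  set.seed(24)
  for (i in 1:10) {
    ss <- list(p = sample(letters, 8), q = sample(letters, 12),
               r = sample(letters, 5))
    ov <- set_overlap(ss)
    expect_identical(sum(ov$count), length(unique(unlist(ss))))
  }
})

test_that("significant_sets extracts per-comparison sets and unions", {
  set.seed(25)
  meta <- fourgroup_meta()
  d <- fourgroup_design(meta)
  x <- matrix(rnorm(40 * 14), 40, 14,
              dimnames = list(sprintf("P%02d", 1:40), meta$sample_id))
  # plant condition effects in 10 proteins
  den <- meta$condition[match(colnames(x), meta$sample_id)] == "DEN"
  x[1:10, den] <- x[1:10, den] + 5
  tabs <- list(mtfe = anova_tukey(x, d$groups, comparisons = d$comparisons))
  ss <- significant_sets(tabs)
  expect_setequal(ss$mtfe$union,
                  sort(unique(unlist(ss$mtfe[names(d$comparisons)]))))
  expect_true(all(sprintf("P%02d", 1:10) %in% ss$mtfe$union))
})

test_that("paired t matches the hand formula and handles degeneracy", {
  meta <- sample_metadata(data.frame(
    sample_id = c("t1", "n1", "t2", "n2", "t3", "n3"),
    subject_id = rep(c("m1", "m2", "m3"), each = 2),
    genotype = "WT",
    condition = rep(c("Tumor", "Adjacent"), 3),
    cohort = "val", pair_id = rep(c("m1", "m2", "m3"), each = 2),
    replicate = 0L, stringsAsFactors = FALSE))
  # differences 1, 2, 3 -> t = 2 / (1/sqrt(3))
  tumor <- c(2, 4, 6); adj <- c(1, 2, 3)
  m <- matrix(c(tumor[1], adj[1], tumor[2], adj[2], tumor[3], adj[3]),
              1, 6, dimnames = list("P1", meta$sample_id))
  tab <- paired_ttest(m, meta, case = "Tumor", control = "Adjacent")
  expect_equal(tab$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  orc <- oracle_paired_t(c(1, 2, 3))
  expect_equal(tab$p_value, orc$p, tolerance = 1e-10)
  ref <- t.test(tumor, adj, paired = TRUE)
  expect_equal(tab$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tab$p_value, ref$p.value, tolerance = 1e-10)

  # differences {+d, -d, 0}: mean 0 -> t = 0, p = 1 needs sd > 0;
  # spec symmetry case: differences +d and -d across two pairs
  m2 <- m
  m2[1, ] <- c(3, 2, 1, 2, 2, 2)        # diffs +1, -1, 0
  tab2 <- paired_ttest(m2, meta, case = "Tumor", control = "Adjacent")
  expect_equal(tab2$t, 0)
  expect_equal(tab2$p_value, 1)

  # all differences zero -> t 0, p 1; constant nonzero difference -> floored p
  m3 <- m; m3[1, ] <- c(2, 2, 5, 5, 9, 9)
  tab3 <- paired_ttest(m3, meta, case = "Tumor", control = "Adjacent")
  expect_equal(tab3$t, 0); expect_equal(tab3$p_value, 1)
  m4 <- m; m4[1, ] <- c(3, 2, 6, 5, 10, 9)
  tab4 <- paired_ttest(m4, meta, case = "Tumor", control = "Adjacent")
  expect_true(tab4$degenerate)
  expect_lt(tab4$p_value, 1e-300)
  expect_identical(sign(tab4$t), 1)
})

test_that("paired t agrees with t.test on random paired instances", {
  set.seed(26)
  n <- 6
  meta <- sample_metadata(data.frame(
    sample_id = c(paste0("t", 1:n), paste0("n", 1:n)),
    subject_id = rep(paste0("m", 1:n), 2), genotype = "WT",
    condition = rep(c("Tumor", "Adjacent"), each = n),
    cohort = "val", pair_id = rep(paste0("m", 1:n), 2),
    replicate = 0L, stringsAsFactors = FALSE))
  for (i in 1:30) {
    vals <- rnorm(2 * n)
    m <- matrix(vals, 1, 2 * n, dimnames = list("P", meta$sample_id))
    tab <- paired_ttest(m, meta, case = "Tumor", control = "Adjacent")
    ref <- t.test(vals[1:n], vals[(n + 1):(2 * n)], paired = TRUE)
    expect_equal(tab$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(tab$p_value, ref$p.value, tolerance = 1e-8)
    expect_identical(sign(tab$t), sign(tab$mean_diff))
  }
})

test_that("pooled two-sample t matches the hand formula and t.test", {
  g <- c(rep("ctl", 3), rep("hcc", 3))
  names(g) <- sprintf("s%02d", 1:6)
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6, dimnames = list("P", names(g)))
  tab <- two_sample_ttest(m, g, case = "hcc", control = "ctl")
  orc <- oracle_pooled_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(tab$t, orc$t, tolerance = 1e-10)
  expect_equal(tab$t, 3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-10)
  ref <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(tab$p_value, ref$p.value, tolerance = 1e-10)

  same <- matrix(c(1, 2, 3, 1, 2, 3), 1, 6, dimnames = list("P", names(g)))
  tab2 <- two_sample_ttest(same, g)
  expect_equal(tab2$t, 0); expect_equal(tab2$p_value, 1)

  set.seed(27)
  for (i in 1:30) {
    v <- rnorm(6)
    m3 <- matrix(v, 1, 6, dimnames = list("P", names(g)))
    tab3 <- two_sample_ttest(m3, g, case = "hcc", control = "ctl")
    ref3 <- t.test(v[4:6], v[1:3], var.equal = TRUE)
    expect_equal(tab3$t, unname(ref3$statistic), tolerance = 1e-8)
    expect_equal(tab3$p_value, ref3$p.value, tolerance = 1e-8)
  }

  # one group too small -> protein skipped
  v <- c(1, 2, 3, 4, NA, NA)
  m4 <- matrix(v, 1, 6, dimnames = list("P", names(g)))
  tab4 <- two_sample_ttest(m4, g)
  expect_true(is.na(tab4$p_value))
  expect_identical(attr(tab4, "skipped"), "P")
})

test_that("null ANOVA p-values keep the type-I error near alpha", {
  set.seed(28)
  g <- rep(c("a", "b", "c", "d"), c(8, 8, 6, 6))
  x <- matrix(rnorm(1000 * 28), 1000, 28,
              dimnames = list(sprintf("P%04d", 1:1000), sprintf("s%02d", 1:28)))
  tab <- anova_tukey(x, g)
  fpr <- mean(tab$p_value < 0.05)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(fpr, ci[1]); expect_lte(fpr, ci[2])
})
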