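test_that("AUC equals the concordant-pair probability, exactly", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(rep(1, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)

  set.seed(30)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), 1))  # rounded -> ties occur
    expect_identical(roc_auc(s, y)$auc, oracle_auc(s, y))
  }
})

test_that("ROC curve is monotone from (0,0) to (1,1) and integrates to AUC", {
  set.seed(31)
  trapezoid <- function(p) sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)
    r <- roc_auc(s, y)
    expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(trapezoid(r$points), r$auc, tolerance = 1e-12)
    # negating scores flips the AUC
    expect_equal(roc_auc(-s, y)$auc, 1 - r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("cross-validated probabilities separate what is separable", {
  y <- rep(c(FALSE, TRUE), each = 10)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  for (mod in c("lr", "nb")) {
    pr <- crossval_single_feature(x, y, model = mod, seed = 3)
    expect_equal(roc_auc(pr, y)$auc, 1)
  }
  # constant feature -> uninformative probabilities
  prc <- crossval_single_feature(rep(2, 20), y, model = "lr", seed = 3)
  expect_true(all(prc == 0.5))
  expect_equal(roc_auc(as.numeric(prc), y)$auc, 0.5)
})

test_that("permuted labels give null AUC near 0.5", {
  set.seed(32)
  n <- 28
  y <- rep(c(FALSE, TRUE), each = n / 2)
  aucs <- replicate(200, {
    x <- rnorm(n)
    yp <- sample(y)
    pr <- crossval_single_feature(x, yp, model = "nb", seed = 1)
    roc_auc(pr, yp)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("cross-validation is deterministic given the seed; LOO ignores it", {
  set.seed(33)
  y <- rep(c(FALSE, TRUE), each = 8)
  x <- rnorm(16) + y
  a <- crossval_single_feature(x, y, model = "lr", seed = 7)
  b <- crossval_single_feature(x, y, model = "lr", seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  l1 <- crossval_single_feature(x, y, model = "lr", scheme = "loo", seed = 1)
  l2 <- crossval_single_feature(x, y, model = "lr", scheme = "loo", seed = 99)
  expect_identical(as.numeric(l1), as.numeric(l2))
})

test_that("feature ranking recovers a planted marker and breaks ties by id", {
  set.seed(34)
  n <- 28
  labels <- setNames(rep(c(FALSE, TRUE), each = 14), sprintf("s%02d", 1:n))
  x <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("P%03d", 1:50), names(labels)))
  x["P007", labels] <- x["P007", labels] + 4
  rk <- rank_features(x, labels, seed = 11)
  expect_identical(rk$protein_id[1], "P007")
  expect_identical(rk$rank, seq_len(nrow(rk)))
  expect_true(all(rk$avg_auc >= 0 & rk$avg_auc <= 1))
  expect_true(all(diff(rk$avg_auc) <= 1e-12))

  # identical rows -> adjacent ranks resolved by id
  x2 <- x[1:10, ]
  x2["P009", ] <- x2["P002", ]
  rk2 <- rank_features(x2, labels, seed = 11)
  i2 <- which(rk2$protein_id == "P002"); i9 <- which(rk2$protein_id == "P009")
  expect_identical(abs(i2 - i9), 1L)
  expect_lt(i2, i9)

  # determinism
  rk3 <- rank_features(x2, labels, seed = 11)
  expect_identical(rk2$protein_id, rk3$protein_id)
  expect_identical(rk2$avg_auc, rk3$avg_auc)

  # restriction panel
  rk4 <- rank_features(x, labels, seed = 11,
                       restrict_to = marker_panel("m", "mito", c("P007", "P010")))
  expect_identical(nrow(rk4), 2L)
  expect_error(rank_features(x, labels, restrict_to = c("ZZ")), "no protein")
})

test_that("consensus of two rankings follows the spec set algebra", {
  mk_rank <- function(ids) {
    data.frame(protein_id = ids, rank = seq_along(ids),
               stringsAsFactors = FALSE)
  }
  a <- mk_rank(sprintf("P%02d", 1:20))
  expect_identical(attr(consensus_top_k(a, a, 10), "overlap"), 10L)
  b <- mk_rank(sprintf("P%02d", 20:1))
  expect_identical(attr(consensus_top_k(a, b, 10), "overlap"), 0L)
  c2 <- mk_rank(c(sprintf("P%02d", 1:9), "P99", sprintf("P%02d", 10:20)))
  expect_identical(attr(consensus_top_k(a, c2, 10), "overlap"), 9L)
  expect_error(consensus_top_k(a, b, 25), "exceeds")
  # ordering by average rank
  cons <- consensus_top_k(a, c2, 10)
  expect_identical(cons$protein_id[1], "P01")
  expect_true(all(diff(cons$avg_rank) >= 0))
})

test_that("marker evaluation tests and ROCs validation candidates directly", {
  set.seed(35)
  cfg <- sim_config(n_proteins = 200L, pairing = "paired", n_pairs = 8L,
                    scenario_counts = c(0L, rep(0L, 4L), 10L, rep(0L, 4L)),
                    effect_moderate = 0.24)  # redistribution at 2x noise sd
  coh <- generate_cohort(cfg, seed = 8)
  pair <- align_fractions(coh$mito, coh$lysate, coh$meta)
  E <- compute_mtfe(pair)
  planted <- coh$truth$protein_id[coh$truth$scenario == 6][1:5]
  ev <- evaluate_markers(unclass(E), coh$meta, c(planted, "NOPE"),
                         design = "paired", case = "Tumor",
                         control = "Adjacent")
  expect_identical(attr(ev, "skipped"), "NOPE")
  expect_gt(mean(ev$auc), 0.9)
  expect_true(all(ev$p_value < 0.05))
  rocs <- attr(ev, "roc")
  expect_identical(names(rocs), planted)

  # marker identical across groups -> AUC 0.5, p 1
  m <- matrix(1, 1, 16, dimnames = list("M", coh$meta$sample_id))
  ev2 <- evaluate_markers(m, coh$meta, "M", design = "paired",
                          case = "Tumor", control = "Adjacent")
  expect_equal(ev2$auc, 0.5)
  expect_equal(ev2$p_value, 1)

  # complete separation -> AUC 1 regardless of direction, flip recorded
  m3 <- matrix(rep(c(5, 1), times = 8)[order(rep(1:8, 2))], 1, 16,
               dimnames = list("M", coh$meta$sample_id))
  tum <- coh$meta$condition[match(colnames(m3), coh$meta$sample_id)] == "Tumor"
  m3[1, ] <- ifelse(tum, 0, 10)
  ev3 <- evaluate_markers(m3, coh$meta, "M", design = "paired",
                          case = "Tumor", control = "Adjacent")
  expect_equal(ev3$auc, 1)
  expect_true(ev3$flipped)
})
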