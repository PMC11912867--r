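bench_fixture <- function(n_genes = 300, n_tfs = 10, regulon = 30,
                          n_exp = 10, seed = TEST_SEED, ...) {
  cfg <- simulation_config(n_genes = n_genes, n_tfs = n_tfs,
                           regulon_size = regulon, n_experiments = n_exp,
                           seed = seed, ...)
  regs <- simulate_regulons(cfg)
  sig <- simulate_perturbation_signatures(regs, cfg)
  regs$source <- "chip"
  regs$rank <- stats::ave(seq_len(nrow(regs)), regs$tf, FUN = seq_along)
  net <- combine_networks(list(regs), weighted = FALSE)
  list(net = net, mat = sig$mat, meta = sig$meta, cfg = cfg)
}

test_that("signature orientation negates gain experiments and is an involution", {
  fx <- bench_fixture(n_exp = 6)
  or <- orient_signatures(fx$mat, fx$meta)
  gain <- fx$meta$experiment[fx$meta$direction == "gain"]
  loss <- fx$meta$experiment[fx$meta$direction == "loss"]
  expect_equal(or[, gain], -fx$mat[, gain])
  expect_equal(or[, loss], fx$mat[, loss])
  expect_equal(orient_signatures(or, fx$meta)[, gain], fx$mat[, gain])
  bad <- fx$meta; bad$direction[1] <- NA
  expect_error(orient_signatures(fx$mat, bad), "direction")
})

test_that("a perfect classifier attains AUROC 1 and random scores sit at chance", {
  fx <- bench_fixture()
  or <- orient_signatures(fx$mat, fx$meta)
  ev <- evaluate(fx$net, or, fx$meta, method = "mlm")
  expect_equal(ev$auroc, 1)       # effect 3 vs sigma 1: clean recovery
  expect_equal(ev$n_experiments, 10L)
  # i.i.d. scores: AUROC ~ 0.5 and AUPRC ~ prevalence
  set.seed(TEST_SEED)
  vals <- stats::rnorm(5000)
  pos <- rep(c(TRUE, FALSE), c(100, 4900))
  expect_lt(abs(grnest:::auroc_ranksum(vals, pos) - 0.5), 0.06)
  expect_lt(abs(grnest:::auprc_average_precision(vals, pos) - 0.02), 0.02)
})

test_that("AUROC equals the brute-force pairwise comparison count", {
  # 2 experiments x 3 TFs with fixed scores
  vals <- c(3.0, -1.0, 0.5, 2.0, 0.0, -2.0)
  pos <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  brute <- 0; n <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    brute <- brute + (vals[i] > vals[j]) + 0.5 * (vals[i] == vals[j])
    n <- n + 1
  }
  expect_equal(grnest:::auroc_ranksum(vals, pos), brute / n)
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(TEST_SEED)
    v <- stats::rnorm(200); p <- stats::runif(200) < 0.2
    expect_equal(grnest:::auroc_ranksum(v, p),
                 as.numeric(pROC::auc(pROC::roc(p, v, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("network shuffling preserves structure and is seed-deterministic", {
  fx <- bench_fixture()
  s1 <- shuffle_network(fx$net, seed = 7)
  s2 <- shuffle_network(fx$net, seed = 7)
  s3 <- shuffle_network(fx$net, seed = 8)
  expect_identical(s1$target, s2$target)
  expect_false(identical(s1$target, s3$target))
  # degree sequence and per-TF weight multisets preserved
  expect_equal(table(s1$source), table(fx$net$source))
  expect_equal(sort(s1$target), sort(fx$net$target))
  expect_false(anyDuplicated(paste(s1$source, s1$target)) > 0)
  # edge set differs from the original
  expect_gt(sum(!paste(s1$source, s1$target) %in%
                  paste(fx$net$source, fx$net$target)), 0)
})

test_that("shuffled-network null sits at chance and separates from truth", {
  fx <- bench_fixture()
  or <- orient_signatures(fx$mat, fx$meta)
  np <- null_performance(fx$net, or, fx$meta, method = "mlm",
                         n_shuffles = 10, seed = TEST_SEED)
  expect_equal(np$auroc_mean, 0.5, tolerance = 0.15)
  expect_equal(length(np$auroc), 10L)
  # SD uses the n-1 denominator
  np2 <- null_performance(fx$net, or, fx$meta, method = "mlm",
                          n_shuffles = 2, seed = TEST_SEED)
  expect_equal(np2$auroc_sd, stats::sd(np2$auroc))
  expect_error(null_performance(fx$net, or, fx$meta, n_shuffles = 1), ">= 2")
})

test_that("experiments for TFs outside the network are dropped and counted", {
  fx <- bench_fixture()
  meta <- fx$meta
  meta$perturbed_tf[1] <- "not_a_tf"
  or <- orient_signatures(fx$mat, meta)
  expect_message(ev <- evaluate(fx$net, or, meta, method = "mlm"), "dropped")
  expect_equal(ev$n_dropped, 1L)
  expect_equal(ev$n_experiments, nrow(meta) - 1L)
})

test_that("per-group performance partitions the pooled set", {
  fx <- bench_fixture()
  or <- orient_signatures(fx$mat, fx$meta)
  global <- evaluate(fx$net, or, fx$meta, method = "mlm")
  tfs <- unique(fx$meta$perturbed_tf)
  # one family holding every TF equals the global evaluation
  one <- per_tf_performance(fx$net, or, fx$meta, method = "mlm",
                            grouping = stats::setNames(rep("fam", length(tfs)),
                                                       tfs))
  expect_equal(one$auroc, global$auroc)
  expect_equal(one$auprc, global$auprc)
  # a disjoint two-family split partitions experiments exactly
  fam <- stats::setNames(rep(c("f1", "f2"), length.out = length(tfs)), tfs)
  two <- per_tf_performance(fx$net, or, fx$meta, method = "mlm",
                            grouping = fam)
  expect_equal(sum(two$n_experiments), global$n_experiments)
  # singleton default grouping flags low-n groups
  solo <- per_tf_performance(fx$net, or, fx$meta, method = "mlm")
  expect_true(all(solo$low_n == (solo$n_experiments < 2)))
})
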