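test_that("rank-quantile transform: best, ties, no-match, missing", {
  # best among N matched promoters gets 1/N
  s <- c(10, 9, 8, 7, 6, rep(0, 5))
  q <- rank_quantile_transform(s)
  expect_equal(q[1], 1 / 5)
  expect_equal(q[6:10], rep(1, 5))       # no match -> exactly 1
  # two tied at the top of N = 4 matched promoters -> (1+2)/2/4
  q2 <- rank_quantile_transform(c(5, 5, 3, 1))
  expect_equal(q2[1:2], rep(0.375, 2))
  # NA preserved; all-NA errors
  q3 <- rank_quantile_transform(c(2, NA, 0))
  expect_true(is.na(q3[2]))
  expect_error(rank_quantile_transform(c(NA, NA)), "missing")
})

test_that("species markers: NA for absent orthologue, 0 for no match, score for implant", {
  cfg <- small_sim_config(implant_rate = 1, ortholog_dropout = 0)
  motifs <- simulate_motifs(cfg)[1]
  fam <- simulate_species_family(cfg, motifs)
  orth <- fam$orthology
  # knock one gene out of species sp01's orthology to force NA
  victim <- orth$focal_gene[orth$species == "sp01"][1]
  orth <- orth[!(orth$species == "sp01" & orth$focal_gene == victim), ]
  bs <- best_scores_by_species(motifs, lapply(fam$species, `[[`, "promoters"),
                               orth, p_threshold = 1e-3)
  expect_true(is.na(bs$best_score[bs$species == "sp01" & bs$target == victim]))
  truth <- fam$ground_truth$true_regulons
  cons_t <- truth$target[truth$conserved & truth$tf == motifs[[1]]$tf_id]
  hit <- bs[bs$target %in% cons_t, ]
  # implant_rate 1, dropout 0: conserved targets match in every species
  expect_true(all(hit$best_score > 0, na.rm = TRUE))
  # a TF absent in a species marks every target NA there
  tfo <- tibble::tibble(tf = motifs[[1]]$tf_id, species = "sp02",
                        present = FALSE)
  bs2 <- best_scores_by_species(motifs, lapply(fam$species, `[[`, "promoters"),
                                orth, tf_orthology = tfo, p_threshold = 1e-3)
  expect_true(all(is.na(bs2$best_score[bs2$species == "sp02"])))
  expect_error(best_scores_by_species(motifs, list(), orth), "no species")
})

test_that("conservation score is the product over non-missing quantiles", {
  bs <- tibble::tibble(
    tf = "tf1",
    target = rep(c("a", "b", "c"), 2),
    species = rep(c("s1", "s2"), each = 3),
    best_score = c(5, 1, 0, 4, 0, 0))
  cr <- conservation_records(bs)
  r <- cr$records
  # a: best in both species -> (1/2) * 1 ... s1 has 2 matched, s2 has 1
  expect_equal(unname(r$score[r$target == "a"]), (1 / 2) * 1)
  expect_equal(unname(r$score[r$target == "c"]), 1)  # no match anywhere
  # adding a species where the target has quantile 1 leaves score unchanged
  bs3 <- dplyr::bind_rows(bs, tibble::tibble(
    tf = "tf1", target = c("a", "b", "c"), species = "s3",
    best_score = 0))
  r3 <- conservation_records(bs3)$records
  expect_equal(r3$score, r$score)
  expect_equal(r3$n_species, r$n_species + 1L)
})

test_that("permutation p-values match exhaustive enumeration on a tiny instance", {
  Q <- matrix(c(0.1, 0.5, 1.0,
                0.2, 0.6, 1.0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  obs <- apply(Q, 1, prod)
  # exact null: all 3! x 3! joint permutations, per-target tail
  P <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
             c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cnt <- integer(3)
  for (i in 1:6) for (j in 1:6) {
    # row r of the null receives quantile of row P[i, r] in s1, etc.
    prod_null <- Q[P[i, ], 1] * Q[P[j, ], 2]
    cnt <- cnt + (prod_null <= obs + 1e-12)
  }
  p_exact <- cnt / 36
  p_hat <- permutation_null_pvalues(Q, iterations = 4000, seed = TEST_SEED)
  expect_equal(p_hat, p_exact, tolerance = 0.05, ignore_attr = TRUE)
  # determinism at fixed seed
  expect_identical(p_hat,
                   permutation_null_pvalues(Q, iterations = 4000,
                                            seed = TEST_SEED))
  # a target carrying the smallest quantile in every species attains the
  # minimum possible p up to permutation ties
  Q2 <- matrix(c(0.01, 0.4, 0.7, 0.9,
                 0.02, 0.5, 0.6, 0.8), 4, 2)
  B <- 500
  p2 <- permutation_null_pvalues(Q2, iterations = B, seed = TEST_SEED)
  expect_equal(which.min(p2), 1L)
  expect_gte(p2[1], 1 / (1 + B))
  # ties occur only when the permutation reassembles the target's own
  # quantiles: probability (1/4)^2 per species pair here
  expect_equal(p2[1], 1 / 16, tolerance = 0.5)
})

test_that("single-species p-values converge to the quantile itself", {
  N <- 40
  Q <- matrix(seq_len(N) / N, ncol = 1)
  p <- permutation_null_pvalues(Q, iterations = 4000, seed = TEST_SEED)
  expect_equal(p, seq_len(N) / N, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("BH adjustment matches hand computation and a reference", {
  expect_equal(bh_fdr(0.04), 0.04)                      # single p
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # reference step-up on random vectors
  set.seed(TEST_SEED)
  for (i in 1:5) {
    p <- stats::runif(20)
    m <- length(p)
    o <- order(p)
    ref <- numeric(m)
    ref[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
    ref <- pmin(ref, 1)
    expect_equal(bh_fdr(p), ref)
  }
})

test_that("conservation-filtered regulons recover implanted targets", {
  cfg <- small_sim_config(n_genes = 80, implant_rate = 1,
                          ortholog_dropout = 0, n_tfs = 2)
  motifs <- simulate_motifs(cfg)
  fam <- simulate_species_family(cfg, motifs)
  prof <- score_promoters(motifs, fam$focal$promoters, p_threshold = 1e-3)
  focal <- build_motif_regulons(prof, cutoff = Inf)
  cons <- suppressMessages(compute_conservation(
    motifs, lapply(fam$species, `[[`, "promoters"), fam$orthology,
    iterations = 500, seed = TEST_SEED, p_threshold = 1e-3))
  # vacuous FDR filter returns the focal top-N
  vac <- build_conserved_motif_regulons(cons, focal,
                                        initial_score_cutoff = 10,
                                        fdr_cutoff = 1)
  top10 <- focal[focal$rank <= 10, ]
  expect_setequal(paste(vac$tf, vac$target), paste(top10$tf, top10$target))
  # real filter: retained targets are enriched for the conserved truth
  reg <- build_conserved_motif_regulons(cons, focal,
                                        initial_score_cutoff = 10,
                                        fdr_cutoff = 0.5)
  truth <- fam$ground_truth$true_regulons
  truth_set <- paste(truth$tf, truth$target)[truth$conserved]
  expect_gt(mean(paste(reg$tf, reg$target) %in% truth_set), 0.8)
})

test_that("conservation ordering re-ranks ChIP targets by p-value", {
  chip <- tibble::tibble(tf = "tf1", target = c("a", "b", "c"),
                         score = c(9, 5, 1), rank = 1:3, source = "chip")
  recs <- tibble::tibble(tf = "tf1", target = c("a", "b", "c"),
                         score = 1, pvalue = c(0.9, 0.01, 0.5), fdr = 1)
  out <- order_targets_by_conservation(chip, recs)
  expect_equal(out$target, c("b", "c", "a"))  # smallest p first
  expect_equal(out$rank, 1:3)
  # all p equal: original ChIP priority preserved (stable)
  recs$pvalue <- 0.5
  expect_equal(order_targets_by_conservation(chip, recs)$target,
               chip$target)
  # TF without records passes through with a message
  other <- tibble::tibble(tf = "tf2", target = c("x", "y"), score = c(2, 1),
                          rank = 1:2, source = "chip")
  expect_message(out2 <- order_targets_by_conservation(other, recs),
                 "passed through")
  expect_equal(out2$target, other$target)
  # truncation after re-ordering keeps the smallest p-values
  recs$pvalue <- c(0.9, 0.01, 0.5)
  cut <- order_targets_by_conservation(chip, recs)
  expect_equal(cut$target[cut$rank <= 2], c("b", "c"))
})
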