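# independent oracle: OLS by explicit normal equations
ols_oracle <- function(X, y) {
  Xf <- cbind(1, X)
  XtX <- t(Xf) %*% Xf
  beta <- solve(XtX, t(Xf) %*% y)
  res <- y - Xf %*% beta
  df <- length(y) - ncol(Xf)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  list(t = (beta / se)[-1], df = df)
}

toy_net <- function(weights) {
  tibble::tibble(source = rep(names(weights), lengths(weights)),
                 target = unlist(lapply(weights, names)),
                 weight = unlist(weights), sources = "chip")
}

test_that("design matrix places weights and drops empty TFs", {
  net <- toy_net(list(tfA = c(g2 = 0.67)))
  X <- build_design_matrix(net, c("g1", "g2", "g3"))
  expect_equal(X[, "tfA"], c(g1 = 0, g2 = 0.67, g3 = 0))
  net2 <- rbind(net, tibble::tibble(source = "tfB", target = "g9",
                                    weight = 1, sources = "chip"))
  expect_warning(X2 <- build_design_matrix(net2, c("g1", "g2", "g3")),
                 "tfB")
  expect_equal(colnames(X2), "tfA")
  expect_error(build_design_matrix(toy_net(list(tfA = c(gZ = 1))),
                                   c("g1", "g2")), "no network target")
})

test_that("ulm: perfect fit, orthogonal fit, and OLS oracle agreement", {
  set.seed(TEST_SEED)
  genes <- paste0("g", 1:60)
  net <- toy_net(list(tfA = stats::setNames(rep(1, 20), genes[1:20])))
  X <- build_design_matrix(net, genes)
  y <- X[, 1]                      # y = x exactly
  a <- estimate_ulm(stats::setNames(y, genes), net)
  expect_gt(abs(a$score), 1e6)
  expect_equal(a$pvalue, .Machine$double.xmin)
  # orthogonal on a balanced fixture: t ~ 0
  y2 <- rep(c(1, -1), 30)          # balanced within and outside the regulon
  a2 <- estimate_ulm(stats::setNames(y2, genes), net)
  expect_lt(abs(a2$score), 1e-8)
  # oracle agreement on noisy fixtures
  for (i in 1:5) {
    y3 <- X[, 1] * 0.8 + stats::rnorm(60)
    a3 <- estimate_ulm(stats::setNames(y3, genes), net)
    orc <- ols_oracle(X[, 1, drop = FALSE], y3)
    expect_equal(a3$score, unname(orc$t), tolerance = 1e-10)
  }
})

test_that("mlm disentangles overlapping TFs and matches the oracle", {
  genes <- paste0("g", 1:50)
  net <- toy_net(list(tfA = stats::setNames(rep(1, 10), genes[1:10]),
                      tfB = stats::setNames(rep(1, 10), genes[11:20])))
  X <- build_design_matrix(net, genes)
  y <- 2 * X[, "tfA"] - 1 * X[, "tfB"]
  a <- estimate_mlm(stats::setNames(y + stats::rnorm(50, sd = 0.1), genes), net)
  expect_gt(a$score[a$tf == "tfA"], 0)
  expect_lt(a$score[a$tf == "tfB"], 0)
  # single-TF network: mlm equals ulm exactly
  net1 <- toy_net(list(tfA = stats::setNames(rep(1, 10), genes[1:10])))
  set.seed(TEST_SEED)
  y1 <- stats::rnorm(50)
  m <- estimate_mlm(stats::setNames(y1, genes), net1)
  u <- estimate_ulm(stats::setNames(y1, genes), net1)
  expect_equal(m$score, u$score, tolerance = 1e-12)
  expect_equal(m$pvalue, u$pvalue, tolerance = 1e-12)
  # duplicate regulons are diagnosed
  netd <- toy_net(list(tfA = stats::setNames(rep(1, 5), genes[1:5]),
                       tfB = stats::setNames(rep(1, 5), genes[1:5])))
  expect_error(estimate_mlm(stats::setNames(y1, genes), netd),
               "rank deficient")
})

test_that("linear-model scores are invariant to shifts and weight scaling", {
  set.seed(TEST_SEED)
  genes <- paste0("g", 1:80)
  net <- toy_net(list(tfA = stats::setNames(runif(25, 0.3, 1), genes[1:25]),
                      tfB = stats::setNames(runif(25, 0.3, 1), genes[30:54])))
  y <- stats::setNames(stats::rnorm(80), genes)
  base_u <- estimate_ulm(y, net); base_m <- estimate_mlm(y, net)
  # adding a constant to y is absorbed by the intercept
  expect_equal(estimate_ulm(y + 5, net)$score, base_u$score,
               tolerance = 1e-9)
  expect_equal(estimate_mlm(y + 5, net)$score, base_m$score,
               tolerance = 1e-9)
  # doubling all edge weights leaves t-statistics unchanged
  net2 <- net; net2$weight <- pmin(net2$weight * 2, 1)
  net2$weight <- net$weight * 2   # allow >1 internally for the property
  expect_equal(estimate_ulm(y, net2)$score, base_u$score, tolerance = 1e-9)
  expect_equal(estimate_mlm(y, net2)$score, base_m$score, tolerance = 1e-9)
  # wsum raw doubles
  w1 <- estimate_wsum(y, net, permutations = 0)
  w2 <- estimate_wsum(y, net2, permutations = 0)
  expect_equal(w2$score, 2 * w1$score, tolerance = 1e-12)
})

test_that("wsum: raw sums, null expectation, determinism", {
  genes <- paste0("g", 1:30)
  net <- toy_net(list(tfA = c(g5 = 1)))
  y0 <- stats::setNames(rep(0, 30), genes)
  expect_equal(estimate_wsum(y0, net, permutations = 0)$score, 0)
  y <- y0; y["g5"] <- 3
  expect_equal(estimate_wsum(y, net, permutations = 0)$score, 3)
  # null mean of the permuted raw score is (sum w) * mean(y)
  set.seed(TEST_SEED)
  net2 <- toy_net(list(tfA = stats::setNames(runif(10, 0.5, 1), genes[1:10])))
  yr <- stats::setNames(stats::rnorm(30, mean = 2), genes)
  w <- estimate_wsum(yr, net2, permutations = 2000, seed = TEST_SEED)
  raw <- w$score[w$method == "wsum"]
  z <- w$score[w$method == "wsum_norm"]
  expected <- sum(net2$weight) * mean(yr)
  # replay the same permutation stream: the null mean matches the analytic
  # expectation (sum w) * mean(y) within Monte-Carlo error
  set.seed(TEST_SEED)
  X <- build_design_matrix(net2, genes)
  perms <- replicate(2000, sum(X[, 1] * yr[sample.int(30)]))
  expect_equal(mean(perms), expected, tolerance = 0.15)
  expect_equal(z, (raw - mean(perms)) / stats::sd(perms), tolerance = 1e-8)
  # same seed, same normalized score
  w2 <- estimate_wsum(yr, net2, permutations = 2000, seed = TEST_SEED)
  expect_identical(w$score, w2$score)
})

test_that("consensus averages per-method z-scores", {
  grid <- expand.grid(tf = c("a", "b", "c", "d"), experiment = "e1",
                      stringsAsFactors = FALSE)
  m1 <- tibble::tibble(grid, method = "ulm", score = c(2, 1, -1, -2),
                       pvalue = 0.5)
  # identical standardized scores: consensus equals each method's z
  m2 <- m1; m2$method <- "mlm"; m2$score <- m1$score * 10
  cons <- consensus_score(list(m1, m2))
  z <- (m1$score - mean(m1$score)) / stats::sd(m1$score)
  expect_equal(cons$score[match(m1$tf, cons$tf)], z)
  # opposite signs of equal magnitude cancel
  m3 <- m1; m3$method <- "mlm"; m3$score <- -m1$score
  cons2 <- consensus_score(list(m1, m3))
  expect_equal(cons2$score, rep(0, 4))
  expect_error(consensus_score(list(m1)), "2 methods")
})

test_that("meta-analysis: z-scores, mean across studies, geometric-mean p", {
  a1 <- tibble::tibble(tf = c("a", "b", "c"), experiment = "e1",
                       method = "mlm", score = c(4, 0, -4),
                       pvalue = c(0.01, 1, 0.5))
  m1 <- meta_analyze(a1)
  expect_equal(m1$mean_z[m1$tf == "a"],
               (4 - 0) / stats::sd(c(4, 0, -4)))  # single experiment
  # a TF at z = +2 in each of 5 experiments has mean z = 2 -- construct
  # scores whose per-experiment z for tf a is the same value
  multi <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(tf = c("a", "b", "c"), experiment = paste0("e", i),
                   method = "mlm", score = c(4, 0, -4) * i,
                   pvalue = c(0.01, 0.0001, 1))
  }))
  mm <- meta_analyze(multi)
  z_one <- (4 - 0) / stats::sd(c(4, 0, -4))
  expect_equal(mm$mean_z[mm$tf == "a"], z_one)
  expect_equal(mm$geom_p[mm$tf == "a"], 0.01)
  # geometric mean of (0.01, 0.0001) is 0.001
  two <- multi[multi$experiment %in% c("e1", "e2"), ]
  two$pvalue[two$tf == "a"] <- c(0.01, 0.0001)
  m2 <- meta_analyze(two)
  expect_equal(m2$geom_p[m2$tf == "a"], 0.001)
  # zero within-experiment variance errors
  flat <- tibble::tibble(tf = c("a", "b"), experiment = "e1", method = "mlm",
                         score = c(1, 1), pvalue = 0.5)
  expect_error(meta_analyze(flat), "variance")
})
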