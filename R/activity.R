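# TF activity estimation from differential-expression signatures using a
# weighted GRN: univariate linear model (ulm), multivariate linear model
# (mlm), weighted sum (raw and permutation-normalized), consensus, and
# cross-study meta-analysis.
#
# Signatures are a genes x experiments numeric matrix of signed DE
# statistics. Networks are unsigned: weights are non-negative, so increased
# activity of a repressor surfaces as a negative estimated activity.

#' Build the genes x TFs design matrix for a network
#'
#' Entry (g, t) is the weight of edge t -> g, or 0 when g is not a target of
#' t. Rows follow `genes` (the signature's gene universe: non-targets are
#' retained -- they inform the intercept and the residual variance); columns
#' are sorted TF ids. TFs whose column is all zero after intersection with
#' the gene universe are dropped with a warning.
#'
#' @param net network tibble (`source`, `target`, `weight`).
#' @param genes ordered character vector of gene ids.
#' @return genes x TFs numeric matrix.
#' @export
build_design_matrix <- function(net, genes) {
  tfs <- sort(unique(net$source))
  keep <- net$target %in% genes
  stop_if(!any(keep), "no network target is present in the signature genes")
  X <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  sub <- net[keep, , drop = FALSE]
  X[cbind(match(sub$target, genes), match(sub$source, tfs))] <- sub$weight
  zero <- colSums(X != 0) == 0L
  if (any(zero)) {
    warning("dropping TF(s) with no targets in the signature: ",
            paste(utils::head(tfs[zero], 10L), collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  X
}

as_signature_matrix <- function(mat) {
  if (is.numeric(mat) && is.null(dim(mat))) {
    mat <- matrix(mat, ncol = 1, dimnames = list(names(mat), "signature"))
  }
  mat <- as.matrix(mat)
  stop_if(is.null(rownames(mat)), "signature matrix needs gene rownames")
  stop_if(any(!is.finite(mat)), "signature contains non-finite values")
  mat
}

activity_tibble <- function(score, pvalue, method) {
  tibble::tibble(
    tf = rep(rownames(score), ncol(score)),
    experiment = rep(colnames(score), each = nrow(score)),
    method = method,
    score = as.vector(score),
    pvalue = as.vector(pvalue))
}

#' Univariate linear model activities
#'
#' Per TF and experiment: OLS of the gene statistics on an intercept and the
#' TF's weight column. The activity score is the slope t-statistic; p-value
#' from the t distribution with G - 2 degrees of freedom, two-sided. TFs
#' whose weight column has zero variance are skipped with a warning.
#'
#' @param mat genes x experiments signature matrix (or a named vector).
#' @param net network tibble.
#' @return activity tibble `tf`, `experiment`, `method`, `score`, `pvalue`.
#' @export
estimate_ulm <- function(mat, net) {
  mat <- as_signature_matrix(mat)
  stop_if(nrow(mat) < 3L, "ulm needs at least 3 genes")
  X <- build_design_matrix(net, rownames(mat))
  sdx <- apply(X, 2, stats::sd)
  if (any(sdx == 0)) {
    warning("skipping zero-variance TF column(s): ",
            paste(colnames(X)[sdx == 0], collapse = ", "))
    X <- X[, sdx > 0, drop = FALSE]
  }
  G <- nrow(mat); df <- G - 2
  r <- stats::cor(X, mat)                      # TFs x experiments
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt(df / (1 - r^2))
  pval <- pmax(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin)
  activity_tibble(tstat, pval, "ulm")
}

# collinearity diagnosis for mlm: pairs of identical columns
find_duplicate_columns <- function(X) {
  key <- apply(X, 2, paste, collapse = "\r")
  dup <- split(colnames(X), key)
  dup <- dup[lengths(dup) > 1L]
  vapply(dup, paste, "", collapse = " = ")
}

#' Multivariate linear model activities
#'
#' Fits, per experiment, a single OLS of the gene statistics on the
#' intercept plus all TF columns jointly, which can disentangle the separate
#' effects of TFs with overlapping regulons. The score for TF t is its
#' coefficient t-statistic; p from the t distribution with G - T - 1 degrees
#' of freedom, two-sided. Requires G > T + 1 and a full-column-rank design;
#' rank deficiency is reported naming duplicate regulons when detectable.
#'
#' @inheritParams estimate_ulm
#' @return activity tibble.
#' @export
estimate_mlm <- function(mat, net) {
  mat <- as_signature_matrix(mat)
  X <- build_design_matrix(net, rownames(mat))
  G <- nrow(mat); Tn <- ncol(X)
  stop_if(G <= Tn + 1, "mlm needs more genes than TFs + 1 (G = ", G,
          ", T = ", Tn, ")")
  Xf <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) {
    dups <- find_duplicate_columns(X)
    stop("design matrix is rank deficient",
         if (length(dups)) paste0("; duplicate regulons: ",
                                  paste(dups, collapse = "; ")) else "",
         call. = FALSE)
  }
  coef <- qr.coef(qrx, mat)                    # (T+1) x experiments
  res <- mat - Xf %*% coef
  df <- G - Tn - 1
  sigma2 <- colSums(res^2) / df
  vdiag <- diag(chol2inv(chol(crossprod(Xf))))
  se <- sqrt(outer(vdiag, sigma2))
  tstat <- (coef / se)[-1L, , drop = FALSE]
  pval <- pmax(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin)
  activity_tibble(tstat, pval, "mlm")
}

#' Weighted-sum activities (raw and permutation-normalized)
#'
#' The raw score of TF t is the weighted sum of its targets' statistics,
#' sum_g w_tg y_g. The normalized score is a z relative to a null obtained
#' by permuting the statistics across genes `permutations` times; its
#' p-value is two-sided normal. TFs with a zero null standard deviation get
#' NA normalized scores.
#'
#' @inheritParams estimate_ulm
#' @param permutations number of gene-label permutations (default 1000).
#' @param seed optional seed for the permutation null.
#' @return activity tibble holding both methods: `wsum` (raw; p-values NA)
#'   and `wsum_norm`.
#' @export
estimate_wsum <- function(mat, net, permutations = 1000, seed = NULL) {
  mat <- as_signature_matrix(mat)
  X <- build_design_matrix(net, rownames(mat))
  raw <- crossprod(X, mat)                     # TFs x experiments
  out_raw <- activity_tibble(raw, matrix(NA_real_, nrow(raw), ncol(raw)),
                             "wsum")
  if (permutations < 1) return(out_raw)
  if (!is.null(seed)) set.seed(seed)
  G <- nrow(mat)
  nullsum <- matrix(0, nrow(raw), ncol(raw))
  nullsq <- matrix(0, nrow(raw), ncol(raw))
  for (i in seq_len(permutations)) {
    perm <- crossprod(X, mat[sample.int(G), , drop = FALSE])
    nullsum <- nullsum + perm
    nullsq <- nullsq + perm^2
  }
  mu <- nullsum / permutations
  sdv <- sqrt(pmax(nullsq / permutations - mu^2, 0) *
                permutations / (permutations - 1))
  z <- (raw - mu) / sdv
  z[sdv == 0] <- NA_real_
  pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  dplyr::bind_rows(out_raw, activity_tibble(z, pval, "wsum_norm"))
}

#' Consensus activity score across methods
#'
#' Within each experiment and method, scores are standardized to z-scores
#' across TFs; the consensus is the mean of the available method z-scores
#' per (TF, experiment), with a two-sided standard-normal p-value. TFs
#' missing from some methods use the methods that did score them.
#'
#' @param method_scores list of activity tibbles (one per method) sharing
#'   the TF x experiment grid, or a single combined tibble.
#' @return activity tibble with `method = "consensus"`.
#' @export
consensus_score <- function(method_scores) {
  df <- if (is.data.frame(method_scores)) method_scores else
    dplyr::bind_rows(method_scores)
  stop_if(dplyr::n_distinct(df$method) < 2L,
          "consensus needs at least 2 methods")
  df <- df[!is.na(df$score), , drop = FALSE]
  z <- stats::ave(df$score, df$experiment, df$method,
                  FUN = function(s) (s - mean(s)) / stats::sd(s))
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(tf = df$tf, experiment = df$experiment, z = z),
                    .data$tf, .data$experiment),
    score = mean(.data$z), n_methods = dplyr::n(), .groups = "drop")
  tibble::tibble(tf = agg$tf, experiment = agg$experiment,
                 method = "consensus", score = agg$score,
                 pvalue = pmax(2 * stats::pnorm(-abs(agg$score)),
                               .Machine$double.xmin))
}

#' Estimate TF activities with a chosen method
#'
#' Dispatcher over [estimate_ulm()], [estimate_mlm()], [estimate_wsum()] and
#' the multimethod consensus (ulm + mlm + normalized wsum). The multivariate
#' linear model is the default, being the strongest single method in
#' perturbation benchmarks.
#'
#' @inheritParams estimate_ulm
#' @param method one of `"mlm"`, `"ulm"`, `"wsum"`, `"wsum_norm"`,
#'   `"consensus"`.
#' @param permutations,seed weighted-sum null parameters.
#' @return activity tibble.
#' @export
estimate_activity <- function(mat, net,
                              method = c("mlm", "ulm", "wsum", "wsum_norm",
                                         "consensus"),
                              permutations = 1000, seed = NULL) {
  method <- match.arg(method)
  switch(method,
    mlm = estimate_mlm(mat, net),
    ulm = estimate_ulm(mat, net),
    wsum = {
      a <- estimate_wsum(mat, net, permutations, seed)
      a[a$method == "wsum", , drop = FALSE]
    },
    wsum_norm = {
      a <- estimate_wsum(mat, net, permutations, seed)
      a[a$method == "wsum_norm", , drop = FALSE]
    },
    consensus = consensus_score(list(
      estimate_ulm(mat, net), estimate_mlm(mat, net),
      {
        a <- estimate_wsum(mat, net, permutations, seed)
        a[a$method == "wsum_norm", , drop = FALSE]
      })))
}

#' Meta-analysis of activities across experiments of one condition
#'
#' Per experiment, TF activity scores are converted to z-scores (subtract
#' the mean over all TFs, divide by their standard deviation). Per TF, the
#' mean z across experiments and the geometric mean of the per-experiment
#' p-values (computed in log space) are reported, ready for a volcano plot
#' of mean z against -log10 geometric-mean p.
#'
#' @param activities activity tibble covering >= 1 experiment (one method).
#' @return tibble `tf`, `mean_z`, `geom_p`, `neg_log10_p`, `n_experiments`.
#' @export
meta_analyze <- function(activities) {
  stop_if(nrow(activities) == 0L, "no activities supplied")
  stop_if(dplyr::n_distinct(activities$method) > 1L,
          "meta_analyze expects a single method")
  sds <- tapply(activities$score, activities$experiment, stats::sd)
  stop_if(any(sds == 0), "zero score variance within experiment(s): ",
          paste(names(sds)[sds == 0], collapse = ", "))
  z <- stats::ave(activities$score, activities$experiment,
                  FUN = function(s) (s - mean(s)) / stats::sd(s))
  d <- tibble::tibble(tf = activities$tf, z = z,
                      logp = log(pmax(activities$pvalue,
                                      .Machine$double.xmin)))
  agg <- dplyr::summarise(
    dplyr::group_by(d, .data$tf),
    mean_z = mean(.data$z),
    geom_p = exp(mean(.data$logp)),
    n_experiments = dplyr::n(), .groups = "drop")
  agg$neg_log10_p <- -log10(agg$geom_p)
  agg[order(-abs(agg$mean_z)), ]
}
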