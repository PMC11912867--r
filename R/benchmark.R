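# Perturbation benchmarking: orientation of signatures, pooled AUROC/AUPRC
# over (experiment, TF) pairs, shuffled-network nulls, per-TF/family
# summaries.
#
# Experiment metadata is a tibble with columns `experiment`, `perturbed_tf`,
# `direction` ("loss" or "gain"); the signature matrix columns are named by
# `experiment`.

#' Orient perturbation signatures loss-like
#'
#' Negates every gene statistic of gain-direction (overexpression)
#' experiments so all perturbations point the same way; loss-direction
#' signatures are unchanged.
#'
#' @param mat genes x experiments signature matrix.
#' @param meta experiment metadata (`experiment`, `perturbed_tf`,
#'   `direction`).
#' @return the oriented matrix.
#' @export
orient_signatures <- function(mat, meta) {
  stop_if(any(is.na(meta$direction)) ||
            !all(meta$direction %in% c("loss", "gain")),
          "direction must be 'loss' or 'gain' for every experiment")
  gain <- meta$experiment[meta$direction == "gain"]
  flip <- colnames(mat) %in% gain
  mat[, flip] <- -mat[, flip, drop = FALSE]
  mat
}

# AUROC by the rank-sum (Mann-Whitney) formula, ties averaged
auroc_ranksum <- function(values, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  stop_if(n1 == 0L, "no positives in the pooled set")
  stop_if(n0 == 0L, "no negatives in the pooled set")
  r <- rank(values)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUPRC as step-wise average precision over the pooled ranked list
auprc_average_precision <- function(values, positive) {
  ord <- order(-values)
  pos <- positive[ord]
  prec <- cumsum(pos) / seq_along(pos)
  mean(prec[pos])
}

#' Benchmark a network against perturbation signatures
#'
#' Runs the chosen activity method per experiment, pools every (experiment,
#' TF) score into one ranked list and asks whether the perturbed TFs are
#' recovered. With `negate_scores = TRUE` (default) the classifier value is
#' the negated activity score: oriented perturbations are loss-like, so a
#' perturbed TF should show the most negative activity. With
#' `negate_scores = FALSE` the absolute score is ranked instead. Experiments
#' whose perturbed TF is absent from the network are dropped and counted.
#'
#' @param net network tibble.
#' @param mat oriented genes x experiments signature matrix.
#' @param meta experiment metadata.
#' @param method activity method (see [estimate_activity()]).
#' @param negate_scores rank by negated score (TRUE) or absolute score.
#' @param permutations,seed weighted-sum null parameters, where relevant.
#' @return list with `auroc`, `auprc`, `n_experiments`, `n_unique_tfs`,
#'   `n_dropped`, and the pooled `scores` tibble.
#' @export
evaluate <- function(net, mat, meta, method = "mlm", negate_scores = TRUE,
                     permutations = 1000, seed = NULL) {
  keep <- meta$perturbed_tf %in% unique(net$source)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("evaluate: dropped ", n_dropped,
            " experiment(s) whose perturbed TF is not in the network")
  }
  meta <- meta[keep, , drop = FALSE]
  stop_if(nrow(meta) == 0L, "no experiment's perturbed TF is in the network")
  mat <- mat[, meta$experiment, drop = FALSE]
  act <- estimate_activity(mat, net, method = method,
                           permutations = permutations, seed = seed)
  act <- act[!is.na(act$score), , drop = FALSE]
  act$classifier <- if (negate_scores) -act$score else abs(act$score)
  act$positive <- act$tf ==
    meta$perturbed_tf[match(act$experiment, meta$experiment)]
  list(
    auroc = auroc_ranksum(act$classifier, act$positive),
    auprc = auprc_average_precision(act$classifier, act$positive),
    n_experiments = nrow(meta),
    n_unique_tfs = dplyr::n_distinct(meta$perturbed_tf),
    n_dropped = n_dropped,
    scores = act)
}

#' Shuffle a network's targets
#'
#' Permutes the target column across all edges, preserving the total edge
#' count, each TF's regulon size and each TF's weight multiset. Duplicate
#' (TF, target) collisions created by the permutation are re-drawn (the
#' colliding rows are re-permuted together with a random batch of other
#' rows); fixed points are allowed.
#'
#' @param net network tibble.
#' @param seed optional integer seed.
#' @return a shuffled network tibble.
#' @export
shuffle_network <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(net)
  targets <- net$target[sample.int(n)]
  for (i in seq_len(1000L)) {
    dup <- duplicated(paste(net$source, targets)) |
      duplicated(paste(net$source, targets), fromLast = TRUE)
    if (!any(dup)) break
    idx <- unique(c(which(dup), sample.int(n, min(n, sum(dup) + 5L))))
    targets[idx] <- targets[sample(idx)]
  }
  out <- net
  out$target <- targets
  out$sources <- NULL
  out
}

#' Null performance over shuffled networks
#'
#' Evaluates `n_shuffles` independently shuffled copies of the network
#' (default 100) and reports the mean and standard deviation of AUROC and
#' AUPRC, the random-expectation band against which a real network is
#' judged.
#'
#' @inheritParams evaluate
#' @param n_shuffles number of shuffled networks (>= 2).
#' @param seed integer seed; shuffle i uses a child seed derived from it.
#' @return list `auroc_mean`, `auroc_sd`, `auprc_mean`, `auprc_sd`,
#'   `n_shuffles`, plus the per-shuffle `auroc` and `auprc` vectors.
#' @export
null_performance <- function(net, mat, meta, method = "mlm", n_shuffles = 100,
                             seed = 1, negate_scores = TRUE,
                             permutations = 1000) {
  stop_if(n_shuffles < 2, "n_shuffles must be >= 2")
  auroc <- auprc <- numeric(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    sn <- shuffle_network(net, seed = child_seed(seed, i))
    ev <- evaluate(sn, mat, meta, method = method,
                   negate_scores = negate_scores,
                   permutations = permutations, seed = child_seed(seed, i))
    auroc[i] <- ev$auroc; auprc[i] <- ev$auprc
  }
  list(auroc_mean = mean(auroc), auroc_sd = stats::sd(auroc),
       auprc_mean = mean(auprc), auprc_sd = stats::sd(auprc),
       n_shuffles = n_shuffles, auroc = auroc, auprc = auprc)
}

#' Per-TF or per-family benchmark summaries
#'
#' Evaluates the network restricted to experiments whose perturbed TF falls
#' in each group (default: one group per TF). Groups without experiments are
#' omitted; single-experiment groups are flagged `low_n`.
#'
#' @inheritParams evaluate
#' @param grouping optional named character vector mapping TF -> family.
#' @return tibble `group`, `auroc`, `auprc`, `n_experiments`,
#'   `n_unique_tfs`, `low_n`.
#' @export
per_tf_performance <- function(net, mat, meta, method = "mlm",
                               grouping = NULL, negate_scores = TRUE,
                               permutations = 1000, seed = NULL) {
  if (is.null(grouping)) {
    grouping <- stats::setNames(unique(meta$perturbed_tf),
                                unique(meta$perturbed_tf))
  }
  groups <- split(names(grouping), unname(grouping))
  # score all experiments once, then slice the pooled table per group
  ev <- evaluate(net, mat, meta, method = method,
                 negate_scores = negate_scores,
                 permutations = permutations, seed = seed)
  pooled <- ev$scores
  meta <- meta[meta$experiment %in% pooled$experiment, , drop = FALSE]
  rows <- lapply(names(groups), function(g) {
    exps <- meta$experiment[meta$perturbed_tf %in% groups[[g]]]
    if (length(exps) == 0L) return(NULL)
    sub <- pooled[pooled$experiment %in% exps, , drop = FALSE]
    tibble::tibble(
      group = g,
      auroc = auroc_ranksum(sub$classifier, sub$positive),
      auprc = auprc_average_precision(sub$classifier, sub$positive),
      n_experiments = length(exps),
      n_unique_tfs = dplyr::n_distinct(
        meta$perturbed_tf[meta$experiment %in% exps]),
      low_n = length(exps) < 2L)
  })
  dplyr::bind_rows(rows)
}
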