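# Promoter scanning with PWMs, homotypic scoring and motif-evidence regulons.

# Precompute everything needed to scan one motif against many sequences.
pfm_scan_context <- function(pfm, background = rep(0.25, 4),
                             p_threshold = 1e-4, precision = 1e-3) {
  lom <- log_odds_matrix(pfm, background)
  dist <- pwm_score_distribution(lom, background, precision)
  # log-odds matrix for scoring the minus strand in plus coordinates:
  # reverse positions and complement bases
  lom_rc <- lom[rev(seq_len(nrow(lom))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(lom_rc) <- DNA_BASES
  # smallest integer score with tail p <= threshold
  ok <- dist$tail <= p_threshold
  min_int <- if (any(ok)) dist$support[which(ok)[1L]] else Inf
  list(pfm = pfm, lom = lom, lom_rc = lom_rc, dist = dist,
       p_threshold = p_threshold, min_int = min_int, precision = precision)
}

# vectorized sliding-window log-odds scores; windows containing N score -Inf
window_scores <- function(lom, idx) {
  L <- nrow(lom)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(L)) {
    v <- lom[cbind(i, idx[i:(i + n - 1L)])]
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  s
}

#' Scan one promoter sequence for motif matches
#'
#' Slides the motif over the sequence (both strands by default) and reports
#' every position whose exact match p-value is at or below `p_threshold`,
#' sorted by descending score. Positions overlapping an ambiguous base (N)
#' are never reported. Minus-strand matches are reported at their plus-strand
#' offset.
#'
#' @param pfm a [new_pfm()] object.
#' @param sequence promoter DNA string (plus-strand orientation, position 0 =
#'   most upstream base), or a one-row promoter record with a `sequence`
#'   column.
#' @param p_threshold report matches with p-value at or below this (default
#'   1e-4, the conventional scanning default).
#' @param both_strands scan the reverse complement too?
#' @param background,precision see [exact_match_pvalue()].
#' @return tibble with columns `tf`, `offset` (0-based), `strand`, `score`,
#'   `pvalue`.
#' @export
scan_promoter <- function(pfm, sequence, p_threshold = 1e-4,
                          both_strands = TRUE, background = rep(0.25, 4),
                          precision = 1e-3) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1L]]
  ctx <- pfm_scan_context(pfm, background, p_threshold, precision)
  scan_with_context(ctx, sequence, both_strands)
}

scan_with_context <- function(ctx, sequence, both_strands = TRUE) {
  idx <- encode_dna(sequence)
  sp <- window_scores(ctx$lom, idx)
  res <- list(data.frame(offset = seq_along(sp) - 1L,
                         strand = rep("+", length(sp)), score = sp))
  if (both_strands) {
    sm <- window_scores(ctx$lom_rc, idx)
    res[[2L]] <- data.frame(offset = seq_along(sm) - 1L,
                            strand = rep("-", length(sm)), score = sm)
  }
  res <- do.call(rbind, res)
  keep <- is.finite(res$score) & round(res$score / ctx$precision) >= ctx$min_int
  res <- res[keep, , drop = FALSE]
  if (nrow(res)) {
    res$pvalue <- vapply(res$score, function(s) pwm_tail_p(ctx$dist, s), 0)
    res <- res[order(-res$score, res$offset, res$strand), , drop = FALSE]
  } else {
    res$pvalue <- numeric(0)
  }
  tibble::tibble(tf = ctx$pfm$tf_id, offset = res$offset, strand = res$strand,
                 score = res$score, pvalue = res$pvalue)
}

#' Homotypic binding-site score
#'
#' Combines multiple motif matches in one promoter into a single score with
#' exponentially diminishing returns: the best match counts in full, the
#' second best is divided by `diminishing`, the third by `diminishing^2`, and
#' so on. The default base of 5 is the benchmark-selected value.
#'
#' @param match_scores numeric vector of retained match scores, sorted
#'   descending. An unsorted vector is an error.
#' @param diminishing diminishing-returns base, greater than 1.
#' @return the combined score; 0 for an empty vector.
#' @export
homotypic_score <- function(match_scores, diminishing = 5) {
  stop_if(diminishing <= 1, "diminishing must be > 1")
  if (length(match_scores) == 0L) return(0)
  stop_if(is.unsorted(rev(match_scores)),
          "match_scores must be sorted in descending order")
  sum(match_scores / diminishing^(seq_along(match_scores) - 1L))
}

#' Scan a promoter set with a motif collection
#'
#' Runs [scan_promoter()] for every (motif, promoter) pair and summarises
#' matches per pair into a promoter motif profile: number of significant
#' matches, best score and its p-value, and the homotypic score.
#'
#' @param pfms list of [new_pfm()] objects.
#' @param promoters promoter table with `gene_id` and `sequence` columns
#'   (see [fetch_sequences()]).
#' @inheritParams scan_promoter
#' @param diminishing homotypic diminishing-returns base.
#' @return tibble with columns `tf`, `gene`, `n_matches`, `best_score`,
#'   `best_p`, `homotypic_score`; one row per (tf, promoter) pair with at
#'   least one significant match.
#' @export
score_promoters <- function(pfms, promoters, p_threshold = 1e-4,
                            both_strands = TRUE, background = rep(0.25, 4),
                            precision = 1e-3, diminishing = 5) {
  stop_if(is.null(promoters$sequence), "promoters must carry sequences")
  out <- vector("list", length(pfms))
  for (k in seq_along(pfms)) {
    ctx <- pfm_scan_context(pfms[[k]], background, p_threshold, precision)
    rows <- lapply(seq_len(nrow(promoters)), function(j) {
      m <- scan_with_context(ctx, promoters$sequence[[j]], both_strands)
      if (nrow(m) == 0L) return(NULL)
      data.frame(tf = ctx$pfm$tf_id, gene = promoters$gene_id[[j]],
                 n_matches = nrow(m), best_score = m$score[1L],
                 best_p = m$pvalue[1L],
                 homotypic_score = homotypic_score(m$score, diminishing))
    })
    out[[k]] <- do.call(rbind, rows)
  }
  tibble::as_tibble(do.call(rbind, out) %||%
                      data.frame(tf = character(), gene = character(),
                                 n_matches = integer(), best_score = numeric(),
                                 best_p = numeric(), homotypic_score = numeric()))
}

#' Build motif-evidence regulons from promoter profiles
#'
#' Orders each TF's scored promoters by the chosen score (best single match
#' by default; homotypic combined score optionally) and keeps the top
#' `cutoff` targets. Ties are broken by lower best-match p-value, then by
#' gene id, for determinism.
#'
#' @param profiles output of [score_promoters()].
#' @param ordering `"best_match"` or `"homotypic"`.
#' @param cutoff maximum targets per TF (default 1000, the benchmark-optimal
#'   regulon size for motif evidence); `Inf` keeps every significant hit.
#' @return regulon tibble with columns `tf`, `target`, `score`, `rank`,
#'   `source = "motif"`.
#' @export
build_motif_regulons <- function(profiles, ordering = c("best_match", "homotypic"),
                                 cutoff = 1000) {
  ordering <- match.arg(ordering)
  score <- switch(ordering, best_match = profiles$best_score,
                  homotypic = profiles$homotypic_score)
  df <- tibble::tibble(tf = profiles$tf, target = profiles$gene, score = score,
                       best_p = profiles$best_p)
  df <- df[order(df$tf, -df$score, df$best_p, df$target), ]
  df$rank <- stats::ave(seq_len(nrow(df)), df$tf, FUN = seq_along)
  df <- df[df$rank <= cutoff, , drop = FALSE]
  tibble::tibble(tf = df$tf, target = df$target, score = df$score,
                 rank = df$rank, source = "motif")
}

#' Enforce a one-motif-per-TF map
#'
#' Motif-collection hygiene: drops indirectly inferred motifs that derive
#' from another focal-species TF's directly measured motif, and resolves
#' motifs assigned to several TFs down to one chosen TF (the choice is
#' user-supplied, e.g. by similarity score and expression).
#'
#' @param motif_map tibble with columns `motif_id`, `tf_id`, `provenance`
#'   and optionally `derived_from_tf` (focal TF the motif was inferred from).
#' @param prefer named character vector: for each multiply-assigned
#'   `motif_id`, the `tf_id` to keep. Unresolved conflicts are an error.
#' @return the filtered map with one motif per TF.
#' @export
resolve_motif_map <- function(motif_map, prefer = NULL) {
  m <- motif_map
  if (!is.null(m$derived_from_tf)) {
    drop <- m$provenance == "inferred" & !is.na(m$derived_from_tf) &
      m$derived_from_tf %in% m$tf_id[m$provenance == "direct"]
    m <- m[!drop, , drop = FALSE]
  }
  dup <- unique(m$motif_id[duplicated(m$motif_id)])
  for (id in dup) {
    stop_if(is.null(prefer) || !id %in% names(prefer),
            "motif ", id, " maps to several TFs; supply a preference")
    m <- m[m$motif_id != id | m$tf_id == prefer[[id]], , drop = FALSE]
  }
  stop_if(anyDuplicated(m$tf_id) > 0L,
          "a TF retains more than one motif after resolution")
  tibble::as_tibble(m)
}
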