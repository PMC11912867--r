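#' Construct a position frequency matrix
#'
#' A PFM holds per-position base probabilities (columns A, C, G, T) for one
#' TF binding motif, together with its provenance: `"direct"` (measured from
#' the TF's own DNA-binding domain in vitro), `"inferred"` (transferred from a
#' similar DNA-binding domain) or `"denovo"` (discovered from ChIP peak
#' sequences).
#'
#' @param probs numeric L x 4 matrix of base probabilities, one row per motif
#'   position; columns in A, C, G, T order. Each row must sum to 1 (tolerance
#'   1e-6). L must be at least 4.
#' @param motif_id,tf_id identifiers. One motif maps to one TF.
#' @param pseudocount small positive mass mixed with the background when
#'   forming log-odds scores; guards against -Inf for zero-probability cells.
#' @param provenance one of `"direct"`, `"inferred"`, `"denovo"`.
#' @return an object of class `pfm`.
#' @export
new_pfm <- function(probs, motif_id, tf_id = motif_id, pseudocount = 0.01,
                    provenance = c("direct", "inferred", "denovo")) {
  provenance <- match.arg(provenance)
  probs <- as.matrix(probs)
  stop_if(ncol(probs) != 4L, "PFM must have 4 columns (A, C, G, T)")
  stop_if(nrow(probs) < 4L, "PFM must have length >= 4")
  stop_if(any(probs < 0), "PFM probabilities must be non-negative")
  stop_if(any(abs(rowSums(probs) - 1) > 1e-6),
          "PFM rows must sum to 1 (tolerance 1e-6)")
  stop_if(!is.numeric(pseudocount) || pseudocount < 0,
          "pseudocount must be a non-negative number")
  colnames(probs) <- DNA_BASES
  structure(
    list(motif_id = as.character(motif_id), tf_id = as.character(tf_id),
         probs = probs, pseudocount = pseudocount, provenance = provenance),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s (TF %s), length %d, provenance %s\n",
              x$motif_id, x$tf_id, nrow(x$probs), x$provenance))
  invisible(x)
}

motif_length <- function(pfm) nrow(pfm$probs)

consensus_string <- function(pfm) {
  paste(DNA_BASES[max.col(pfm$probs, ties.method = "first")], collapse = "")
}

#' Log-odds scoring matrix for a PFM
#'
#' Entry (i, b) is `log2(p'[i,b] / background[b])` where `p'` mixes the PFM
#' probabilities with `pseudocount` mass proportional to the background:
#' `p' = (probs + pseudocount * background) / (1 + pseudocount)`. With a zero
#' pseudocount a zero-probability cell scores -Inf.
#'
#' @param pfm a [new_pfm()] object.
#' @param background length-4 positive vector of base frequencies (A,C,G,T),
#'   summing to 1.
#' @return L x 4 numeric matrix of log2 likelihood ratios.
#' @export
log_odds_matrix <- function(pfm, background = rep(0.25, 4)) {
  stop_if(length(background) != 4L || any(background <= 0),
          "background must be 4 strictly positive frequencies")
  stop_if(abs(sum(background) - 1) > 1e-6, "background must sum to 1")
  bg <- matrix(background, nrow = nrow(pfm$probs), ncol = 4, byrow = TRUE)
  adj <- (pfm$probs + pfm$pseudocount * bg) / (1 + pfm$pseudocount)
  lom <- log2(adj / bg)
  dimnames(lom) <- dimnames(pfm$probs)
  lom
}

# Exact null distribution of the log-odds score of a random L-mer drawn
# i.i.d. from `background`. Scores are discretized to `precision`; -Inf
# entries (zero pseudocount) route probability mass into `p_neginf`.
# Returns support (integer units of `precision`), probabilities, and the
# upper-tail function values.
pwm_score_distribution <- function(lom, background, precision = 1e-3) {
  stop_if(any(is.nan(lom)), "log-odds matrix contains NaN")
  L <- nrow(lom)
  I <- round(lom / precision)
  finite <- is.finite(I)
  p <- 1
  offset <- 0L     # integer score of p[1]
  p_neginf <- 0
  for (i in seq_len(L)) {
    row <- I[i, ]
    fin <- which(finite[i, ])
    if (length(fin) == 0L) {
      p_neginf <- p_neginf + sum(p)
      p <- numeric(0)
      break
    }
    p_neginf <- p_neginf + sum(p) * sum(background[-fin])
    lo <- min(row[fin]); hi <- max(row[fin])
    newp <- numeric(length(p) + (hi - lo))
    for (b in fin) {
      sh <- row[b] - lo
      idx <- seq_along(p) + sh
      newp[idx] <- newp[idx] + p * background[b]
    }
    p <- newp
    offset <- offset + lo
  }
  support <- if (length(p)) offset + seq_along(p) - 1L else integer(0)
  keep <- p > 0
  support <- support[keep]; p <- p[keep]
  tail <- rev(cumsum(rev(p)))
  list(support = support, prob = p, tail = tail,
       p_neginf = p_neginf, precision = precision)
}

# P(score >= s) for the distribution object above
pwm_tail_p <- function(dist, score) {
  if (!is.finite(score)) {
    if (score == -Inf) return(1)
    stop_if(is.nan(score), "non-finite score")
    return(if (score == Inf) 0 else NA_real_)
  }
  s <- round(score / dist$precision)
  if (length(dist$support) == 0L) return(0)
  idx <- findInterval(s - 0.5, dist$support) + 1L  # first support >= s
  if (idx > length(dist$support)) 0 else dist$tail[idx]
}

#' Exact match p-value for a PWM score
#'
#' Computes the probability that a random L-mer, with bases drawn i.i.d. from
#' `background`, attains a log-odds score at least `score`. The per-position
#' score distributions are discretized (default 1e-3) and convolved exactly,
#' the same dynamic program used by standard motif scanners.
#'
#' @param lom log-odds matrix from [log_odds_matrix()].
#' @inheritParams log_odds_matrix
#' @param score the score whose upper-tail probability is required.
#' @param precision discretization width for scores.
#' @return a probability in \[0, 1\].
#' @export
exact_match_pvalue <- function(lom, background = rep(0.25, 4), score,
                               precision = 1e-3) {
  stop_if(is.nan(score), "score must not be NaN")
  dist <- pwm_score_distribution(lom, background, precision)
  pwm_tail_p(dist, score)
}

#' Score of the best attainable match
#' @inheritParams exact_match_pvalue
#' @return the maximum achievable log-odds score.
#' @export
max_attainable_score <- function(lom) sum(apply(lom, 1, max))
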