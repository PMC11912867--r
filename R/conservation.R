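# Cross-species motif conservation: per-species best scores in orthologous
# promoters, rank-quantile transform, product conservation score, permutation
# empirical p-values, BH FDR, and conservation-driven regulon filtering /
# re-ordering. The approach is alignment-free: only motif presence/strength
# per orthologous promoter is compared, never aligned sequence.

#' Best motif score per orthologous promoter per species
#'
#' For each TF and focal gene, extracts the best significant motif match
#' score in the orthologous promoter of each additional species. Markers:
#' `NA` when the orthologous promoter is absent in a species (no one-to-one
#' orthologue, or the promoter was incomplete and filtered); `0` when the
#' promoter is present but shows no significant match. When the TF itself
#' has no one-to-one orthologue in a species, every target is `NA` for that
#' TF in that species (motif conservation is meaningless where the
#' trans-factor is absent).
#'
#' @param pfms list of [new_pfm()] objects (one per TF).
#' @param species_promoters named list (by species) of promoter tables with
#'   sequences; complete windows only, already candidacy-filtered.
#' @param orthology tibble `focal_gene`, `species`, `species_gene`;
#'   one-to-one within each species.
#' @param tf_orthology optional tibble `tf`, `species`, `present` (logical).
#'   Omitted = every TF present in every species.
#' @param p_threshold,background,precision scanning parameters, as in
#'   [scan_promoter()].
#' @return long tibble `tf`, `target` (focal gene id), `species`,
#'   `best_score` (NA / 0 / positive score).
#' @export
best_scores_by_species <- function(pfms, species_promoters, orthology,
                                   tf_orthology = NULL, p_threshold = 1e-4,
                                   background = rep(0.25, 4), precision = 1e-3) {
  stop_if(length(species_promoters) == 0L, "no species promoter sets")
  stop_if(is.null(names(species_promoters)),
          "species_promoters must be a named list")
  focal_genes <- sort(unique(orthology$focal_gene))
  out <- list()
  for (sp in names(species_promoters)) {
    prom <- species_promoters[[sp]]
    stop_if(is.null(prom), "species without promoter set: ", sp)
    orth <- orthology[orthology$species == sp, , drop = FALSE]
    stop_if(anyDuplicated(orth$focal_gene) || anyDuplicated(orth$species_gene),
            "orthology for species ", sp, " is not one-to-one")
    map <- match(focal_genes, orth$focal_gene)
    sp_gene <- orth$species_gene[map]
    prow <- match(sp_gene, prom$gene_id)
    for (k in seq_along(pfms)) {
      pfm <- pfms[[k]]
      present <- TRUE
      if (!is.null(tf_orthology)) {
        hit <- tf_orthology$present[tf_orthology$tf == pfm$tf_id &
                                      tf_orthology$species == sp]
        present <- length(hit) == 0L || isTRUE(hit[[1L]])
      }
      if (!present) {
        best <- rep(NA_real_, length(focal_genes))
      } else {
        ctx <- pfm_scan_context(pfm, background, p_threshold, precision)
        best <- vapply(prow, function(j) {
          if (is.na(j)) return(NA_real_)
          m <- scan_with_context(ctx, prom$sequence[[j]])
          if (nrow(m) == 0L) 0 else m$score[1L]
        }, 0)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        tf = pfm$tf_id, target = focal_genes, species = sp, best_score = best)
    }
  }
  dplyr::bind_rows(out)
}

#' Rank-quantile transform of best scores within one species
#'
#' Converts the best match scores of one TF in one species into
#' rank-quantiles: the best-scoring promoter gets rank 1 and quantile
#' 1/N (close to 0), ties receive the mean of their rank range, and
#' promoters with no motif match (score 0) get quantile exactly 1. N is the
#' number of matched promoters. `NA` (absent orthologue) stays `NA`.
#'
#' @param scores numeric vector of best scores (NA / 0 / positive).
#' @return numeric vector of quantiles in (0, 1\], NA preserved.
#' @export
rank_quantile_transform <- function(scores) {
  stop_if(all(is.na(scores)), "all scores missing")
  out <- rep(NA_real_, length(scores))
  matched <- which(!is.na(scores) & scores > 0)
  none <- which(!is.na(scores) & scores <= 0)
  if (length(matched)) {
    r <- rank(-scores[matched], ties.method = "average")
    out[matched] <- r / length(matched)
  }
  out[none] <- 1
  out
}

#' Conservation records: product score over species
#'
#' Builds one record per (TF, focal target): the per-species rank-quantiles,
#' their product over non-missing species (the conservation score; small =
#' conserved), and the number of species entering the product. Targets
#' missing in every species are dropped with a message.
#'
#' @param best_scores long tibble from [best_scores_by_species()].
#' @return list with `records` (tibble `tf`, `target`, `n_species`, `score`)
#'   and `quantiles` (named list per TF of targets x species matrices, used
#'   by the permutation null).
#' @export
conservation_records <- function(best_scores) {
  species <- sort(unique(best_scores$species))
  recs <- list(); qmats <- list()
  for (tf in sort(unique(best_scores$tf))) {
    sub <- best_scores[best_scores$tf == tf, , drop = FALSE]
    targets <- sort(unique(sub$target))
    Q <- matrix(NA_real_, length(targets), length(species),
                dimnames = list(targets, species))
    for (sp in species) {
      s <- sub[sub$species == sp, , drop = FALSE]
      v <- s$best_score[match(targets, s$target)]
      if (all(is.na(v))) next  # TF absent in this species
      Q[, sp] <- rank_quantile_transform(v)
    }
    n_sp <- rowSums(!is.na(Q))
    if (any(n_sp == 0L)) {
      message("conservation_records: ", sum(n_sp == 0L),
              " target(s) of ", tf, " missing in every species; dropped")
    }
    keep <- n_sp > 0L
    Q <- Q[keep, , drop = FALSE]
    score <- exp(rowSums(log(Q), na.rm = TRUE))
    recs[[tf]] <- tibble::tibble(tf = tf, target = rownames(Q),
                                 n_species = as.integer(n_sp[keep]),
                                 score = score)
    qmats[[tf]] <- Q
  }
  list(records = dplyr::bind_rows(recs), quantiles = qmats)
}

#' Permutation empirical p-values for conservation scores
#'
#' For one TF: within each species, the rank-quantiles are shuffled among
#' the targets that are non-missing in that species (the missingness
#' pattern, the per-species score distribution, and each target's species
#' count are all preserved). Each target's observed product is compared to
#' its own null products over `iterations` shuffles; the empirical p uses
#' the add-one estimator `(1 + #\{null <= observed\}) / (1 + iterations)` so
#' p is never zero. Small products (strong conservation) give small p.
#'
#' @param Q targets x species quantile matrix (NA = missing).
#' @param iterations number of shuffles (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of p-values, one per row of `Q`.
#' @export
permutation_null_pvalues <- function(Q, iterations = 10000, seed = NULL) {
  stop_if(iterations < 1, "iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  LQ <- log(Q)
  obs <- rowSums(LQ, na.rm = TRUE)
  n <- nrow(Q)
  count <- integer(n)
  nonna <- lapply(seq_len(ncol(Q)), function(j) which(!is.na(Q[, j])))
  tol <- 1e-12
  for (it in seq_len(iterations)) {
    null <- numeric(n)
    for (j in seq_len(ncol(Q))) {
      idx <- nonna[[j]]
      if (length(idx) < 2L) {
        if (length(idx) == 1L) null[idx] <- null[idx] + LQ[idx, j]
        next
      }
      null[idx] <- null[idx] + LQ[sample(idx), j]
    }
    count <- count + (null <= obs + tol)
  }
  (1 + count) / (1 + iterations)
}

#' Full conservation scoring pipeline
#'
#' Scans the orthologous promoter sets, transforms to rank-quantiles,
#' computes product conservation scores, permutation empirical p-values and
#' Benjamini-Hochberg FDR values (adjusted within each TF's target list).
#'
#' @inheritParams best_scores_by_species
#' @param iterations,seed see [permutation_null_pvalues()].
#' @param fdr_scope `"per_tf"` (default) adjusts within each TF;
#'   `"global"` adjusts across all records.
#' @return tibble `tf`, `target`, `n_species`, `score`, `pvalue`, `fdr`.
#' @export
compute_conservation <- function(pfms, species_promoters, orthology,
                                 tf_orthology = NULL, iterations = 10000,
                                 seed = NULL, p_threshold = 1e-4,
                                 background = rep(0.25, 4), precision = 1e-3,
                                 fdr_scope = c("per_tf", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  bs <- best_scores_by_species(pfms, species_promoters, orthology,
                               tf_orthology, p_threshold, background, precision)
  cr <- conservation_records(bs)
  recs <- cr$records
  pv <- numeric(nrow(recs))
  for (i in seq_along(cr$quantiles)) {
    tf <- names(cr$quantiles)[i]
    rows <- which(recs$tf == tf)
    pv[rows] <- permutation_null_pvalues(
      cr$quantiles[[tf]],
      iterations = iterations,
      seed = if (is.null(seed)) NULL else child_seed(seed, i))
  }
  recs$pvalue <- pv
  recs$fdr <- if (fdr_scope == "per_tf") {
    stats::ave(recs$pvalue, recs$tf, FUN = bh_fdr)
  } else {
    bh_fdr(recs$pvalue)
  }
  recs
}

#' Benjamini-Hochberg FDR
#'
#' Standard step-up false discovery rate adjustment.
#' @param pvalues numeric vector in (0, 1\].
#' @return adjusted values, same length.
#' @export
bh_fdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Conservation-filtered motif regulons
#'
#' Takes each TF's top `initial_score_cutoff` focal-species targets (by best
#' motif match), keeps those whose conservation FDR is at or below
#' `fdr_cutoff` (default 0.8 -- deliberately permissive, as the empirical
#' FDRs are conservative), and orders by ascending FDR then ascending
#' conservation score.
#'
#' @param records conservation records ([compute_conservation()]).
#' @param focal_regulons focal-species motif regulons ordered by best match
#'   ([build_motif_regulons()] with `cutoff = Inf`).
#' @param initial_score_cutoff focal-species pre-filter size per TF.
#' @param fdr_cutoff conservation FDR threshold.
#' @return regulon tibble (`source = "motif"`).
#' @export
build_conserved_motif_regulons <- function(records, focal_regulons,
                                           initial_score_cutoff = 1000,
                                           fdr_cutoff = 0.8) {
  top <- focal_regulons[focal_regulons$rank <= initial_score_cutoff, ,
                        drop = FALSE]
  m <- dplyr::inner_join(
    top, records[c("tf", "target", "score", "pvalue", "fdr")],
    by = c("tf", "target"), suffix = c("_focal", ""))
  m <- m[m$fdr <= fdr_cutoff, , drop = FALSE]
  m <- m[order(m$tf, m$fdr, m$score, m$target), , drop = FALSE]
  tibble::tibble(tf = m$tf, target = m$target, score = m$score,
                 rank = stats::ave(seq_len(nrow(m)), m$tf, FUN = seq_along),
                 source = "motif")
}

#' Re-order ChIP regulons by motif conservation
#'
#' Keeps each TF's target set unchanged but orders targets by ascending
#' conservation p-value (most conserved first) computed from a supplied
#' per-TF motif (de novo or known); ties and targets without a record keep
#' their original ChIP priority (targets without records sort last). TFs
#' with no conservation records pass through unchanged.
#'
#' @param chip_regulons ChIP regulon tibble.
#' @param records conservation records for the same TFs.
#' @return re-ordered regulon tibble with recomputed ranks.
#' @export
order_targets_by_conservation <- function(chip_regulons, records) {
  tf_with <- unique(records$tf)
  skipped <- setdiff(unique(chip_regulons$tf), tf_with)
  if (length(skipped)) {
    message("order_targets_by_conservation: no motif/records for TF(s) ",
            paste(utils::head(skipped, 10L), collapse = ", "),
            "; passed through unchanged")
  }
  m <- dplyr::left_join(
    chip_regulons, records[c("tf", "target", "pvalue")],
    by = c("tf", "target"))
  key_p <- ifelse(m$tf %in% tf_with & !is.na(m$pvalue), m$pvalue, Inf)
  m <- m[order(m$tf, key_p, m$rank), , drop = FALSE]
  m$rank <- stats::ave(seq_len(nrow(m)), m$tf, FUN = seq_along)
  m$pvalue <- NULL
  m
}
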