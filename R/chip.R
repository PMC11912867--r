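# ChIP evidence: narrowPeak ingest, peak-to-promoter assignment, target
# prioritization, HOT (high-occupancy target) regions and HOT exclusion.

#' Read an ENCODE narrowPeak file
#'
#' BED6+4 with signalValue (column 7) as the peak-strength field and the
#' summit offset in column 10. Coordinates are kept 0-based half-open.
#'
#' @param path narrowPeak file.
#' @param tf_id,experiment_id labels attached to every peak.
#' @return tibble `tf`, `experiment`, `chrom`, `start`, `end`, `signal`,
#'   `summit_offset`.
#' @export
read_narrowpeak <- function(path, tf_id, experiment_id) {
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  tibble::tibble(
    tf = tf_id, experiment = experiment_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    signal = gr$signalValue,
    summit_offset = gr$peak
  )
}

#' Write peaks as narrowPeak
#' @param peaks peak tibble as returned by [read_narrowpeak()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   paste0(peaks$tf, "_", peaks$experiment, "_", seq_len(nrow(peaks))),
                   0L, ".", peaks$signal, -1, -1,
                   peaks$summit_offset %||% as.integer((peaks$end - peaks$start) %/% 2))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

peaks_as_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Assign ChIP peaks to overlapping promoters
#'
#' A peak is assigned to every promoter it overlaps by at least one base
#' (half-open intervals; an abutting peak does not overlap). A peak spanning
#' the overlap of two promoters therefore yields two hits: each bound
#' promoter counts the TF as a potential regulator regardless of greater
#' proximity of the peak to another gene's TSS.
#'
#' @param peaks peak tibble.
#' @param promoters promoter table.
#' @return hit tibble `tf`, `gene`, `experiment`, `signal`.
#' @export
peaks_to_promoter_hits <- function(peaks, promoters) {
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(tf = character(), gene = character(),
                          experiment = character(), signal = numeric()))
  }
  ov <- GenomicRanges::findOverlaps(peaks_as_granges(peaks),
                                    promoters_as_granges(promoters))
  tibble::tibble(
    tf = peaks$tf[S4Vectors::queryHits(ov)],
    gene = promoters$gene_id[S4Vectors::subjectHits(ov)],
    experiment = peaks$experiment[S4Vectors::queryHits(ov)],
    signal = peaks$signal[S4Vectors::queryHits(ov)]
  )
}

#' Prioritize ChIP targets into ordered regulons
#'
#' Per TF, targets are ordered first by repeated occurrence across
#' independent experiments (number of distinct experiments with a hit on the
#' promoter, descending), then by the strongest peak signal (descending),
#' then by gene id (ascending) for a deterministic total order.
#'
#' @param hits hit table from [peaks_to_promoter_hits()].
#' @return regulon tibble `tf`, `target`, `score` (max signal), `rank`,
#'   `source = "chip"`, plus `n_experiments`.
#' @export
prioritize_chip_targets <- function(hits) {
  agg <- dplyr::summarise(
    dplyr::group_by(hits, tf = .data$tf, target = .data$gene),
    n_experiments = dplyr::n_distinct(.data$experiment),
    score = max(.data$signal), .groups = "drop")
  agg <- agg[order(agg$tf, -agg$n_experiments, -agg$score, agg$target), ]
  agg$rank <- stats::ave(seq_len(nrow(agg)), agg$tf, FUN = seq_along)
  tibble::tibble(tf = agg$tf, target = agg$target, score = agg$score,
                 rank = agg$rank, source = "chip",
                 n_experiments = agg$n_experiments)
}

#' Merge peaks into candidate HOT regions
#'
#' Pools every peak across the TF panel and merges overlapping intervals
#' into maximal blocks, the download-free alternative to an externally
#' supplied HOT table.
#'
#' @param peaks peak tibble across all TFs/experiments.
#' @return region tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
derive_hot_regions <- function(peaks) {
  red <- GenomicRanges::reduce(peaks_as_granges(peaks))
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(red)),
                 start = GenomicRanges::start(red) - 1L,
                 end = GenomicRanges::end(red))
}

#' Count distinct TFs binding each region
#'
#' Annotates each region with the number of distinct TFs having at least one
#' overlapping peak in any experiment. Repeated experiments for one TF count
#' once: a region should not become HOT merely because consistently bound
#' TFs were assayed many times.
#'
#' @param peaks peak tibble across the TF panel.
#' @param regions region tibble (`chrom`, `start`, `end`).
#' @return regions with an `n_tfs` column.
#' @export
compute_hot_regions <- function(peaks, regions) {
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  ov <- GenomicRanges::findOverlaps(peaks_as_granges(peaks), rg)
  pairs <- unique(data.frame(region = S4Vectors::subjectHits(ov),
                             tf = peaks$tf[S4Vectors::queryHits(ov)]))
  counts <- table(factor(pairs$region, levels = seq_len(nrow(regions))))
  regions$n_tfs <- as.integer(counts)
  regions
}

#' Exclude targets whose promoters fall in HOT regions
#'
#' Removes from every regulon any target whose promoter overlaps a region
#' bound by at least `cutoff` distinct TFs (default 50, the
#' benchmark-selected exclusion criterion). Regulon ordering is otherwise
#' preserved and ranks are recomputed.
#'
#' @param regulons regulon tibble (e.g. from [prioritize_chip_targets()]).
#' @param hot region tibble with `n_tfs` (see [compute_hot_regions()]).
#' @param promoters promoter table locating each target's promoter.
#' @param cutoff HOT threshold on distinct TF count (comparison is `>=`).
#' @return the filtered regulons.
#' @export
exclude_hot_promoters <- function(regulons, hot, promoters, cutoff = 50) {
  stop_if(cutoff < 1, "cutoff must be >= 1")
  hot_regions <- hot[hot$n_tfs >= cutoff, , drop = FALSE]
  if (nrow(hot_regions) == 0L) return(regulons)
  rg <- GenomicRanges::GRanges(hot_regions$chrom,
                               IRanges::IRanges(hot_regions$start + 1L,
                                                hot_regions$end))
  ov <- GenomicRanges::findOverlaps(promoters_as_granges(promoters), rg)
  hot_genes <- unique(promoters$gene_id[S4Vectors::queryHits(ov)])
  out <- regulons[!regulons$target %in% hot_genes, , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$tf, FUN = seq_along)
  out
}

#' Build ChIP-evidence regulons
#'
#' prioritize -> optional HOT exclusion -> optional top-N truncation.
#' Defaults (HOT exclusion at 50, no target cutoff) reproduce the ChIP
#' component of the combined-network recipe: unrestricted regulon size with
#' HOT promoters excluded performs best for ChIP evidence.
#'
#' @param hits hit table.
#' @param hot HOT region table with `n_tfs`, or NULL to skip exclusion.
#' @param promoters promoter table (needed when `hot` is given).
#' @param cutoff_targets optional per-TF regulon size cap.
#' @param hot_cutoff distinct-TF threshold, or NULL to skip HOT exclusion.
#' @return regulon tibble.
#' @export
build_chip_regulons <- function(hits, hot = NULL, promoters = NULL,
                                cutoff_targets = NULL, hot_cutoff = 50) {
  reg <- prioritize_chip_targets(hits)
  if (!is.null(hot) && !is.null(hot_cutoff)) {
    stop_if(is.null(promoters), "promoters required for HOT exclusion")
    reg <- exclude_hot_promoters(reg, hot, promoters, hot_cutoff)
  }
  if (!is.null(cutoff_targets)) {
    reg <- reg[reg$rank <= cutoff_targets, , drop = FALSE]
  }
  reg
}
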