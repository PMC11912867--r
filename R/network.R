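# Network data model: evidence integration with source-count weighting,
# regulon-size filtering, named recipes, and TSV round trip.
#
# A network is a tibble with columns `source` (TF), `target`, `weight`,
# `sources` (comma-joined evidence labels from {chip, motif, ey1h}).
# A regulon collection is a tibble with columns `tf`, `target`, `score`,
# `rank`, `source` (one evidence label).

SOURCE_WEIGHTS <- c(0.33, 0.67, 1.0)  # 1, 2, 3 contributing evidence sources

validate_regulons <- function(regulons) {
  stop_if(nrow(regulons) == 0L, "empty regulon collection")
  bad <- setdiff(unique(regulons$source), EVIDENCE_SOURCES)
  stop_if(length(bad) > 0L,
          "unknown evidence source label(s): ", paste(bad, collapse = ", "))
  invisible(regulons)
}

#' Combine evidence regulons into a weighted network
#'
#' Takes the union of all (TF, target) pairs across evidence collections.
#' With `weighted = TRUE` an interaction supported by all three evidence
#' types (ChIP, motif, eY1H) gets the maximum weight 1, while interactions
#' in two or one sources get 0.67 and 0.33 respectively (stored exactly as
#' printed, not as thirds). With `weighted = FALSE` every weight is 1.
#' Regulon collections must be unfiltered: the minimum-target filter is
#' applied once, after combination, because a TF below threshold in each
#' single source can still reach it by pooling targets.
#'
#' @param regulon_sets list of regulon tibbles (columns `tf`, `target`,
#'   `source`, optionally `score`, `rank`).
#' @param weighted apply source-count weights?
#' @return network tibble `source`, `target`, `weight`, `sources`, `rank`
#'   (best rank across contributing sources, NA when absent).
#' @export
combine_networks <- function(regulon_sets, weighted = TRUE) {
  stop_if(length(regulon_sets) == 0L, "no regulon collections supplied")
  all <- dplyr::bind_rows(lapply(regulon_sets, function(r) {
    validate_regulons(r)
    tibble::tibble(tf = as.character(r$tf), target = as.character(r$target),
                   source = r$source,
                   rank = if (!"rank" %in% names(r)) NA_integer_ else
                     as.integer(r$rank))
  }))
  agg <- dplyr::summarise(
    dplyr::group_by(all, .data$tf, .data$target),
    sources = join_sources(.data$source),
    n_sources = dplyr::n_distinct(.data$source),
    rank = if (all(is.na(.data$rank))) NA_integer_ else
      min(.data$rank, na.rm = TRUE),
    .groups = "drop")
  tibble::tibble(
    source = agg$tf, target = agg$target,
    weight = if (weighted) SOURCE_WEIGHTS[agg$n_sources] else 1.0,
    sources = agg$sources, rank = agg$rank)
}

#' Drop TFs with small regulons
#'
#' Removes every TF with fewer than `min_targets` targets (default 15):
#' linear-model activity estimates fit to very few data points are spurious.
#' Surviving edges are untouched; removals are reported via `message()`.
#'
#' @param net network tibble.
#' @param min_targets minimum regulon size; a TF with exactly this many
#'   targets is retained.
#' @return the filtered network.
#' @export
filter_min_targets <- function(net, min_targets = 15) {
  stop_if(min_targets < 1, "min_targets must be >= 1")
  sizes <- table(net$source)
  drop <- names(sizes)[sizes < min_targets]
  if (length(drop)) {
    message("filter_min_targets: removed ", length(drop), " TF(s): ",
            paste(utils::head(drop, 10L), collapse = ", "),
            if (length(drop) > 10L) ", ..." else "")
  }
  net[!net$source %in% drop, , drop = FALSE]
}

#' Assemble a named network recipe
#'
#' Three published recipes are supported:
#' \describe{
#'   \item{celest}{HOT-excluded full ChIP regulons + top-1000 motif regulons
#'     (best single match) + eY1H; weighted; minimum 15 targets.}
#'   \item{orthcelest}{conservation-filtered motif regulons (initial score
#'     cutoff then FDR filter) + conservation-ordered, HOT-excluded ChIP
#'     regulons cut at 1000 + eY1H; weighted; minimum 15 targets.}
#'   \item{maxcelest}{conservation-ordered ChIP regulons with no HOT
#'     exclusion cut at 500 + top-1000 motif regulons + eY1H; weighted;
#'     minimum 15 targets. Maximizes TF coverage: no TF is lost to HOT
#'     exclusion or conservation filtering.}
#' }
#'
#' @param recipe one of `"celest"`, `"orthcelest"`, `"maxcelest"`.
#' @param chip_hits ChIP hit table ([peaks_to_promoter_hits()]).
#' @param hot HOT region table with `n_tfs`.
#' @param promoters promoter table (for HOT exclusion).
#' @param motif_profiles promoter motif profiles ([score_promoters()]).
#' @param ey1h_regulons eY1H regulon tibble (`source = "ey1h"`).
#' @param motif_conservation conservation records for the in vitro motifs
#'   (required for `orthcelest`).
#' @param chip_conservation conservation records used to re-order ChIP
#'   targets (required for `orthcelest` and `maxcelest`).
#' @param params named list overriding defaults: `motif_cutoff` (1000),
#'   `chip_cutoff` (1000 for orthcelest, 500 for maxcelest), `hot_cutoff`
#'   (50), `min_targets` (15), `fdr_cutoff` (0.8), `initial_score_cutoff`
#'   (1000), `weighted` (TRUE).
#' @return network tibble with a `recipe` attribute.
#' @export
assemble_recipe <- function(recipe = c("celest", "orthcelest", "maxcelest"),
                            chip_hits, hot, promoters, motif_profiles,
                            ey1h_regulons,
                            motif_conservation = NULL,
                            chip_conservation = NULL,
                            params = list()) {
  recipe <- match.arg(recipe)
  p <- utils::modifyList(
    list(motif_cutoff = 1000, hot_cutoff = 50, min_targets = 15,
         fdr_cutoff = 0.8, initial_score_cutoff = 1000, weighted = TRUE,
         chip_cutoff = if (recipe == "maxcelest") 500 else 1000),
    params)
  if (recipe %in% c("orthcelest", "maxcelest")) {
    stop_if(is.null(chip_conservation),
            "recipe ", recipe, " requires ChIP conservation records")
  }
  if (recipe == "orthcelest") {
    stop_if(is.null(motif_conservation),
            "recipe orthcelest requires motif conservation records")
  }
  chip <- switch(
    recipe,
    celest = build_chip_regulons(chip_hits, hot, promoters,
                                 cutoff_targets = NULL,
                                 hot_cutoff = p$hot_cutoff),
    orthcelest = {
      r <- build_chip_regulons(chip_hits, hot, promoters,
                               cutoff_targets = NULL,
                               hot_cutoff = p$hot_cutoff)
      r <- order_targets_by_conservation(r, chip_conservation)
      r[r$rank <= p$chip_cutoff, , drop = FALSE]
    },
    maxcelest = {
      r <- build_chip_regulons(chip_hits, hot = NULL, promoters = NULL,
                               cutoff_targets = NULL, hot_cutoff = NULL)
      r <- order_targets_by_conservation(r, chip_conservation)
      r[r$rank <= p$chip_cutoff, , drop = FALSE]
    })
  motif <- if (recipe == "orthcelest") {
    focal <- build_motif_regulons(motif_profiles, "best_match", cutoff = Inf)
    build_conserved_motif_regulons(motif_conservation, focal,
                                   initial_score_cutoff = p$initial_score_cutoff,
                                   fdr_cutoff = p$fdr_cutoff)
  } else {
    build_motif_regulons(motif_profiles, "best_match", cutoff = p$motif_cutoff)
  }
  net <- combine_networks(list(chip, motif, ey1h_regulons),
                          weighted = p$weighted)
  net <- filter_min_targets(net, p$min_targets)
  attr(net, "recipe") <- recipe
  attr(net, "parameters") <- p
  net
}

#' Read / write a network TSV
#'
#' The canonical on-disk format is a TSV with header columns `source`,
#' `target`, `weight` and optionally `sources` (comma-joined evidence
#' labels); this layout is directly consumable by downstream
#' activity-inference frameworks.
#'
#' @param path file path.
#' @return `read_network`: a network tibble. `write_network`: `path`,
#'   invisibly.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("source", "target", "weight")
  missing <- setdiff(need, names(df))
  stop_if(length(missing) > 0L,
          "network file lacks column(s) ", paste(missing, collapse = ", "),
          "; found: ", paste(names(df), collapse = ", "))
  bad <- which(!is.finite(df$weight) | df$weight <= 0 | df$weight > 1)
  stop_if(length(bad) > 0L,
          "weight outside (0, 1] at data row(s): ",
          paste(utils::head(bad), collapse = ", "))
  if (is.null(df$sources)) df$sources <- NA_character_
  tibble::as_tibble(df[c("source", "target", "weight", "sources")])
}

#' @rdname read_network
#' @param net network tibble.
#' @export
write_network <- function(net, path) {
  df <- data.frame(source = net$source, target = net$target,
                   weight = net$weight,
                   sources = net$sources %||% NA_character_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binary TF-promoter interactions (e.g. eY1H) as regulons
#'
#' Expects a TSV with TF and target columns; optionally filters to rows
#' whose `quality_col` equals `quality_keep` (e.g. the high-quality subset
#' of a yeast one-hybrid screen).
#'
#' @param path TSV file.
#' @param tf_col,target_col column names holding TF and target ids.
#' @param quality_col,quality_keep optional quality filter.
#' @return regulon tibble with `source = "ey1h"`; ranks follow file order
#'   within each TF (the assay is binary, so order carries no priority).
#' @export
read_interactions <- function(path, tf_col = "tf", target_col = "target",
                              quality_col = NULL, quality_keep = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stop_if(!all(c(tf_col, target_col) %in% names(df)),
          "interaction file lacks columns ", tf_col, "/", target_col)
  if (!is.null(quality_col)) {
    df <- df[df[[quality_col]] == quality_keep, , drop = FALSE]
  }
  df <- unique(df[c(tf_col, target_col)])
  names(df) <- c("tf", "target")
  df <- df[order(df$tf), , drop = FALSE]
  tibble::tibble(tf = df$tf, target = df$target, score = NA_real_,
                 rank = stats::ave(seq_len(nrow(df)), df$tf, FUN = seq_along),
                 source = "ey1h")
}
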