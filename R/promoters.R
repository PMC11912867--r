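# Promoter windows: derivation from gene annotations, candidacy filtering,
# sequence extraction. Coordinates are 0-based half-open throughout; GFF3
# input (1-based closed) is converted on read.

#' Read gene annotations from GFF3
#'
#' Keeps features of type `gene` and derives the gene-level TSS: the leftmost
#' base for plus-strand genes, the rightmost for minus-strand genes, as a
#' 0-based position. Optional numeric attribute `detection_fraction` and
#' logical attributes matching `operon_downstream*` are carried through when
#' present (they are inputs, not computed here).
#'
#' @param path GFF3 file.
#' @return tibble with columns `gene_id`, `chrom`, `tss` (0-based), `strand`
#'   and any candidacy attributes found.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  stop_if(length(gr) == 0L, "no gene features in ", path)
  df <- tibble::tibble(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tss = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                 GenomicRanges::end(gr) - 1L,
                 GenomicRanges::start(gr) - 1L)
  )
  extra <- S4Vectors::mcols(gr)
  if ("detection_fraction" %in% colnames(extra)) {
    df$detection_fraction <- as.numeric(as.character(extra$detection_fraction))
  }
  for (nm in grep("^operon", colnames(extra), value = TRUE)) {
    df[[nm]] <- as.logical(as.character(extra[[nm]]))
  }
  df
}

#' Derive promoter windows around gene TSSs
#'
#' The promoter of a plus-strand gene with TSS at 0-based position t is the
#' half-open window `[t - upstream, t + downstream)`; for a minus-strand gene
#' it is `[t - downstream + 1, t + upstream + 1)`. Windows truncated by a
#' chromosome edge are marked incomplete (and must be excluded from
#' cross-species promoter sets). Defaults cover 1000 bp upstream and 200 bp
#' downstream of the TSS.
#'
#' @param genes tibble with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param upstream,downstream non-negative window extents in bp.
#' @return tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `complete`.
#' @export
extract_promoter_windows <- function(genes, chrom_lengths,
                                     upstream = 1000, downstream = 200) {
  stop_if(upstream < 0 || downstream < 0,
          "upstream and downstream must be non-negative")
  unknown <- setdiff(unique(genes$chrom), names(chrom_lengths))
  stop_if(length(unknown) > 0L,
          "unknown chromosome(s): ", paste(unknown, collapse = ", "))
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss - downstream + 1L, genes$tss - upstream)
  end <- ifelse(minus, genes$tss + upstream + 1L, genes$tss + downstream)
  len <- unname(chrom_lengths[genes$chrom])
  complete <- start >= 0L & end <= len
  tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(pmax(start, 0L)), end = as.integer(pmin(end, len)),
    strand = genes$strand, complete = complete
  )
}

#' Filter promoters to candidate target genes
#'
#' A candidate target must have robust, differentiated expression (detected
#' in at least `min_detection` of the reference expression samples) and must
#' not be annotated as downstream within an operon in any evidence source:
#' operon-internal genes are unlikely to be controlled by sequence proximal
#' to their annotated TSS.
#'
#' @param promoters output of [extract_promoter_windows()].
#' @param genes gene table carrying `detection_fraction` and one or more
#'   logical `operon_downstream*` columns.
#' @param min_detection retention threshold on `detection_fraction`
#'   (default 2/3).
#' @return the retained promoter rows.
#' @export
filter_candidate_targets <- function(promoters, genes, min_detection = 2 / 3) {
  stop_if(is.null(genes$detection_fraction),
          "genes must carry detection_fraction")
  op_cols <- grep("^operon", names(genes), value = TRUE)
  op_any <- if (length(op_cols)) {
    Reduce(`|`, lapply(op_cols, function(c) isTRUE_vec(genes[[c]])))
  } else rep(FALSE, nrow(genes))
  keep_genes <- genes$gene_id[genes$detection_fraction >= min_detection & !op_any]
  out <- promoters[promoters$gene_id %in% keep_genes, , drop = FALSE]
  if (nrow(out) == 0L) message("filter_candidate_targets: no genes retained")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Attach promoter sequences from a genome
#'
#' Extracts each window's sequence from a genome; minus-strand windows are
#' reverse-complemented so that position 0 of every promoter sequence is its
#' most upstream base.
#'
#' @param promoters promoter table (0-based half-open windows).
#' @param genome a [Biostrings::DNAStringSet] named by chromosome, or a path
#'   to a FASTA file.
#' @return `promoters` with a `sequence` character column.
#' @export
fetch_sequences <- function(promoters, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(promoters$chrom), names(genome))
  stop_if(length(missing_chr) > 0L,
          "genome lacks chromosome(s): ", paste(missing_chr, collapse = ", "))
  lens <- Biostrings::width(genome)[match(promoters$chrom, names(genome))]
  bad <- promoters$start < 0L | promoters$end > lens
  stop_if(any(bad), "window out of sequence bounds for gene(s): ",
          paste(utils::head(promoters$gene_id[bad]), collapse = ", "))
  seqs <- character(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    s <- Biostrings::subseq(genome[[promoters$chrom[i]]],
                            start = promoters$start[i] + 1L,
                            end = promoters$end[i])
    if (promoters$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  promoters$sequence <- seqs
  promoters
}

#' Write promoter windows as BED
#'
#' 0-based half-open BED6 with the gene id in the name column.
#' @param promoters promoter table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  df <- data.frame(promoters$chrom, promoters$start, promoters$end,
                   promoters$gene_id, 0L, promoters$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# promoter table -> GRanges (1-based closed) for overlap arithmetic
promoters_as_granges <- function(promoters) {
  GenomicRanges::GRanges(
    seqnames = promoters$chrom,
    ranges = IRanges::IRanges(start = promoters$start + 1L,
                              end = promoters$end),
    strand = "*", gene_id = promoters$gene_id
  )
}
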