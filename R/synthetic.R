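# Synthetic data with known ground truth: motifs, focal + congeneric
# promoter/genome sets with controlled motif conservation, ChIP peaks with
# HOT regions, and perturbation signatures. Everything is seed-deterministic
# and parses back through the package's own readers, so the full pipeline is
# testable without downloads.

#' Simulation configuration
#'
#' Central knob set for the generators. Defaults describe the emulated study
#' conditions: 2000 candidate target genes, 50 TFs with regulons of 100
#' targets, perturbation effect size 3 against unit noise, 50 perturbation
#' experiments; 7 congeneric species with a 6/7 per-species implant rate for
#' conserved sites and 15% orthologue dropout; motifs of length 8 with 0.85
#' consensus-base probability; promoter windows of 1000 bp upstream + 200 bp
#' downstream.
#'
#' @param n_genes,n_tfs candidate target genes and TFs.
#' @param n_species congeneric species for conservation scoring.
#' @param motif_length motif length (>= 6).
#' @param consensus_prob probability mass on the consensus base per column.
#' @param implant_rate per-species probability that a conserved target's
#'   orthologous promoter carries the implanted site.
#' @param ortholog_dropout probability a gene lacks an orthologue in a
#'   species.
#' @param tf_ortholog_dropout probability a TF lacks an orthologue in a
#'   species (0: every TF present everywhere).
#' @param n_conserved,n_decoys per TF: targets with cross-species implants
#'   vs focal-only implants (decoys), used by the species-family generator.
#' @param regulon_size targets per TF for regulon-level simulation.
#' @param activity_effect perturbation effect size A.
#' @param noise_sd residual noise standard deviation.
#' @param n_experiments perturbation experiments.
#' @param gain_fraction fraction of experiments that are overexpression
#'   (gain) rather than loss.
#' @param base_composition named length-4 base frequencies (A,C,G,T);
#'   uniform by default. `at_rich_composition()` gives a skewed preset for
#'   stress-testing p-value calibration.
#' @param upstream,downstream promoter window extents.
#' @param gene_spacing bp between consecutive TSSs on the synthetic
#'   chromosome.
#' @param peak_width ChIP peak width in bp.
#' @param n_hot,hot_k HOT promoters to designate, and distinct TFs binding
#'   each.
#' @param multi_exp_fraction fraction of TFs assayed in two ChIP
#'   experiments.
#' @param seed base seed; all generators derive child seeds from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_tfs = 50, n_species = 7,
                              motif_length = 8, consensus_prob = 0.85,
                              implant_rate = 6 / 7, ortholog_dropout = 0.15,
                              tf_ortholog_dropout = 0,
                              n_conserved = 20, n_decoys = 20,
                              regulon_size = 100, activity_effect = 3,
                              noise_sd = 1, n_experiments = 50,
                              gain_fraction = 0.25,
                              base_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                              upstream = 1000, downstream = 200,
                              gene_spacing = 2000, peak_width = 150,
                              n_hot = 10, hot_k = 60,
                              multi_exp_fraction = 0.2, seed = 1) {
  stop_if(motif_length < 6, "motif_length must be >= 6")
  stop_if(n_genes <= n_tfs + 1, "n_genes must exceed n_tfs + 1")
  stop_if(any(c(implant_rate, ortholog_dropout, tf_ortholog_dropout,
                gain_fraction) < 0) ||
            any(c(implant_rate, ortholog_dropout, tf_ortholog_dropout,
                  gain_fraction) > 1),
          "probabilities must lie in [0, 1]")
  stop_if(abs(sum(base_composition) - 1) > 1e-6,
          "base_composition must sum to 1")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' AT-rich base composition preset
#' @return named frequency vector (A 0.32, C 0.18, G 0.18, T 0.32).
#' @export
at_rich_composition <- function() c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)

gene_ids <- function(n) sprintf("g%04d", seq_len(n))
tf_ids <- function(n) sprintf("tf%03d", seq_len(n))

#' Simulate TF binding motifs
#'
#' One information-rich motif per TF: each column puts `consensus_prob`
#' (default 0.85) on a random consensus base and spreads the rest evenly,
#' yielding motifs discriminative enough that their own consensus string
#' scores below the conventional 1e-4 scanning threshold.
#'
#' @param config a [simulation_config()].
#' @return named list of [new_pfm()] objects, one per TF.
#' @export
simulate_motifs <- function(config) {
  set.seed(child_seed(config$seed, 101L))
  L <- config$motif_length
  off <- (1 - config$consensus_prob) / 3
  out <- list()
  for (tf in tf_ids(config$n_tfs)) {
    cons <- sample.int(4L, L, replace = TRUE)
    probs <- matrix(off, L, 4)
    probs[cbind(seq_len(L), cons)] <- config$consensus_prob
    out[[tf]] <- new_pfm(probs, motif_id = paste0(tf, "_m"), tf_id = tf,
                         provenance = "direct")
  }
  out
}

random_genome <- function(len, composition) {
  paste(sample(DNA_BASES, len, replace = TRUE, prob = composition),
        collapse = "")
}

# build the standard synthetic chromosome layout for n genes
genome_layout <- function(config, n_genes) {
  spacing <- config$gene_spacing
  tss <- config$upstream + 300L + (seq_len(n_genes) - 1L) * spacing
  len <- max(tss) + config$upstream + config$downstream + 500L
  list(tss = tss, chrom = "chrI", length = len)
}

# implant `site` into the genome string so the promoter sequence (upstream-
# first orientation) carries it at `offset`
implant_site <- function(genome_chars, win_start, win_end, strand, offset, site) {
  L <- nchar(site)
  if (strand == "+") {
    pos <- win_start + offset              # 0-based genomic
    genome_chars[(pos + 1):(pos + L)] <- strsplit(site, "")[[1]]
  } else {
    pos <- win_end - offset - L
    genome_chars[(pos + 1):(pos + L)] <- strsplit(revcomp(site), "")[[1]]
  }
  genome_chars
}

build_species_instance <- function(config, n_genes, genes_present, strands,
                                   implants, motifs, id_prefix) {
  lay <- genome_layout(config, n_genes)
  chars <- sample(DNA_BASES, lay$length, replace = TRUE,
                  prob = config$base_composition)
  present <- which(genes_present)
  genes <- tibble::tibble(
    gene_id = paste0(id_prefix, gene_ids(n_genes)[present]),
    chrom = lay$chrom, tss = lay$tss[present], strand = strands[present],
    detection_fraction = 1, operon_downstream = FALSE)
  prom <- extract_promoter_windows(
    genes, stats::setNames(lay$length, lay$chrom),
    upstream = config$upstream, downstream = config$downstream)
  prom <- prom[prom$complete, , drop = FALSE]
  implant_log <- list()
  if (nrow(implants) > 0L) {
    for (i in seq_len(nrow(implants))) {
      g <- implants$gene_index[i]
      if (!genes_present[g]) next
      row <- match(paste0(id_prefix, gene_ids(n_genes)[g]), prom$gene_id)
      if (is.na(row)) next
      site <- consensus_string(motifs[[implants$tf[i]]])
      L <- nchar(site)
      wlen <- prom$end[row] - prom$start[row]
      offset <- sample((L + 1):(wlen - 2L * L), 1L)
      chars <- implant_site(chars, prom$start[row], prom$end[row],
                            prom$strand[row], offset, site)
      implant_log[[length(implant_log) + 1L]] <- tibble::tibble(
        tf = implants$tf[i], gene = gene_ids(n_genes)[g],
        species_gene = prom$gene_id[row], offset = offset)
    }
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chars, collapse = ""), lay$chrom))
  prom <- fetch_sequences(prom, genome)
  list(genes = genes, genome = genome, promoters = prom,
       chrom_lengths = stats::setNames(lay$length, lay$chrom),
       implants = dplyr::bind_rows(implant_log))
}

#' Simulate a focal species plus congeneric promoter sets
#'
#' Background promoters are i.i.d. from the base composition. Per TF,
#' `n_conserved` true conserved targets carry the motif consensus in the
#' focal promoter and, independently with probability `implant_rate`, in
#' each orthologous species promoter; `n_decoys` decoy targets carry a
#' focal-only implant. Orthologues drop out per species with probability
#' `ortholog_dropout`.
#'
#' @param config a [simulation_config()].
#' @param motifs list from [simulate_motifs()] (defaults to generating one).
#' @return list with `focal` (genes, genome, promoters with sequences,
#'   chrom_lengths), `species` (named list of the same per congeneric
#'   species), `orthology`, `tf_orthology`, and `ground_truth`
#'   (`true_regulons` tibble with a `conserved` flag, plus implant logs).
#' @export
simulate_species_family <- function(config, motifs = simulate_motifs(config)) {
  set.seed(child_seed(config$seed, 202L))
  n <- config$n_genes
  tfs <- names(motifs)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  # ground-truth target assignment
  truth <- list()
  for (tf in tfs) {
    picked <- sample.int(n, config$n_conserved + config$n_decoys)
    truth[[tf]] <- tibble::tibble(
      tf = tf, gene_index = picked,
      conserved = rep(c(TRUE, FALSE),
                      c(config$n_conserved, config$n_decoys)))
  }
  truth <- dplyr::bind_rows(truth)
  truth$target <- gene_ids(n)[truth$gene_index]

  focal <- build_species_instance(
    config, n, genes_present = rep(TRUE, n), strands = strands,
    implants = truth, motifs = motifs, id_prefix = "")

  species_names <- sprintf("sp%02d", seq_len(config$n_species))
  species <- list(); orth <- list(); tf_orth <- list()
  for (s in species_names) {
    present <- stats::runif(n) >= config$ortholog_dropout
    tf_present <- stats::runif(length(tfs)) >= config$tf_ortholog_dropout
    sp_implants <- truth[truth$conserved &
                           stats::runif(nrow(truth)) <= config$implant_rate &
                           tf_present[match(truth$tf, tfs)], , drop = FALSE]
    inst <- build_species_instance(
      config, n, genes_present = present, strands = strands,
      implants = sp_implants, motifs = motifs,
      id_prefix = paste0(s, "_"))
    species[[s]] <- inst
    orth[[s]] <- tibble::tibble(
      focal_gene = gene_ids(n)[present], species = s,
      species_gene = paste0(s, "_", gene_ids(n)[present]))
    tf_orth[[s]] <- tibble::tibble(tf = tfs, species = s,
                                   present = tf_present)
  }
  list(
    focal = focal,
    species = species,
    orthology = dplyr::bind_rows(orth),
    tf_orthology = dplyr::bind_rows(tf_orth),
    ground_truth = list(
      true_regulons = truth[c("tf", "target", "conserved")],
      focal_implants = focal$implants,
      species_implants = lapply(species, `[[`, "implants"))
  )
}

#' Simulate ChIP peaks with HOT regions
#'
#' True-target promoters receive one peak per experiment with lognormal
#' signal; a designated subset of promoters additionally receives peaks
#' from `hot_k` distinct TFs, forming HOT regions. A fraction of TFs is
#' assayed in two experiments whose peaks are jittered copies.
#'
#' @param config a [simulation_config()].
#' @param regulons tibble `tf`, `target` of true regulons.
#' @param promoters promoter table locating each target.
#' @return list with `peaks` (peak tibble), `hot_intervals` (tibble of the
#'   designated HOT promoter windows) and `hot_genes`.
#' @export
simulate_chip_peaks <- function(config, regulons, promoters) {
  set.seed(child_seed(config$seed, 303L))
  tfs <- unique(regulons$tf)
  multi <- stats::setNames(
    stats::runif(length(tfs)) < config$multi_exp_fraction, tfs)
  hot_rows <- sample.int(nrow(promoters), min(config$n_hot, nrow(promoters)))
  hot_genes <- promoters$gene_id[hot_rows]
  hot_tf_sets <- lapply(hot_rows, function(i) {
    sample(tfs, min(config$hot_k, length(tfs)))
  })
  mk_peak <- function(tf, rows, experiment, jitter) {
    centre <- (promoters$start[rows] + promoters$end[rows]) %/% 2L +
      sample(seq(-jitter, jitter), length(rows), replace = TRUE)
    half <- config$peak_width %/% 2L
    tibble::tibble(
      tf = tf, experiment = experiment, chrom = promoters$chrom[rows],
      start = pmax(centre - half, 0L), end = centre + half,
      signal = stats::rlnorm(length(rows), meanlog = 2, sdlog = 0.5),
      summit_offset = half)
  }
  peaks <- list()
  for (tf in tfs) {
    rows <- match(regulons$target[regulons$tf == tf], promoters$gene_id)
    rows <- rows[!is.na(rows)]
    hot_for_tf <- hot_rows[vapply(hot_tf_sets, function(s) tf %in% s, TRUE)]
    rows <- union(rows, hot_for_tf)
    if (length(rows) == 0L) next
    peaks[[length(peaks) + 1L]] <- mk_peak(tf, rows, paste0(tf, "_e1"), 0L)
    if (multi[[tf]]) {
      peaks[[length(peaks) + 1L]] <- mk_peak(tf, rows, paste0(tf, "_e2"), 10L)
    }
  }
  list(peaks = dplyr::bind_rows(peaks),
       hot_intervals = tibble::tibble(
         chrom = promoters$chrom[hot_rows],
         start = promoters$start[hot_rows],
         end = promoters$end[hot_rows]),
       hot_genes = hot_genes)
}

#' Simulate TF perturbation signatures
#'
#' Per experiment, one TF is perturbed: the gene statistics are
#' `y = X a + e` with `e ~ N(0, noise_sd^2)`, where X is the regulon
#' indicator matrix and the perturbed TF's activity is `-activity_effect`
#' for loss experiments or `+activity_effect` for gain experiments (all
#' other activities zero). Perturbed TFs cycle through the TF panel.
#'
#' @param regulons tibble `tf`, `target` (or a network with `source`,
#'   `target`).
#' @param config a [simulation_config()].
#' @param genes gene universe (default: all `n_genes` synthetic ids).
#' @return list `mat` (genes x experiments), `meta` (tibble `experiment`,
#'   `perturbed_tf`, `direction`), `true_activities`.
#' @export
simulate_perturbation_signatures <- function(regulons, config,
                                             genes = gene_ids(config$n_genes)) {
  set.seed(child_seed(config$seed, 404L))
  if ("source" %in% names(regulons) && !"tf" %in% names(regulons)) {
    regulons <- tibble::tibble(tf = regulons$source, target = regulons$target)
  }
  tfs <- sort(unique(regulons$tf))
  X <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  keep <- regulons$target %in% genes
  X[cbind(match(regulons$target[keep], genes),
          match(regulons$tf[keep], tfs))] <- 1
  nE <- config$n_experiments
  perturbed <- tfs[((seq_len(nE) - 1L) %% length(tfs)) + 1L]
  direction <- ifelse(stats::runif(nE) < config$gain_fraction, "gain", "loss")
  A <- ifelse(direction == "gain", config$activity_effect,
              -config$activity_effect)
  mat <- matrix(stats::rnorm(length(genes) * nE, sd = config$noise_sd),
                length(genes), nE,
                dimnames = list(genes, sprintf("exp%03d", seq_len(nE))))
  for (i in seq_len(nE)) {
    mat[, i] <- mat[, i] + X[, perturbed[i]] * A[i]
  }
  list(mat = mat,
       meta = tibble::tibble(experiment = colnames(mat),
                             perturbed_tf = perturbed,
                             direction = direction),
       true_activities = tibble::tibble(experiment = colnames(mat),
                                        tf = perturbed, activity = A))
}

#' Simulate plain regulons (no sequences)
#'
#' Per TF, `regulon_size` targets sampled uniformly from the gene universe.
#' @param config a [simulation_config()].
#' @return tibble `tf`, `target`.
#' @export
simulate_regulons <- function(config) {
  set.seed(child_seed(config$seed, 505L))
  dplyr::bind_rows(lapply(tf_ids(config$n_tfs), function(tf) {
    tibble::tibble(tf = tf,
                   target = gene_ids(config$n_genes)[
                     sample.int(config$n_genes, config$regulon_size)])
  }))
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA genomes, GFF3 annotations (with detection/operon attributes),
#' a MEME minimal motif file, orthology and ground-truth TSVs, narrowPeak
#' files per TF ChIP experiment, and the signature matrix + metadata TSVs.
#' Everything round-trips through the package's own readers.
#'
#' @param sim output of [simulate_species_family()].
#' @param dir output directory (created if needed).
#' @param motifs motif list to write (optional).
#' @param chip optional output of [simulate_chip_peaks()].
#' @param signatures optional output of
#'   [simulate_perturbation_signatures()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, motifs = NULL, chip = NULL,
                             signatures = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_instance <- function(inst, prefix) {
    Biostrings::writeXStringSet(
      inst$genome, file.path(dir, paste0(prefix, ".fa")))
    gr <- GenomicRanges::GRanges(
      inst$genes$chrom,
      IRanges::IRanges(
        start = ifelse(inst$genes$strand == "-",
                       inst$genes$tss - 998L, inst$genes$tss + 1L),
        width = 1000L),
      strand = inst$genes$strand)
    gr$type <- "gene"
    gr$ID <- inst$genes$gene_id
    gr$detection_fraction <- inst$genes$detection_fraction
    gr$operon_downstream <- inst$genes$operon_downstream
    rtracklayer::export(gr, file.path(dir, paste0(prefix, ".gff3")),
                        format = "gff3")
  }
  write_instance(sim$focal, "focal")
  for (s in names(sim$species)) write_instance(sim$species[[s]], s)
  utils::write.table(sim$orthology, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ground_truth$true_regulons,
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(motifs)) write_meme(motifs, file.path(dir, "motifs.meme"))
  if (!is.null(chip)) {
    for (e in unique(chip$peaks$experiment)) {
      write_narrowpeak(chip$peaks[chip$peaks$experiment == e, ],
                       file.path(dir, paste0(e, ".narrowPeak")))
    }
  }
  if (!is.null(signatures)) {
    utils::write.table(
      data.frame(gene = rownames(signatures$mat), signatures$mat,
                 check.names = FALSE),
      file.path(dir, "signatures.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(signatures$meta, file.path(dir, "benchmark_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
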