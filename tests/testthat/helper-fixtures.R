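# Shared fixtures, built in code. The base seed 42 is fixed for the whole
# suite.

TEST_SEED <- 42L

random_pfm <- function(L, seed, pseudocount = 0.01) {
  set.seed(seed)
  probs <- t(apply(matrix(stats::rgamma(L * 4, 1), L, 4), 1,
                   function(r) r / sum(r)))
  new_pfm(probs, sprintf("m%d", seed), sprintf("tf%d", seed),
          pseudocount = pseudocount)
}

# enumerate all 4^L words and their exact scores under a background
enumerate_scores <- function(lom, background = rep(0.25, 4)) {
  L <- nrow(lom)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  score <- apply(words, 1, function(w) sum(lom[cbind(seq_len(L), w)]))
  prob <- apply(words, 1, function(w) prod(background[w]))
  list(score = score, prob = prob)
}

random_dna <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# a 3-source toy regulon set with known overlaps
toy_regulon_sets <- function() {
  chip <- tibble::tibble(tf = "tfA", target = c("g1", "g2", "g3"),
                         score = c(9, 8, 7), rank = 1:3, source = "chip")
  motif <- tibble::tibble(tf = "tfA", target = c("g1", "g2", "g4"),
                          score = c(5, 4, 3), rank = 1:3, source = "motif")
  ey1h <- tibble::tibble(tf = "tfA", target = c("g1", "g5"),
                         score = NA_real_, rank = 1:2, source = "ey1h")
  list(chip = chip, motif = motif, ey1h = ey1h)
}

toy_promoters <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chrI",
    start = c(100L, 250L, 1000L),
    end = c(300L, 450L, 1200L),    # gA and gB overlap in [250, 300)
    strand = c("+", "+", "-"),
    complete = TRUE)
}

small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60, n_tfs = 4, n_species = 3, n_conserved = 5,
         n_decoys = 5, regulon_size = 10, n_experiments = 8,
         seed = TEST_SEED),
    list(...))
  do.call(simulation_config, args)
}
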