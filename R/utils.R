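# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

EVIDENCE_SOURCES <- c("chip", "motif", "ey1h")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# encode a DNA string as 1..4 indices (A,C,G,T); anything else (N, gaps) -> NA
encode_dna <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

join_sources <- function(x) paste(sort(unique(x)), collapse = ",")

# deterministic child seeds for repeated stochastic stages
child_seed <- function(seed, i) {
  (seed * 1009L + i * 9973L) %% 2147483647L
}
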