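# MEME minimal motif format IO (letter-probability matrix blocks).

#' Read motifs in MEME minimal format
#'
#' Parses the minimal text format: a `MEME version` header, optional
#' `ALPHABET`/`Background letter frequencies` lines, then one
#' `MOTIF <id> [<alt>]` block per motif with its
#' `letter-probability matrix` lines.
#'
#' @param path file path.
#' @param pseudocount,provenance passed to [new_pfm()] for every motif; the
#'   alternate name field, when present, is taken as the TF id.
#' @return named list of [new_pfm()] objects (names = motif ids).
#' @export
read_meme <- function(path, pseudocount = 0.01, provenance = "direct") {
  lines <- readLines(path)
  stop_if(!any(grepl("^MEME version", lines)), "not a MEME minimal file: ", path)
  starts <- grep("^MOTIF\\b", lines)
  stop_if(length(starts) == 0L, "no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    head_parts <- strsplit(trimws(lines[[s]]), "\\s+")[[1]]
    motif_id <- head_parts[2]
    tf_id <- if (length(head_parts) >= 3) head_parts[3] else motif_id
    j <- s + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[[j]])) {
      j <- j + 1L
    }
    stop_if(j > length(lines), "motif ", motif_id, " has no probability matrix")
    rows <- list()
    j <- j + 1L
    while (j <= length(lines) && grepl("^\\s*[0-9.eE+-]+\\s", lines[[j]])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[[j]]), "\\s+")[[1]])
      j <- j + 1L
    }
    probs <- do.call(rbind, rows)
    out[[motif_id]] <- new_pfm(probs, motif_id, tf_id,
                               pseudocount = pseudocount,
                               provenance = provenance)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pfms list of [new_pfm()] objects.
#' @param path output file.
#' @param background length-4 background frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""), con)
  for (p in pfms) {
    writeLines(sprintf("MOTIF %s %s", p$motif_id, p$tf_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$probs)), con)
    apply(p$probs, 1, function(r) {
      writeLines(sprintf(" %.10f %.10f %.10f %.10f", r[1], r[2], r[3], r[4]), con)
    })
    writeLines("", con)
  }
  invisible(path)
}
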