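# Tabular IO for signatures, metadata, orthology and conservation records.

#' Read a signature matrix TSV
#'
#' Gene rows by experiment columns of signed DE statistics; first column
#' holds gene ids.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
read_signatures <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Read perturbation metadata TSV
#'
#' Columns `experiment`, `perturbed_tf`, `direction` (loss/gain).
#' @param path TSV file.
#' @return metadata tibble.
#' @export
read_benchmark_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("experiment", "perturbed_tf", "direction")
  stop_if(!all(need %in% names(df)),
          "metadata must have columns ", paste(need, collapse = ", "))
  tibble::as_tibble(df[need])
}

#' Read an orthology map TSV
#'
#' Columns `focal_gene`, `species`, `species_gene`; one-to-one within each
#' species.
#' @param path TSV file.
#' @return orthology tibble.
#' @export
read_orthology <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("focal_gene", "species", "species_gene")
  stop_if(!all(need %in% names(df)),
          "orthology must have columns ", paste(need, collapse = ", "))
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, ]
    stop_if(anyDuplicated(sub$focal_gene) || anyDuplicated(sub$species_gene),
            "orthology for species ", sp, " is not one-to-one")
  }
  tibble::as_tibble(df[need])
}

#' Write / read conservation records TSV
#' @param records conservation record tibble.
#' @param path file path.
#' @return `path` invisibly / a tibble.
#' @export
write_conservation <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_conservation
#' @export
read_conservation <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
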