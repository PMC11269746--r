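# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA alignments, presence/absence TSV tables, and JSON ground truth.

#' Read an aligned FASTA file into a character matrix
#'
#' @param path FASTA file.
#' @return character matrix (sequences x columns) of class `aa_msa`.
#' @export
read_fasta_msa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1) stop("sequences are not aligned (unequal widths)")
  m <- do.call(rbind, strsplit(as.character(ss), ""))
  rownames(m) <- names(ss)
  structure(m, class = c("aa_msa", class(m)))
}

#' Write a character-matrix alignment as FASTA
#'
#' @param msa character matrix (sequences x columns).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta_msa <- function(msa, path) {
  seqs <- apply(msa, 1, paste, collapse = "")
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a species x ortholog presence/absence table
#'
#' TSV with the species id in the first column and one 0/1 column per
#' ortholog group.
#'
#' @param path TSV file.
#' @return integer matrix with species rownames.
#' @export
read_pa_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  m
}

#' Write a presence/absence table as TSV
#'
#' @param table species x OG 0/1 matrix with rownames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pa_table <- function(table, path) {
  d <- data.frame(species = rownames(table), table, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation's ground truth as JSON
#'
#' Stores the full per-node state history and the planted loss orders of an
#' `og_sim` object.
#'
#' @param sim an `og_sim` from [simulate_binary_ogs()].
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_true_history <- function(sim, path) {
  jsonlite::write_json(list(history = as.data.frame(sim$history),
                            truth = sim$truth),
                       path, dataframe = "columns", digits = NA)
  invisible(path)
}
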