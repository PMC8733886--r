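# FASTA sequence-database I/O (via Biostrings).

#' Read a FASTA sequence database
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Data frame of class `sequence_db` with columns `id` (first token of
#'   each header) and `seq` (upper-case amino-acid sequence), file order
#'   preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop_classed(sprintf("FASTA file not found: %s", path), "format_error")
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop_classed(sprintf("duplicated FASTA identifiers: %s",
                         paste(dup, collapse = ", ")), "format_error")
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0))
    stop_classed("FASTA contains empty sequences", "format_error")
  sequence_db(ids, seqs)
}

#' Construct a sequence database
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of amino-acid sequences.
#' @return A `sequence_db` data frame.
#' @export
sequence_db <- function(id, seq) {
  stopifnot(length(id) == length(seq), !anyDuplicated(id), all(nchar(seq) > 0))
  structure(data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                       stringsAsFactors = FALSE),
            class = c("sequence_db", "data.frame"))
}

#' Write a sequence database as FASTA
#'
#' @param db A `sequence_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  ss <- Biostrings::AAStringSet(db$seq)
  names(ss) <- db$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
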