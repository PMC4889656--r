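#' FASTA helpers for proteomes and 16S sequences
#'
#' Thin wrappers over Biostrings readers/writers returning the plain named
#' character vectors used by the orthology functions.
#'
#' @param path FASTA path.
#' @return `read_proteome`: named character vector of protein sequences;
#'   `read_first_seq`: the first sequence as a character scalar (e.g. a
#'   16S rRNA entry).
#' @export
read_proteome <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_proteome
#' @export
read_first_seq <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop_validation("empty FASTA: %s", path)
  as.character(x[[1]])
}

#' @rdname read_proteome
#' @param seqs Named character vector of sequences.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
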