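## Internal sequence helpers. Sequences are handled as plain uppercase
## character strings inside the package; Biostrings objects are accepted
## and converted at the boundary.

#' @keywords internal
#' @noRd
as_dna_string <- function(seq, allow_n = TRUE, what = "sequence") {
  if (inherits(seq, "DNAString") || inherits(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- toupper(seq)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", s)
  if (nchar(bad) > 0L) {
    stop(what, " contains characters outside ", alphabet, ": '",
         substr(bad, 1L, 10L), "'", call. = FALSE)
  }
  s
}

#' @keywords internal
#' @noRd
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on
#' plain character strings. `N` is preserved.
#'
#' @param seq a single DNA string (A/C/G/T/N, case-insensitive).
#' @return the reverse complement, uppercase.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  s <- as_dna_string(seq, allow_n = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read sequences from a FASTA file
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
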