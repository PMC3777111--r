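# Shared low-level helpers: the amino-acid alphabet, sequence encoding and
# FASTA I/O (via Biostrings).

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Sequences may additionally contain `X` (unknown residue), which scores
#' zero in every scoring scheme.
#'
#' @return Character vector of the 20 standard one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# integer-encode one sequence; X (and only X) maps to 0
encode_seq <- function(s, allow_x = TRUE) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  codes <- match(chars, aa_alphabet(), nomatch = 0L)
  bad <- codes == 0L & chars != "X"
  if (any(bad)) {
    stop("sequence contains residues outside the 20-letter alphabet + X: ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  if (!allow_x && any(codes == 0L)) {
    stop("sequence contains X but the caller does not allow unknown residues",
         call. = FALSE)
  }
  codes
}

check_protein <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  invisible(encode_seq(s))
}

#' Read a protein FASTA file as a named character vector
#'
#' Sequence names are the full header lines (without `>`); callers that use
#' structured headers parse them further.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write a named character vector of protein sequences as FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
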