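# Multiple alignment of kinase domains: the input from which both the
# position-specific profile and the functional-residue motif model are
# built.

#' Construct a domain alignment from gapped sequences
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (gap symbol `-`; `.` is normalised to `-`).
#' @return An object of class `kin_alignment`: list with `ids`, `seqs` and
#'   `n_columns`.
#' @export
as_alignment <- function(seqs) {
  if (length(seqs) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("alignment rows must be named", call. = FALSE)
  }
  seqs <- gsub(".", "-", toupper(seqs), fixed = TRUE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("gapped sequences must all have equal length", call. = FALSE)
  }
  ok <- grepl(sprintf("^[%sX-]*$", paste(aa_alphabet(), collapse = "")), seqs)
  if (!all(ok)) {
    stop("alignment rows contain characters outside the amino-acid alphabet: ",
         paste(names(seqs)[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(ids = names(seqs), seqs = unname(seqs),
                 n_columns = widths[1L]),
            class = "kin_alignment")
}

#' Read a domain alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file.
#' @return A `kin_alignment`.
#' @export
read_alignment <- function(path) {
  as_alignment(read_fasta(path))
}

#' @export
print.kin_alignment <- function(x, ...) {
  cat("Domain alignment: ", length(x$ids), " rows x ", x$n_columns,
      " columns\n", sep = "")
  invisible(x)
}

# alignment as a character matrix (rows x columns)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

# fraction of rows with a residue (not gap) in each column
aln_occupancy <- function(mat) {
  colMeans(mat != "-")
}
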