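# Functional-residue motif model.  Kinase catalytic substructures are more
# constrained by function than by stability, so general-purpose profiles
# underweight them.  This model scores only "viable" residues -- residues
# actually observed at an alignment column among curated active kinases --
# and weights each column inversely to its variability (1 / number of
# viable residues), so an invariant catalytic column counts twice as much
# as a column with two viable residues.

#' Build a functional-residue motif model from a domain alignment
#'
#' For each alignment column with residue occupancy at least
#' `min_occupancy`, the viable set is the set of residues observed in the
#' column and the column weight is `1 / |viable set|`.  Columns are indexed
#' in the coordinate system of the profile built from the same alignment
#' (see [build_profile()]), so profile hit column maps can be applied
#' directly.  `min_occupancy` below 0.5 is raised to 0.5 so that every
#' motif column is also a profile match column.
#'
#' @param aln A [kin_alignment][as_alignment].
#' @param min_occupancy Minimum fraction of non-gap rows for a column to
#'   enter the model (default 0.5, matching the profile match-column rule).
#' @return An object of class `kin_motif`: list with `columns` (data.frame:
#'   `column` = profile column index, `aln_column` = original alignment
#'   column, `viable` = string of viable residues, `weight`) and
#'   `total_weight`.
#' @export
build_motif <- function(aln, min_occupancy = 0.5) {
  stopifnot(inherits(aln, "kin_alignment"))
  if (!is.numeric(min_occupancy) || min_occupancy <= 0 || min_occupancy > 1) {
    stop("min_occupancy must be in (0, 1]", call. = FALSE)
  }
  min_occupancy <- max(min_occupancy, 0.5)
  mat <- aln_matrix(aln)
  occ <- aln_occupancy(mat)
  match_cols <- which(occ >= 0.5)          # profile coordinate system
  motif_cols <- which(occ >= min_occupancy)
  motif_cols <- intersect(motif_cols, match_cols)

  rows <- lapply(motif_cols, function(col) {
    observed <- sort(unique(mat[, col]))
    observed <- observed[observed %in% aa_alphabet()]   # drop gaps and X
    if (!length(observed)) return(NULL)
    data.frame(column = match(col, match_cols),
               aln_column = col,
               viable = paste(observed, collapse = ""),
               weight = 1 / length(observed),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    stop("no qualifying motif columns at occupancy >= ", min_occupancy,
         call. = FALSE)
  }
  structure(list(columns = rows, total_weight = sum(rows$weight)),
            class = "kin_motif")
}

#' @export
print.kin_motif <- function(x, ...) {
  cat("Functional-residue motif model: ", nrow(x$columns), " columns, ",
      "total weight ", format(x$total_weight, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Score a protein against a motif model
#'
#' Each motif column aligned through `column_map` contributes its weight
#' when the aligned query residue is in the column's viable set, and zero
#' otherwise; motif columns absent from the alignment contribute zero.
#' The sum is normalised by the model's total weight, so the score is in
#' \[0, 1\] and the twilight cutoff is scale-free.
#'
#' @param model A `kin_motif`.
#' @param protein A single amino-acid sequence.
#' @param column_map Integer vector from a [score_sequence()] hit built
#'   from the same alignment as the motif model.
#' @return List with `value` (normalised score in \[0, 1\]) and
#'   `matched_columns` (number of motif columns with a viable residue).
#' @export
motif_score <- function(model, protein, column_map) {
  stopifnot(inherits(model, "kin_motif"))
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  cols <- model$columns
  total <- 0
  matched <- 0L
  for (i in seq_len(nrow(cols))) {
    pos <- column_map[cols$column[i]]
    if (is.na(pos) || pos < 1L || pos > length(chars)) next
    if (grepl(chars[pos], cols$viable[i], fixed = TRUE)) {
      total <- total + cols$weight[i]
      matched <- matched + 1L
    }
  }
  list(value = total / model$total_weight, matched_columns = matched)
}

#' Serialise a motif model to TSV
#'
#' Columns: `column_index`, `aln_column`, `viable_residues`, `weight`.
#'
#' @param model A `kin_motif`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif <- function(model, path) {
  out <- data.frame(column_index = model$columns$column,
                    aln_column = model$columns$aln_column,
                    viable_residues = model$columns$viable,
                    weight = model$columns$weight)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif model from its TSV serialisation
#'
#' @param path Path written by [write_motif()].
#' @return A `kin_motif`.
#' @export
read_motif <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "integer", "character",
                                   "numeric"))
  rows <- data.frame(column = tab$column_index, aln_column = tab$aln_column,
                     viable = tab$viable_residues, weight = tab$weight,
                     stringsAsFactors = FALSE)
  structure(list(columns = rows, total_weight = sum(rows$weight)),
            class = "kin_motif")
}
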