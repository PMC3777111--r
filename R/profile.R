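# Position-specific profile built from a kinase-domain alignment, scored
# against query proteins with affine-gap local alignment.  This is the
# native profile-search backend; externally produced HMMER results can be
# supplied instead via parse_hmmer().

#' Build a position-specific profile from a domain alignment
#'
#' Per-column log-odds scores (in bits) are
#' `log2(((count_a + pseudocount * bg_a) / (n_rows + pseudocount)) / bg_a)`
#' for each residue `a`.  Columns with more than 50% gaps are dropped
#' (match-column rule); the retained columns define the profile coordinate
#' system used by hits' column maps and by the motif model.
#'
#' @param aln A [kin_alignment][as_alignment].
#' @param pseudocount Positive pseudocount mass added per column.
#' @param gap_open,gap_extend Affine gap penalties in bits applied at every
#'   column (defaults 5 and 0.5, i.e. 10 and 1 in half-bit units).
#' @param background Background residue frequencies over [aa_alphabet()]
#'   (default uniform 1/20).
#' @return An object of class `kin_profile`: list with `scores` (matrix,
#'   columns x 20 residues, bits), `columns` (original alignment column of
#'   each profile column), `n_columns`, `gap_open`, `gap_extend`,
#'   `background` and `consensus` (highest-scoring residue per column).
#' @export
build_profile <- function(aln, pseudocount = 1,
                          gap_open = 5, gap_extend = 0.5,
                          background = NULL) {
  stopifnot(inherits(aln, "kin_alignment"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20L || any(background <= 0)) {
    stop("background must be 20 positive frequencies", call. = FALSE)
  }
  background <- background / sum(background)

  mat <- aln_matrix(aln)
  n_rows <- nrow(mat)
  keep <- which(aln_occupancy(mat) >= 0.5)  # > 50% gaps dropped
  if (!length(keep)) stop("no match columns (all columns > 50% gaps)",
                          call. = FALSE)

  alpha <- aa_alphabet()
  scores <- matrix(0, nrow = length(keep), ncol = 20L,
                   dimnames = list(NULL, alpha))
  for (k in seq_along(keep)) {
    col <- mat[, keep[k]]
    counts <- vapply(alpha, function(a) sum(col == a), 0L)
    p <- (counts + pseudocount * background) / (n_rows + pseudocount)
    scores[k, ] <- log2(p / background)
  }

  structure(list(scores = scores,
                 columns = keep,
                 n_columns = length(keep),
                 gap_open = gap_open,
                 gap_extend = gap_extend,
                 background = background,
                 consensus = paste(alpha[max.col(scores, ties.method = "first")],
                                   collapse = "")),
            class = "kin_profile")
}

#' @export
print.kin_profile <- function(x, ...) {
  cat("Position-specific profile: ", x$n_columns, " match columns",
      " (gap open ", x$gap_open, ", extend ", x$gap_extend, " bits)\n",
      sep = "")
  invisible(x)
}

#' Score one protein against a profile
#'
#' Affine-gap local (Smith-Waterman-style) alignment of the protein
#' against the profile's position-specific scores.  The bit score is the
#' optimal local score; the E-value is `db_size * 2^(-bit_score)`, clamped
#' to at most `10 * db_size`.  The E-value model is deliberately simple:
#' only ordering and threshold behaviour matter downstream, and users
#' wanting calibrated statistics can supply HMMER output instead.
#'
#' @param profile A `kin_profile`.
#' @param protein A single amino-acid sequence.
#' @param db_size Number of sequences in the search set (for the E-value).
#' @return An object of class `kin_profile_hit`: list with `bit_score`,
#'   `e_value` and `column_map` (integer vector of length
#'   `profile$n_columns`; entry `i` is the 1-based query position aligned
#'   to profile column `i`, `NA` where unaligned).
#' @export
score_sequence <- function(profile, protein, db_size = 1) {
  stopifnot(inherits(profile, "kin_profile"))
  check_protein(protein)
  res <- .profile_sw_cpp(profile$scores, encode_seq(protein),
                         profile$gap_open, profile$gap_extend)
  bit <- res$score
  e <- min(db_size * 2^(-bit), 10 * db_size)
  column_map <- rep(NA_integer_, profile$n_columns)
  if (length(res$columns)) column_map[res$columns] <- res$positions
  structure(list(bit_score = bit, e_value = e, column_map = column_map),
            class = "kin_profile_hit")
}

#' Score every protein in a set against a profile
#'
#' @param profile A `kin_profile`.
#' @param seqs Named character vector of protein sequences.
#' @param db_size Search-set size for E-values (default `length(seqs)`).
#' @return List with `table` (data.frame: `query_id`, `bit_score`,
#'   `e_value`) and `column_maps` (named list of integer vectors).
#' @export
score_proteome <- function(profile, seqs, db_size = length(seqs)) {
  hits <- lapply(seqs, function(s) score_sequence(profile, s, db_size))
  list(table = data.frame(query_id = names(seqs),
                          bit_score = vapply(hits, `[[`, 0, "bit_score"),
                          e_value = vapply(hits, `[[`, 0, "e_value"),
                          row.names = NULL, stringsAsFactors = FALSE),
       column_maps = lapply(hits, `[[`, "column_map"))
}

#' Parse HMMER search output into per-protein profile scores
#'
#' Accepts HMMER3 `--tblout` or `--domtblout` tabular files, or classic
#' HMMER2 `hmmsearch` text output (the "Scores for complete sequences"
#' table); the dialect is auto-detected.  One score is kept per protein
#' (the better of full-sequence and best-domain score for `--domtblout`).
#' Raw scores are mapped through the affine transform `a*s + b` so that
#' score cutoffs can be applied on the user's chosen scale.
#'
#' @param report Path to the HMMER output file.
#' @param score_scale Numeric `c(a, b)` applied as `a*score + b`
#'   (default identity).
#' @return data.frame with columns `query_id`, `bit_score`, `e_value`,
#'   one row per protein, best score kept.
#' @export
parse_hmmer <- function(report, score_scale = c(1, 0)) {
  stopifnot(is.numeric(score_scale), length(score_scale) == 2L)
  lines <- readLines(report)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  is_h2 <- any(grepl("Scores for complete sequences", lines, fixed = TRUE))

  if (is_h2) {
    start <- which(grepl("Scores for complete sequences", lines, fixed = TRUE))[1L]
    rows <- list()
    i <- start + 1L
    seen_rule <- FALSE
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^-+\\s", ln) || grepl("^-+$", trimws(ln))) { seen_rule <- TRUE; i <- i + 1L; next }
      if (seen_rule) {
        if (!nzchar(trimws(ln))) break
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(f) < 4L) stop("malformed HMMER2 line ", i, ": '", ln, "'",
                                 call. = FALSE)
        k <- length(f)
        score <- suppressWarnings(as.numeric(f[k - 2L]))
        evalue <- suppressWarnings(as.numeric(f[k - 1L]))
        if (is.na(score) || is.na(evalue)) {
          stop("malformed HMMER2 line ", i, ": '", ln, "'", call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = f[1L], bit_score = score, e_value = evalue,
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
    tab <- do.call(rbind, rows)
  } else {
    if (!length(body)) {
      return(data.frame(query_id = character(0), bit_score = numeric(0),
                        e_value = numeric(0), stringsAsFactors = FALSE))
    }
    fields <- strsplit(trimws(body), "\\s+")
    nf <- lengths(fields)
    is_dom <- min(nf) >= 22L           # domtblout has >= 22 columns
    rows <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (is_dom) {
        if (length(f) < 22L) stop("malformed domtblout line: '", body[i], "'",
                                  call. = FALSE)
        data.frame(query_id = f[1L],
                   bit_score = as.numeric(f[14L]),   # this-domain score
                   e_value = as.numeric(f[7L]),      # full-sequence E-value
                   stringsAsFactors = FALSE)
      } else {
        if (length(f) < 10L) stop("malformed tblout line: '", body[i], "'",
                                  call. = FALSE)
        data.frame(query_id = f[1L],
                   bit_score = as.numeric(f[6L]),    # full-sequence score
                   e_value = as.numeric(f[5L]),
                   stringsAsFactors = FALSE)
      }
    })
    tab <- do.call(rbind, rows)
    if (any(is.na(tab$bit_score)) || any(is.na(tab$e_value))) {
      bad <- which(is.na(tab$bit_score) | is.na(tab$e_value))[1L]
      stop("malformed HMMER tabular line: '", body[bad], "'", call. = FALSE)
    }
  }

  # best score per protein (best-domain rule)
  tab <- tab[order(tab$query_id, -tab$bit_score), , drop = FALSE]
  tab <- tab[!duplicated(tab$query_id), , drop = FALSE]
  tab$bit_score <- score_scale[1L] * tab$bit_score + score_scale[2L]
  rownames(tab) <- NULL
  tab
}
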