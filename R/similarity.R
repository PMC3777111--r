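# Ranked similarity search of candidate kinases against the reference
# database: the native affine-gap Smith-Waterman engine, plus a reader for
# standard BLAST tabular (-outfmt 6) output produced externally.

# Karlin-Altschul constants for the native E-value.  Approximate; the
# pipeline consumes thresholded E-values and hit order only, and cutoffs
# are parameters, so exact BLAST statistics are not required.
KA_LAMBDA <- 0.267
KA_K <- 0.041

# BLOSUM62 restricted to the 20-letter alphabet, cached per session
.kin_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix over the 20-letter alphabet
#'
#' Taken from Biostrings and restricted to [aa_alphabet()]; the default
#' matrix for the native similarity engine (gap open 11, extend 1 --
#' standard protein-search defaults).
#'
#' @return 20 x 20 numeric matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.kin_env$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .kin_env$blosum62 <- env$BLOSUM62[aa_alphabet(), aa_alphabet()]
  }
  .kin_env$blosum62
}

#' Local pairwise alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman with deterministic traceback (ties broken
#' diagonal > up > left).  Unknown residues (`X`) score zero against
#' everything; any other residue outside the matrix alphabet is an error.
#'
#' @param a,b Protein sequences (single strings).
#' @param matrix Substitution matrix with residue dimnames
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1).
#' @return List with `score` (0 when no positive-scoring local alignment
#'   exists) and the aligned span `a_start`, `a_end`, `b_start`, `b_end`
#'   (zeros when score is 0).
#' @export
sw_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                     gap_extend = 1) {
  check_protein(a, "sequence a")
  check_protein(b, "sequence b")
  alpha <- rownames(matrix)
  .pair_sw_cpp(encode_with(a, alpha), encode_with(b, alpha), matrix,
               gap_open, gap_extend)
}

# encode against an arbitrary matrix alphabet; X scores 0, anything else
# outside the alphabet is an error
encode_with <- function(s, alpha) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  codes <- match(chars, alpha, nomatch = 0L)
  bad <- codes == 0L & chars != "X"
  if (any(bad)) {
    stop("residue(s) outside matrix alphabet: ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  codes
}

#' Search one query against the reference database
#'
#' Aligns the query to every reference entry and returns one hit per entry
#' with positive score, ranked by E-value ascending; ties are broken by
#' bit score descending, then reference id lexicographically, so ranking
#' is stable and deterministic.  E-values follow the Karlin-Altschul form
#' `K * m * n * exp(-lambda * raw_score)` with `m` the query length and
#' `n` the total residue count of the database, so doubling the database
#' doubles every E-value without changing scores or ranks.
#'
#' @param query A protein sequence.
#' @param db A `kin_refdb`.
#' @param query_id Id recorded in the result rows.
#' @param matrix,gap_open,gap_extend Passed to [sw_align()].
#' @param encoded_db Optional list of integer-encoded reference sequences
#'   (an internal cache used when searching many queries).
#' @return data.frame with columns `query_id`, `reference_id`,
#'   `raw_score`, `bit_score`, `e_value`, `rank` (ranks 1..k).
#' @export
similarity_search <- function(query, db, query_id = "query",
                              matrix = blosum62(), gap_open = 11,
                              gap_extend = 1, encoded_db = NULL) {
  stopifnot(inherits(db, "kin_refdb"))
  if (!nrow(db$entries)) stop("reference database is empty", call. = FALSE)
  n_db <- sum(nchar(db$entries$sequence))
  m <- nchar(query)
  alpha <- rownames(matrix)
  if (is.null(encoded_db)) {
    encoded_db <- lapply(db$entries$sequence, encode_with, alpha = alpha)
  }
  raw <- .search_scores_cpp(encode_with(query, alpha), encoded_db, matrix,
                            gap_open, gap_extend)
  keep <- raw > 0
  if (!any(keep)) {
    return(data.frame(query_id = character(0), reference_id = character(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      e_value = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  raw <- raw[keep]
  ids <- db$entries$id[keep]
  bit <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  e <- KA_K * m * n_db * exp(-KA_LAMBDA * raw)
  ord <- order(e, -bit, ids)
  data.frame(query_id = query_id,
             reference_id = ids[ord],
             raw_score = raw[ord],
             bit_score = bit[ord],
             e_value = e[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

# search many queries; returns a named list of hit data.frames
search_all <- function(queries, db, matrix = blosum62(), gap_open = 11,
                       gap_extend = 1) {
  alpha <- rownames(matrix)
  encoded_db <- lapply(db$entries$sequence, encode_with, alpha = alpha)
  out <- vector("list", length(queries))
  names(out) <- names(queries)
  for (id in names(queries)) {
    out[[id]] <- similarity_search(queries[[id]], db, query_id = id,
                                   matrix = matrix, gap_open = gap_open,
                                   gap_extend = gap_extend,
                                   encoded_db = encoded_db)
  }
  out
}

#' Read BLAST tabular output (-outfmt 6) as ranked similarity hits
#'
#' HSPs are collapsed to the best per (query, reference) pair (smallest
#' E-value, then largest bit score) and re-ranked per query by E-value
#' then bit score.  Subjects absent from the reference database are
#' rejected and reported via the `"rejects"` attribute and a warning.
#'
#' @param path Path to a 12-column BLAST tabular file (query, subject,
#'   percent identity, alignment length, mismatches, gap opens, qstart,
#'   qend, sstart, send, evalue, bitscore).
#' @param db A `kin_refdb` used to validate subject ids.
#' @return Named list (by query id) of hit data.frames in the
#'   [similarity_search()] layout (`raw_score` is `NA` for parsed hits).
#' @export
parse_blast_tab <- function(path, db) {
  stopifnot(inherits(db, "kin_refdb"))
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, quote = "",
               comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse BLAST tabular file: ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 12L) {
    stop("BLAST tabular file must have 12 columns, found ", ncol(tab),
         call. = FALSE)
  }
  names(tab)[c(1L, 2L, 11L, 12L)] <- c("query_id", "reference_id",
                                       "e_value", "bit_score")
  if (!is.numeric(tab$e_value) || !is.numeric(tab$bit_score)) {
    stop("malformed BLAST tabular row: non-numeric evalue/bitscore",
         call. = FALSE)
  }
  known <- tab$reference_id %in% db$entries$id
  rejects <- unique(tab$reference_id[!known])
  tab <- tab[known, , drop = FALSE]

  out <- lapply(split(tab, tab$query_id), function(q) {
    q <- q[order(q$e_value, -q$bit_score), , drop = FALSE]
    q <- q[!duplicated(q$reference_id), , drop = FALSE]   # best HSP per subject
    data.frame(query_id = q$query_id,
               reference_id = q$reference_id,
               raw_score = NA_real_,
               bit_score = q$bit_score,
               e_value = q$e_value,
               rank = seq_len(nrow(q)),
               stringsAsFactors = FALSE)
  })
  if (length(rejects)) {
    warning(length(rejects), " subject id(s) absent from the reference ",
            "database were rejected; see attr(x, 'rejects')", call. = FALSE)
  }
  attr(out, "rejects") <- rejects
  out
}
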