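# Reference kinome database: curated kinase sequences labelled with the
# hierarchical group/family/subfamily vocabulary.  ePK entries hold the
# kinase-domain sequence only; aPK (atypical) entries hold the full
# protein.  Entries labelled "unclassified" are retained but never
# contribute to classification consensus.

#' Load a reference kinome database
#'
#' The FASTA header dialect is `>id|species|group/family/subfamily|class`
#' where the label field may have 1-3 levels or be `unclassified`, and the
#' class field is `ePK` or `aPK`.  A companion TSV (columns `id`,
#' `species`, `label`, `kinase_class`) overrides or supplies header
#' metadata.  Entries whose metadata cannot be parsed are rejected and
#' reported via a warning and the `"rejected"` attribute; duplicate or
#' metadata-less ids are errors.
#'
#' @param db_fasta Path to the reference FASTA.
#' @param meta_tsv Optional path to the companion metadata TSV.
#' @return An object of class `kin_refdb`: list with `entries` (data.frame
#'   with columns `id`, `species`, `group`, `family`, `subfamily`, `depth`,
#'   `kinase_class`, `sequence`) and `species` (sorted unique species).
#' @export
load_reference <- function(db_fasta, meta_tsv = NULL) {
  seqs <- read_fasta(db_fasta)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "|", fixed = TRUE), `[[`, "", 1L)
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate reference id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  meta <- NULL
  if (!is.null(meta_tsv)) {
    meta <- read.table(meta_tsv, sep = "\t", header = TRUE,
                       colClasses = "character", quote = "",
                       comment.char = "")
    need <- c("id", "species", "label", "kinase_class")
    if (!all(need %in% names(meta))) {
      stop("metadata TSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(meta$id)) {
      stop("duplicate id(s) in metadata TSV: ",
           paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
           call. = FALSE)
    }
  }

  n <- length(seqs)
  species <- label <- class <- character(n)
  rejected <- character(0)
  reasons <- character(0)
  keep <- rep(TRUE, n)

  for (i in seq_len(n)) {
    id <- ids[i]
    row <- if (!is.null(meta) && id %in% meta$id) meta[meta$id == id, ] else NULL
    if (!is.null(row)) {
      species[i] <- row$species
      label[i] <- row$label
      class[i] <- row$kinase_class
    } else {
      fields <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
      if (length(fields) != 4L) {
        stop("missing metadata for reference id '", id,
             "' (header has no |species|label|class fields and no TSV row)",
             call. = FALSE)
      }
      species[i] <- trimws(fields[2L])
      label[i] <- trimws(fields[3L])
      class[i] <- trimws(fields[4L])
    }
    ok <- tryCatch({
      parse_label(label[i])
      if (!class[i] %in% c("ePK", "aPK")) stop("bad class")
      if (species[i] == "") stop("empty species")
      encode_seq(seqs[[i]])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      keep[i] <- FALSE
      rejected <- c(rejected, id)
      reasons <- c(reasons, sprintf("id '%s': unparsable metadata (species='%s', label='%s', class='%s')",
                                    id, species[i], label[i], class[i]))
    }
  }

  lab <- split_labels(label[keep])
  entries <- data.frame(id = ids[keep],
                        species = species[keep],
                        group = lab$group, family = lab$family,
                        subfamily = lab$subfamily, depth = lab$depth,
                        kinase_class = class[keep],
                        sequence = unname(seqs[keep]),
                        stringsAsFactors = FALSE)
  db <- structure(list(entries = entries,
                       species = sort(unique(entries$species))),
                  class = "kin_refdb")
  if (length(rejected)) {
    attr(db, "rejected") <- data.frame(id = rejected, reason = reasons,
                                       stringsAsFactors = FALSE)
    warning(length(rejected), " entr",
            if (length(rejected) == 1L) "y" else "ies",
            " rejected for unparsable metadata; see attr(db, 'rejected')",
            call. = FALSE)
  }
  db
}

# construct a kin_refdb directly from an entries data.frame (internal; used
# by the fixture generator)
new_refdb <- function(entries) {
  if (anyDuplicated(entries$id)) stop("duplicate reference ids", call. = FALSE)
  structure(list(entries = entries, species = sort(unique(entries$species))),
            class = "kin_refdb")
}

#' @export
print.kin_refdb <- function(x, ...) {
  cat("Reference kinome database: ", nrow(x$entries), " entries (",
      sum(x$entries$kinase_class == "ePK"), " ePK, ",
      sum(x$entries$kinase_class == "aPK"), " aPK), ",
      length(x$species), " species\n", sep = "")
  invisible(x)
}

#' Write a reference database back to FASTA (and optional TSV)
#'
#' Uses the same header dialect that [load_reference()] reads, so a
#' load/write cycle round-trips ids, labels and sequences byte-exactly.
#'
#' @param db A `kin_refdb`.
#' @param fasta_path Output FASTA path.
#' @param tsv_path Optional output path for a companion metadata TSV.
#' @return `fasta_path`, invisibly.
#' @export
write_reference <- function(db, fasta_path, tsv_path = NULL) {
  e <- db$entries
  label <- join_labels(e$group, e$family, e$subfamily)
  label[label == ""] <- "unclassified"
  headers <- paste(e$id, e$species, label, e$kinase_class, sep = "|")
  write_fasta(setNames(e$sequence, headers), fasta_path)
  if (!is.null(tsv_path)) {
    write.table(data.frame(id = e$id, species = e$species, label = label,
                           kinase_class = e$kinase_class),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Core kinase labels shared by a set of reference species
#'
#' A core kinase is a classification label (at its full stated depth)
#' present in every species of `core_species`.  Absence of a core label
#' from a newly annotated kinome flags a possible gene-set gap.
#'
#' @param db A `kin_refdb`.
#' @param core_species Character vector of species tokens, all present in
#'   `db$species`.
#' @return Sorted character vector of slash-delimited core labels.
#' @export
core_kinases <- function(db, core_species) {
  unknown <- setdiff(core_species, db$species)
  if (length(unknown)) {
    stop("unknown species token(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!length(core_species)) return(character(0))
  e <- db$entries[db$entries$depth > 0L, , drop = FALSE]
  labels_by_species <- lapply(core_species, function(sp) {
    unique(join_labels(e$group[e$species == sp], e$family[e$species == sp],
                       e$subfamily[e$species == sp]))
  })
  sort(Reduce(intersect, labels_by_species))
}
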