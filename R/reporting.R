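# Draft-kinome outputs: the per-protein table, the compact summary with
# missing core kinases, the phylogenetic profile against the reference
# kinomes, gene product names and the parameter file.

#' Draft kinome table
#'
#' One row per input protein (kinome members, twilight, subthreshold and
#' non-candidates alike).  The `depth` column separates potentially novel
#' kinases (0-1) from conserved ones (2-3); classification fields stay
#' empty for unclassified kinases, which are marked in
#' `unclassified_flag`.
#'
#' @param kinome A `kin_kinome`.
#' @return data.frame with columns `id`, `category`, `group`, `family`,
#'   `subfamily`, `depth`, `unclassified_flag`, `tk_flag`, `hmm_score`,
#'   `motif_score`, `best_blast_evalue`, `product_name`.
#' @export
draft_table <- function(kinome) {
  stopifnot(inherits(kinome, "kin_kinome"))
  out <- kinome$calls
  names(out)[names(out) == "query_id"] <- "id"
  out
}

# TSV with a commented header line listing the column names
write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Summarise a draft kinome
#'
#' Counts kinome members in total, per group and unclassified; reports the
#' kinome as a percentage of the predicted protein set; and lists missing
#' core kinases -- core labels (present in every species of
#' `core_species` in the reference database) absent from the new kinome
#' at their full stated depth.  A partial call does not satisfy a deeper
#' core label.
#'
#' @param kinome A `kin_kinome`.
#' @param db A `kin_refdb`.
#' @param core_species Species defining the core (default: all reference
#'   species).
#' @return An object of class `kin_summary`: list with `total`,
#'   `per_group` (named integer vector), `unclassified`,
#'   `percent_of_proteome` and `missing_core`.
#' @export
summarize_kinome <- function(kinome, db, core_species = db$species) {
  stopifnot(inherits(kinome, "kin_kinome"))
  members <- kinome$calls[kinome$calls$category %in% KINOME_CATEGORIES, ,
                          drop = FALSE]
  classified <- members[members$depth > 0L, , drop = FALSE]
  per_group <- if (nrow(classified)) {
    tab <- table(classified$group)
    setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  core <- core_kinases(db, core_species)
  present <- join_labels(members$group, members$family, members$subfamily)
  structure(list(total = nrow(members),
                 per_group = per_group,
                 unclassified = nrow(members) - nrow(classified),
                 percent_of_proteome =
                   if (kinome$proteome_size > 0L)
                     100 * nrow(members) / kinome$proteome_size
                   else NA_real_,
                 missing_core = setdiff(core, present)),
            class = "kin_summary")
}

#' @export
print.kin_summary <- function(x, ...) {
  cat("Total kinases:        ", x$total, "\n")
  cat("Unclassified:         ", x$unclassified, "\n")
  if (!is.na(x$percent_of_proteome)) {
    cat("Percent of proteome:  ", format(x$percent_of_proteome, digits = 3),
        "%\n", sep = "")
  }
  if (length(x$per_group)) {
    cat("Per group:\n")
    for (g in names(x$per_group)) cat("  ", g, ": ", x$per_group[[g]], "\n",
                                      sep = "")
  }
  cat("Missing core kinases: ", length(x$missing_core), "\n")
  if (length(x$missing_core)) {
    cat(paste0("  ", x$missing_core, collapse = "\n"), "\n")
  }
  invisible(x)
}

write_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(summary)
  sink()
  invisible(path)
}

#' Phylogenetic profile of the new kinome against reference kinomes
#'
#' Counts of classified kinases per label (truncated to `depth`) per
#' species; the new kinome occupies the first column.  Kinases classified
#' less deeply than `depth` are excluded, so each column sums to that
#' species' count of kinases classified at least to `depth`.
#'
#' @param kinome A `kin_kinome`.
#' @param db A `kin_refdb`.
#' @param depth Truncation depth, 1 (group), 2 (family) or 3 (subfamily).
#' @param new_name Column name for the new kinome (default `"new"`).
#' @return Integer matrix, labels x species.
#' @export
phylo_profile <- function(kinome, db, depth = 1L, new_name = "new") {
  stopifnot(inherits(kinome, "kin_kinome"), depth %in% 1:3)
  members <- kinome$calls[kinome$calls$category %in% KINOME_CATEGORIES &
                            kinome$calls$depth >= depth, , drop = FALSE]
  new_labels <- truncate_label(
    join_labels(members$group, members$family, members$subfamily), depth)

  e <- db$entries[db$entries$depth >= depth, , drop = FALSE]
  ref_labels <- truncate_label(join_labels(e$group, e$family, e$subfamily),
                               depth)

  all_labels <- sort(unique(c(new_labels, ref_labels)))
  species <- c(new_name, db$species)
  mat <- matrix(0L, nrow = length(all_labels), ncol = length(species),
                dimnames = list(all_labels, species))
  for (lab in new_labels) mat[lab, new_name] <- mat[lab, new_name] + 1L
  for (i in seq_along(ref_labels)) {
    sp <- e$species[i]
    mat[ref_labels[i], sp] <- mat[ref_labels[i], sp] + 1L
  }
  mat
}

#' Gene product names for a draft kinome
#'
#' Classified kinases are named from their label tokens followed by
#' "protein kinase"; unclassified kinases are "serine/threonine protein
#' kinase"; twilight hits are "protein kinase subdomain-containing
#' protein".
#'
#' @param kinome A `kin_kinome`.
#' @return data.frame with `id` and `product_name` for kinome members and
#'   twilight hits.
#' @export
product_names <- function(kinome) {
  keep <- kinome$calls$category %in% c(KINOME_CATEGORIES, "twilight")
  data.frame(id = kinome$calls$query_id[keep],
             product_name = kinome$calls$product_name[keep],
             stringsAsFactors = FALSE)
}

#' Write the full set of draft-kinome output files
#'
#' Writes `draft_kinome.tsv`, `summary.txt`, `phylo_profile.tsv`,
#' `product_names.tsv` and `params.used` into `dir`.  Re-running on the
#' same kinome reproduces the files byte-identically.
#'
#' @param kinome A `kin_kinome`.
#' @param db A `kin_refdb`.
#' @param dir Output directory (created if absent).
#' @param core_species Passed to [summarize_kinome()].
#' @param profile_depth Passed to [phylo_profile()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(kinome, db, dir, core_species = db$species,
                          profile_depth = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(draft = file.path(dir, "draft_kinome.tsv"),
             summary = file.path(dir, "summary.txt"),
             phylo = file.path(dir, "phylo_profile.tsv"),
             names = file.path(dir, "product_names.tsv"),
             params = file.path(dir, "params.used"))
  write_tsv_commented(draft_table(kinome), paths[["draft"]])
  write_summary(summarize_kinome(kinome, db, core_species),
                paths[["summary"]])
  prof <- phylo_profile(kinome, db, profile_depth)
  prof_df <- data.frame(label = rownames(prof), prof, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv_commented(prof_df, paths[["phylo"]])
  write_tsv_commented(product_names(kinome), paths[["names"]])
  write_params(kinome$params, paths[["params"]])
  invisible(paths)
}
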