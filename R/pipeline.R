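# The three-phase decision algorithm.  Phase 1 scores every protein
# against the domain profile and (for candidates) against the reference
# database.  Phase 2 rescues conserved unusual kinases and protein
# kinase-like atypical kinases by similarity, then partitions the
# remaining candidates into high-confidence ePKs, twilight hits and
# subthreshold rejects using the motif gate and two profile-score
# cutoffs.  Phase 3 classifies kinome members by consensus of consecutive
# top similarity hits, with partial classification and the TK policy.

KINOME_CATEGORIES <- c("ePK", "unusual_ePK", "aPK")

#' Compute all per-protein scores needed by the decision pipeline
#'
#' Builds the profile and motif model from the alignment, scores every
#' protein against both, and runs the similarity search for every protein
#' whose profile E-value passes `similarity_evalue`.  The result can be
#' fed to [call_kinome()] repeatedly with different parameters (e.g. for
#' ROC sweeps) without re-scoring.
#'
#' @param proteome Named character vector of protein sequences, or a path
#'   to a FASTA file.
#' @param db A `kin_refdb`.
#' @param aln A [kin_alignment][as_alignment] of reference kinase domains.
#' @param similarity_evalue Profile E-value gate above which the (costly)
#'   similarity search is skipped; must be at least as permissive as the
#'   candidate cutoff later used in [call_kinome()].  Default `Inf`
#'   (search everything).
#' @param hmmer Optional path to HMMER output ([parse_hmmer()]); when
#'   given, its scores and E-values replace the native profile scores for
#'   gating (column maps for motif scoring still come from the native
#'   alignment).  Proteins absent from the report keep score `-Inf`.
#' @param blast_tab Optional path to BLAST tabular output
#'   ([parse_blast_tab()]); when given it replaces the native similarity
#'   search.
#' @param hmmer_scale `score_scale` passed to [parse_hmmer()].
#' @return An object of class `kin_scores`.
#' @export
kinome_scores <- function(proteome, db, aln, similarity_evalue = Inf,
                          hmmer = NULL, blast_tab = NULL,
                          hmmer_scale = c(1, 0)) {
  if (is.character(proteome) && is.null(names(proteome)) &&
      length(proteome) == 1L && file.exists(proteome)) {
    proteome <- read_fasta(proteome)
    names(proteome) <- vapply(strsplit(names(proteome), "\\s+"), `[[`, "", 1L)
  }
  stopifnot(inherits(db, "kin_refdb"), inherits(aln, "kin_alignment"))
  if (anyDuplicated(names(proteome))) {
    stop("duplicate protein id(s) in proteome", call. = FALSE)
  }

  profile <- build_profile(aln)
  motif_model <- build_motif(aln)
  n <- length(proteome)

  if (n == 0L) {
    return(structure(list(profile = profile, motif_model = motif_model,
                          db = db, proteome_ids = character(0),
                          profile_table = data.frame(query_id = character(0),
                                                     bit_score = numeric(0),
                                                     e_value = numeric(0)),
                          motif_table = data.frame(query_id = character(0),
                                                   value = numeric(0)),
                          similarity = list(),
                          similarity_evalue = similarity_evalue),
                     class = "kin_scores"))
  }

  scored <- score_proteome(profile, proteome)
  prof_tab <- scored$table

  if (!is.null(hmmer)) {
    ext <- parse_hmmer(hmmer, score_scale = hmmer_scale)
    idx <- match(prof_tab$query_id, ext$query_id)
    prof_tab$bit_score <- ifelse(is.na(idx), -Inf, ext$bit_score[idx])
    prof_tab$e_value <- ifelse(is.na(idx), Inf, ext$e_value[idx])
  }

  motif_vals <- vapply(seq_len(n), function(i) {
    motif_score(motif_model, proteome[[i]],
                scored$column_maps[[i]])$value
  }, 0)
  motif_tab <- data.frame(query_id = names(proteome), value = motif_vals,
                          stringsAsFactors = FALSE)

  if (!is.null(blast_tab)) {
    similarity <- parse_blast_tab(blast_tab, db)
  } else {
    want <- prof_tab$query_id[prof_tab$e_value <= similarity_evalue]
    similarity <- search_all(proteome[want], db)
  }

  structure(list(profile = profile, motif_model = motif_model, db = db,
                 proteome_ids = names(proteome),
                 profile_table = prof_tab, motif_table = motif_tab,
                 similarity = similarity,
                 similarity_evalue = similarity_evalue),
            class = "kin_scores")
}

#' @export
print.kin_scores <- function(x, ...) {
  cat("Pipeline scores for ", length(x$proteome_ids), " proteins (",
      length(x$similarity), " similarity-searched)\n", sep = "")
  invisible(x)
}

#' Select candidate kinases with the relaxed profile E-value gate
#'
#' @param profile_hits data.frame with `query_id` and `e_value` columns
#'   (e.g. the `profile_table` of a `kin_scores`).
#' @param params A `kin_params`.
#' @return List with `candidates` and `non_candidates` (character vectors
#'   of ids); the boundary is inclusive (`e_value <= cutoff` passes).
#' @export
select_candidates <- function(profile_hits, params) {
  pass <- profile_hits$e_value <= params$hmm_evalue_candidate
  list(candidates = profile_hits$query_id[pass],
       non_candidates = profile_hits$query_id[!pass])
}

#' Rescue conserved unusual kinases and atypical kinases by similarity
#'
#' Candidates that would not survive the typical-kinase partition (profile
#' score below the identification cutoff, or motif score below the
#' twilight gate) but whose rank-1 similarity hit passes the atypical
#' E-value gate are rescued into the kinome regardless of their profile
#' and motif scores: category `aPK` when the rank-1 reference is an aPK,
#' `unusual_ePK` otherwise.  Rescued sequences bypass the twilight
#' partition.  Candidates that already qualify as typical ePKs are left to
#' the partition, so rescue only recovers poor scorers.
#'
#' @param candidates Character vector of candidate ids.
#' @param similarity_hits Named list (by query id) of ranked hit
#'   data.frames.
#' @param db A `kin_refdb`.
#' @param params A `kin_params`.
#' @param hmm_scores,motif_values Named numeric vectors of per-protein
#'   profile bit scores and motif scores.
#' @return data.frame with columns `query_id` and `category` for the
#'   rescued sequences.
#' @export
rescue_unusual <- function(candidates, similarity_hits, db, params,
                           hmm_scores, motif_values) {
  rows <- list()
  for (id in candidates) {
    typical <- hmm_scores[[id]] >= params$hmm_score_identification &&
      motif_values[[id]] >= params$motif_score_twilight
    if (typical) next
    hits <- similarity_hits[[id]]
    if (is.null(hits) || !nrow(hits)) next
    if (hits$e_value[1L] > params$blast_evalue_atypical) next
    ref_class <- db$entries$kinase_class[match(hits$reference_id[1L],
                                               db$entries$id)]
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = id,
      category = if (identical(ref_class, "aPK")) "aPK" else "unusual_ePK",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Partition remaining candidates into ePKs, twilight hits and rejects
#'
#' The motif gate applies first: candidates below the motif cutoff are
#' subthreshold regardless of profile score.  Candidates passing the motif
#' gate are ePKs when their profile score reaches the identification
#' cutoff, twilight hits when it reaches only the twilight floor, and
#' subthreshold otherwise.  All boundaries are inclusive.
#'
#' @param remaining Character vector of candidate ids not rescued.
#' @param hmm_scores,motif_values Named numeric vectors.
#' @param params A `kin_params`.
#' @return List with `ePK`, `twilight` and `subthreshold` id vectors.
#' @export
partition_typical <- function(remaining, hmm_scores, motif_values, params) {
  h <- unlist(hmm_scores[remaining])
  m <- unlist(motif_values[remaining])
  if (!length(remaining)) h <- m <- numeric(0)
  sub <- m < params$motif_score_twilight |
    h < params$hmm_score_twilight
  epk <- !sub & h >= params$hmm_score_identification
  twi <- !sub & !epk
  list(ePK = remaining[epk], twilight = remaining[twi],
       subthreshold = remaining[sub])
}

#' Consensus classification from consecutive top similarity hits
#'
#' Considers the first `n_consistent_hits` hits whose references carry a
#' classification (unclassified reference entries never contribute).  If
#' fewer exist the sequence is unclassified.  The label is the deepest
#' level at which all considered hits assert and agree: group-level
#' disagreement leaves the sequence unclassified (`consistent = FALSE`);
#' agreement at group but not family yields a depth-1 label, at family but
#' not subfamily a depth-2 label.  A unanimous subfamily additionally
#' requires the top considered hit's `log10(e_value)` to pass the
#' subfamily gate, otherwise the call is truncated to depth 2.
#'
#' @param ranked_hits Ranked hit data.frame for one query.
#' @param db A `kin_refdb`.
#' @param params A `kin_params`.
#' @return List with `label` (a `kin_label`) and `consistent` (logical;
#'   `FALSE` only for group-level disagreement or too few labelled hits).
#' @export
consensus_label <- function(ranked_hits, db, params) {
  n <- params$n_consistent_hits
  if (is.null(ranked_hits) || !nrow(ranked_hits)) {
    return(list(label = new_label(character(0)), consistent = FALSE))
  }
  idx <- match(ranked_hits$reference_id, db$entries$id)
  lab <- db$entries[idx, c("group", "family", "subfamily", "depth")]
  keep <- lab$depth > 0L
  hits <- ranked_hits[keep, , drop = FALSE]
  lab <- lab[keep, , drop = FALSE]
  if (nrow(hits) < n) {
    return(list(label = new_label(character(0)), consistent = FALSE))
  }
  hits <- hits[seq_len(n), , drop = FALSE]
  lab <- lab[seq_len(n), , drop = FALSE]

  if (length(unique(lab$group)) != 1L) {
    return(list(label = new_label(character(0)), consistent = FALSE))
  }
  tokens <- lab$group[1L]

  if (all(lab$family != "") && length(unique(lab$family)) == 1L) {
    tokens <- c(tokens, lab$family[1L])
    if (all(lab$subfamily != "") && length(unique(lab$subfamily)) == 1L) {
      if (log10(hits$e_value[1L]) <= params$log10_evalue_subfamily) {
        tokens <- c(tokens, lab$subfamily[1L])
      }
    }
  }
  list(label = new_label(tokens), consistent = TRUE)
}

#' Conservative tyrosine-kinase policy for non-metazoan input
#'
#' Outside metazoan mode, a consensus label in the TK group is rewritten
#' to the tyrosine kinase-like group `TKL` at depth 1 and flagged, because
#' TK-group calls in early-branching species require manual verification.
#' In metazoan mode labels pass through unchanged.
#'
#' @param label A `kin_label`.
#' @param params A `kin_params`.
#' @return List with `label` and `tk_flag`.
#' @export
tk_policy <- function(label, params) {
  if (!params$metazoan_mode && identical(label$group, "TK")) {
    return(list(label = new_label("TKL"), tk_flag = TRUE))
  }
  list(label = label, tk_flag = FALSE)
}

# classify one identified ePK / unusual_ePK: not-classified gate, then
# consensus, then TK policy; returns label fields, flags and product name
classify_candidate <- function(ranked_hits, hmm_score, db, params) {
  best_e <- if (!is.null(ranked_hits) && nrow(ranked_hits)) {
    ranked_hits$e_value[1L]
  } else Inf
  weak_blast <- best_e > params$blast_evalue_classification
  weak_hmm <- hmm_score < params$hmm_score_classification
  blocked <- if (identical(params$strict_classification_gate, "or")) {
    weak_blast || weak_hmm
  } else {
    weak_blast && weak_hmm
  }

  if (!blocked) {
    cons <- consensus_label(ranked_hits, db, params)
    if (cons$label$depth > 0L) {
      pol <- tk_policy(cons$label, params)
      lab <- pol$label
      return(list(label = lab, unclassified_flag = FALSE,
                  tk_flag = pol$tk_flag,
                  best_blast_evalue = best_e,
                  product_name = product_name_for(lab, "ePK")))
    }
  }
  list(label = new_label(character(0)), unclassified_flag = TRUE,
       tk_flag = FALSE, best_blast_evalue = best_e,
       product_name = "serine/threonine protein kinase")
}

product_name_for <- function(label, category) {
  if (label$depth > 0L) {
    tokens <- c(label$group, label$family, label$subfamily)
    paste(paste(tokens[tokens != ""], collapse = " "), "protein kinase")
  } else if (category == "aPK") {
    "atypical protein kinase"
  } else {
    "serine/threonine protein kinase"
  }
}

#' Run the decision pipeline on precomputed scores
#'
#' @param scores A `kin_scores` from [kinome_scores()].
#' @param params A `kin_params`.
#' @return An object of class `kin_kinome`: list with `calls` (one row per
#'   input protein: `query_id`, `category`, `group`, `family`,
#'   `subfamily`, `depth`, `unclassified_flag`, `tk_flag`, `hmm_score`,
#'   `motif_score`, `best_blast_evalue`, `product_name`), `params` and
#'   `proteome_size`.  Kinome members are the calls with category `ePK`,
#'   `unusual_ePK` or `aPK`; twilight, subthreshold and non-candidate
#'   calls are recorded but are not part of the draft kinome.
#' @export
call_kinome <- function(scores, params = default_params()) {
  stopifnot(inherits(scores, "kin_scores"))
  params <- validate_params(params)
  if (is.finite(scores$similarity_evalue) &&
      params$hmm_evalue_candidate > scores$similarity_evalue) {
    stop("scores were computed with similarity_evalue = ",
         scores$similarity_evalue, ", more stringent than the requested ",
         "candidate cutoff ", params$hmm_evalue_candidate,
         "; recompute kinome_scores()", call. = FALSE)
  }
  ids <- scores$proteome_ids
  prof <- scores$profile_table
  hmm_scores <- setNames(as.list(prof$bit_score), prof$query_id)
  evals <- setNames(prof$e_value, prof$query_id)
  motif_values <- setNames(as.list(scores$motif_table$value),
                           scores$motif_table$query_id)

  sel <- select_candidates(prof, params)
  rescued <- rescue_unusual(sel$candidates, scores$similarity,
                            scores$db, params, hmm_scores, motif_values)
  remaining <- setdiff(sel$candidates, rescued$query_id)
  part <- partition_typical(remaining, hmm_scores, motif_values, params)

  category <- setNames(rep("non_candidate", length(ids)), ids)
  category[rescued$query_id] <- rescued$category
  category[part$ePK] <- "ePK"
  category[part$twilight] <- "twilight"
  category[part$subthreshold] <- "subthreshold"

  n <- length(ids)
  calls <- data.frame(query_id = ids,
                      category = unname(category[ids]),
                      group = character(n), family = character(n),
                      subfamily = character(n),
                      depth = integer(n),
                      unclassified_flag = logical(n), tk_flag = logical(n),
                      hmm_score = as.numeric(unlist(hmm_scores[ids])),
                      motif_score = as.numeric(unlist(motif_values[ids])),
                      best_blast_evalue = rep(NA_real_, n),
                      product_name = character(n),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(calls = calls, params = params, proteome_size = 0L),
                     class = "kin_kinome"))
  }

  for (i in seq_len(n)) {
    id <- ids[i]
    cat_i <- calls$category[i]
    hits <- scores$similarity[[id]]
    if (cat_i %in% c("ePK", "unusual_ePK")) {
      cl <- classify_candidate(hits, hmm_scores[[id]], scores$db, params)
      calls$group[i] <- cl$label$group
      calls$family[i] <- cl$label$family
      calls$subfamily[i] <- cl$label$subfamily
      calls$depth[i] <- cl$label$depth
      calls$unclassified_flag[i] <- cl$unclassified_flag
      calls$tk_flag[i] <- cl$tk_flag
      calls$best_blast_evalue[i] <- cl$best_blast_evalue
      calls$product_name[i] <- cl$product_name
    } else if (cat_i == "aPK") {
      # label inherited from the rank-1 (aPK) reference; the consensus
      # rules are designed for ePKs
      lab <- new_label(character(0))
      best_e <- NA_real_
      if (!is.null(hits) && nrow(hits)) {
        best_e <- hits$e_value[1L]
        ref <- scores$db$entries[match(hits$reference_id[1L],
                                       scores$db$entries$id), ]
        tokens <- c(ref$group, ref$family, ref$subfamily)
        lab <- new_label(tokens[tokens != ""])
      }
      calls$group[i] <- lab$group
      calls$family[i] <- lab$family
      calls$subfamily[i] <- lab$subfamily
      calls$depth[i] <- lab$depth
      calls$best_blast_evalue[i] <- best_e
      calls$product_name[i] <- product_name_for(lab, "aPK")
    } else if (cat_i == "twilight") {
      calls$product_name[i] <- "protein kinase subdomain-containing protein"
      if (!is.null(hits) && nrow(hits)) {
        calls$best_blast_evalue[i] <- hits$e_value[1L]
      }
    } else if (cat_i == "subthreshold") {
      calls$product_name[i] <- "subthreshold"
      if (!is.null(hits) && nrow(hits)) {
        calls$best_blast_evalue[i] <- hits$e_value[1L]
      }
    }
  }

  structure(list(calls = calls, params = params, proteome_size = n),
            class = "kin_kinome")
}

#' @export
print.kin_kinome <- function(x, ...) {
  members <- x$calls$category %in% KINOME_CATEGORIES
  cat("Draft kinome: ", sum(members), " kinases in a proteome of ",
      x$proteome_size, " proteins\n", sep = "")
  print(table(x$calls$category))
  invisible(x)
}

#' Annotate a predicted proteome end to end
#'
#' Runs all three phases: profile and motif scoring, similarity search of
#' candidates, rescue, partition and classification.  Deterministic given
#' its inputs and parameters.
#'
#' @param proteome Named character vector of sequences or FASTA path.
#' @param db A `kin_refdb`.
#' @param aln A [kin_alignment][as_alignment].
#' @param params A `kin_params`.
#' @param hmmer,blast_tab Optional external search results; see
#'   [kinome_scores()].
#' @return A `kin_kinome`.
#' @export
annotate_proteome <- function(proteome, db, aln, params = default_params(),
                              hmmer = NULL, blast_tab = NULL) {
  params <- validate_params(params)
  scores <- kinome_scores(proteome, db, aln,
                          similarity_evalue = params$hmm_evalue_candidate,
                          hmmer = hmmer, blast_tab = blast_tab)
  call_kinome(scores, params)
}
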