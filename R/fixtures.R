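# Deterministic synthetic-data generator.  Emulates the hierarchical
# structure of a curated kinome database -- groups divided into families
# divided into subfamilies -- by nested mutation from a random ancestral
# domain, with a set of conserved "motif" columns standing in abstractly
# for the catalytic substructures (each motif column admits a small set of
# viable residues that is preserved through every mutation).  Test
# proteomes plant typical kinases, conserved unusual kinases, atypical
# kinases, species-specific kinases, twilight sequences and non-kinases,
# together with a matching truth table.  Everything is a pure function of
# the fixture spec (including its seed).

#' Specification for the synthetic fixture generator
#'
#' Divergences are substitution fractions and must be strictly increasing
#' subfamily < family < group.  Mutations are substitutions only (the
#' generated domains are gapless), so the alignment used to build profile
#' and motif models is exactly the set of reference domains.  The default
#' proteome plants 50 kinases (36 typical, 5 unusual, 4 species-specific,
#' 5 atypical) plus 6 twilight sequences among 194 random non-kinases.
#'
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @param n_groups,families_per_group,subfamilies_per_family Hierarchy
#'   shape of the reference database.
#' @param members_per_subfamily Reference members per subfamily, one per
#'   synthetic species (also the number of species).
#' @param domain_length Kinase-domain length in residues.
#' @param n_motif_columns Number of conserved functional-residue columns.
#' @param within_subfamily_divergence,within_family_divergence,within_group_divergence
#'   Substitution fractions applied at each level of the nested mutation.
#' @param query_divergence Substitution fraction applied when deriving a
#'   planted proteome sequence from its reference template.
#' @param n_typical,n_unusual,n_species_specific,n_apk,n_twilight,n_family_level,n_non_kinase
#'   Planted counts per category (`n_family_level` plants sequences at a
#'   family consensus, between its subfamilies, for classification
#'   ambiguity studies; default 0).
#' @param n_unusual_families,n_apk_families Distinct divergent reference
#'   families backing the unusual-kinase and atypical-kinase plants.
#' @param unusual_divergence,apk_divergence Substitution fraction between
#'   the ancestral domain and the unusual / atypical reference base
#'   sequences (high, so they score poorly against the profile).
#' @param twilight_divergence Substitution fraction for the planted
#'   twilight sequences: degraded copies of the ancestral domain that
#'   keep the motif columns viable but fall below typical-kinase profile
#'   scores (emulating protein kinase-like sequences).
#' @param non_kinase_length_mean,non_kinase_length_sd Length distribution
#'   of the random non-kinase proteins.
#' @return An object of class `kin_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_groups = 4L, families_per_group = 2L,
                         subfamilies_per_family = 2L,
                         members_per_subfamily = 3L,
                         domain_length = 160L, n_motif_columns = 20L,
                         within_subfamily_divergence = 0.04,
                         within_family_divergence = 0.12,
                         within_group_divergence = 0.28,
                         query_divergence = 0.05,
                         n_typical = 36L, n_unusual = 5L,
                         n_species_specific = 4L, n_apk = 5L,
                         n_twilight = 6L, n_family_level = 0L,
                         n_non_kinase = 194L,
                         n_unusual_families = 4L, n_apk_families = 4L,
                         unusual_divergence = 0.45, apk_divergence = 0.5,
                         twilight_divergence = 0.52,
                         non_kinase_length_mean = 320,
                         non_kinase_length_sd = 60) {
  spec <- as.list(environment())
  if (spec$n_groups < 1L) stop("degenerate spec: n_groups must be >= 1",
                               call. = FALSE)
  if (!(within_subfamily_divergence < within_family_divergence &&
        within_family_divergence < within_group_divergence)) {
    stop("divergences must be strictly increasing subfamily < family < group",
         call. = FALSE)
  }
  counts <- c(n_typical, n_unusual, n_species_specific, n_apk, n_twilight,
              n_family_level, n_non_kinase)
  if (any(counts < 0L)) stop("planted counts must be >= 0", call. = FALSE)
  if (n_motif_columns >= domain_length) {
    stop("n_motif_columns must be < domain_length", call. = FALSE)
  }
  structure(spec, class = "kin_fixture_spec")
}

rand_chars <- function(n) sample(aa_alphabet(), n, replace = TRUE)

# substitution-only mutation; motif columns stay within their viable set
mutate_chars <- function(chars, rate, motif_pos, motif_viable) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    k <- match(i, motif_pos)
    if (!is.na(k)) {
      alts <- setdiff(motif_viable[[k]], chars[i])
      if (length(alts)) chars[i] <- sample(alts, 1L)
    } else {
      chars[i] <- sample(setdiff(aa_alphabet(), chars[i]), 1L)
    }
  }
  chars
}

#' Generate the synthetic reference database and domain alignment
#'
#' Derives group, family and subfamily consensus domains by nested
#' mutation from a random ancestor, emits labelled members across the
#' synthetic species, and adds divergent unusual-kinase families,
#' full-length atypical-kinase families and a couple of unclassified
#' entries.  The alignment holds the typical ePK member domains (gapless
#' by construction).
#'
#' @param spec A [fixture_spec()].
#' @return List with `db` (a `kin_refdb`), `alignment` (a
#'   `kin_alignment`) and `internals` (motif positions and viable sets,
#'   consensus sequences and per-category template ids, used by
#'   [make_proteome()]).
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "kin_fixture_spec"))
  set.seed(spec$seed)

  L <- spec$domain_length
  ancestor <- rand_chars(L)
  motif_pos <- sort(sample.int(L, spec$n_motif_columns))
  motif_viable <- lapply(seq_len(spec$n_motif_columns), function(i) {
    sample(aa_alphabet(), 2L)
  })
  for (k in seq_along(motif_pos)) ancestor[motif_pos[k]] <- motif_viable[[k]][1L]

  mut <- function(chars, rate) mutate_chars(chars, rate, motif_pos,
                                            motif_viable)
  species <- paste0("sp", LETTERS[seq_len(spec$members_per_subfamily)])

  entries <- list()
  aln_rows <- character(0)
  group_cons <- list()
  family_cons <- list()
  subfam_cons <- list()
  add_entry <- function(id, sp, group, family, subfamily, class, seq) {
    lab <- c(group, family, subfamily)
    entries[[length(entries) + 1L]] <<- data.frame(
      id = id, species = sp, group = group, family = family,
      subfamily = subfamily, depth = sum(lab != ""), kinase_class = class,
      sequence = seq, stringsAsFactors = FALSE)
  }

  for (g in seq_len(spec$n_groups)) {
    gname <- paste0("G", g)
    gcons <- mut(ancestor, spec$within_group_divergence)
    group_cons[[gname]] <- gcons
    for (f in seq_len(spec$families_per_group)) {
      fname <- paste0(gname, "F", f)
      fcons <- mut(gcons, spec$within_family_divergence)
      family_cons[[fname]] <- fcons
      for (s in seq_len(spec$subfamilies_per_family)) {
        sname <- paste0(fname, "S", s)
        scons <- mut(fcons, spec$within_subfamily_divergence)
        subfam_cons[[sname]] <- scons
        for (m in seq_len(spec$members_per_subfamily)) {
          member <- mut(scons, spec$within_subfamily_divergence)
          id <- paste0(sname, "_", species[m])
          seq <- paste(member, collapse = "")
          add_entry(id, species[m], gname, fname, sname, "ePK", seq)
          aln_rows[id] <- seq
        }
      }
    }
  }

  unusual_base <- list()
  for (u in seq_len(spec$n_unusual_families)) {
    uname <- paste0("UNK", u)
    base <- mut(ancestor, spec$unusual_divergence)
    unusual_base[[uname]] <- base
    for (m in seq_len(spec$members_per_subfamily)) {
      member <- mut(base, spec$within_subfamily_divergence)
      add_entry(paste0(uname, "_", species[m]), species[m],
                "Other", uname, "", "ePK", paste(member, collapse = ""))
    }
  }

  apk_base <- list()
  for (a in seq_len(spec$n_apk_families)) {
    aname <- paste0("APK", a)
    core <- mut(ancestor, spec$apk_divergence)
    full <- c(rand_chars(60L), core, rand_chars(60L))
    apk_base[[aname]] <- full
    for (m in seq_len(spec$members_per_subfamily)) {
      member <- mutate_chars(full, spec$within_subfamily_divergence,
                             motif_pos + 60L, motif_viable)
      add_entry(paste0(aname, "_", species[m]), species[m],
                "Atypical", aname, "", "aPK", paste(member, collapse = ""))
    }
  }

  # unclassified entries: retained in the database but never contributing
  # to classification consensus
  for (m in seq_len(min(2L, spec$members_per_subfamily))) {
    member <- mut(ancestor, 0.4)
    add_entry(paste0("UNCL", m, "_", species[m]), species[m],
              "", "", "", "ePK", paste(member, collapse = ""))
  }

  db <- new_refdb(do.call(rbind, entries))
  list(db = db,
       alignment = as_alignment(aln_rows),
       internals = list(spec = spec, ancestor = ancestor,
                        motif_pos = motif_pos, motif_viable = motif_viable,
                        species = species, group_cons = group_cons,
                        family_cons = family_cons, subfam_cons = subfam_cons,
                        unusual_base = unusual_base, apk_base = apk_base))
}

#' Generate a test proteome with planted truth
#'
#' Plants (i) typical kinases: lightly mutated copies of reference
#' subfamily members; (ii) unusual kinases: lightly mutated copies of the
#' divergent unusual-family references (low profile score, conserved
#' motif, strong similarity to their reference); (iii) species-specific
#' kinases: novel-family derivatives of a group consensus (truth label at
#' group depth); (iv) atypical kinases: copies of full-length aPK
#' references; (v) twilight sequences: heavily degraded copies of the
#' ancestral domain retaining viable motif residues (kinase-like motifs,
#' sub-identification profile score); (vi) family-consensus sequences
#' (when requested):
#' equidistant from their family's subfamilies, truth label at family
#' depth; and (vii) non-kinases: random proteins.  Kinase-bearing plants
#' are embedded in random flanking sequence so the domain sits inside a
#' longer protein.
#'
#' @param spec The [fixture_spec()] used for [make_reference()].
#' @param ref The list returned by [make_reference()].
#' @return List with `proteome` (named character vector, shuffled order)
#'   and `truth` (data.frame: `protein_id`, `is_kinase`, `label`,
#'   `species_specific`, `category`; same order as the proteome).
#' @export
make_proteome <- function(spec, ref) {
  stopifnot(inherits(spec, "kin_fixture_spec"))
  set.seed(spec$seed + 1L)
  internals <- ref$internals
  motif_pos <- internals$motif_pos
  motif_viable <- internals$motif_viable
  mut <- function(chars, rate) mutate_chars(chars, rate, motif_pos,
                                            motif_viable)
  db <- ref$db

  seqs <- character(0)
  truth <- list()
  add <- function(seq, is_kinase, label, species_specific, category) {
    seqs[[length(seqs) + 1L]] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      is_kinase = is_kinase, label = label,
      species_specific = species_specific, category = category,
      stringsAsFactors = FALSE)
  }
  with_flanks <- function(chars) {
    paste(c(rand_chars(sample(30:80, 1L)), chars,
            rand_chars(sample(30:80, 1L))), collapse = "")
  }

  epk <- db$entries[db$entries$kinase_class == "ePK" &
                      db$entries$depth == 3L, , drop = FALSE]
  if (spec$n_typical > 0L) {
    if (!nrow(epk)) stop("no typical templates available", call. = FALSE)
    tmpl <- epk[1L + (seq_len(spec$n_typical) - 1L) %% nrow(epk), ]
    for (i in seq_len(spec$n_typical)) {
      chars <- strsplit(tmpl$sequence[i], "")[[1]]
      add(with_flanks(mut(chars, spec$query_divergence)), TRUE,
          join_labels(tmpl$group[i], tmpl$family[i], tmpl$subfamily[i]),
          FALSE, "typical")
    }
  }

  unusual <- db$entries[db$entries$group == "Other", , drop = FALSE]
  if (spec$n_unusual > 0L) {
    if (!nrow(unusual)) stop("no unusual templates available", call. = FALSE)
    tmpl <- unusual[1L + (seq_len(spec$n_unusual) - 1L) %% nrow(unusual), ]
    for (i in seq_len(spec$n_unusual)) {
      chars <- strsplit(tmpl$sequence[i], "")[[1]]
      add(with_flanks(mut(chars, spec$query_divergence)), TRUE,
          join_labels(tmpl$group[i], tmpl$family[i], tmpl$subfamily[i]),
          FALSE, "unusual")
    }
  }

  if (spec$n_species_specific > 0L) {
    gnames <- names(internals$group_cons)
    for (i in seq_len(spec$n_species_specific)) {
      g <- gnames[1L + (i - 1L) %% length(gnames)]
      novel <- mut(internals$group_cons[[g]],
                   spec$within_family_divergence * 1.5)
      add(with_flanks(mut(novel, spec$query_divergence)), TRUE, g, TRUE,
          "species_specific")
    }
  }

  apk <- db$entries[db$entries$kinase_class == "aPK", , drop = FALSE]
  if (spec$n_apk > 0L) {
    if (!nrow(apk)) stop("no atypical templates available", call. = FALSE)
    tmpl <- apk[1L + (seq_len(spec$n_apk) - 1L) %% nrow(apk), ]
    for (i in seq_len(spec$n_apk)) {
      chars <- strsplit(tmpl$sequence[i], "")[[1]]
      seq <- paste(mutate_chars(chars, spec$query_divergence,
                                motif_pos + 60L, motif_viable),
                   collapse = "")
      add(seq, TRUE, join_labels(tmpl$group[i], tmpl$family[i],
                                 tmpl$subfamily[i]),
          FALSE, "apk")
    }
  }

  if (spec$n_twilight > 0L) {
    for (i in seq_len(spec$n_twilight)) {
      chars <- mut(internals$ancestor, spec$twilight_divergence)
      add(with_flanks(chars), FALSE, "", FALSE, "twilight")
    }
  }

  if (spec$n_family_level > 0L) {
    fnames <- names(internals$family_cons)
    for (i in seq_len(spec$n_family_level)) {
      f <- fnames[1L + (i - 1L) %% length(fnames)]
      g <- sub("F[0-9]+$", "", f)
      chars <- mut(internals$family_cons[[f]],
                   spec$within_subfamily_divergence)
      add(with_flanks(chars), TRUE, paste(g, f, sep = "/"), FALSE,
          "family_level")
    }
  }

  if (spec$n_non_kinase > 0L) {
    for (i in seq_len(spec$n_non_kinase)) {
      len <- max(50L, round(stats::rnorm(1L, spec$non_kinase_length_mean,
                                         spec$non_kinase_length_sd)))
      add(paste(rand_chars(len), collapse = ""), FALSE, "", FALSE,
          "non_kinase")
    }
  }

  truth <- do.call(rbind, truth)
  ord <- sample.int(length(seqs))
  seqs <- unlist(seqs)[ord]
  truth <- truth[ord, , drop = FALSE]
  ids <- sprintf("prot%04d", seq_along(seqs))
  names(seqs) <- ids
  truth <- cbind(data.frame(protein_id = ids, stringsAsFactors = FALSE),
                 truth)
  rownames(truth) <- NULL
  list(proteome = seqs, truth = truth)
}

#' Calibrate pipeline cutoffs from the fixture's own score distributions
#'
#' The documented default cutoffs are stated on the HMMER2/BLAST score
#' scales; the native scoring engines use a different scale, so
#' fixture-based runs derive their cutoffs from the planted categories'
#' score distributions: each threshold is placed midway between the two
#' score populations it must separate (geometric midpoint for E-values).
#' The calibrated parameters are what the generator emits in its
#' parameter file.
#'
#' @param scores A `kin_scores` computed on the fixture proteome.
#' @param truth The fixture truth table (with its `category` column).
#' @param base Baseline parameters for the fields not calibrated.
#' @return A `kin_params`.
#' @export
calibrate_params <- function(scores, truth, base = default_params()) {
  stopifnot(inherits(scores, "kin_scores"))
  if (!"category" %in% names(truth)) {
    stop("truth table lacks the generator's 'category' column", call. = FALSE)
  }
  prof <- scores$profile_table
  idx <- match(truth$protein_id, prof$query_id)
  hmm <- prof$bit_score[idx]
  ev <- prof$e_value[idx]
  motif <- scores$motif_table$value[match(truth$protein_id,
                                          scores$motif_table$query_id)]
  rank1 <- vapply(truth$protein_id, function(id) {
    h <- scores$similarity[[id]]
    if (is.null(h) || !nrow(h)) NA_real_ else h$e_value[1L]
  }, 0)

  cat_of <- truth$category
  pick <- function(x, cats) x[cat_of %in% cats]
  mid <- function(lo, hi) (lo + hi) / 2
  gmid <- function(a, b) 10^((log10(a) + log10(b)) / 2)

  high_cats <- c("typical", "species_specific", "family_level")
  resc_cats <- c("unusual", "apk")

  p <- unclass(base)

  hi_scores <- pick(hmm, high_cats)
  low_scores <- pick(hmm, c(resc_cats, "twilight"))
  if (length(hi_scores) && length(low_scores)) {
    p$hmm_score_identification <- mid(min(hi_scores), max(low_scores))
  }

  twi_scores <- pick(hmm, "twilight")
  nk_scores <- pick(hmm, "non_kinase")
  if (length(twi_scores)) {
    floor_hi <- if (length(nk_scores)) max(nk_scores) else -Inf
    cand <- mid(min(twi_scores), floor_hi)
    p$hmm_score_twilight <- min(cand, min(twi_scores) - 1e-9)
  }

  kin_motif_vals <- pick(motif, c(high_cats, "twilight"))
  nk_motif_vals <- pick(motif, "non_kinase")
  if (length(kin_motif_vals) && length(nk_motif_vals)) {
    cand <- mid(min(kin_motif_vals), max(nk_motif_vals))
    cand <- min(cand, min(kin_motif_vals) - 0.01)
    p$motif_score_twilight <- max(0.05, min(0.95, cand))
  }

  kin_ev <- pick(ev, c(high_cats, resc_cats, "twilight"))
  nk_ev <- pick(ev, "non_kinase")
  if (length(kin_ev)) {
    cand <- max(kin_ev) * 2
    if (length(nk_ev)) cand <- min(max(cand, max(kin_ev) * 2),
                                   gmid(max(kin_ev), min(nk_ev)))
    p$hmm_evalue_candidate <- max(cand, max(kin_ev) * 1.01)
  }

  resc_e <- pick(rank1, resc_cats)
  other_e <- pick(rank1, c("twilight", "non_kinase"))
  other_e <- other_e[!is.na(other_e)]
  if (length(resc_e)) {
    hi <- if (length(other_e)) min(other_e) else 1
    p$blast_evalue_atypical <- gmid(max(resc_e), max(hi, max(resc_e) * 10))
  }

  kin_e <- pick(rank1, c(high_cats, resc_cats))
  kin_e <- kin_e[!is.na(kin_e)]
  if (length(kin_e)) {
    hi <- if (length(other_e)) min(other_e) else 1
    p$blast_evalue_classification <- gmid(max(kin_e), max(hi, max(kin_e) * 10))
  }
  p$hmm_score_classification <- p$hmm_score_identification

  typ_e <- pick(rank1, "typical")
  typ_e <- typ_e[!is.na(typ_e)]
  if (length(typ_e)) {
    p$log10_evalue_subfamily <- max(log10(typ_e)) + 1
  }

  validate_params(structure(p, class = "kin_params"))
}

#' Generate, score and calibrate a complete fixture
#'
#' Convenience wrapper: builds the reference database, alignment, proteome
#' and truth set, computes all pipeline scores and calibrates cutoffs.
#' When `dir` is given, writes `refdb.fasta`, `refdb.tsv`,
#' `alignment.fasta`, `proteome.fasta`, `truth.tsv` and `params.used`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @return List with `db`, `alignment`, `proteome`, `truth`, `scores`,
#'   `params` and (when written) `paths`.
#' @export
make_fixture <- function(spec = fixture_spec(), dir = NULL) {
  ref <- make_reference(spec)
  pr <- make_proteome(spec, ref)
  scores <- kinome_scores(pr$proteome, ref$db, ref$alignment)
  params <- calibrate_params(scores, pr$truth)
  out <- list(db = ref$db, alignment = ref$alignment,
              internals = ref$internals,
              proteome = pr$proteome, truth = pr$truth,
              scores = scores, params = params)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(refdb = file.path(dir, "refdb.fasta"),
               refdb_tsv = file.path(dir, "refdb.tsv"),
               alignment = file.path(dir, "alignment.fasta"),
               proteome = file.path(dir, "proteome.fasta"),
               truth = file.path(dir, "truth.tsv"),
               params = file.path(dir, "params.used"))
    write_reference(ref$db, paths[["refdb"]], paths[["refdb_tsv"]])
    write_fasta(setNames(ref$alignment$seqs, ref$alignment$ids),
                paths[["alignment"]])
    write_fasta(pr$proteome, paths[["proteome"]])
    write.table(pr$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_params(params, paths[["params"]])
    out$paths <- paths
  }
  out
}
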