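# Independent oracles: plain-R dynamic programming for local affine-gap
# alignment, and a per-sequence recount of the confusion rules.  These are
# written directly from the recurrences / rule statements and share no
# code with the package implementations they check.

# local affine-gap DP over a generic cell-score function
oracle_local_dp <- function(n, m, cell_score, gap_open, gap_extend) {
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      pre <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- cell_score(i - 1L, j - 1L) + pre
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

oracle_profile_score <- function(scores, qcodes, gap_open, gap_extend) {
  oracle_local_dp(nrow(scores), length(qcodes), function(i, j) {
    if (qcodes[j] == 0L) 0 else scores[i, qcodes[j]]
  }, gap_open, gap_extend)
}

oracle_pair_score <- function(acodes, bcodes, sub, gap_open, gap_extend) {
  oracle_local_dp(length(acodes), length(bcodes), function(i, j) {
    if (acodes[i] == 0L || bcodes[j] == 0L) 0 else sub[acodes[i], bcodes[j]]
  }, gap_open, gap_extend)
}

# slash-label depth without package helpers
oracle_depth <- function(lab) {
  if (lab == "") 0L else length(strsplit(lab, "/", fixed = TRUE)[[1]])
}

oracle_prefix <- function(lab, depth) {
  if (lab == "" || depth == 0L) return("")
  tok <- strsplit(lab, "/", fixed = TRUE)[[1]]
  if (length(tok) < depth) return(NA_character_)
  paste(tok[seq_len(depth)], collapse = "/")
}

# per-sequence recount of the confusion rules, written case by case
oracle_confusion <- function(truth, calls, level, exclude_ss = FALSE) {
  if (exclude_ss) truth <- truth[!truth$species_specific, , drop = FALSE]
  TP <- FP <- FN <- TN <- 0L
  kinome_cats <- c("ePK", "unusual_ePK", "aPK")
  for (i in seq_len(nrow(truth))) {
    id <- truth$protein_id[i]
    j <- match(id, calls$query_id)
    is_called <- !is.na(j) && calls$category[j] %in% kinome_cats
    c_lab <- if (is_called) {
      tok <- c(calls$group[j], calls$family[j], calls$subfamily[j])
      paste(tok[tok != ""], collapse = "/")
    } else ""
    c_dep <- oracle_depth(c_lab)
    t_kin <- truth$is_kinase[i]
    t_lab <- truth$label[i]
    t_dep <- oracle_depth(t_lab)

    if (level == "identification") {
      if (t_kin && is_called) TP <- TP + 1L
      else if (t_kin && !is_called) FN <- FN + 1L
      else if (!t_kin && is_called) FP <- FP + 1L
      else TN <- TN + 1L
    } else if (level == "partial") {
      if (t_kin && t_dep > 0L) {
        if (c_dep == 0L) FN <- FN + 1L
        else if (c_dep <= t_dep &&
                 identical(oracle_prefix(t_lab, c_dep), c_lab)) TP <- TP + 1L
        else FP <- FP + 1L
      } else {
        if (c_dep > 0L) FP <- FP + 1L else TN <- TN + 1L
      }
    } else {
      if (t_kin && t_dep > 0L) {
        if (c_dep == 0L) FN <- FN + 1L
        else if (identical(c_lab, t_lab)) TP <- TP + 1L
        else if (c_dep < t_dep &&
                 identical(oracle_prefix(t_lab, c_dep), c_lab)) FN <- FN + 1L
        else FP <- FP + 1L
      } else {
        if (c_dep > 0L) FP <- FP + 1L else TN <- TN + 1L
      }
    }
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN, P = sum(truth$is_kinase))
}

random_protein <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}
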