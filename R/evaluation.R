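# ROC calculus for scoring a draft kinome against a curated truth set.
# Predictions are scored at three levels: identification (is the protein
# a kinase), partial classification (credit for correct but possibly
# shallow labels) and full classification (exact match at the reference's
# stated depth).  In every analysis P, the positive count, is the total
# number of kinases in the reference set.

#' Read a curated truth set
#'
#' TSV with header columns `protein_id`, `is_kinase`, `label`,
#' `species_specific` (and optionally extras such as `category`, which are
#' kept).
#'
#' @param path Path to the truth TSV.
#' @return data.frame with at least the four standard columns; `label` is
#'   the slash-delimited classification (empty for unclassified).
#' @export
read_truth <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("protein_id", "is_kinase", "label", "species_specific")
  if (!all(need %in% names(tab))) {
    stop("truth TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$is_kinase <- tolower(tab$is_kinase) %in% c("true", "1", "yes")
  tab$species_specific <- tolower(tab$species_specific) %in%
    c("true", "1", "yes")
  tab$label[is.na(tab$label)] <- ""
  tab
}

# does the call label agree with the truth label at every level the call
# asserts? (call must be no deeper than truth)
label_is_prefix <- function(call_label, call_depth, truth_label, truth_depth) {
  call_depth <= truth_depth &&
    identical(truncate_label(truth_label, call_depth), call_label)
}

#' Confusion counts for a draft kinome against a truth set
#'
#' At the identification level a protein either is or is not called a
#' kinase.  At the partial level a classified reference kinase scores TP
#' for any correct (possibly shallower) classification, FP for a wrong
#' assertion at any level (a wrong subfamily negates correct group/family
#' credit, and a call deeper than the reference's stated depth is a wrong
#' assertion), and FN when no classification is offered; agreement that a
#' sequence is an unclassified kinase, or is not a kinase, is TN.  At the
#' full level only an exact match at the reference's stated depth is TP;
#' correct-but-shallower calls are FN.  `P` is always the number of
#' reference kinases in the (possibly filtered) truth set.
#'
#' Ids present in the calls but absent from the truth set are counted as
#' identification FPs (when called as kinases) and reported via the
#' `"extra_calls"` attribute; at the classification levels they are
#' ignored, having no reference classification to compare against.
#'
#' @param truth Truth data.frame ([read_truth()] layout).
#' @param calls A `kin_kinome` or its `calls` data.frame.
#' @param level `"identification"`, `"partial"` or `"full"`.
#' @param exclude_species_specific Drop truth entries flagged
#'   species-specific from `P` and all counts (used for the
#'   conserved-kinase statistic).
#' @return An object of class `kin_confusion`: list with `TP`, `FP`, `FN`,
#'   `TN`, `P` and `level`.
#' @export
confusion_counts <- function(truth, calls,
                             level = c("identification", "partial", "full"),
                             exclude_species_specific = FALSE) {
  level <- match.arg(level)
  if (inherits(calls, "kin_kinome")) calls <- calls$calls
  if (exclude_species_specific) {
    drop_ids <- truth$protein_id[truth$species_specific]
    truth <- truth[!truth$species_specific, , drop = FALSE]
    calls <- calls[!calls$query_id %in% drop_ids, , drop = FALSE]
  }

  extra <- setdiff(calls$query_id, truth$protein_id)
  idx <- match(truth$protein_id, calls$query_id)

  called_kinase <- ifelse(is.na(idx), FALSE,
                          calls$category[idx] %in% KINOME_CATEGORIES)
  call_label <- ifelse(is.na(idx) | !called_kinase, "",
                       join_labels(calls$group[idx], calls$family[idx],
                                   calls$subfamily[idx]))
  call_depth <- ifelse(is.na(idx) | !called_kinase, 0L, calls$depth[idx])

  truth_depth <- vapply(truth$label,
                        function(l) parse_label(l)$depth, 0L,
                        USE.NAMES = FALSE)
  P <- sum(truth$is_kinase)

  TP <- FP <- FN <- TN <- 0L
  n <- nrow(truth)
  if (level == "identification") {
    TP <- sum(truth$is_kinase & called_kinase)
    FN <- sum(truth$is_kinase & !called_kinase)
    FP <- sum(!truth$is_kinase & called_kinase)
    TN <- sum(!truth$is_kinase & !called_kinase)
    if (length(extra)) {
      extra_kinase <- calls$category[match(extra, calls$query_id)] %in%
        KINOME_CATEGORIES
      FP <- FP + sum(extra_kinase)
      TN <- TN + sum(!extra_kinase)
    }
  } else {
    for (i in seq_len(n)) {
      t_kin <- truth$is_kinase[i]
      t_lab <- truth$label[i]
      t_dep <- truth_depth[i]
      c_lab <- call_label[i]
      c_dep <- call_depth[i]
      if (t_kin && t_dep > 0L) {
        if (c_dep == 0L) {
          FN <- FN + 1L
        } else if (level == "partial") {
          if (label_is_prefix(c_lab, c_dep, t_lab, t_dep)) TP <- TP + 1L
          else FP <- FP + 1L
        } else {  # full
          if (identical(c_lab, t_lab)) TP <- TP + 1L
          else if (label_is_prefix(c_lab, c_dep, t_lab, t_dep)) FN <- FN + 1L
          else FP <- FP + 1L
        }
      } else {
        # reference is an unclassified kinase or not a kinase: any
        # classification asserted is FP, otherwise agreement -> TN
        if (c_dep > 0L) FP <- FP + 1L else TN <- TN + 1L
      }
    }
  }

  out <- structure(list(TP = as.integer(TP), FP = as.integer(FP),
                        FN = as.integer(FN), TN = as.integer(TN),
                        P = as.integer(P), level = level),
                   class = "kin_confusion")
  attr(out, "extra_calls") <- extra
  out
}

#' @export
print.kin_confusion <- function(x, ...) {
  cat(sprintf("Confusion (%s): TP=%d FP=%d FN=%d TN=%d (P=%d)\n",
              x$level, x$TP, x$FP, x$FN, x$TN, x$P))
  invisible(x)
}

#' ROC metrics from confusion counts
#'
#' `TPR = TP / P` (sensitivity / recall, with P the reference positive
#' count), `PPV = TP / (TP + FP)` (precision), `FDR = FP / (TP + FP)` and
#' `F = 2 * PPV * TPR / (PPV + TPR)`.  When no positive calls were made
#' (`TP + FP = 0`) the convention is `PPV = 1`, `FDR = 0`; `F = 0` when
#' both rates are zero.
#'
#' @param c A `kin_confusion` (or list with `TP`, `FP`, `FN`, `P`).
#' @return List of class `kin_metrics` with `TPR`, `PPV`, `FDR`, `F`.
#' @export
confusion_metrics <- function(c) {
  TPR <- if (c$P > 0) c$TP / c$P else NA_real_
  if (c$TP + c$FP > 0) {
    PPV <- c$TP / (c$TP + c$FP)
    FDR <- c$FP / (c$TP + c$FP)
  } else {
    PPV <- 1
    FDR <- 0
  }
  F <- if (!is.na(TPR) && (PPV + TPR) > 0) 2 * PPV * TPR / (PPV + TPR) else 0
  structure(list(TPR = TPR, PPV = PPV, FDR = FDR, F = F),
            class = "kin_metrics")
}

#' @export
print.kin_metrics <- function(x, ...) {
  cat(sprintf("TPR=%.4f PPV=%.4f FDR=%.4f F=%.4f\n", x$TPR, x$PPV, x$FDR,
              x$F))
  invisible(x)
}

#' Macro-average metrics across species
#'
#' The unweighted arithmetic mean of each metric over the per-species
#' values, the convention used to summarise benchmark performance across
#' test kinomes.
#'
#' @param per_species List of `kin_metrics` (or lists with the same
#'   fields), one per species.
#' @return A `kin_metrics` with averaged fields.
#' @export
macro_average <- function(per_species) {
  if (!length(per_species)) stop("empty metrics list", call. = FALSE)
  avg <- function(f) mean(vapply(per_species, function(m) m[[f]], 0))
  structure(list(TPR = avg("TPR"), PPV = avg("PPV"), FDR = avg("FDR"),
                 F = avg("F")),
            class = "kin_metrics")
}

#' Sweep one pipeline parameter and trace the ROC curve
#'
#' Re-runs the decision pipeline (on precomputed scores, so only the
#' decision phases are repeated) once per parameter value and evaluates
#' the resulting kinome against the truth set at the requested level.
#'
#' @param scores A `kin_scores`.
#' @param truth Truth data.frame.
#' @param param_name Name of one `kin_params` field.
#' @param values Vector of settings to try.
#' @param level Evaluation level (see [confusion_counts()]).
#' @param params Baseline parameters for the fields not swept.
#' @param exclude_species_specific Passed to [confusion_counts()].
#' @return data.frame with columns `value`, `TPR`, `FDR`, `PPV`, `F`.
#' @export
roc_sweep <- function(scores, truth, param_name, values,
                      level = "identification", params = default_params(),
                      exclude_species_specific = FALSE) {
  if (!param_name %in% names(PARAM_TYPES)) {
    stop("unknown parameter name: '", param_name, "'", call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    p <- params
    p[[param_name]] <- v
    k <- call_kinome(scores, validate_params(p))
    m <- confusion_metrics(confusion_counts(truth, k, level,
                                            exclude_species_specific))
    data.frame(value = v, TPR = m$TPR, FDR = m$FDR, PPV = m$PPV, F = m$F)
  })
  do.call(rbind, rows)
}
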