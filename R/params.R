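# Pipeline cutoffs.  The documented defaults are the optimised values for
# HMMER2 bit scores and BLAST E-values; the native scoring engines use a
# different scale, so fixture-based runs calibrate their own cutoffs (see
# calibrate_params()) and every cutoff is an ordinary parameter.

PARAM_TYPES <- c(
  hmm_evalue_candidate = "numeric",
  hmm_score_identification = "numeric",
  motif_score_twilight = "numeric",
  hmm_score_twilight = "numeric",
  blast_evalue_atypical = "numeric",
  blast_evalue_classification = "numeric",
  hmm_score_classification = "numeric",
  n_consistent_hits = "integer",
  log10_evalue_subfamily = "numeric",
  metazoan_mode = "logical",
  strict_classification_gate = "character"
)

#' Default pipeline parameters
#'
#' The identification cutoffs: `hmm_evalue_candidate` (relaxed candidate
#' gate, default 100), `hmm_score_identification` (typical-kinase score
#' floor, -66), `motif_score_twilight` (functional-residue score gate,
#' 0.4), `hmm_score_twilight` (twilight score floor, -173) and
#' `blast_evalue_atypical` (rescue gate for unusual ePKs and atypical
#' kinases, 1e-20).  The classification cutoffs:
#' `blast_evalue_classification` (1e-10), `hmm_score_classification`
#' (-30), `n_consistent_hits` (consecutive agreeing top hits, 3) and
#' `log10_evalue_subfamily` (top-hit E-value gate for subfamily-depth
#' calls, -30).  `metazoan_mode` (default off) disables the conservative
#' TK-to-TKL rewrite.  `strict_classification_gate` selects whether the
#' not-classified gate requires both weak similarity AND a weak profile
#' score (`"and"`, the default) or either (`"or"`).
#'
#' @param ... Named overrides of any default.
#' @return An object of class `kin_params` (named list).
#' @export
default_params <- function(...) {
  p <- list(hmm_evalue_candidate = 100,
            hmm_score_identification = -66,
            motif_score_twilight = 0.4,
            hmm_score_twilight = -173,
            blast_evalue_atypical = 1e-20,
            blast_evalue_classification = 1e-10,
            hmm_score_classification = -30,
            n_consistent_hits = 3L,
            log10_evalue_subfamily = -30,
            metazoan_mode = FALSE,
            strict_classification_gate = "and")
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(over)] <- over
  validate_params(structure(p, class = "kin_params"))
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  p$n_consistent_hits <- as.integer(p$n_consistent_hits)
  if (p$n_consistent_hits < 1L) {
    stop("n_consistent_hits must be >= 1", call. = FALSE)
  }
  if (p$hmm_score_twilight > p$hmm_score_identification) {
    stop("hmm_score_twilight must be <= hmm_score_identification",
         call. = FALSE)
  }
  evs <- c("hmm_evalue_candidate", "blast_evalue_atypical",
           "blast_evalue_classification")
  for (k in evs) {
    if (!is.numeric(p[[k]]) || p[[k]] <= 0) {
      stop(k, " must be a positive E-value", call. = FALSE)
    }
  }
  if (!p$strict_classification_gate %in% c("and", "or")) {
    stop("strict_classification_gate must be 'and' or 'or'", call. = FALSE)
  }
  p$metazoan_mode <- isTRUE(p$metazoan_mode)
  structure(p, class = "kin_params")
}

#' @export
print.kin_params <- function(x, ...) {
  cat("Pipeline parameters:\n")
  for (k in names(PARAM_TYPES)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write pipeline parameters as a key=value file
#'
#' The emitted file documents the parameters used for a run and can be
#' edited and read back with [read_params()].
#'
#' @param params A `kin_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  lines <- c("# pipeline parameters (key=value); edit and reuse via read_params()",
             vapply(names(PARAM_TYPES), function(k) {
               v <- params[[k]]
               v <- if (is.logical(v)) ifelse(v, "true", "false")
                    else format(v, digits = 17)
               paste0(k, "=", v)
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read pipeline parameters from a key=value file
#'
#' Unknown keys are an error naming the key; keys missing from the file
#' take their defaults (from `base`) with a message.
#'
#' @param path Path to a file written by [write_params()] (possibly
#'   edited).
#' @param base Parameters supplying defaults for missing keys.
#' @return A `kin_params`.
#' @export
read_params <- function(path, base = default_params()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  p <- unclass(base)
  seen <- character(0)
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1L) stop("malformed parameter line: '", ln, "'", call. = FALSE)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (!key %in% names(PARAM_TYPES)) {
      stop("unknown parameter key: '", key, "'", call. = FALSE)
    }
    p[[key]] <- switch(PARAM_TYPES[[key]],
      numeric = {
        x <- suppressWarnings(as.numeric(val))
        if (is.na(x)) stop("unparsable numeric value for ", key, ": '", val,
                           "'", call. = FALSE)
        x
      },
      integer = {
        x <- suppressWarnings(as.integer(val))
        if (is.na(x)) stop("unparsable integer value for ", key, ": '", val,
                           "'", call. = FALSE)
        x
      },
      logical = {
        if (!tolower(val) %in% c("true", "false", "0", "1")) {
          stop("unparsable logical value for ", key, ": '", val, "'",
               call. = FALSE)
        }
        tolower(val) %in% c("true", "1")
      },
      character = val)
    seen <- c(seen, key)
  }
  missing <- setdiff(names(PARAM_TYPES), seen)
  if (length(missing)) {
    message("parameters not in file, using defaults: ",
            paste(missing, collapse = ", "))
  }
  validate_params(structure(p, class = "kin_params"))
}
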