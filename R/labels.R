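# Hierarchical classification labels: group / family / subfamily with a
# depth of 0 (unclassified) to 3.  Vocabulary tokens are opaque,
# case-sensitive strings; the package hard-codes no group list so any
# KinBase-style vocabulary can be used.

#' Parse a slash-delimited classification label
#'
#' Labels follow the three-level group/family/subfamily hierarchy, e.g.
#' `"CMGC/CDK/CDC2"`.  An empty string or `"unclassified"` denotes an
#' unclassified label (depth 0).
#'
#' @param text A single string with 0-3 slash-delimited non-empty tokens.
#' @return An object of class `kin_label`: a list with fields `group`,
#'   `family`, `subfamily` (empty string when unset) and `depth` (0-3).
#' @examples
#' parse_label("CMGC/CDK/CDC2")
#' parse_label("Other")
#' parse_label("")
#' @export
parse_label <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("label must be a single string", call. = FALSE)
  }
  text <- trimws(text)
  if (text == "" || tolower(text) == "unclassified") {
    return(new_label(character(0)))
  }
  tokens <- strsplit(text, "/", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty field; detect it from the raw text
  if (endsWith(text, "/") || any(tokens == "")) {
    stop("malformed label (empty token): '", text, "'", call. = FALSE)
  }
  if (length(tokens) > 3L) {
    stop("malformed label (more than 3 levels): '", text, "'", call. = FALSE)
  }
  new_label(tokens)
}

new_label <- function(tokens) {
  tokens <- as.character(tokens)
  depth <- length(tokens)
  structure(list(group     = if (depth >= 1L) tokens[1L] else "",
                 family    = if (depth >= 2L) tokens[2L] else "",
                 subfamily = if (depth >= 3L) tokens[3L] else "",
                 depth     = depth),
            class = "kin_label")
}

#' Format a classification label back to its slash-delimited form
#'
#' @param label A `kin_label`, or a list with `group`/`family`/`subfamily`.
#' @return A string; `""` for an unclassified (depth 0) label.
#' @export
format_label <- function(label) {
  tokens <- c(label$group, label$family, label$subfamily)
  paste(tokens[tokens != ""], collapse = "/")
}

#' @export
print.kin_label <- function(x, ...) {
  if (x$depth == 0L) cat("<unclassified>\n")
  else cat(format_label(x), " (depth ", x$depth, ")\n", sep = "")
  invisible(x)
}

# Vectorised label splitting: character vector of slash-delimited labels ->
# data.frame(group, family, subfamily, depth).  Errors on malformed input.
split_labels <- function(texts) {
  parsed <- lapply(texts, parse_label)
  data.frame(group     = vapply(parsed, `[[`, "", "group"),
             family    = vapply(parsed, `[[`, "", "family"),
             subfamily = vapply(parsed, `[[`, "", "subfamily"),
             depth     = vapply(parsed, `[[`, 0L, "depth"),
             stringsAsFactors = FALSE)
}

# Join label component columns back to slash-delimited strings.
join_labels <- function(group, family, subfamily) {
  out <- character(length(group))
  for (i in seq_along(group)) {
    tokens <- c(group[i], family[i], subfamily[i])
    out[i] <- paste(tokens[tokens != ""], collapse = "/")
  }
  out
}

# Truncate a label string to a given depth ("" if shallower than depth).
truncate_label <- function(text, depth) {
  vapply(text, function(t) {
    if (t == "") return("")
    tokens <- strsplit(t, "/", fixed = TRUE)[[1]]
    if (length(tokens) < depth) return("")
    paste(tokens[seq_len(depth)], collapse = "/")
  }, "", USE.NAMES = FALSE)
}
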