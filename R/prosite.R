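# Parser and scanner for PROSITE-syntax protein motifs.
#
# Supported dialect (the constructs that occur in practice for family
# motifs): fixed residues (L), residue classes ([AL]), wildcards x, x(n),
# x(m,n), '-' separators, optional surrounding parentheses.  N/C-terminal
# anchors ('<', '>'), negated classes ('{...}') and repeats of non-wildcard
# elements are rejected loudly rather than half-supported.

#' Parse a PROSITE-syntax pattern
#'
#' @param text Pattern string, e.g. `"C-L-x(2)-[AL]"`.  A single pair of
#'   surrounding parentheses and a trailing period are stripped.
#' @return Object of class `prosite_pattern`: list with `elements`
#'   (`data.frame` of `type` (`"fixed"`, `"class"`, `"wildcard"`),
#'   `residues`, `min_rep`, `max_rep`), `min_span`, `max_span`, `source`.
#' @examples
#' p <- parse_prosite("C-L-x(2)-[AL]")
#' p$min_span  # 5
#' @export
parse_prosite <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  src <- text
  s <- gsub("[[:space:]]", "", text)
  s <- sub("\\.$", "", s)
  if (grepl("^\\(", s) && grepl("\\)$", s)) s <- substr(s, 2L, nchar(s) - 1L)
  if (!nzchar(s)) stop("empty pattern", call. = FALSE)
  tokens <- strsplit(s, "-", fixed = TRUE)[[1]]
  aa <- paste(.AA20, collapse = "")
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    err <- function(why) stop(sprintf("element %d ('%s'): %s", i, tok, why),
                              call. = FALSE)
    if (!nzchar(tok)) err("empty element")
    if (grepl("[<>]", tok)) err("terminal anchors are not supported")
    if (grepl("^\\{", tok)) err("negated classes are not supported")
    if (grepl(sprintf("^[%s]$", aa), tok)) {
      elements[[i]] <- data.frame(type = "fixed", residues = tok,
                                  min_rep = 1L, max_rep = 1L,
                                  stringsAsFactors = FALSE)
    } else if (grepl("^\\[[A-Z]*\\]$", tok)) {
      res <- substr(tok, 2L, nchar(tok) - 1L)
      if (!nzchar(res)) err("empty residue class")
      if (!grepl(sprintf("^[%s]+$", aa), res)) err("non-residue letters in class")
      elements[[i]] <- data.frame(type = "class", residues = res,
                                  min_rep = 1L, max_rep = 1L,
                                  stringsAsFactors = FALSE)
    } else if (tok == "x") {
      elements[[i]] <- data.frame(type = "wildcard", residues = "",
                                  min_rep = 1L, max_rep = 1L,
                                  stringsAsFactors = FALSE)
    } else if (grepl("^x\\(\\d+\\)$", tok)) {
      n <- as.integer(sub("^x\\((\\d+)\\)$", "\\1", tok))
      if (n < 1L) err("repeat count must be >= 1")
      elements[[i]] <- data.frame(type = "wildcard", residues = "",
                                  min_rep = n, max_rep = n,
                                  stringsAsFactors = FALSE)
    } else if (grepl("^x\\(\\d+,\\d+\\)$", tok)) {
      mn <- as.integer(sub("^x\\((\\d+),(\\d+)\\)$", "\\1", tok))
      mx <- as.integer(sub("^x\\((\\d+),(\\d+)\\)$", "\\2", tok))
      if (mn > mx || mx < 1L) err("invalid repeat range")
      elements[[i]] <- data.frame(type = "wildcard", residues = "",
                                  min_rep = mn, max_rep = mx,
                                  stringsAsFactors = FALSE)
    } else if (grepl("^\\[", tok) || grepl("\\]$", tok)) {
      err("unbalanced brackets")
    } else {
      err("unrecognised element")
    }
  }
  elements <- do.call(rbind, elements)
  structure(list(elements = elements,
                 min_span = sum(elements$min_rep),
                 max_span = sum(elements$max_rep),
                 source = src),
            class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("prosite_pattern:", render_prosite(x), "\n")
  cat(nrow(x$elements), "elements, span", x$min_span, "-", x$max_span,
      "residues\n")
  invisible(x)
}

#' Render a parsed pattern back to PROSITE syntax
#'
#' `parse_prosite(render_prosite(p))` reproduces `p`'s element list.
#'
#' @param pattern A `prosite_pattern`.
#' @return Pattern string.
#' @export
render_prosite <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  e <- pattern$elements
  toks <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    toks[i] <- switch(e$type[i],
      fixed = e$residues[i],
      class = sprintf("[%s]", e$residues[i]),
      wildcard = if (e$min_rep[i] == 1L && e$max_rep[i] == 1L) "x"
                 else if (e$min_rep[i] == e$max_rep[i])
                   sprintf("x(%d)", e$min_rep[i])
                 else sprintf("x(%d,%d)", e$min_rep[i], e$max_rep[i]))
  }
  paste(toks, collapse = "-")
}

# Greedy backtracking matcher: at each flexible wildcard the longest
# repeat is tried first, mirroring greedy regular-expression semantics, so
# the reported match per start is the leftmost-longest in that sense.
# Returns 0-based half-open end position, or -1 if no match from `pos`.
.match_elements <- function(chars, pos, e, idx) {
  if (idx > nrow(e)) return(pos)
  n <- length(chars)
  type <- e$type[idx]
  if (type == "wildcard") {
    for (rep in seq(e$max_rep[idx], e$min_rep[idx])) {
      if (pos + rep > n) next
      r <- .match_elements(chars, pos + rep, e, idx + 1L)
      if (r >= 0L) return(r)
    }
    return(-1L)
  }
  if (pos + 1L > n) return(-1L)
  ch <- chars[pos + 1L]
  ok <- if (type == "fixed") ch == e$residues[idx]
        else grepl(ch, e$residues[idx], fixed = TRUE)
  if (!ok) return(-1L)
  .match_elements(chars, pos + 1L, e, idx + 1L)
}

#' Scan protein sequences with a PROSITE pattern
#'
#' Every start position is tried, so overlapping matches are all reported;
#' per (sequence, start) the greedy (longest-first wildcard) match is
#' returned.
#'
#' @param pattern A `prosite_pattern` from [parse_prosite()] (a character
#'   pattern is parsed on the fly).
#' @param proteins [Biostrings::AAStringSet] or named character vector.
#' @return `data.frame` with `sequence_id`, `start`, `end` (0-based
#'   half-open residue coordinates) and `match` (the matched substring).
#' @export
scan_pattern <- function(pattern, proteins) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  aa <- .as_aa_set(proteins)
  e <- pattern$elements
  out <- list()
  for (i in seq_along(aa)) {
    s <- as.character(aa[[i]])
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < pattern$min_span) next
    for (start in 0:(n - pattern$min_span)) {
      end <- .match_elements(chars, start, e, 1L)
      if (end >= 0L) {
        out[[length(out) + 1L]] <- data.frame(
          sequence_id = names(aa)[i], start = start, end = end,
          match = substr(s, start + 1L, end), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), match = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
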