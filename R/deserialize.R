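# Deserialization: the identifier doubles as a descriptor. The formula fixes
# how many atoms of each element exist; labels are implied by expanding the
# formula in ascending atomic number (label 1 = lightest element's first
# atom) -- NOT Hill print order, which differs (a formula starts with C, but
# labels start with H). Edges and features then attach to those labels.

RE_EDGE_BLOCK <- "^(\\((\\d+)-(\\d+)\\))+$"
RE_FEAT_BLOCK <- "^(\\((\\d+):([A-Z]+=-?\\d+)(,[A-Z]+=-?\\d+)*\\))+$"

#' Parse an identifier string
#'
#' Splits a tuple identifier into its formula, edge-tuple and node-feature
#' blocks with strict validation: tuple labels must be in range and
#' ascending within each tuple, the edge list sorted strictly increasing,
#' feature entries sorted by label with fields in lexicographic order, and
#' feature field names limited to `CHG`, `MASS`, `RAD`. A fourth block
#' (reserved for future custom data) is preserved verbatim and otherwise
#' ignored.
#'
#' @param s Identifier string.
#' @return Object of class `tucan_parsed`: list with `n`, `element` (one
#'   symbol per label, ascending atomic number), `formula` (named counts in
#'   the order printed), `edges`, `features`, `extra`.
#' @examples
#' p <- parse_tucan_string("CH4/(1-5)(2-5)(3-5)(4-5)")
#' p$element
#' @export
parse_tucan_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  if (grepl("\\s", s)) stop("identifier must not contain whitespace", call. = FALSE)
  blocks <- strsplit(s, "/", fixed = TRUE)[[1L]]
  if (length(blocks) == 0L || !nzchar(blocks[[1L]])) {
    stop("missing formula block", call. = FALSE)
  }
  if (length(blocks) > 4L) stop("too many '/'-separated blocks", call. = FALSE)

  counts <- parse_formula(blocks[[1L]])
  # per-label element list: ascending atomic number
  z <- element_to_atomic_number(names(counts))
  ordz <- order(z)
  element <- rep(names(counts)[ordz], counts[ordz])
  n <- length(element)

  edges <- matrix(integer(0), ncol = 2L)
  features <- vector("list", n)
  extra <- NULL
  seen_feat <- FALSE
  for (blk in blocks[-1L]) {
    if (!nzchar(blk)) next  # an omitted (empty) block written as "//"
    if (!is.null(extra)) stop("unexpected content after custom block", call. = FALSE)
    if (grepl(RE_EDGE_BLOCK, blk)) {
      if (nrow(edges) > 0L || seen_feat) {
        stop("edge block out of order: ", sQuote(blk), call. = FALSE)
      }
      edges <- parse_edge_block(blk, n)
    } else if (grepl(RE_FEAT_BLOCK, blk)) {
      if (seen_feat) stop("duplicate feature block", call. = FALSE)
      seen_feat <- TRUE
      features <- parse_feature_block(blk, n)
    } else {
      extra <- blk  # reserved custom-data block: kept verbatim, ignored
    }
  }
  structure(list(n = n, element = element, formula = counts, edges = edges,
                 features = features, extra = extra),
            class = "tucan_parsed")
}

parse_formula <- function(block) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", block)[[1L]]
  toks <- regmatches(block, list(m))[[1L]]
  if (paste(toks, collapse = "") != block) {
    stop("malformed formula block: ", sQuote(block), call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(cnt) || any(cnt < 1L)) {
    stop("invalid element count in formula: ", sQuote(block), call. = FALSE)
  }
  if (anyDuplicated(sym)) {
    stop("element repeated in formula: ",
         sQuote(sym[duplicated(sym)][[1L]]), call. = FALSE)
  }
  element_to_atomic_number(sym)
  stats::setNames(as.integer(cnt), sym)
}

parse_edge_block <- function(block, n) {
  m <- gregexpr("\\((\\d+)-(\\d+)\\)", block)[[1L]]
  toks <- regmatches(block, list(m))[[1L]]
  ab <- t(vapply(strsplit(gsub("[()]", "", toks), "-", fixed = TRUE),
                 as.integer, integer(2L)))
  bad <- which(ab[, 1L] >= ab[, 2L])
  if (length(bad) > 0L) {
    stop("edge tuple not in ascending order: ", sQuote(toks[[bad[[1L]]]]), call. = FALSE)
  }
  if (any(ab > n) || any(ab < 1L)) {
    stop("edge label out of range [1, ", n, "]", call. = FALSE)
  }
  if (nrow(ab) > 1L) {
    prev <- ab[-nrow(ab), , drop = FALSE]
    nxt <- ab[-1L, , drop = FALSE]
    ok <- prev[, 1L] < nxt[, 1L] | (prev[, 1L] == nxt[, 1L] & prev[, 2L] < nxt[, 2L])
    if (!all(ok)) {
      stop("edge list not sorted strictly increasing at ",
           sQuote(toks[[which(!ok)[[1L]] + 1L]]), call. = FALSE)
    }
  }
  ab
}

parse_feature_block <- function(block, n) {
  m <- gregexpr("\\((\\d+):[^)]*\\)", block)[[1L]]
  toks <- regmatches(block, list(m))[[1L]]
  labels <- as.integer(sub("^\\((\\d+):.*$", "\\1", toks))
  if (any(labels > n) || any(labels < 1L)) {
    stop("feature label out of range [1, ", n, "]", call. = FALSE)
  }
  if (is.unsorted(labels, strictly = TRUE)) {
    stop("feature entries not sorted by increasing label", call. = FALSE)
  }
  features <- vector("list", n)
  for (k in seq_along(toks)) {
    body <- sub("^\\(\\d+:(.*)\\)$", "\\1", toks[[k]])
    kv <- strsplit(body, ",", fixed = TRUE)[[1L]]
    nm <- sub("=.*$", "", kv)
    if (!all(nm %in% FEATURE_FIELDS)) {
      stop("unknown feature field ", sQuote(setdiff(nm, FEATURE_FIELDS)[[1L]]),
           " (expected CHG, MASS or RAD)", call. = FALSE)
    }
    if (is.unsorted(nm, strictly = TRUE)) {
      stop("feature fields not in lexicographic order in ",
           sQuote(toks[[k]]), call. = FALSE)
    }
    val <- as.integer(sub("^[A-Z]+=", "", kv))
    features[[labels[[k]]]] <- validate_features(stats::setNames(val, nm))
  }
  features
}

#' Reconstruct a molecular graph from a parsed identifier
#'
#' Node `i` mirrors label `i`: elements come from the formula expanded in
#' ascending atomic number, edges and features attach by label. Serializing
#' the canonicalized result of a canonical string reproduces that string.
#'
#' @param parsed A `tucan_parsed` object from [parse_tucan_string()].
#' @return A [molecular_graph()].
#' @export
to_graph <- function(parsed) {
  stopifnot(inherits(parsed, "tucan_parsed"))
  molecular_graph(parsed$element, parsed$edges, parsed$features)
}

#' Deserialize an identifier string into a molecular graph
#'
#' @param s Identifier string.
#' @param strict If `TRUE`, reject strings that are grammatical but not
#'   canonical (i.e. whose re-serialization differs from the input).
#' @return A [molecular_graph()].
#' @examples
#' g <- tucan_deserialize("CH4/(1-5)(2-5)(3-5)(4-5)")
#' hill_formula(g)
#' @export
tucan_deserialize <- function(s, strict = FALSE) {
  g <- to_graph(parse_tucan_string(s))
  if (isTRUE(strict)) {
    rs <- tucan_serialize(g)
    if (rs != s) {
      stop("identifier is not canonical: re-serializes to ", sQuote(rs),
           call. = FALSE)
    }
  }
  g
}

#' Reconstruct a coordinate-free molfile from an identifier
#'
#' Deserializes the string and writes the graph as a v3000 molfile with
#' atoms in label order, zeroed coordinates and all bonds as type 1.
#'
#' @param s Identifier string.
#' @param strict Passed to [tucan_deserialize()].
#' @return Molfile document as a single string.
#' @export
tucan_to_molfile <- function(s, strict = FALSE) {
  write_molfile_v3000(tucan_deserialize(s, strict = strict))
}
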