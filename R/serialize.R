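# Serialization of a canonically labeled graph into the identifier string:
#   HillFormula [ "/" edge tuples ] [ "/" node features ]
# Pure printable ASCII; no whitespace; blocks separated by "/". Empty edge
# and feature blocks are omitted, so a monoatomic species is its formula.

# named integer vector of element counts in Hill order: C then H then the
# rest alphabetically; with no carbon present, everything alphabetical
hill_formula_counts <- function(element) {
  counts <- table(element)
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")), method = "radix")
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms, method = "radix")
  }
  stats::setNames(as.integer(counts[ord]), ord)
}

format_hill <- function(counts) {
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Hill formula of a molecule
#'
#' Sum formula in Hill order: carbon first, hydrogen second, all remaining
#' elements alphabetically by symbol; with no carbon present all elements are
#' alphabetical. A count of one is printed without a digit.
#'
#' @param graph A [molecular_graph()] (or [molfile_data()]).
#' @return The formula as a single string.
#' @examples
#' hill_formula(tucan_graph_fixture("zeise"))  # "C2H4Cl3Pt"
#' @export
hill_formula <- function(graph) {
  if (inherits(graph, "tucan_molfile")) graph <- build_graph(graph)
  stopifnot(inherits(graph, "tucan_graph"))
  format_hill(hill_formula_counts(graph$element))
}

#' Output labels for serialization
#'
#' Assigns the 1-based labels printed in the identifier: atoms sorted by
#' ascending atomic number, ties broken by ascending canonical label, then
#' numbered 1..n. Hydrogens therefore always come first and the heaviest
#' element last, regardless of Hill print order.
#'
#' @param graph A [molecular_graph()].
#' @param canon Canonical labeling from [canonical_labeling()]; computed when
#'   omitted.
#' @return Integer vector: output label per node.
#' @export
assign_output_labels <- function(graph, canon = NULL) {
  stopifnot(inherits(graph, "tucan_graph"))
  if (is.null(canon)) canon <- canonical_labeling(graph)
  ord <- order(graph$Z, canon)
  labels <- integer(graph$n)
  labels[ord] <- seq_len(graph$n)
  labels
}

# "(label:FIELD=VALUE,...)" entries sorted by increasing label; fields are
# already name-sorted by validate_features()
feature_block <- function(graph, labels) {
  has <- which(!vapply(graph$features, is.null, logical(1L)))
  if (length(has) == 0L) return("")
  has <- has[order(labels[has])]
  paste(vapply(has, function(v) {
    f <- graph$features[[v]]
    sprintf("(%d:%s)", labels[[v]],
            paste0(names(f), "=", unname(f), collapse = ","))
  }, character(1L)), collapse = "")
}

edge_block <- function(graph, labels) {
  e <- graph$edges
  if (nrow(e) == 0L) return("")
  a <- pmin(labels[e[, 1L]], labels[e[, 2L]])
  b <- pmax(labels[e[, 1L]], labels[e[, 2L]])
  ord <- order(a, b)
  paste(sprintf("(%d-%d)", a[ord], b[ord]), collapse = "")
}

serialize_with_labels <- function(graph, labels) {
  blocks <- c(format_hill(hill_formula_counts(graph$element)),
              edge_block(graph, labels),
              feature_block(graph, labels))
  paste(blocks[nzchar(blocks)], collapse = "/")
}

#' Serialize a molecular graph into its canonical identifier
#'
#' Produces the tuple-style identifier string: Hill formula, then the sorted
#' edge-tuple list `(a-b)` with `a < b` and tuples ordered by `(a, b)`, then
#' the node-feature list `(label:FIELD=VALUE,...)` sorted by label. Every
#' edge appears exactly once. The string is identical for every input atom
#' ordering of the same molecule.
#'
#' @param graph A [molecular_graph()] (or [molfile_data()]).
#' @param canon Canonical labeling; computed when omitted.
#' @return The identifier string (printable ASCII).
#' @examples
#' tucan_serialize(tucan_graph_fixture("methane"))  # "CH4/(1-5)(2-5)(3-5)(4-5)"
#' @export
tucan_serialize <- function(graph, canon = NULL) {
  if (inherits(graph, "tucan_molfile")) graph <- build_graph(graph)
  stopifnot(inherits(graph, "tucan_graph"))
  labels <- assign_output_labels(graph, canon)
  serialize_with_labels(graph, labels)
}

#' Serialize a molfile to its canonical identifier
#'
#' Convenience wrapper: parse a v3000 molfile, build the graph, canonicalize
#' and serialize.
#'
#' @param text Molfile path or contents (see [parse_molfile_v3000()]).
#' @return The identifier string.
#' @export
molfile_to_tucan <- function(text) {
  tucan_serialize(build_graph(parse_molfile_v3000(text)))
}
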