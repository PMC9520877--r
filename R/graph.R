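# Internal molecular graph: undirected, labeled, no multi-edges, no loops.
# Atoms are nodes 1..n; bonds are unordered node pairs. Each node carries its
# element symbol, atomic number, and any CHG/MASS/RAD features. Display-only
# custom attributes may be attached but never influence canonicalization.

#' Construct a molecular graph
#'
#' @param element Character vector of element symbols (one per node).
#' @param edges Two-column integer matrix of node index pairs (1-based), or
#'   `NULL` for an edgeless graph.
#' @param features List of named integer vectors (`CHG`/`MASS`/`RAD`) per
#'   node, `NULL` entries allowed.
#' @param custom Optional list of display-only attributes per node; carried
#'   along but excluded from canonicalization.
#' @return An object of class `tucan_graph` with components `n`, `element`,
#'   `Z`, `features`, `edges` (rows stored with smaller index first),
#'   `adjacency` (list of neighbor index vectors) and `custom`.
#' @examples
#' h2 <- molecular_graph(c("H", "H"), rbind(c(1, 2)))
#' h2$Z
#' @export
molecular_graph <- function(element, edges = NULL, features = NULL,
                            custom = NULL) {
  md <- molfile_data(element, edges, features)
  n <- md$atom_count
  e <- md$bonds
  if (nrow(e) > 0L) {
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  adjacency <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1L]; b <- e[k, 2L]
    adjacency[[a]] <- c(adjacency[[a]], b)
    adjacency[[b]] <- c(adjacency[[b]], a)
  }
  adjacency <- lapply(adjacency, sort)
  if (is.null(custom)) custom <- vector("list", n)
  # flat directed incidence (both directions), grouped by source node --
  # lets partition refinement run fully vectorized
  deg <- lengths(adjacency)
  src <- rep.int(seq_len(n), deg)
  dst <- unlist(adjacency, use.names = FALSE)
  if (is.null(dst)) dst <- integer(0)
  structure(
    list(n = n, element = md$element, Z = element_to_atomic_number(md$element),
         features = md$features, edges = e, adjacency = adjacency,
         custom = custom, deg = deg, src = src, dst = dst,
         slot = cbind(src, 1L + sequence(deg))),
    class = "tucan_graph"
  )
}

#' Build a molecular graph from parsed molfile data
#'
#' Node `i` corresponds to ATOM record `i`; every bond becomes one undirected
#' edge; features are copied through unchanged.
#'
#' @param data A [molfile_data()] object.
#' @return A [molecular_graph()].
#' @export
build_graph <- function(data) {
  stopifnot(inherits(data, "tucan_molfile"))
  molecular_graph(data$element, data$bonds, data$features)
}

#' @export
print.tucan_graph <- function(x, ...) {
  cat(sprintf("<molecular graph: %d nodes, %d edges, formula %s>\n",
              x$n, nrow(x$edges), format_hill(hill_formula_counts(x$element))))
  invisible(x)
}

#' Atomic numbers of a node's neighbors
#'
#' Returns the multiset of atomic numbers adjacent to a node, sorted in
#' decreasing order -- the neighbor part of the node's invariant code.
#'
#' @param graph A [molecular_graph()].
#' @param node Node index (1-based).
#' @return Integer vector, decreasing; empty for an isolated node.
#' @export
neighbor_atomic_numbers <- function(graph, node) {
  stopifnot(inherits(graph, "tucan_graph"))
  if (length(node) != 1L || is.na(node) || node < 1L || node > graph$n) {
    stop("no such node: ", node, call. = FALSE)
  }
  sort(graph$Z[graph$adjacency[[node]]], decreasing = TRUE)
}

#' Relabel the nodes of a graph
#'
#' Renames node `i` to `mapping[i]`, carrying all node attributes along and
#' renaming edge endpoints consistently. Composing with the inverse mapping
#' restores the original graph.
#'
#' @param graph A [molecular_graph()].
#' @param mapping Integer vector: a bijection of `1:n` giving each node's new
#'   index.
#' @return The relabeled [molecular_graph()].
#' @export
relabel <- function(graph, mapping) {
  stopifnot(inherits(graph, "tucan_graph"))
  mapping <- as.integer(mapping)
  if (length(mapping) != graph$n || anyNA(mapping) ||
      !setequal(mapping, seq_len(graph$n))) {
    stop("mapping must be a bijection of 1:", graph$n, call. = FALSE)
  }
  inv <- integer(graph$n)
  inv[mapping] <- seq_len(graph$n)
  e <- graph$edges
  if (nrow(e) > 0L) e <- cbind(mapping[e[, 1L]], mapping[e[, 2L]])
  molecular_graph(graph$element[inv], e, graph$features[inv],
                  custom = graph$custom[inv])
}

# structural equality on the fields canonicalization and output consume
graph_identical <- function(a, b) {
  isTRUE(all.equal(a$element, b$element)) &&
    identical(a$edges, b$edges) &&
    identical(unname(lapply(a$features, identity)),
              unname(lapply(b$features, identity)))
}
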