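# Canonical labeling from topology plus atomic number only.
#
# Pipeline: per-node invariant codes -> initial partition -> iterative 1-D
# Weisfeiler-Lehman (Morgan) refinement -> individualization-refinement with
# minimal-serialization tie-breaking. Entirely deterministic; no RNG.
#
# Partitions are integer vectors assigning each node a cell index 1..k.
# Cell numbering is always derived by sorting cell keys in the C locale
# (radix sort), so partition indices are independent of input node order.

#' Per-node invariant codes
#'
#' The invariant code of a node is its atomic number followed by the
#' multiset of its neighbors' atomic numbers sorted in decreasing order.
#' It encodes the element, the degree, and the element configuration of the
#' immediate neighborhood -- the only chemistry-specific invariant used
#' anywhere in the canonicalization is the atomic number.
#'
#' @param graph A [molecular_graph()].
#' @return List of integer vectors, one per node: `c(Z, neighbor Z values)`.
#' @examples
#' g <- tucan_graph_fixture("methane")
#' assign_invariant_codes(g)[[1]]  # carbon: 6 then 1 1 1 1
#' @export
assign_invariant_codes <- function(graph) {
  stopifnot(inherits(graph, "tucan_graph"))
  lapply(seq_len(graph$n), function(v) {
    c(graph$Z[[v]], sort(graph$Z[graph$adjacency[[v]]], decreasing = TRUE))
  })
}

#' Initial partition from invariant codes
#'
#' Nodes with identical invariant codes share a cell. Cells are numbered in
#' increasing code order (atomic number first, then the decreasing neighbor
#' multiset compared lexicographically), so cell 1 holds the lightest, least
#' connected atoms.
#'
#' @param codes List of invariant codes from [assign_invariant_codes()].
#' @return Integer vector: cell index (1-based) per node.
#' @export
initial_partition <- function(codes) {
  n <- length(codes)
  len <- lengths(codes)
  m <- matrix(0L, n, max(len))
  for (i in seq_len(n)) m[i, seq_len(len[[i]])] <- codes[[i]]
  row_groups(m)
}

# contiguous group ids for the rows of an integer matrix, numbered in
# lexicographic row order (zero-padding at the tail, so shorter content
# sorts first) -- the single source of cell-numbering determinism
row_groups <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(1L)
  o <- do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
  ms <- m[o, , drop = FALSE]
  changed <- rowSums(ms[-1L, , drop = FALSE] != ms[-n, , drop = FALSE]) > 0L
  grp <- integer(n)
  grp[o] <- cumsum(c(TRUE, changed))
  grp
}

#' Weisfeiler-Lehman partition refinement
#'
#' Iteratively splits every cell by the multiset of neighbor cell indices
#' until no node can be assigned to a new cell (the partition is equitable).
#' Cells are never merged; rerunning on a stable partition is the identity.
#'
#' @param graph A [molecular_graph()].
#' @param partition Integer vector of cell indices per node.
#' @return The stable (equitable) partition as an integer vector.
#' @export
refine_partitions <- function(graph, partition) {
  refine_rounds(graph, partition)$partition
}

# as refine_partitions, but keeps each round for tracing.
# Refinement key of a node: (own cell, ascending multiset of neighbor
# cells), laid out as one matrix row; row_groups() renumbers the cells, so
# parent cell order is preserved and cells are never merged.
refine_rounds <- function(graph, partition) {
  stopifnot(inherits(graph, "tucan_graph"), length(partition) == graph$n)
  n <- graph$n
  rounds <- list()
  if (n == 1L) return(list(partition = 1L, rounds = rounds))
  width <- max(graph$deg) + 1L
  repeat {
    m <- matrix(0L, n, width)
    m[, 1L] <- partition
    nc <- partition[graph$dst]
    o <- order(graph$src, nc)
    m[graph$slot] <- nc[o]
    np <- row_groups(m)
    if (max(np) == max(partition)) break
    partition <- np
    rounds[[length(rounds) + 1L]] <- np
  }
  list(partition = partition, rounds = rounds)
}


# serialized-form key of a labeling: the edge-tuple stream as a flat
# integer vector, plus the feature stream as flattened (label, feature-rank)
# pairs where ranks order the serialized feature strings. Compared
# lexicographically, edges first. Numeric labels (not string bytes) keep the
# comparison consistent across the 9/10 label boundary.
form_key <- function(graph, labels) {
  e <- graph$edges
  edge_key <- integer(0)
  if (nrow(e) > 0L) {
    a <- pmin(labels[e[, 1L]], labels[e[, 2L]])
    b <- pmax(labels[e[, 1L]], labels[e[, 2L]])
    ord <- order(a, b)
    edge_key <- as.integer(rbind(a[ord], b[ord]))
  }
  fr <- feature_ranks(graph)
  has <- which(fr > 0L)
  feat_key <- integer(0)
  if (length(has) > 0L) {
    has <- has[order(labels[has])]
    feat_key <- as.integer(rbind(labels[has], fr[has]))
  }
  list(edge = edge_key, feat = feat_key)
}

# 0 = no features; otherwise 1-based rank of the serialized field string
feature_ranks <- function(graph) {
  fs <- vapply(graph$features, function(f) {
    if (is.null(f)) "" else paste0(names(f), "=", f, collapse = ",")
  }, character(1L))
  out <- ifelse(fs == "", 0L, match(fs, sort.int(unique(fs[fs != ""]), method = "radix")))
  as.integer(out)
}

key_less <- function(a, b) {
  d <- which(a$edge != b$edge)
  if (length(d) > 0L) return(a$edge[[d[[1L]]]] < b$edge[[d[[1L]]]])
  la <- a$feat; lb <- b$feat
  m <- min(length(la), length(lb))
  if (m > 0L) {
    d <- which(la[seq_len(m)] != lb[seq_len(m)])
    if (length(d) > 0L) return(la[[d[[1L]]]] < lb[[d[[1L]]]])
  }
  length(la) < length(lb)
}

# v and w are interchangeable by an automorphism that branching cannot tell
# apart iff they carry identical features and their neighborhoods outside
# the pair coincide -- either exactly (transposition twins), or up to a
# matching of pendant (degree-1) neighbors with equal element and features
# (swapping v, w together with their pendant leaves: covers NH3, CO and
# similar terminal ligands). Branching on only one of them cannot change
# the minimum.
nodes_are_twins <- function(graph, v, w) {
  if (!identical(graph$features[[v]], graph$features[[w]])) return(FALSE)
  sv <- setdiff(graph$adjacency[[v]], w)
  sw <- setdiff(graph$adjacency[[w]], v)
  if (identical(sv, sw)) return(TRUE)
  pv <- setdiff(sv, sw)
  pw <- setdiff(sw, sv)
  if (length(pv) != length(pw)) return(FALSE)
  if (any(graph$deg[pv] != 1L) || any(graph$deg[pw] != 1L)) return(FALSE)
  leaf_key <- function(nodes) {
    sort(vapply(nodes, function(u) {
      paste(c(graph$Z[[u]], graph$features[[u]],
              names(graph$features[[u]])), collapse = "|")
    }, character(1L)), method = "radix")
  }
  identical(leaf_key(pv), leaf_key(pw))
}

#' Canonical labeling of a molecular graph
#'
#' Computes a bijection node -> canonical label in `1:n` such that the
#' serialized identifier under that labeling is the lexicographically
#' smallest achievable over *all* labelings that respect element grouping
#' (labels ascending by atomic number; edge-tuple stream compared first,
#' feature block second). Because the minimum is unique, the resulting
#' identifier is invariant under any permutation of the input atom order.
#'
#' The minimum is found by exact branch and bound. Element blocks are
#' assigned from the heaviest element down; within a block, positions are
#' filled in ascending label order. Three sound prunings keep the search
#' small: an admissible optimistic bound on the flattened tuple stream,
#' twin pruning (candidates interchangeable by a transposition or
#' pendant-matching automorphism), and automorphism pruning (whenever two
#' complete labelings serialize identically, the permutation relating them
#' is an automorphism; stored generators that fix all assigned atoms and
#' map a candidate onto an explored one prove the branch redundant).
#' Blocks whose members bond only to heavier elements -- hydrogens, in
#' practice -- are never branched over: once the heavy scaffold is placed,
#' their optimal order is forced (rows sorted, ties broken by features).
#'
#' @param graph A [molecular_graph()].
#' @param stable Optional stable partition from [refine_partitions()]; used
#'   only to order the exploration (never changes the result), computed when
#'   omitted.
#' @return Integer vector `labels` with `labels[i]` the canonical label of
#'   node `i`, grouped by ascending atomic number.
#' @examples
#' g <- tucan_graph_fixture("zeise")
#' canonical_labeling(g)
#' @export
canonical_labeling <- function(graph, stable = NULL) {
  stopifnot(inherits(graph, "tucan_graph"))
  n <- graph$n
  if (n == 1L) return(1L)
  if (is.null(stable)) {
    stable <- refine_partitions(graph, initial_partition(assign_invariant_codes(graph)))
  }
  Z <- graph$Z
  adj <- graph$adjacency
  bz <- sort.int(unique(Z), method = "radix")
  nb <- length(bz)
  bid <- match(Z, bz)                      # node -> element block
  bsize <- tabulate(bid, nbins = nb)
  bstart <- cumsum(c(0L, bsize[-nb]))      # block b owns labels bstart[b]+1..
  members <- split(seq_len(n), bid)
  # a block is "deferred" when every member bonds only to heavier elements:
  # its labels appear in no other row of the tuple stream, so its internal
  # order is forced by sorting once the scaffold is placed
  deferred <- vapply(seq_len(nb), function(b) {
    all(vapply(members[[b]], function(v) {
      length(adj[[v]]) == 0L || all(bid[adj[[v]]] > b)
    }, logical(1L)))
  }, logical(1L))
  seqpos <- unlist(lapply(rev(which(!deferred)), function(b) {
    bstart[[b]] + seq_len(bsize[[b]])
  }), use.names = FALSE)
  if (is.null(seqpos)) seqpos <- integer(0)
  res <- canonical_search_cpp(
    n = n, adjacency = adj, bid = bid, bstart = as.integer(bstart),
    bsize = bsize, deferred = deferred, seqpos = as.integer(seqpos),
    stable = as.integer(stable), featrank = feature_ranks(graph),
    twin = twin_matrix(graph), edge_matrix = graph$edges,
    max_generators = 128L
  )
  as.integer(res$labels)
}

# symmetric matrix of candidate interchangeability (see nodes_are_twins);
# only pairs agreeing on element, degree and features can be twins, so
# comparisons are restricted to those groups
twin_matrix <- function(graph) {
  n <- graph$n
  tw <- matrix(FALSE, n, n)
  key <- paste(graph$Z, graph$deg, feature_ranks(graph))
  for (b in split(seq_len(n), key)) {
    if (length(b) < 2L) next
    for (i in seq_along(b)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (nodes_are_twins(graph, b[[i]], b[[j]])) {
          tw[b[[i]], b[[j]]] <- TRUE
          tw[b[[j]], b[[i]]] <- TRUE
        }
      }
    }
  }
  tw
}

#' Brute-force canonical form (test oracle)
#'
#' Enumerates every labeling that respects element grouping (permutations
#' within each element class, labels ascending by atomic number) and returns
#' the lexicographically minimal serialized identifier. Exponential cost --
#' refuses graphs with more than `max_atoms` atoms. Intended as an
#' independent oracle for [canonical_labeling()] on small graphs.
#'
#' @param graph A [molecular_graph()].
#' @param max_atoms Size cap (default 8).
#' @return The minimal identifier string.
#' @export
brute_force_canonical <- function(graph, max_atoms = 8L) {
  stopifnot(inherits(graph, "tucan_graph"))
  if (graph$n > max_atoms) {
    stop("brute-force canonicalization is capped at ", max_atoms, " atoms",
         call. = FALSE)
  }
  # element classes in ascending Z; labels within class are permuted
  ordZ <- order(graph$Z, seq_len(graph$n))
  classes <- split(ordZ, graph$Z[ordZ])  # each: node ids, ascending Z blocks
  offsets <- cumsum(c(0L, vapply(classes, length, integer(1L))))
  perm_sets <- lapply(seq_along(classes), function(i) {
    perms_of(length(classes[[i]]))
  })
  best_key <- NULL
  best_labels <- NULL
  idx <- rep(1L, length(classes))
  n_per <- vapply(perm_sets, nrow, integer(1L))
  repeat {
    labels <- integer(graph$n)
    for (i in seq_along(classes)) {
      labels[classes[[i]]] <- offsets[[i]] + perm_sets[[i]][idx[[i]], ]
    }
    key <- form_key(graph, labels)
    if (is.null(best_key) || key_less(key, best_key)) {
      best_key <- key
      best_labels <- labels
    }
    # advance mixed-radix counter over the class permutations
    j <- 1L
    while (j <= length(idx)) {
      idx[[j]] <- idx[[j]] + 1L
      if (idx[[j]] <= n_per[[j]]) break
      idx[[j]] <- 1L
      j <- j + 1L
    }
    if (j > length(idx)) break
  }
  serialize_with_labels(graph, best_labels)
}

# all permutations of 1..k as a matrix (k! rows)
perms_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                   sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.integer(block)
    r <- r + nrow(sub)
  }
  out
}

#' Per-stage canonicalization trace
#'
#' Returns the intermediate state of every canonicalization stage: invariant
#' codes, the initial partition, the partition after each refinement round,
#' the stable partition, and the final canonical labels. Useful for
#' inspecting how symmetry is broken in a particular molecule.
#'
#' @param graph A [molecular_graph()].
#' @return List with components `codes`, `initial`, `rounds`, `stable`,
#'   `labels`.
#' @export
canonicalization_trace <- function(graph) {
  codes <- assign_invariant_codes(graph)
  initial <- initial_partition(codes)
  ref <- refine_rounds(graph, initial)
  list(codes = codes, initial = initial, rounds = ref$rounds,
       stable = ref$partition,
       labels = canonical_labeling(graph, stable = ref$partition))
}
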