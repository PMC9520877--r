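# molfile v3000 reader/writer.
#
# Only three sets of values are consumed: the COUNTS line, the element symbol
# plus optional CHG/MASS/RAD of each ATOM record, and the two atom indices of
# each BOND record. Coordinates, bond types and every other field are
# discarded -- connectivity and atomic number are all the identifier uses.

FEATURE_FIELDS <- c("CHG", "MASS", "RAD")

#' Construct molfile data from parsed components
#'
#' Low-level constructor for the in-memory representation of a (minimal)
#' molfile: element symbols, per-atom feature fields, and the bond list.
#' Validates bond indices, self-bonds, duplicate bonds and element symbols.
#'
#' @param element Character vector of element symbols, one per atom, in
#'   ATOM-block order.
#' @param bonds Two-column integer matrix of 1-based atom index pairs
#'   (one row per bond), or `NULL` for no bonds.
#' @param features List (length = atom count) of named integer vectors with
#'   names among `CHG`, `MASS`, `RAD`; `NULL` entries mean no fields present.
#'   A field explicitly present with its default value (e.g. `RAD = 0`) is
#'   kept, matching molfile pass-through semantics.
#' @return An object of class `tucan_molfile` with components `atom_count`,
#'   `bond_count`, `element`, `features` and `bonds`.
#' @export
molfile_data <- function(element, bonds = NULL, features = NULL) {
  element <- as.character(element)
  n <- length(element)
  if (n < 1L) stop("a molecule needs at least one atom", call. = FALSE)
  element_to_atomic_number(element)  # validates symbols
  if (is.null(bonds) || (is.matrix(bonds) && nrow(bonds) == 0L)) {
    bonds <- matrix(integer(0), ncol = 2L)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (anyNA(bonds) || any(bonds < 1L) || any(bonds > n)) {
    stop("bond atom index out of range [1, ", n, "]", call. = FALSE)
  }
  if (any(bonds[, 1L] == bonds[, 2L])) {
    stop("self-bond (atom bonded to itself) is not allowed", call. = FALSE)
  }
  key <- paste(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  if (anyDuplicated(key)) {
    stop("duplicate bond between atoms ", key[duplicated(key)][1L], call. = FALSE)
  }
  if (is.null(features)) features <- vector("list", n)
  if (length(features) != n) {
    stop("features must have one entry per atom", call. = FALSE)
  }
  features <- lapply(features, validate_features)
  structure(
    list(atom_count = n, bond_count = nrow(bonds), element = element,
         features = features, bonds = bonds),
    class = "tucan_molfile"
  )
}

validate_features <- function(f) {
  if (is.null(f) || length(f) == 0L) return(NULL)
  f2 <- as.integer(f)
  names(f2) <- names(f)
  if (anyNA(f2) || is.null(names(f2)) || !all(names(f2) %in% FEATURE_FIELDS)) {
    stop("atom features must be named integers among ",
         paste(FEATURE_FIELDS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(f2))) stop("duplicate feature field", call. = FALSE)
  if ("RAD" %in% names(f2) && (f2[["RAD"]] < 0L || f2[["RAD"]] > 3L)) {
    stop("RAD must be in 0..3", call. = FALSE)
  }
  f2[order(names(f2))]
}

#' @export
print.tucan_molfile <- function(x, ...) {
  cat(sprintf("<molfile data: %d atoms, %d bonds>\n", x$atom_count, x$bond_count))
  cat("  formula:", format_hill(hill_formula_counts(x$element)), "\n")
  invisible(x)
}

#' Parse a molfile in v3000 format
#'
#' Reads the connection table of a v3000 molfile: atom/bond counts from the
#' `COUNTS` line, element symbol plus optional `CHG`/`MASS`/`RAD` fields from
#' the ATOM block, and the atom-index pair from each BOND record. Bond types,
#' coordinates and all other fields are discarded. Hydrogens are taken
#' exactly as given: only explicit atoms are considered, implicit hydrogens
#' are never added.
#'
#' Line continuations (`-` at the end of a `M  V30` line) and variable
#' whitespace are tolerated; blocks other than `COUNTS`/`ATOM`/`BOND` are
#' ignored. Unknown element symbols, the `*` pseudo-atom, count/record
#' mismatches, out-of-range bond indices, self-bonds and duplicate bonds are
#' fatal errors.
#'
#' @param text A file path, or a character vector holding the molfile
#'   (either one string with embedded newlines or one element per line).
#' @return A [molfile_data()] object.
#' @examples
#' mol <- parse_molfile_v3000(tucan_fixture_molfile("methane"))
#' mol$atom_count
#' @export
parse_molfile_v3000 <- function(text) {
  lines <- molfile_lines(text)
  v30 <- grepl("^M  V30 ", lines)
  if (!any(v30)) {
    stop("not a v3000 molfile: no 'M  V30' lines found", call. = FALSE)
  }
  body <- sub("^M  V30 ", "", lines[v30])
  # splice line continuations: trailing "-" joins with the next V30 line
  out <- character(0)
  i <- 1L
  while (i <= length(body)) {
    cur <- body[[i]]
    while (grepl("-$", cur) && i < length(body)) {
      i <- i + 1L
      cur <- paste0(sub("-$", "", cur), sub("^\\s+", "", body[[i]]))
    }
    out <- c(out, cur)
    i <- i + 1L
  }
  toks <- lapply(out, function(s) strsplit(trimws(s), "\\s+")[[1L]])

  counts_i <- which(vapply(toks, function(t) length(t) >= 3L && t[[1L]] == "COUNTS", FALSE))
  if (length(counts_i) == 0L) stop("missing 'M  V30 COUNTS' line", call. = FALSE)
  na <- suppressWarnings(as.integer(toks[[counts_i[1L]]][2L]))
  nb <- suppressWarnings(as.integer(toks[[counts_i[1L]]][3L]))
  if (is.na(na) || is.na(nb) || na < 1L || nb < 0L) {
    stop("invalid COUNTS line", call. = FALSE)
  }

  block_range <- function(name) {
    beg <- which(vapply(toks, function(t) length(t) >= 2L &&
                          t[[1L]] == "BEGIN" && t[[2L]] == name, FALSE))
    end <- which(vapply(toks, function(t) length(t) >= 2L &&
                          t[[1L]] == "END" && t[[2L]] == name, FALSE))
    if (length(beg) == 0L) return(NULL)
    if (length(end) == 0L || end[1L] < beg[1L]) {
      stop("unterminated ", name, " block", call. = FALSE)
    }
    if (end[1L] == beg[1L] + 1L) return(integer(0))
    seq.int(beg[1L] + 1L, end[1L] - 1L)
  }

  atom_idx <- block_range("ATOM")
  if (is.null(atom_idx)) stop("missing ATOM block", call. = FALSE)
  if (length(atom_idx) != na) {
    stop("COUNTS declares ", na, " atoms but ATOM block has ",
         length(atom_idx), " records", call. = FALSE)
  }
  element <- character(na)
  features <- vector("list", na)
  for (k in seq_along(atom_idx)) {
    t <- toks[[atom_idx[[k]]]]
    if (length(t) < 6L) stop("malformed ATOM record: ", out[[atom_idx[[k]]]], call. = FALSE)
    idx <- suppressWarnings(as.integer(t[[1L]]))
    if (is.na(idx) || idx != k) {
      stop("ATOM record index ", t[[1L]], " out of sequence (expected ", k, ")",
           call. = FALSE)
    }
    sym <- t[[2L]]
    if (sym == "*") {
      stop("the star (\"*\") pseudo-atom is not supported; ",
           "specify every bond to a real atom explicitly", call. = FALSE)
    }
    element_to_atomic_number(sym)
    element[[k]] <- sym
    kv <- t[-(1:6)]
    kv <- kv[grepl("^(CHG|MASS|RAD)=", kv)]
    if (length(kv) > 0L) {
      nm <- sub("=.*$", "", kv)
      val <- suppressWarnings(as.integer(sub("^[A-Z]+=", "", kv)))
      if (anyNA(val)) stop("non-integer value in ATOM fields: ",
                           paste(kv, collapse = " "), call. = FALSE)
      features[[k]] <- stats::setNames(val, nm)
    }
  }

  bond_idx <- block_range("BOND")
  if (is.null(bond_idx)) bond_idx <- integer(0)
  if (length(bond_idx) != nb) {
    stop("COUNTS declares ", nb, " bonds but BOND block has ",
         length(bond_idx), " records", call. = FALSE)
  }
  bonds <- matrix(integer(0), ncol = 2L)
  if (nb > 0L) {
    bonds <- t(vapply(toks[bond_idx], function(t) {
      if (length(t) < 4L) stop("malformed BOND record", call. = FALSE)
      ab <- suppressWarnings(as.integer(t[3:4]))
      if (anyNA(ab)) stop("non-integer atom index in BOND record", call. = FALSE)
      ab
    }, integer(2L)))
  }
  molfile_data(element, bonds, features)
}

molfile_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

#' Write a molecular graph as a v3000 molfile
#'
#' Emits a syntactically valid, coordinate-free v3000 molfile: atoms in node
#' order with zeroed coordinates, all bonds as type 1, and `CHG`/`MASS`/`RAD`
#' fields only for atoms that carry them. Re-parsing the output reproduces
#' the graph's atoms, features and edge set.
#'
#' @param graph A [molecular_graph()] (or a [molfile_data()] object).
#' @param title Optional title for the molfile header line.
#' @return A single string holding the molfile document.
#' @examples
#' g <- tucan_deserialize("CH4/(1-5)(2-5)(3-5)(4-5)")
#' cat(write_molfile_v3000(g))
#' @export
write_molfile_v3000 <- function(graph, title = "") {
  if (inherits(graph, "tucan_molfile")) graph <- build_graph(graph)
  stopifnot(inherits(graph, "tucan_graph"))
  n <- graph$n
  bonds <- graph$edges
  atom_lines <- vapply(seq_len(n), function(i) {
    f <- graph$features[[i]]
    extra <- if (is.null(f)) "" else
      paste0(" ", paste0(names(f), "=", unname(f), collapse = " "))
    sprintf("M  V30 %d %s 0.0 0.0 0.0 0%s", i, graph$element[[i]], extra)
  }, character(1L))
  bond_lines <- if (nrow(bonds) == 0L) character(0) else
    sprintf("M  V30 %d 1 %d %d", seq_len(nrow(bonds)), bonds[, 1L], bonds[, 2L])
  paste(c(
    title, "  tucan", "",
    "  0  0  0     0  0            999 V3000",
    "M  V30 BEGIN CTAB",
    sprintf("M  V30 COUNTS %d %d 0 0 0", n, nrow(bonds)),
    "M  V30 BEGIN ATOM", atom_lines, "M  V30 END ATOM",
    if (nrow(bonds) > 0L) c("M  V30 BEGIN BOND", bond_lines, "M  V30 END BOND"),
    "M  V30 END CTAB", "M  END", ""
  ), collapse = "\n")
}
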