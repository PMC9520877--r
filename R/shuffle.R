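# Permutation (shuffle) validation: the identifier must be bit-identical for
# every atom input ordering of the same molecule.

#' Apply a random atom-order permutation to molfile data
#'
#' Reorders the atom records and remaps the bond indices consistently,
#' yielding an isomorphic description of the same molecule.
#'
#' @param data A [molfile_data()] object.
#' @param order Integer vector: new atom order (position `k` takes old atom
#'   `order[k]`); a random permutation when omitted.
#' @return A [molfile_data()] object.
#' @export
shuffle_atoms <- function(data, order = sample(data$atom_count)) {
  stopifnot(inherits(data, "tucan_molfile"))
  n <- data$atom_count
  order <- as.integer(order)
  if (!setequal(order, seq_len(n))) {
    stop("order must be a permutation of 1:", n, call. = FALSE)
  }
  inv <- integer(n)
  inv[order] <- seq_len(n)
  b <- data$bonds
  if (nrow(b) > 0L) b <- cbind(inv[b[, 1L]], inv[b[, 2L]])
  molfile_data(data$element[order], b, data$features[order])
}

#' Shuffle test: permutation invariance of the identifier
#'
#' Canonicalizes and serializes `permutations` random atom-order permutations
#' of a molecule and checks that every run yields the same string. This is
#' the core validation protocol for any canonicalization scheme.
#'
#' @param data A [molfile_data()] object (or a [molecular_graph()]).
#' @param permutations Number of random permutations (default 100).
#' @param seed Integer seed for the permutation stream; the caller's RNG
#'   state is left untouched.
#' @param serializer Function mapping molfile data to a string; the package
#'   serializer by default (injectable so the harness itself can be tested
#'   against a deliberately order-sensitive serializer).
#' @return List with `pass` (logical), `n_unique`, `reference` (the string),
#'   and on failure `mismatch`, the first differing string.
#' @examples
#' shuffle_test(tucan_fixture("zeise"), permutations = 10, seed = 1)$pass
#' @export
shuffle_test <- function(data, permutations = 100L, seed = 1L,
                         serializer = NULL) {
  if (inherits(data, "tucan_graph")) {
    data <- molfile_data(data$element, data$edges, data$features)
  }
  stopifnot(inherits(data, "tucan_molfile"), permutations >= 1L)
  if (is.null(serializer)) {
    serializer <- function(d) tucan_serialize(build_graph(d))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  reference <- serializer(data)
  for (k in seq_len(permutations)) {
    s <- serializer(shuffle_atoms(data))
    if (s != reference) {
      return(list(pass = FALSE, n_unique = 2L, reference = reference,
                  mismatch = s, at_permutation = k))
    }
  }
  list(pass = TRUE, n_unique = 1L, reference = reference)
}
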