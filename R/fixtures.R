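# Built-in fixture library: molecules spanning organic, main-group and
# organometallic chemistry (all with explicit hydrogens), plus highly
# symmetric element-uniform "difficult" graphs (emitted as all-carbon
# pseudo-molecules so that only topology discriminates). Everything is
# generated in code and bit-reproducible.

ring_edges <- function(n, offset = 0L) {
  cbind(offset + seq_len(n), offset + c(seq_len(n)[-1L], 1L))
}

path_edges <- function(n, offset = 0L) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(offset + seq_len(n - 1L), offset + seq_len(n - 1L) + 1L)
}

# append h[i] explicit hydrogens to heavy atom i
with_hydrogens <- function(heavy, bonds, h, features = NULL) {
  n0 <- length(heavy)
  element <- c(heavy, rep("H", sum(h)))
  extra <- cbind(rep(seq_len(n0), h), n0 + seq_len(sum(h)))
  if (!is.null(features)) features <- c(features, vector("list", sum(h)))
  molfile_data(element, rbind(bonds, extra), features)
}

alkane <- function(k) {
  h <- if (k == 1L) 4L else c(3L, rep(2L, k - 2L), 3L)
  with_hydrogens(rep("C", k), path_edges(k), h)
}

star_molecule <- function(center, leaves) {
  n <- length(leaves)
  molfile_data(c(center, leaves), cbind(1L, 1L + seq_len(n)))
}

uniform_graph <- function(edges, n) {
  molfile_data(rep("C", n), edges)
}

complete_edges <- function(n) {
  t(utils::combn(n, 2L))
}

bipartite_edges <- function(a, b) {
  as.matrix(expand.grid(seq_len(a), a + seq_len(b)))
}

hypercube_edges <- function(d) {
  v <- 0:(2L^d - 1L)
  e <- NULL
  for (bit in 0:(d - 1L)) {
    u <- v[bitwAnd(v, bitwShiftL(1L, bit)) == 0L]
    e <- rbind(e, cbind(u + 1L, bitwOr(u, bitwShiftL(1L, bit)) + 1L))
  }
  e
}

prism_edges <- function(n) {
  rbind(ring_edges(n), ring_edges(n, offset = n), cbind(seq_len(n), n + seq_len(n)))
}

circulant_edges <- function(n, jumps) {
  e <- NULL
  for (j in jumps) e <- rbind(e, cbind(seq_len(n), ((seq_len(n) - 1L + j) %% n) + 1L))
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

# Cayley graph on Z4 x Z4 with connection set {+-(1,0), +-(0,1), +-(1,1)};
# strongly regular (16, 6, 2, 2), cospectral with the 4x4 rook's graph but
# not isomorphic to it -- a classic canonicalization stress case
shrikhande_edges <- function() {
  id <- function(x, y) (x %% 4L) * 4L + (y %% 4L) + 1L
  e <- NULL
  for (x in 0:3) for (y in 0:3) {
    for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
      e <- rbind(e, c(id(x, y), id(x + d[[1L]], y + d[[2L]])))
    }
  }
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

rook_edges <- function(k) {
  id <- function(r, c) (r - 1L) * k + c
  e <- NULL
  for (r in seq_len(k)) e <- rbind(e, complete_edges(k) + (r - 1L) * k)
  for (c in seq_len(k)) {
    rows <- t(utils::combn(k, 2L))
    e <- rbind(e, cbind(id(rows[, 1L], c), id(rows[, 2L], c)))
  }
  e
}

petersen_edges <- function() {
  rbind(ring_edges(5L),                       # outer pentagon
        cbind(5L + seq_len(5L), 5L + c(3L, 4L, 5L, 1L, 2L)),  # inner pentagram
        cbind(seq_len(5L), 5L + seq_len(5L)))  # spokes
}

zeise_fixture <- function() {
  # trichloro(ethylene)platinate(II) anion: PtCl3(C2H4), charge -1 overall
  element <- c("Cl", "Cl", "Cl", "Pt", "C", "C", "H", "H", "H", "H")
  bonds <- rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L),   # Pt-Cl
                 c(4L, 5L), c(4L, 6L), c(5L, 6L),   # Pt-C, C-C
                 c(5L, 7L), c(5L, 8L), c(6L, 9L), c(6L, 10L))
  features <- list(c(CHG = -1L), c(CHG = -1L), c(CHG = -1L),
                   c(CHG = 2L, MASS = 196L, RAD = 0L),
                   NULL, NULL, NULL, NULL, NULL, NULL)
  molfile_data(element, bonds, features)
}

bicyclooctenone_fixture <- function() {
  # bicyclo[5.1.0]oct-1(7)-en-8-one, C8H10O: seven-membered ring C1..C7,
  # cyclopropanone bridge C8 across C1-C7, ketone O on C8, 2 H on C2..C6
  heavy <- c(rep("C", 8L), "O")
  bonds <- rbind(ring_edges(7L), c(1L, 8L), c(7L, 8L), c(8L, 9L))
  with_hydrogens(heavy, bonds, c(0L, 2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L))
}

ferrocene_fixture <- function() {
  # Fe1, cyclopentadienyl rings C2..C6 and C7..C11, one H per ring carbon;
  # all ten Fe-C bonds explicit (no multi-center star atom)
  heavy <- c("Fe", rep("C", 10L))
  bonds <- rbind(ring_edges(5L, offset = 1L), ring_edges(5L, offset = 6L),
                 cbind(1L, 1L + seq_len(10L)))
  with_hydrogens(heavy, bonds, c(0L, rep(1L, 10L)))
}

metal_carbonyl <- function(metal, k) {
  # M(CO)k: M1, carbons 2..k+1, oxygens k+2..2k+1
  element <- c(metal, rep("C", k), rep("O", k))
  bonds <- rbind(cbind(1L, 1L + seq_len(k)), cbind(1L + seq_len(k), 1L + k + seq_len(k)))
  molfile_data(element, bonds)
}

fixture_builders <- function() {
  fx <- list()
  add <- function(name, category, fun) {
    fx[[name]] <<- list(category = category, fun = fun)
  }

  ## organic
  alk <- c("methane", "ethane", "propane", "butane", "pentane", "hexane",
           "heptane", "octane")
  for (k in seq_along(alk)) {
    local({kk <- k; add(alk[[kk]], "organic", function() alkane(kk))})
  }
  cyc <- c("cyclopropane", "cyclobutane", "cyclopentane", "cyclohexane",
           "cycloheptane", "cyclooctane")
  for (k in seq_along(cyc)) {
    local({n <- k + 2L
           add(cyc[[k]], "organic", function()
             with_hydrogens(rep("C", n), ring_edges(n), rep(2L, n)))})
  }
  add("benzene", "organic", function()
    with_hydrogens(rep("C", 6L), ring_edges(6L), rep(1L, 6L)))
  add("naphthalene", "organic", function() {
    bonds <- rbind(ring_edges(6L), c(1L, 7L), c(7L, 8L), c(8L, 9L),
                   c(9L, 10L), c(10L, 2L))
    with_hydrogens(rep("C", 10L), bonds, c(0L, 0L, rep(1L, 8L)))
  })
  add("ethylene", "organic", function()
    with_hydrogens(c("C", "C"), path_edges(2L), c(2L, 2L)))
  add("acetylene", "organic", function()
    with_hydrogens(c("C", "C"), path_edges(2L), c(1L, 1L)))
  add("propene", "organic", function()
    with_hydrogens(rep("C", 3L), path_edges(3L), c(2L, 1L, 3L)))
  add("butadiene", "organic", function()
    with_hydrogens(rep("C", 4L), path_edges(4L), c(2L, 1L, 1L, 2L)))
  add("methanol", "organic", function()
    with_hydrogens(c("C", "O"), path_edges(2L), c(3L, 1L)))
  add("ethanol", "organic", function()
    with_hydrogens(c("C", "C", "O"), path_edges(3L), c(3L, 2L, 1L)))
  add("dimethyl_ether", "organic", function()
    with_hydrogens(c("C", "O", "C"), path_edges(3L), c(3L, 0L, 3L)))
  add("formaldehyde", "organic", function()
    with_hydrogens(c("C", "O"), path_edges(2L), c(2L, 0L)))
  add("acetone", "organic", function()
    with_hydrogens(c("C", "C", "C", "O"), rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)),
                   c(3L, 0L, 3L, 0L)))
  add("formic_acid", "organic", function()
    with_hydrogens(c("C", "O", "O"), rbind(c(1L, 2L), c(1L, 3L)), c(1L, 0L, 1L)))
  add("acetic_acid", "organic", function()
    with_hydrogens(c("C", "C", "O", "O"), rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)),
                   c(3L, 0L, 0L, 1L)))
  add("methylamine", "organic", function()
    with_hydrogens(c("C", "N"), path_edges(2L), c(3L, 2L)))
  add("acetonitrile", "organic", function()
    with_hydrogens(c("C", "C", "N"), path_edges(3L), c(3L, 0L, 0L)))
  add("glycine", "organic", function()
    with_hydrogens(c("N", "C", "C", "O", "O"),
                   rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(3L, 5L)),
                   c(2L, 2L, 0L, 0L, 1L)))
  halides <- c(F = "methyl_fluoride", Cl = "methyl_chloride",
               Br = "methyl_bromide", I = "methyl_iodide")
  for (x in names(halides)) {
    local({hal <- x
           add(halides[[hal]], "organic", function()
             with_hydrogens(c("C", hal), path_edges(2L), c(3L, 0L)))})
  }
  add("bicyclooctenone", "organic", bicyclooctenone_fixture)
  add("methane_13c", "organic", function()
    molfile_data(c("C", "H", "H", "H", "H"), cbind(1L, 2:5),
                 list(c(MASS = 13L), NULL, NULL, NULL, NULL)))
  add("methyl_radical", "organic", function()
    molfile_data(c("C", "H", "H", "H"), cbind(1L, 2:4),
                 list(c(RAD = 2L), NULL, NULL, NULL)))

  ## main group / clusters / small species
  add("water", "main-group", function()
    with_hydrogens("O", NULL, 2L))
  add("heavy_water", "main-group", function()
    molfile_data(c("O", "H", "H"), rbind(c(1L, 2L), c(1L, 3L)),
                 list(NULL, c(MASS = 2L), c(MASS = 2L))))
  add("ammonia", "main-group", function() with_hydrogens("N", NULL, 3L))
  add("hydrogen_peroxide", "main-group", function()
    with_hydrogens(c("O", "O"), path_edges(2L), c(1L, 1L)))
  add("hydrazine", "main-group", function()
    with_hydrogens(c("N", "N"), path_edges(2L), c(2L, 2L)))
  add("carbon_dioxide", "main-group", function()
    molfile_data(c("C", "O", "O"), rbind(c(1L, 2L), c(1L, 3L))))
  add("carbon_monoxide", "main-group", function()
    molfile_data(c("C", "O"), rbind(c(1L, 2L))))
  add("hydrogen_cyanide", "main-group", function()
    with_hydrogens(c("C", "N"), path_edges(2L), c(1L, 0L)))
  add("dihydrogen", "main-group", function()
    molfile_data(c("H", "H"), rbind(c(1L, 2L))))
  add("dinitrogen", "main-group", function()
    molfile_data(c("N", "N"), rbind(c(1L, 2L))))
  add("dioxygen", "main-group", function()
    molfile_data(c("O", "O"), rbind(c(1L, 2L))))
  add("diborane", "main-group", function() {
    # B2H6 with the two bridging hydrogens bonded to both borons
    element <- c("B", "B", rep("H", 6L))
    bonds <- rbind(c(1L, 3L), c(1L, 4L), c(2L, 5L), c(2L, 6L),
                   c(1L, 7L), c(2L, 7L), c(1L, 8L), c(2L, 8L))
    molfile_data(element, bonds)
  })
  add("white_phosphorus", "main-group", function()
    molfile_data(rep("P", 4L), complete_edges(4L)))
  add("octasulfur", "main-group", function()
    molfile_data(rep("S", 8L), ring_edges(8L)))
  add("sulfur_hexafluoride", "main-group", function()
    star_molecule("S", rep("F", 6L)))
  add("phosphorus_pentafluoride", "main-group", function()
    star_molecule("P", rep("F", 5L)))
  add("xenon_tetrafluoride", "main-group", function()
    star_molecule("Xe", rep("F", 4L)))
  add("boron_trifluoride", "main-group", function()
    star_molecule("B", rep("F", 3L)))
  add("silane", "main-group", function() with_hydrogens("Si", NULL, 4L))
  add("hydrogen_sulfide", "main-group", function() with_hydrogens("S", NULL, 2L))
  add("phosphine", "main-group", function() with_hydrogens("P", NULL, 3L))
  add("hydroxide", "main-group", function()
    molfile_data(c("O", "H"), rbind(c(1L, 2L)), list(c(CHG = -1L), NULL)))
  add("ammonium", "main-group", function()
    molfile_data(c("N", rep("H", 4L)), cbind(1L, 2:5),
                 c(list(c(CHG = 1L)), vector("list", 4L))))
  add("sodium_chloride", "main-group", function()
    molfile_data(c("Na", "Cl"), NULL, list(c(CHG = 1L), c(CHG = -1L))))
  add("helium", "main-group", function() molfile_data("He"))
  add("neon", "main-group", function() molfile_data("Ne"))

  ## coordination / organometallic
  add("zeise", "organometallic", zeise_fixture)
  add("ferrocene", "organometallic", ferrocene_fixture)
  add("nickel_tetracarbonyl", "organometallic", function()
    metal_carbonyl("Ni", 4L))
  add("iron_pentacarbonyl", "organometallic", function()
    metal_carbonyl("Fe", 5L))
  add("hexaamminecobalt", "organometallic", function() {
    element <- c("Co", rep("N", 6L), rep("H", 18L))
    bonds <- rbind(cbind(1L, 1L + seq_len(6L)),
                   cbind(rep(1L + seq_len(6L), each = 3L), 7L + seq_len(18L)))
    molfile_data(element, bonds,
                 c(list(c(CHG = 3L)), vector("list", 24L)))
  })
  add("cisplatin", "organometallic", function() {
    element <- c("Pt", "N", "N", "Cl", "Cl", rep("H", 6L))
    bonds <- rbind(cbind(1L, 2:5),
                   cbind(rep(2:3, each = 3L), 5L + seq_len(6L)))
    molfile_data(element, bonds)
  })

  ## difficult element-uniform graphs
  add("cube", "difficult-graph", function()
    uniform_graph(hypercube_edges(3L), 8L))
  add("hypercube-4", "difficult-graph", function()
    uniform_graph(hypercube_edges(4L), 16L))
  add("petersen", "difficult-graph", function()
    uniform_graph(petersen_edges(), 10L))
  add("cycle-12", "difficult-graph", function()
    uniform_graph(ring_edges(12L), 12L))
  add("complete-4", "difficult-graph", function()
    uniform_graph(complete_edges(4L), 4L))
  add("complete-5", "difficult-graph", function()
    uniform_graph(complete_edges(5L), 5L))
  add("complete-6", "difficult-graph", function()
    uniform_graph(complete_edges(6L), 6L))
  add("bipartite-3-3", "difficult-graph", function()
    uniform_graph(bipartite_edges(3L, 3L), 6L))
  add("bipartite-4-4", "difficult-graph", function()
    uniform_graph(bipartite_edges(4L, 4L), 8L))
  add("prism-5", "difficult-graph", function()
    uniform_graph(prism_edges(5L), 10L))
  add("prism-6", "difficult-graph", function()
    uniform_graph(prism_edges(6L), 12L))
  add("moebius-8", "difficult-graph", function()
    uniform_graph(rbind(ring_edges(8L), cbind(1:4, 5:8)), 8L))
  add("circulant-13-1-5", "difficult-graph", function()
    uniform_graph(circulant_edges(13L, c(1L, 5L)), 13L))
  add("shrikhande", "difficult-graph", function()
    uniform_graph(shrikhande_edges(), 16L))
  add("rook-4", "difficult-graph", function()
    uniform_graph(rook_edges(4L), 16L))

  fx
}

.fixture_cache <- new.env(parent = emptyenv())

fixture_db <- function() {
  if (is.null(.fixture_cache$db)) .fixture_cache$db <- fixture_builders()
  .fixture_cache$db
}

#' Names of the built-in fixtures
#'
#' @param category Optional filter: one of `"organic"`, `"main-group"`,
#'   `"organometallic"`, `"difficult-graph"`.
#' @return Character vector of fixture names.
#' @examples
#' length(tucan_fixture_names())
#' tucan_fixture_names("difficult-graph")
#' @export
tucan_fixture_names <- function(category = NULL) {
  db <- fixture_db()
  nm <- names(db)
  if (!is.null(category)) {
    cats <- vapply(db, `[[`, character(1L), "category")
    if (!category %in% cats) stop("unknown fixture category: ", category, call. = FALSE)
    nm <- nm[cats == category]
  }
  nm
}

#' Generate a built-in fixture molecule
#'
#' Deterministically constructs one of the built-in fixture molecules or
#' difficult graphs as molfile data. Difficult graphs are element-uniform
#' (all carbon), so only their topology discriminates nodes.
#'
#' @param name Fixture name; see [tucan_fixture_names()].
#' @return A [molfile_data()] object.
#' @examples
#' tucan_fixture("zeise")
#' @export
tucan_fixture <- function(name) {
  db <- fixture_db()
  if (!name %in% names(db)) stop("unknown fixture: ", sQuote(name), call. = FALSE)
  db[[name]]$fun()
}

#' Built-in fixture as a molecular graph
#'
#' @param name Fixture name; see [tucan_fixture_names()].
#' @return A [molecular_graph()].
#' @export
tucan_graph_fixture <- function(name) {
  build_graph(tucan_fixture(name))
}

#' Built-in fixture as v3000 molfile text
#'
#' @param name Fixture name; see [tucan_fixture_names()].
#' @return Molfile document as a single string.
#' @export
tucan_fixture_molfile <- function(name) {
  write_molfile_v3000(build_graph(tucan_fixture(name)), title = name)
}

#' Built-in fixture as plain edge-list text
#'
#' One `a b` pair per line (1-based atom indices), preceded by a comment
#' line with the atom count -- a convenient exchange format for the
#' element-uniform difficult graphs.
#'
#' @param name Fixture name; see [tucan_fixture_names()].
#' @return Character vector of lines.
#' @export
tucan_fixture_edgelist <- function(name) {
  d <- tucan_fixture(name)
  c(sprintf("# %s: %d nodes, %d edges", name, d$atom_count, d$bond_count),
    sprintf("%d %d", d$bonds[, 1L], d$bonds[, 2L]))
}
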