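# A v3000 molfile for Zeise's anion written the way a drawing program
# would: real coordinates, bond types, explicit CHG/MASS/RAD fields, and an
# atom order different from the fixture's. Exercises the parser on
# realistic input rather than on our own writer's output.
zeise_molfile_text <- function() {
  paste(c(
    "zeise",
    "  ChemDraw",
    "",
    "  0  0  0     0  0            999 V3000",
    "M  V30 BEGIN CTAB",
    "M  V30 COUNTS 10 10 0 0 0",
    "M  V30 BEGIN ATOM",
    "M  V30 1 C -0.7145 0.4125 0.0000 0",
    "M  V30 2 C -0.7145 -0.4125 0.0000 0",
    "M  V30 3 Pt 0.5774 0.0000 0.0000 0 CHG=2 MASS=196 RAD=0",
    "M  V30 4 Cl 1.4024 0.7145 0.0000 0 CHG=-1",
    "M  V30 5 Cl 1.4024 -0.7145 0.0000 0 CHG=-1",
    "M  V30 6 Cl 0.5774 -1.0000 0.0000 0 CHG=-1",
    "M  V30 7 H -1.2145 0.9125 0.0000 0",
    "M  V30 8 H -0.2145 0.9125 0.0000 0",
    "M  V30 9 H -1.2145 -0.9125 0.0000 0",
    "M  V30 10 H -0.2145 -0.9125 0.0000 0",
    "M  V30 END ATOM",
    "M  V30 BEGIN BOND",
    "M  V30 1 2 1 2",
    "M  V30 2 1 1 3",
    "M  V30 3 1 2 3",
    "M  V30 4 1 3 4",
    "M  V30 5 1 3 5",
    "M  V30 6 1 3 6",
    "M  V30 7 1 1 7",
    "M  V30 8 1 1 8",
    "M  V30 9 1 2 9",
    "M  V30 10 1 2 10",
    "M  V30 END BOND",
    "M  V30 END CTAB",
    "M  END"
  ), collapse = "\n")
}

ZEISE_STRING <- paste0(
  "C2H4Cl3Pt/(1-5)(2-5)(3-6)(4-6)(5-6)(5-10)(6-10)(7-10)(8-10)(9-10)/",
  "(7:CHG=-1)(8:CHG=-1)(9:CHG=-1)(10:CHG=2,MASS=196,RAD=0)"
)

# molfile data for a random graph, used in property-style tests
random_molfile <- function(n, elements = c("C", "N", "O", "H"), p_edge = 0.4) {
  el <- sample(elements, n, replace = TRUE)
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  molfile_data(el, if (any(keep)) pairs[keep, , drop = FALSE] else NULL)
}

expect_isomorphic <- function(g1, g2) {
  ig <- function(g) {
    gr <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, g$n - igraph::vcount(gr)))
    igraph::set_vertex_attr(gr, "Z", value = g$Z)
  }
  expect_true(igraph::isomorphic(ig(g1), ig(g2),
                                 method = "vf2",
                                 vertex.color1 = g1$Z, vertex.color2 = g2$Z))
}
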