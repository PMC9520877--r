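test_that("the Zeise string parses back to labeled atoms, edges and features", {
  p <- parse_tucan_string(ZEISE_STRING)
  expect_equal(p$n, 10L)
  # formula expansion follows ascending atomic number, not Hill print order
  expect_identical(p$element, c(rep("H", 4), rep("C", 2), rep("Cl", 3), "Pt"))
  expect_equal(nrow(p$edges), 10L)
  expect_identical(p$features[[7L]], c(CHG = -1L))
  expect_identical(p$features[[10L]], c(CHG = 2L, MASS = 196L, RAD = 0L))

  ne <- parse_tucan_string("Ne")
  expect_equal(ne$n, 1L)
  expect_equal(nrow(ne$edges), 0L)
})

test_that("malformed strings are rejected with the offending token named", {
  expect_error(parse_tucan_string("C2H4Cl3Pt/(5-1)"), "ascending")
  expect_error(parse_tucan_string("CH4/(1-5)(1-5)(2-5)(3-5)"), "sorted strictly")
  expect_error(parse_tucan_string("CH4/(2-5)(1-5)(3-5)(4-5)"), "sorted strictly")
  expect_error(parse_tucan_string("CH4/(1-9)"), "out of range")
  expect_error(parse_tucan_string("H2/(1:FOO=1)"), "unknown feature field")
  expect_error(parse_tucan_string("H2/(1:MASS=2,CHG=1)"), "lexicographic")
  expect_error(parse_tucan_string("H2/(2:CHG=1)(1:CHG=1)"), "sorted by increasing")
  expect_error(parse_tucan_string("H2/(9:CHG=1)"), "out of range")
  expect_error(parse_tucan_string("C2H4 /(1-5)"), "whitespace")
  expect_error(parse_tucan_string("CxH4"), "unknown element")
  expect_error(parse_tucan_string("C0H4"), "invalid element count")
  expect_error(parse_tucan_string("CH4C2"), "repeated")
  expect_error(parse_tucan_string(""), "formula")
})

test_that("a reserved fourth block is accepted verbatim and ignored", {
  p <- parse_tucan_string("CH4/(1-5)(2-5)(3-5)(4-5)//future-custom-data")
  expect_equal(p$n, 5L)
  expect_identical(p$extra, "future-custom-data")
  expect_identical(tucan_serialize(to_graph(p)), "CH4/(1-5)(2-5)(3-5)(4-5)")
})

test_that("canonical strings are fixed points of deserialize-then-serialize", {
  for (f in tucan_fixture_names()) {
    s <- tucan_serialize(build_graph(tucan_fixture(f)))
    g <- tucan_deserialize(s)
    expect_identical(tucan_serialize(g), s, label = f)
  }
})

test_that("deserialization reconstructs a graph isomorphic to the original", {
  for (f in c("zeise", "ferrocene", "bicyclooctenone", "diborane", "petersen",
              "sodium_chloride")) {
    g <- build_graph(tucan_fixture(f))
    h <- tucan_deserialize(tucan_serialize(g))
    expect_equal(h$n, g$n)
    expect_identical(sort(table(h$element), method = "radix"),
                     sort(table(g$element), method = "radix"))
    expect_identical(sort(lengths(h$adjacency)), sort(lengths(g$adjacency)))
    expect_isomorphic(g, h)
    # feature multisets survive
    fs <- function(x) sort(vapply(x$features, function(f2)
      paste(names(f2), f2, collapse = ";"), character(1)), method = "radix")
    expect_identical(fs(h), fs(g))
  }
})

test_that("non-canonical but grammatical strings re-canonicalize; strict rejects", {
  # a hand-numbered ethanol string with the hydroxyl H non-canonically at 1
  s <- "C2H6O/(1-9)(2-7)(3-7)(4-7)(5-8)(6-8)(7-8)(8-9)"
  g <- tucan_deserialize(s)
  rs <- tucan_serialize(g)
  expect_false(rs == s)
  expect_identical(tucan_serialize(tucan_deserialize(rs)), rs)
  expect_error(tucan_deserialize(s, strict = TRUE), "not canonical")
  expect_identical(tucan_deserialize(rs, strict = TRUE)$n, 9L)
})

test_that("reconstructed molfiles re-serialize to the identical string", {
  for (f in c("zeise", "hexaamminecobalt", "cyclohexane")) {
    s <- tucan_serialize(build_graph(tucan_fixture(f)))
    mol <- tucan_to_molfile(s)
    expect_identical(molfile_to_tucan(mol), s)
  }
})
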