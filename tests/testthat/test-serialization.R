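test_that("Hill formulas put C, H first and fall back to alphabetical", {
  expect_identical(hill_formula(tucan_graph_fixture("zeise")), "C2H4Cl3Pt")
  expect_identical(hill_formula(tucan_graph_fixture("glycine")), "C2H5NO2")
  expect_identical(hill_formula(build_graph(molfile_data("Ne"))), "Ne")
  # no carbon: everything alphabetical, including H
  expect_identical(hill_formula(tucan_graph_fixture("water")), "H2O")
  expect_identical(hill_formula(tucan_graph_fixture("sodium_chloride")), "ClNa")
  expect_identical(hill_formula(tucan_graph_fixture("ammonia")), "H3N")
})

test_that("output labels ascend with atomic number, Zeise and ferrocene style", {
  z <- tucan_graph_fixture("zeise")
  lab <- assign_output_labels(z)
  expect_setequal(lab[z$element == "H"], 1:4)
  expect_setequal(lab[z$element == "C"], 5:6)
  expect_setequal(lab[z$element == "Cl"], 7:9)
  expect_equal(lab[z$element == "Pt"], 10L)

  fc <- tucan_graph_fixture("ferrocene")
  lab <- assign_output_labels(fc)
  expect_setequal(lab[fc$element == "H"], 1:10)
  expect_setequal(lab[fc$element == "C"], 11:20)
  expect_equal(lab[fc$element == "Fe"], 21L)

  expect_equal(assign_output_labels(build_graph(molfile_data("U"))), 1L)
})

test_that("serialization produces the published Zeise string and clean grammar", {
  expect_identical(tucan_serialize(tucan_graph_fixture("zeise")), ZEISE_STRING)
  expect_identical(tucan_serialize(tucan_graph_fixture("methane")),
                   "CH4/(1-5)(2-5)(3-5)(4-5)")
  # monoatomic and disconnected species: mandatory formula block only
  expect_identical(tucan_serialize(build_graph(molfile_data("Ne"))), "Ne")
  expect_identical(tucan_serialize(tucan_graph_fixture("sodium_chloride")),
                   "ClNa/(1:CHG=1)(2:CHG=-1)")
})

test_that("every fixture string is printable ASCII obeying the tuple grammar", {
  grammar <- paste0(
    "^([A-Z][a-z]?[0-9]*)+",
    "(/(\\((\\d+)-(\\d+)\\))+)?",
    "(/(\\((\\d+):[A-Z]+=-?\\d+(,[A-Z]+=-?\\d+)*\\))+)?$"
  )
  for (f in tucan_fixture_names()) {
    s <- tucan_serialize(build_graph(tucan_fixture(f)))
    expect_true(all(utf8ToInt(s) >= 33L & utf8ToInt(s) <= 126L), label = f)
    expect_match(s, grammar, label = f)
    # edge tuples strictly increasing, each ascending, labels in range
    p <- parse_tucan_string(s)
    if (nrow(p$edges) > 0L) {
      expect_true(all(p$edges[, 1L] < p$edges[, 2L]), label = f)
      expect_true(all(p$edges <= p$n), label = f)
    }
  }
})

test_that("distinct molecules get distinct strings, isomorphic ones identical", {
  nm <- tucan_fixture_names()
  strings <- vapply(nm, function(f) tucan_serialize(build_graph(tucan_fixture(f))),
                    character(1))
  expect_false(anyDuplicated(strings) > 0L)
  # the classic cospectral pair must be told apart
  expect_false(strings[["shrikhande"]] == strings[["rook-4"]])
  set.seed(29)
  for (f in c("zeise", "diborane", "petersen")) {
    mol <- tucan_fixture(f)
    for (i in 1:5) {
      expect_identical(tucan_serialize(build_graph(shuffle_atoms(mol))),
                       strings[[f]])
    }
  }
})
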