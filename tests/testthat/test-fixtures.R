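test_that("the fixture library spans the required breadth", {
  difficult <- tucan_fixture_names("difficult-graph")
  molecules <- setdiff(tucan_fixture_names(), difficult)
  expect_gte(length(molecules), 50L)
  expect_gte(length(difficult), 10L)
  expect_error(tucan_fixture("no_such_molecule"), "unknown fixture")
  expect_error(tucan_fixture_names("no_such_category"), "unknown fixture category")
})

test_that("fixture generation is deterministic and bit-reproducible", {
  for (f in c("zeise", "octane", "shrikhande", "hexaamminecobalt")) {
    expect_identical(tucan_fixture(f), tucan_fixture(f))
    expect_identical(tucan_fixture_molfile(f), tucan_fixture_molfile(f))
  }
  el <- tucan_fixture_edgelist("petersen")
  expect_length(el, 16L)  # header plus 15 edges
  expect_match(el[[1L]], "10 nodes, 15 edges")
})

test_that("named fixtures have their documented shapes", {
  z <- tucan_fixture("zeise")
  expect_equal(c(z$atom_count, z$bond_count), c(10L, 10L))
  expect_equal(tucan_fixture("bicyclooctenone")$atom_count, 19L)
  q4 <- tucan_fixture("hypercube-4")
  expect_equal(c(q4$atom_count, q4$bond_count), c(16L, 32L))
  expect_true(all(q4$element == "C"))  # element-uniform: only topology counts
  pet <- tucan_fixture("petersen")
  expect_equal(c(pet$atom_count, pet$bond_count), c(10L, 15L))
  expect_true(all(lengths(build_graph(pet)$adjacency) == 3L))
  srg <- build_graph(tucan_fixture("shrikhande"))
  expect_true(all(lengths(srg$adjacency) == 6L))
})

test_that("explicit hydrogens are present where chemically required", {
  for (f in c("methane", "benzene", "ferrocene", "bicyclooctenone", "glycine")) {
    expect_true("H" %in% tucan_fixture(f)$element, label = f)
  }
})

test_that("the shuffle harness passes on valid input and catches a broken serializer", {
  res <- shuffle_test(tucan_fixture("zeise"), permutations = 25L, seed = 1L)
  expect_true(res$pass)
  expect_equal(res$n_unique, 1L)
  expect_identical(res$reference, ZEISE_STRING)

  expect_true(shuffle_test(molfile_data("He"), permutations = 5L, seed = 1L)$pass)

  # mutant serializer that echoes input order must be flagged
  mutant <- function(d) paste(d$element, collapse = "")
  res2 <- shuffle_test(tucan_fixture("zeise"), permutations = 25L, seed = 1L,
                       serializer = mutant)
  expect_false(res2$pass)
  expect_true(!is.null(res2$mismatch))
})

test_that("shuffling preserves the molecule and leaves the caller's RNG alone", {
  set.seed(99)
  before <- .Random.seed
  res <- shuffle_test(tucan_fixture("glycine"), permutations = 10L, seed = 5L)
  expect_true(res$pass)
  expect_identical(.Random.seed, before)
  # same seed, same outcome
  expect_identical(res$reference,
                   shuffle_test(tucan_fixture("glycine"), 10L, seed = 5L)$reference)
  expect_error(shuffle_atoms(tucan_fixture("water"), c(1L, 1L, 2L)), "permutation")
})
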