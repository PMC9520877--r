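test_that("element symbol lookup covers H through Og and is case-sensitive", {
  expect_identical(element_to_atomic_number(c("H", "C", "Pt", "Og")),
                   c(1L, 6L, 78L, 118L))
  expect_identical(atomic_number_to_element(element_to_atomic_number(
    atomic_number_to_element(1:118))), atomic_number_to_element(1:118))
  expect_error(element_to_atomic_number("h"), "unknown element")
  expect_error(element_to_atomic_number("Xx"), "unknown element")
  expect_error(element_to_atomic_number("*"), "pseudo-atom")
  expect_error(atomic_number_to_element(119), "1\\.\\.118")
})

test_that("a drawing-program v3000 molfile parses to counts, symbols, features, bonds", {
  mol <- parse_molfile_v3000(zeise_molfile_text())
  expect_s3_class(mol, "tucan_molfile")
  expect_equal(mol$atom_count, 10L)
  expect_equal(mol$bond_count, 10L)
  expect_equal(sort(table(mol$element), method = "radix"),
               sort(table(c(rep("H", 4), rep("C", 2), rep("Cl", 3), "Pt")), method = "radix"))
  # Pt carries all three fields; RAD = 0 is kept because it is present
  pt <- mol$features[[which(mol$element == "Pt")]]
  expect_identical(pt, c(CHG = 2L, MASS = 196L, RAD = 0L))
  cl <- mol$features[which(mol$element == "Cl")]
  expect_true(all(vapply(cl, identical, logical(1), c(CHG = -1L))))
  expect_true(all(vapply(mol$features[mol$element %in% c("C", "H")], is.null, logical(1))))
})

test_that("minimal and malformed molfiles are handled as specified", {
  he <- parse_molfile_v3000(paste(c(
    "", "", "", "  0  0  0     0  0            999 V3000",
    "M  V30 BEGIN CTAB", "M  V30 COUNTS 1 0 0 0 0",
    "M  V30 BEGIN ATOM", "M  V30 1 He 0 0 0 0", "M  V30 END ATOM",
    "M  V30 END CTAB", "M  END"), collapse = "\n"))
  expect_equal(he$atom_count, 1L)
  expect_equal(he$bond_count, 0L)

  bad <- function(atom_line) paste(c(
    "", "", "", "  0  0  0     0  0            999 V3000",
    "M  V30 BEGIN CTAB", "M  V30 COUNTS 1 0 0 0 0",
    "M  V30 BEGIN ATOM", atom_line, "M  V30 END ATOM",
    "M  V30 END CTAB", "M  END"), collapse = "\n")
  expect_error(parse_molfile_v3000(bad("M  V30 1 * 0 0 0 0")), "pseudo-atom")
  expect_error(parse_molfile_v3000(bad("M  V30 1 Zz 0 0 0 0")), "unknown element")
  expect_error(parse_molfile_v3000("not a molfile"), "V30")

  # count/record mismatch, out-of-range, self- and duplicate bonds
  frame <- function(counts, bonds) paste(c(
    "", "", "", "  0  0  0     0  0            999 V3000",
    "M  V30 BEGIN CTAB", counts,
    "M  V30 BEGIN ATOM", "M  V30 1 C 0 0 0 0", "M  V30 2 C 0 0 0 0",
    "M  V30 END ATOM", "M  V30 BEGIN BOND", bonds, "M  V30 END BOND",
    "M  V30 END CTAB", "M  END"), collapse = "\n")
  expect_error(parse_molfile_v3000(frame("M  V30 COUNTS 3 1 0 0 0", "M  V30 1 1 1 2")),
               "ATOM block")
  expect_error(parse_molfile_v3000(frame("M  V30 COUNTS 2 1 0 0 0", "M  V30 1 1 1 5")),
               "out of range")
  expect_error(parse_molfile_v3000(frame("M  V30 COUNTS 2 1 0 0 0", "M  V30 1 1 2 2")),
               "self-bond")
  expect_error(parse_molfile_v3000(frame("M  V30 COUNTS 2 2 0 0 0",
                                         c("M  V30 1 1 1 2", "M  V30 2 1 2 1"))),
               "duplicate bond")
})

test_that("v3000 line continuations and variable whitespace are tolerated", {
  mol <- parse_molfile_v3000(paste(c(
    "", "", "", "  0  0  0     0  0            999 V3000",
    "M  V30 BEGIN CTAB", "M  V30 COUNTS   1   0 0 0 0",
    "M  V30 BEGIN ATOM",
    "M  V30 1 Pt 0 0 0 0 CHG=2 -",
    "M  V30  MASS=196",
    "M  V30 END ATOM", "M  V30 END CTAB", "M  END"), collapse = "\n"))
  expect_identical(mol$features[[1L]], c(CHG = 2L, MASS = 196L))
})

test_that("write_molfile_v3000 round-trips atoms, features and edges", {
  for (f in c("zeise", "methane", "sodium_chloride", "heavy_water", "ferrocene")) {
    mol <- tucan_fixture(f)
    re <- parse_molfile_v3000(write_molfile_v3000(build_graph(mol)))
    expect_identical(re$element, mol$element)
    expect_identical(re$features, mol$features)
    norm <- function(b) {
      b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
      b[order(b[, 1], b[, 2]), , drop = FALSE]
    }
    expect_identical(norm(re$bonds), norm(mol$bonds))
  }
})

test_that("parsing is insensitive to record order up to isomorphism", {
  set.seed(11)
  mol <- parse_molfile_v3000(zeise_molfile_text())
  for (i in 1:5) {
    shuf <- shuffle_atoms(mol)
    expect_isomorphic(build_graph(mol), build_graph(shuf))
    expect_identical(tucan_serialize(build_graph(shuf)), ZEISE_STRING)
  }
})

test_that("molfile_data validates its invariants", {
  expect_error(molfile_data(character(0)), "at least one atom")
  expect_error(molfile_data(c("C", "C"), rbind(c(1, 1))), "self-bond")
  expect_error(molfile_data(c("C", "C"), rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_error(molfile_data("C", rbind(c(1, 2))), "out of range")
  expect_error(molfile_data("C", NULL, list(c(FOO = 1L))), "named integers")
  expect_error(molfile_data("C", NULL, list(c(RAD = 4L))), "RAD")
})
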