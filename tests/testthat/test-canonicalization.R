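test_that("invariant codes capture element plus decreasing neighbor multiset", {
  bz <- tucan_graph_fixture("benzene")
  codes <- assign_invariant_codes(bz)
  for (v in which(bz$element == "C")) {
    expect_identical(codes[[v]], c(6L, 6L, 6L, 1L))
  }
  for (v in which(bz$element == "H")) {
    expect_identical(codes[[v]], c(1L, 6L))
  }
  he <- build_graph(molfile_data("He"))
  expect_identical(assign_invariant_codes(he)[[1L]], 2L)

  b <- tucan_graph_fixture("bicyclooctenone")
  expect_equal(length(unique(assign_invariant_codes(b))), 5L)
})

test_that("initial partitioning groups identical codes, ordered by code", {
  b <- tucan_graph_fixture("bicyclooctenone")
  p <- initial_partition(assign_invariant_codes(b))
  expect_equal(max(p), 5L)

  h2 <- build_graph(molfile_data(c("H", "H"), rbind(c(1, 2))))
  expect_equal(max(initial_partition(assign_invariant_codes(h2))), 1L)

  # fully distinct codes give singleton cells; hydrogens (lowest Z) first
  chain <- build_graph(molfile_data(c("O", "C", "H"), rbind(c(1, 2), c(2, 3))))
  p3 <- initial_partition(assign_invariant_codes(chain))
  expect_equal(max(p3), 3L)
  expect_equal(p3[[3L]], 1L)  # the H
})

test_that("refinement reaches a stable equitable partition and never merges", {
  set.seed(17)
  for (f in c("bicyclooctenone", "naphthalene", "octane", "petersen")) {
    g <- tucan_graph_fixture(f)
    p0 <- initial_partition(assign_invariant_codes(g))
    p1 <- refine_partitions(g, p0)
    # monotone: cell count never decreases, membership only splits
    expect_gte(max(p1), max(p0))
    for (cell in unique(p1)) {
      expect_equal(length(unique(p0[p1 == cell])), 1L)
    }
    # stable: rerunning is the identity
    expect_identical(refine_partitions(g, p1), p1)
  }
  # a discrete partition is already stable
  g <- tucan_graph_fixture("glycine")
  expect_identical(refine_partitions(g, seq_len(g$n)), seq_len(g$n))
  # vertex-transitive rings stay in one cell per element
  bz <- tucan_graph_fixture("benzene")
  pb <- refine_partitions(bz, initial_partition(assign_invariant_codes(bz)))
  expect_equal(max(pb), 2L)  # all C equivalent, all H equivalent
})

test_that("canonical labels are grouped by ascending atomic number", {
  for (f in c("zeise", "glycine", "ferrocene")) {
    g <- tucan_graph_fixture(f)
    cl <- canonical_labeling(g)
    expect_setequal(cl, seq_len(g$n))
    expect_identical(order(g$Z[order(cl)]), seq_len(g$n))  # Z ascending along labels
  }
})

test_that("canonical form equals the brute-force minimum on small graphs", {
  # includes element-uniform symmetric graphs (cube, complete, bipartite)
  nm <- tucan_fixture_names()
  small <- nm[vapply(nm, function(f) tucan_fixture(f)$atom_count <= 8L, logical(1))]
  expect_gte(length(small), 30L)
  for (f in small) {
    g <- tucan_graph_fixture(f)
    expect_identical(tucan_serialize(g), brute_force_canonical(g))
  }
})

test_that("brute force agrees on random heteroatom graphs and enforces its cap", {
  set.seed(23)
  for (i in 1:40) {
    g <- build_graph(random_molfile(sample(3:7, 1)))
    expect_identical(tucan_serialize(g), brute_force_canonical(g))
  }
  expect_error(brute_force_canonical(tucan_graph_fixture("zeise")), "capped")
})

test_that("features change the feature block but never the edge block", {
  edge_block_of <- function(s) strsplit(s, "/", fixed = TRUE)[[1L]][2L]
  plain <- tucan_graph_fixture("cyclohexane")
  feats <- plain$features
  feats[[3L]] <- c(CHG = 1L)  # charge one symmetry-equivalent ring carbon
  charged <- molecular_graph(plain$element, plain$edges, feats)
  s0 <- tucan_serialize(plain)
  s1 <- tucan_serialize(charged)
  expect_false(s0 == s1)
  expect_identical(edge_block_of(s0), edge_block_of(s1))
  # isotope on one of the two symmetric oxygens of CO2
  co2 <- tucan_fixture("carbon_dioxide")
  iso <- molecular_graph(co2$element, co2$bonds,
                         list(NULL, c(MASS = 18L), NULL))
  expect_identical(edge_block_of(tucan_serialize(build_graph(co2))),
                   edge_block_of(tucan_serialize(iso)))
})

test_that("the canonicalization trace exposes every stage consistently", {
  g <- tucan_graph_fixture("bicyclooctenone")
  tr <- canonicalization_trace(g)
  expect_length(tr$codes, g$n)
  expect_equal(max(tr$initial), 5L)
  expect_gte(max(tr$stable), max(tr$initial))
  if (length(tr$rounds) > 0L) {
    counts <- vapply(tr$rounds, max, integer(1))
    expect_true(all(diff(c(max(tr$initial), counts)) >= 0L))
  }
  expect_setequal(tr$labels, seq_len(g$n))
})
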