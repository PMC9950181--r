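test_that("distance to union handles the canonical family motifs", {
  # two parents + child triangle: removing the union and both child edges
  # disconnects the couple
  tri <- nuclear_family(1)
  du <- distance_to_union(tri)
  expect_equal(length(du$finite), 0L)
  expect_equal(du$infinite, 1L)

  # first cousins: spouse-parent-grandparent-parent-spouse = 4
  fc <- first_cousin_couple()
  du <- distance_to_union(fc)
  expect_equal(sort(du$finite), 4L)
  expect_equal(du$infinite, 1L)   # the grandparent couple itself

  expect_error(distance_to_union(hexagon_network()), "labelled")
  expect_error(distance_to_union(
    labeled_network("a", "b", "parent_child")), "no union")
})

test_that("cycle bases have dimension m - n + k with minimum lengths", {
  expect_equal(cycle_basis_lengths(hexagon_network()), c("6" = 1L))
  expect_equal(cycle_basis_lengths(complete_network(4)), c("3" = 3L))
  expect_length(cycle_basis(path_network(6))$cycles, 0L)

  set.seed(61)
  for (rep in 1:15) {
    g <- random_simple_graph(sample(5:10, 1L), p = 0.35)
    n <- igraph::vcount(g); m <- igraph::ecount(g)
    k <- length(connected_components(g))
    for (meth in c("minimum", "fundamental")) {
      cb <- cycle_basis(g, method = meth)
      expect_length(cb$cycles, m - n + k)
      for (cyc in cb$cycles) {
        expect_gte(length(cyc), 3L)
        expect_equal(anyDuplicated(cyc), 0L)
        # consecutive vertices really are adjacent
        ids <- igraph::get_edge_ids(
          g, as.vector(rbind(cyc, cyc[c(seq_along(cyc)[-1L], 1L)])))
        expect_true(all(ids > 0L))
      }
    }
  }
})

test_that("the minimum basis never exceeds the fundamental basis in weight", {
  set.seed(62)
  for (rep in 1:8) {
    g <- random_simple_graph(sample(6:10, 1L), p = 0.4)
    mcb <- cycle_basis(g, method = "minimum")
    fb <- cycle_basis(g, method = "fundamental")
    expect_lte(sum(lengths(mcb$cycles)), sum(lengths(fb$cycles)))
  }
})

test_that("familial exclusion empties a pure nuclear-family basis", {
  fam <- nuclear_family(2)
  expect_equal(unname(cycle_basis_lengths(fam)), c(2L))   # two triangles
  expect_length(cycle_basis_lengths(fam, exclude_familial = TRUE), 0L)
  expect_error(cycle_basis_lengths(hexagon_network(),
                                   exclude_familial = TRUE), "labelled")
})

test_that("cycle classification follows the precedence rules", {
  fam <- nuclear_family(2)
  expect_equal(classify_cycle(c("p1", "p2", "c1"), fam), "trivial")
  expect_equal(classify_cycle(c("p1", "c1", "p2", "c2"), fam), "familial")

  ca <- common_ancestor_motif()
  expect_equal(classify_cycle(c("top", "m1", "x", "y", "m2"), ca),
               "common_ancestor")

  dc <- double_cousin_motif()
  expect_equal(classify_cycle(c("pA", "a1", "b1", "pB", "b2", "a2"), dc),
               "union")

  # mixing a lone parent-child edge with several unions is hybrid
  hy <- labeled_network(
    from = c("a", "b", "c", "d", "e"),
    to   = c("b", "c", "d", "e", "a"),
    relation = c("union", "parent_child", "union", "union", "union"))
  expect_equal(classify_cycle(c("a", "b", "c", "d", "e"), hy), "hybrid")

  expect_error(classify_cycle(c("p1", "p2"), fam), "at least 3")
  expect_error(classify_cycle(c("p1", "p2", "c9"), fam), "absent")
})

test_that("classification is invariant under rotation and reversal", {
  dc <- double_cousin_motif()
  cyc <- c("pA", "a1", "b1", "pB", "b2", "a2")
  k <- length(cyc)
  for (s in seq_len(k)) {
    rot <- cyc[c(s:k, seq_len(s - 1L))]
    expect_equal(classify_cycle(rot, dc), "union")
    expect_equal(classify_cycle(rev(rot), dc), "union")
  }
})

test_that("every basis cycle of a simulated genealogy gets one category", {
  net <- simulate_genealogy(genealogy_sim_params(
    founder_couples = 4, generations = 3, mean_children = 2,
    union_distance_range = c(5, 10), immigrant_rate = 0.2, seed = 3))
  cb <- cycle_basis(net)
  cls <- vapply(cb$cycles, classify_cycle, character(1), net = net)
  expect_true(all(cls %in% c("trivial", "familial", "common_ancestor",
                             "union", "hybrid")))
})

test_that("published persistence prediction and its off-by-one regime", {
  expect_equal(union_cycle_persistence_bound(21), 7L)
  expect_equal(union_cycle_persistence_bound(3), 1L)
  expect_error(union_cycle_persistence_bound(2), ">= 3")

  # computed dim-1 persistence of an isolated cycle C_m is ceiling(m/3) - 1,
  # which equals the published floor(m/3) except when m is divisible by 3
  for (m in 4:15) {
    ph <- network_persistence(cycle_network(m), max_hom_dim = 1)
    d1 <- ph[ph$dim == 1, ]
    computed <- d1$death - d1$birth
    expect_equal(computed, ceiling(m / 3) - 1)
    if (m %% 3 == 0) {
      expect_equal(union_cycle_persistence_bound(m), computed + 1)
    } else {
      expect_equal(union_cycle_persistence_bound(m), computed)
    }
  }
})

test_that("configuration-model rewiring shortens long basis cycles", {
  long <- cycle_network(30)
  orig <- cycle_basis_lengths(long)
  expect_equal(orig, c("30" = 1L))
  degs <- unname(igraph::degree(long))
  set.seed(63)
  rewired_means <- replicate(5, {
    g <- simplify_support(configuration_model(degs))
    lens <- cycle_basis_lengths(g)
    if (length(lens)) {
      sum(as.integer(names(lens)) * lens) / sum(lens)
    } else NA_real_
  })
  rewired_means <- rewired_means[!is.na(rewired_means)]
  expect_true(length(rewired_means) > 0)
  expect_true(mean(rewired_means) < 30)
})
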