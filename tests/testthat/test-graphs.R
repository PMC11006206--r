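test_that("edge lists read into multigraphs with symmetrization and checks", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\t1", "B\tA\t1"), f)
  net <- read_edge_list(f, directed = FALSE)
  expect_equal(n_nodes(net), 2L)
  expect_equal(adjacency(net)["A", "B"], 1)
  expect_equal(adjacency(net)["B", "A"], 1)

  # the cyan worked multigraph: 9 directed edges counting multiplicity,
  # checked through its input-tree layer sizes
  writeLines(c("M C 1", "P C 2", "M P 2", "P M 2", "C M 1", "C P 2"), f)
  cy <- read_edge_list(f, directed = TRUE)
  expect_equal(sum(adjacency(cy)), 10) # 6 rows, multiplicities 1+2+2+2+1+2
  a <- build_input_tree(cy, "C", 3)$layer_sizes
  expect_equal(a, c(1, 3, 11, 35))

  writeLines(character(0), f)
  expect_equal(n_nodes(read_edge_list(f)), 0L)

  writeLines(c("A B 1", "A B 2"), f)
  expect_warning(dup <- read_edge_list(f), "duplicate")
  expect_equal(adjacency(dup)["A", "B"], 3)

  writeLines("A B -1", f)
  expect_error(read_edge_list(f), "positive")
  writeLines("A B 1.5", f)
  expect_error(read_edge_list(f), "integer")
})

test_that("edge-list and GraphML writers round-trip", {
  fx <- fixture("forward_gap_like", seed = 1)
  f <- withr::local_tempfile()
  write_edge_list(fx$net, f)
  expect_identical(adjacency(read_edge_list(f, directed = FALSE)),
                   adjacency(fx$net))
  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(fx$net, g)
  back <- read_graphml(g)
  expect_false(back$directed)
  expect_identical(adjacency(back), adjacency(fx$net))
})

test_that("input trees expand by in-neighborhoods with multiplicity", {
  cy <- fixture("cyan_multigraph")$net
  it <- build_input_tree(cy, "C", 5)
  expect_equal(it$layer_sizes, c(1, 3, 11, 35, 123, 403))
  # layer recurrence of the cyan block: t[n+3] = 9 t[n+1] + 8 t[n]
  a <- it$layer_sizes
  for (i in 1:3) expect_equal(a[i + 3], 9 * a[i + 1] + 8 * a[i])

  iso <- neuron_network(NULL, nodes = "Z")
  expect_equal(build_input_tree(iso, "Z", 5)$layer_sizes, c(1, rep(0, 5)))

  loop2 <- network_from_adjacency(matrix(2, 1, 1, dimnames = list("L", "L")))
  expect_equal(build_input_tree(loop2, "L", 3)$layer_sizes, c(1, 2, 4, 8))

  expect_error(build_input_tree(cy, "missing", 2), "unknown root")
})

test_that("layer sizes match the matrix-power oracle on random graphs", {
  for (seed in 1:12) {
    net <- random_net(sample(3:8, 1), p = 0.4, seed = seed)
    root <- sample(network_nodes(net), 1)
    expect_equal(build_input_tree(net, root, 6)$layer_sizes,
                 powers_layer_sizes(net, root, 6))
  }
})

test_that("input-tree isomorphism distinguishes and classifies correctly", {
  cy <- fixture("cyan_multigraph")$net
  expect_true(input_trees_isomorphic(cy, "M", "M"))
  # M and P differ at layer 1 already (in-degrees 3 vs 4)
  expect_false(input_trees_isomorphic(cy, "M", "P"))

  sinks <- neuron_network(data.frame(tail = c("s1", "s2"),
                                     head = c("t1", "t2")))
  expect_true(input_trees_isomorphic(sinks, "t1", "t2"))
  expect_error(input_trees_isomorphic(sinks, "t1", "zz"), "unknown")
})

test_that("input-tree isomorphism classes equal the minimal coloring cells", {
  for (seed in 1:10) {
    net <- random_net(sample(4:8, 1), p = 0.35, seed = seed + 100)
    nodes <- network_nodes(net)
    part <- minimal_balanced_coloring(net)
    for (u in nodes) {
      for (v in nodes) {
        expect_equal(
          input_trees_isomorphic(net, u, v),
          unname(part$membership[u] == part$membership[v]),
          info = sprintf("seed %d pair %s-%s", seed, u, v)
        )
      }
    }
  }
})

test_that("quotient collapses balanced cells and rejects unbalanced ones", {
  net <- random_net(5, p = 0.5, seed = 7)
  expect_identical(adjacency(quotient_graph(net, singleton_partition(net))),
                   adjacency(net))

  sq <- fixture("bidirectional_square")
  q <- quotient_graph(sq$net, sq$partition)
  expect_equal(n_nodes(q), 1L)
  expect_equal(unname(adjacency(q)[1, 1]), 2)

  # planted graphs collapse onto their generating base
  fx <- fixture("forward_chem_like", seed = 4)
  qb <- quotient_graph(fx$net, fx$partition)
  expect_equal(n_nodes(qb), fx$partition$k)
  expect_equal(unname(adjacency(qb)),
               unname(rbind(c(1, 2, 1, 1), c(0, 0, 1, 2),
                            c(0, 1, 0, 1), c(0, 0, 0, 0))))

  bad <- node_partition(c(A = "x", B = "x"))
  two <- neuron_network(data.frame(tail = "A", head = "B"))
  expect_error(quotient_graph(two, bad), "not balanced")
})

test_that("quotienting preserves the representatives' layer-size sequences", {
  for (nm in c("forward_chem_like", "forward_gap_like")) {
    fx <- fixture(nm, seed = 2)
    base <- quotient_graph(fx$net, fx$partition)
    for (rep_node in network_nodes(base)) {
      expect_equal(
        build_input_tree(base, rep_node, 8)$layer_sizes,
        build_input_tree(fx$net, rep_node, 8)$layer_sizes,
        info = paste(nm, rep_node)
      )
    }
  }
})
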