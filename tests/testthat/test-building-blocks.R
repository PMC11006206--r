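test_that("circuits keep the main fiber and its backward-reachable fibers", {
  # fiber with no in-edges: circuit is its base node alone
  star <- neuron_network(data.frame(tail = c("s1", "s2"), head = "hub"))
  part <- minimal_balanced_coloring(star)
  src_cell <- part$membership[["s1"]]
  circ <- extract_circuit(star, part, src_cell)
  expect_equal(n_nodes(circ), 1L)

  # fully connected single fiber collapses to one self-looped node
  k3 <- network_from_adjacency(
    matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3])) -
      diag(3)
  )
  p3 <- minimal_balanced_coloring(k3)
  circ3 <- extract_circuit(k3, p3, "c1")
  expect_equal(n_nodes(circ3), 1L)
  expect_equal(unname(adjacency(circ3)[1, 1]), 2)

  # backward-reachability oracle on a planted chem-like fixture
  fx <- fixture("backward_chem_like", seed = 3)
  base <- quotient_graph(fx$net, fx$partition)
  for (cell in c("c8", "c9")) {
    circ <- extract_circuit(fx$net, fx$partition, cell)
    main <- attr(circ, "main_fiber")
    # oracle: closure of in-neighborhoods on the base adjacency
    badj <- adjacency(base)
    keep <- main
    repeat {
      pred <- rownames(badj)[rowSums(badj[, keep, drop = FALSE] > 0) > 0]
      nxt <- union(keep, pred)
      if (setequal(nxt, keep)) break
      keep <- nxt
    }
    expect_setequal(network_nodes(circ), keep)
  }
  expect_error(extract_circuit(fx$net, fx$partition, "c99"), "unknown fiber")
})

test_that("building blocks assemble by the four synthesis rules", {
  hub <- fixture("two_regulator_hub")
  blk <- extract_fbb(hub$net, hub$partition, "H")
  expect_setequal(blk$regulators, c("R1", "R2"))
  expect_false(blk$composite)

  sq <- fixture("bidirectional_square")
  bsq <- extract_fbb(sq$net, sq$partition, "Q1")
  expect_setequal(network_nodes(bsq$net), paste0("Q", 1:4))
  expect_setequal(bsq$regulators, paste0("Q", 1:4)) # own feedback

  cf <- composite_fixture()
  bc <- extract_fbb(cf$net, cf$partition, "x1")
  expect_true(bc$composite)
  expect_setequal(network_nodes(bc$net), c("x1", "x2", "a1", "a2", "p", "q"))
})

test_that("branching ratios equal the dominant eigenvalue of the layer growth", {
  cy <- fixture("cyan_multigraph")$net
  n_cy <- branching_ratio(cy, "C")
  # oracle: real root of x^3 - 9x - 8 = 0 from the layer recurrence (1, 3, 11)
  root <- polyroot(c(-8, -9, 0, 1))
  root <- Re(root[abs(Im(root)) < 1e-9 & Re(root) > 0])
  expect_equal(n_cy, root, tolerance = 1e-6)
  expect_equal(round(n_cy, 4), 3.3723)

  hub <- fixture("two_regulator_hub")$net
  expect_equal(branching_ratio(hub, "H"), 0)

  sq <- fixture("bidirectional_square")
  q <- quotient_graph(sq$net, sq$partition)
  expect_equal(branching_ratio(q, network_nodes(q)), 2)

  gold <- fixture("fibonacci_base", a = 1, b = 1, c = 1, d = 0)$net
  expect_equal(branching_ratio(gold, "X"), (1 + sqrt(5)) / 2,
               tolerance = 1e-9)

  # empirical ratio from the input tree agrees within 1e-3 at depth 60
  a <- build_input_tree(cy, "C", 60)$layer_sizes
  expect_lt(abs(sqrt(a[61] / a[59]) - n_cy), 1e-3)
})

test_that("trail counts enumerate edge-simple trails on the simple base", {
  base <- neuron_network(data.frame(
    tail = c("M", "P", "M", "P"), head = c("C", "C", "P", "M")
  ))
  expect_equal(trail_count(base, "C"), 6L)
  # multiplicities ignored: the multigraph version gives the same count
  cy <- fixture("cyan_multigraph")$net
  expect_equal(trail_count(cy, "C"), 6L)

  hub <- fixture("two_regulator_hub")$net
  expect_equal(trail_count(hub, "H"), 2L)

  lone <- neuron_network(NULL, nodes = "Z")
  expect_equal(trail_count(lone, "Z"), 0L)

  expect_error(trail_count(random_net(8, p = 0.9, seed = 2), "n01",
                           max_edges = 10), "capped")
})

test_that("trail counts agree with forward brute-force enumeration", {
  tried <- 0
  for (seed in 1:20) {
    net <- random_net(sample(3:5, 1), p = 0.45, seed = seed + 300)
    if (sum(adjacency(net) != 0) > 10) next
    tried <- tried + 1
    root <- sample(network_nodes(net), 1)
    expect_equal(trail_count(net, root), brute_trails(net, root),
                 info = paste("seed", seed, "root", root))
  }
  expect_gte(tried, 10)
})

test_that("blocks classify as finite, n-loop or Fibonacci", {
  hub <- fixture("two_regulator_hub")
  b1 <- fiber_numbers(extract_fbb(hub$net, hub$partition, "H"))
  expect_equal(b1$n, 0)
  expect_equal(b1$ell, 2L)
  expect_equal(b1$class_label, "finite")

  sq <- fixture("bidirectional_square")
  b2 <- fiber_numbers(extract_fbb(sq$net, sq$partition, "Q1"))
  expect_equal(b2$n, 2)
  expect_equal(b2$ell, 0L)
  expect_equal(b2$class_label, "n-loop")

  cy <- fixture("cyan_multigraph")$net
  b3 <- fiber_numbers(extract_fbb(cy, singleton_partition(cy), "C"))
  expect_equal(round(b3$n, 4), 3.3723)
  expect_equal(b3$ell, 6L)
  expect_equal(b3$class_label, "Fibonacci")

  cf <- composite_fixture()
  b4 <- extract_fbb(cf$net, cf$partition, "x1")
  b4$n <- 0
  expect_equal(classify_fbb(b4), "composite")
})

test_that("multilayer signatures layer the circuit's elementary blocks", {
  sq <- fixture("bidirectional_square")
  sig <- multilayer_signature(sq$net, sq$partition, "Q1")
  expect_length(sig$layers, 1L)
  expect_equal(render_signature(sig), "|2, 0⟩")

  hub <- fixture("two_regulator_hub")
  sig2 <- multilayer_signature(hub$net, hub$partition, "H")
  expect_length(sig2$layers, 1L)
  expect_equal(render_signature(sig2), "|0, 2⟩")

  tl <- two_layer_loop_fixture()
  main_cell <- tl$partition$membership[["m1"]]
  sig3 <- multilayer_signature(tl$net, tl$partition, main_cell)
  expect_equal(render_signature(sig3), "|1, 1⟩ ⊕ |1, 2⟩")

  parsed <- parse_signature(render_signature(sig3))
  expect_length(parsed, 2L)
  expect_equal(parsed[[1]]$n, 1)
  expect_equal(parsed[[1]]$ell, 1L)
  expect_equal(parsed[[2]]$ell, 2L)
})

test_that("collapsing onto the minimal base preserves the common ratio", {
  # C and M share a balanced color in the cyan block, so it collapses onto a
  # 2-node self-looped Fibonacci base with the same dominant eigenvalue
  cy <- fixture("cyan_multigraph")$net
  r0 <- branching_ratio(cy, "C")
  col <- fibonacci_base_collapse(cy)
  expect_equal(n_nodes(col), 2L)
  expect_gt(max(diag(adjacency(col))), 0) # self-loop appears
  expect_equal(max(Mod(eigen(adjacency(col), only.values = TRUE)$values)),
               r0, tolerance = 1e-9)
  # eigen-oracle: the collapsed base [[1, 4], [2, 0]] has ratio (1+sqrt(33))/2
  expect_equal(r0, (1 + sqrt(33)) / 2, tolerance = 1e-9)

  # already-minimal block (discrete coloring): identity
  path3 <- neuron_network(data.frame(tail = c("a", "b"), head = c("b", "c")))
  expect_identical(adjacency(fibonacci_base_collapse(path3)),
                   adjacency(path3))

  # classification is invariant under the collapse
  b_cy <- fiber_numbers(extract_fbb(cy, singleton_partition(cy), "C"))
  b_col <- fiber_numbers(extract_fbb(col, singleton_partition(col), "C"))
  expect_equal(b_cy$class_label, "Fibonacci")
  expect_equal(b_col$class_label, "Fibonacci")
  expect_equal(b_cy$n, b_col$n, tolerance = 1e-6)
})
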