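test_that("parameters carry the documented defaults and identities", {
  p <- model_params()
  expect_equal(p$s_eq, p$a_r / (p$a_r + 2 * p$a_d))
  expect_equal(round(p$s_eq, 2), 0.09)
  expect_equal(p$gamma, 0.125) # 125 V^-1 in 1/mV
  expect_equal(gamma_from_range(36), 2 * log(9) / 36)
  expect_lt(abs(gamma_from_range(36) - 0.1221), 1e-3)
  expect_error(model_params(a_r = -1))
})

test_that("threshold voltages solve the half-activation steady state", {
  p <- model_params()
  iso <- neuron_network(NULL, nodes = "A")
  expect_equal(unname(threshold_voltage(iso, p, "chem1", 0)), p$V_rest)
  # closed form: V_rest + alpha_ext I / alpha_leak
  expect_equal(unname(threshold_voltage(iso, p, "chem2", 7)),
               p$V_rest + 7 / p$alpha_leak)
  expect_equal(unname(threshold_voltage(iso, p, "gap", -3)),
               p$V_rest - 3 / p$alpha_leak)

  # self-consistency: plugging the solution back into the RHS with the
  # sigmoid at 0.5 and s at s_eq gives a residual below 1e-10
  for (m in c("chem1", "chem2")) {
    for (nm in c("forward_chem_like", "backward_chem_like")) {
      fx <- fixture(nm, seed = 6)
      vt <- threshold_voltage(fx$net, p, m, 2)
      st <- if (m == "chem2") c(vt, rep(p$s_eq, n_nodes(fx$net))) else vt
      Iv <- setNames(rep(2, n_nodes(fx$net)), network_nodes(fx$net))
      r <- neuron_rhs(m, st, 0, fx$net, p, I_ext = Iv, V_threshold = vt)
      expect_lt(max(abs(r)), 1e-10)
    }
  }
  gx <- fixture("forward_gap_like", seed = 6)
  vtg <- threshold_voltage(gx$net, p, "gap", 0)
  expect_lt(max(abs(neuron_rhs("gap", vtg, 0, gx$net, p))), 1e-10)
})

test_that("model right-hand sides behave at anchor states", {
  p <- model_params()
  iso <- neuron_network(NULL, nodes = "A")
  for (m in c("gap", "chem1")) {
    expect_equal(unname(neuron_rhs(m, p$V_rest, 0, iso, p,
                                   V_threshold = p$V_rest)), 0)
  }
  # two gap-coupled neurons at equal voltage: only the leak term remains
  duo <- neuron_network(data.frame(tail = "A", head = "B"), directed = FALSE)
  d <- neuron_rhs("gap", c(-30, -30), 0, duo, p)
  expect_equal(unname(d), rep(-p$alpha_leak * (-30 - p$V_rest), 2))
  # gap model rejects asymmetric edge sets
  dir2 <- neuron_network(data.frame(tail = "A", head = "B"))
  expect_error(neuron_rhs("gap", c(-30, -30), 0, dir2, p), "undirected")
})

test_that("stimuli combine drive, oscillation and bounded shared noise", {
  fx <- fixture("forward_chem_like", seed = 2)
  expect_warning(
    build_stimulus(fx$roles$interneurons[1], I_drive = 1,
                   part = fx$partition),
    "partially"
  )
  st <- build_stimulus(fx$roles$interneurons, I_drive = 0.1, I_osc = 0.5,
                       freq = 2, noise_scale = 0.01, part = fx$partition)
  res <- integrate_network("chem1", fx$net, model_params(), st,
                           init = list(V = -35), T = 0.2, dt = 1e-3,
                           seed = 11)
  tr <- res$stimulus
  expect_equal(nrow(tr), 2L)
  # same fiber, shared noise: both targets see the identical stimulus
  expect_identical(tr[1, ], tr[2, ])
  expect_lte(max(abs(tr)), 0.1 + 0.5 + 0.01 + 1e-12)
  expect_equal(attr(tr, "max_amplitude_nominal"), 0.61)

  # constant-only stimulus
  st0 <- build_stimulus("A", I_drive = 2)
  iso <- neuron_network(NULL, nodes = "A")
  r0 <- integrate_network("chem1", iso, model_params(), st0,
                          init = list(V = -35), T = 0.05, dt = 1e-3)
  expect_true(all(r0$stimulus == 2))
})

test_that("free-running gap dynamics settle into global synchrony at rest", {
  p <- model_params()
  gx <- fixture("forward_gap_like", seed = 4)
  set.seed(1)
  res <- integrate_network("gap", gx$net, p, NULL,
                           init = list(V = rnorm(20, -35, 2)),
                           T = 2, dt = 1e-4)
  final <- res$V[, ncol(res$V)]
  expect_lt(max(abs(final - p$V_rest)), 1e-2)
  L <- los_matrix(res, window = 0.5)
  expect_true(all(L >= 0.999))
})

test_that("fiber-constant states stay exactly fiber-constant (flow invariance)", {
  p <- model_params()
  fx <- fixture("backward_chem_like", seed = 5)
  memb <- fx$partition$membership
  set.seed(3)
  cell_vals <- setNames(rnorm(fx$partition$k, -35, 2),
                        names(fx$partition$cells))
  V0 <- setNames(cell_vals[memb], names(memb))
  stim <- build_stimulus(fx$partition$cells[["c1"]], I_drive = 0.5,
                         I_osc = 0.2, freq = 2, part = fx$partition)
  for (m in c("chem1", "chem2")) {
    res <- integrate_network(m, fx$net, p, stim, init = list(V = V0),
                             T = 2, dt = 2e-4, seed = 8)
    spread <- 0
    for (cell in names(fx$partition$cells)) {
      nodes <- fx$partition$cells[[cell]]
      if (length(nodes) < 2) next
      blk <- res$V[nodes, , drop = FALSE]
      spread <- max(spread, max(apply(blk, 2, function(x) diff(range(x)))))
    }
    expect_lt(spread, 1e-10)
    if (m == "chem2") {
      expect_true(all(res$S >= 0 & res$S <= 1))
    }
  }
})

test_that("deterministic integration is order-4 in dt and node-order invariant", {
  p <- model_params()
  iso <- neuron_network(NULL, nodes = "A")
  stim <- build_stimulus("A", I_drive = 1, I_osc = 2, freq = 3)
  errs <- vapply(c(2e-3, 1e-3), function(dt) {
    r <- integrate_network("chem1", iso, p, stim, init = list(V = -35),
                           T = 0.5, dt = dt)
    ref <- integrate_network("chem1", iso, p, stim, init = list(V = -35),
                             T = 0.5, dt = dt / 20)
    abs(r$V[1, ncol(r$V)] - ref$V[1, ncol(ref$V)])
  }, 0)
  expect_gt(errs[1] / errs[2], 12) # halving dt: error drops ~2^4

  # permutation equivariance: relabelled network, same trajectories
  fx <- fixture("forward_chem_like", seed = 7)
  nodes <- network_nodes(fx$net)
  relab <- setNames(sprintf("zz%02d", rev(seq_along(nodes))), nodes)
  adj2 <- adjacency(fx$net)
  dimnames(adj2) <- list(unname(relab[rownames(adj2)]),
                         unname(relab[colnames(adj2)]))
  net2 <- network_from_adjacency(adj2)
  V0 <- setNames(seq(-40, -30, length.out = length(nodes)), nodes)
  V0b <- setNames(V0, unname(relab[names(V0)]))
  r1 <- integrate_network("chem1", fx$net, p, NULL, init = list(V = V0),
                          T = 0.2, dt = 1e-3)
  r2 <- integrate_network("chem1", net2, p, NULL, init = list(V = V0b),
                          T = 0.2, dt = 1e-3)
  expect_equal(r1$V[nodes, ], unname(r2$V[relab[nodes], ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("divergent states are reported with the offending step", {
  # a time step far beyond the stiff gap-coupling stability limit blows up
  p <- model_params()
  duo <- neuron_network(data.frame(tail = "A", head = "B"), directed = FALSE)
  expect_error(
    integrate_network("gap", duo, p, NULL, init = list(V = c(-10, -60)),
                      T = 20, dt = 0.05),
    "diverged"
  )
})
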