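test_that("LoS matches the Gaussian-kernel identities", {
  tt <- seq(0, 1, by = 1e-3)
  V <- rbind(a = sin(2 * pi * tt), b = sin(2 * pi * tt))
  L <- los_matrix(V, sigma = 0.1)
  expect_equal(unname(L["a", "b"]), 1)
  expect_equal(diag(unclass(L)), c(a = 1, b = 1))

  # constant 0.1 mV offset at sigma = 0.1 mV: exp(-1/2) ~ 0.61
  V2 <- rbind(a = rep(0, 100), b = rep(0.1, 100))
  L2 <- los_matrix(V2, sigma = 0.1)
  expect_equal(unname(L2["a", "b"]), exp(-0.5))
  expect_equal(round(unname(L2["a", "b"]), 2), 0.61)

  # ten-sigma offset: negligible
  V3 <- rbind(a = rep(0, 100), b = rep(1, 100))
  expect_lt(unname(los_matrix(V3, sigma = 0.1)["a", "b"]), 1e-21)

  # invariant under common shifts, monotone in the offset
  V4 <- V2 + 42
  expect_equal(unname(los_matrix(V4, sigma = 0.1)["a", "b"]),
               unname(L2["a", "b"]))
  offs <- c(0.05, 0.1, 0.2, 0.4)
  vals <- vapply(offs, function(o) {
    unname(los_matrix(rbind(a = rep(0, 10), b = rep(o, 10)),
                      sigma = 0.1)["a", "b"])
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("ideal LoS is the unit block matrix of the partition", {
  p1 <- node_partition(c(a = 1, b = 2, c = 3))
  expect_equal(unclass(ideal_los(p1)), diag(3), ignore_attr = TRUE)
  p2 <- node_partition(c(a = 1, b = 1, c = 1))
  expect_true(all(ideal_los(p2) == 1))
  p3 <- node_partition(c(a = 1, b = 1, c = 2, d = 2, e = 2))
  I3 <- ideal_los(p3)
  expect_equal(sum(I3), 2^2 + 3^2)
})

test_that("sync difference has the documented sign conventions", {
  p <- node_partition(c(a = 1, b = 1, c = 2, d = 2))
  idl <- ideal_los(p)
  expect_equal(sync_difference(idl, idl), 0)

  # two singleton fibers fully synchronized with each other: -2/(2(n^2-n))
  p2 <- node_partition(c(a = 1, b = 2))
  obs <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(sync_difference(obs, ideal_los(p2)), -2 / (2 * (4 - 2)))

  # a desynchronized within-fiber pair scores positive
  obs3 <- unclass(idl)
  obs3["a", "b"] <- obs3["b", "a"] <- 0.4
  expect_gt(sync_difference(obs3, idl), 0)

  # binarization: only entries at 1 - eps or above count as synchronous
  obs4 <- unclass(idl)
  obs4["a", "b"] <- obs4["b", "a"] <- 0.996
  expect_equal(sync_difference(obs4, idl), 0)
  expect_gt(sync_difference(obs4, idl, eps = 0.001), 0)

  expect_error(sync_difference(matrix(1, 3, 3), ideal_los(p2)), "shape")

  # any binary block matrix scores zero against itself
  for (seed in 1:5) {
    set.seed(seed)
    memb <- sample(1:3, 6, TRUE)
    names(memb) <- letters[1:6]
    X <- ideal_los(node_partition(memb))
    expect_equal(sync_difference(X, X), 0)
  }
})

test_that("PLV detects constant phase relations and rejects random ones", {
  tt <- seq(0, 2, by = 1e-3)
  s1 <- sin(2 * pi * 3 * tt)
  s2 <- sin(2 * pi * 3 * tt + 1.1) # fixed lag
  V <- rbind(a = s1, b = s1, c = s2)
  P <- plv_matrix(V)
  expect_equal(unname(P["a", "a"]), 1)
  expect_equal(unname(P["a", "b"]), 1, tolerance = 1e-6)
  expect_gt(unname(P["a", "c"]), 0.99) # same frequency, constant lag
  expect_true(all(P >= 0 & P <= 1 + 1e-12))

  # independent random-phase signals: PLV near zero over a long window
  set.seed(7)
  n_samp <- 1e4
  ph1 <- cumsum(rnorm(n_samp, 0, 0.5))
  ph2 <- cumsum(rnorm(n_samp, 0, 0.5))
  Vr <- rbind(a = sin(ph1), b = sin(ph2))
  expect_lt(unname(plv_matrix(Vr)["a", "b"]), 0.25)

  # different frequencies drift in phase: low PLV
  V5 <- rbind(a = sin(2 * pi * 2 * tt), b = sin(2 * pi * 3.3 * tt))
  expect_lt(unname(plv_matrix(V5)["a", "b"]), 0.3)
})

test_that("sigma calibration walks down until fibers are resolved", {
  # constructed separations: fibers sit 1 mV apart -> sigma well below 1 mV
  part <- node_partition(c(a = 1, b = 1, c = 2, d = 2))
  V <- rbind(a = rep(0, 200), b = rep(0, 200),
             c = rep(1, 200), d = rep(1, 200))
  sg <- calibrate_sigma(V, part)
  expect_lt(sg, 1)
  # Gaussian-tail bound: at the returned sigma the cross mean is below 1e-3
  expect_lt(mean(exp(-1 / (2 * sg^2))), 1e-3)
  # and one grid step up it is not
  expect_gt(mean(exp(-1 / (2 * 0.5^2))), 1e-3)

  single <- node_partition(c(a = 1, b = 1))
  Vs <- rbind(a = rep(0, 10), b = rep(0, 10))
  expect_warning(sg1 <- calibrate_sigma(Vs, single), "single-fiber")
  expect_equal(sg1, 10)
})

test_that("the paper-scale operating point resolves chem-fixture fibers", {
  # free-running chem run on the richest-fiber network: the calibrated
  # kernel scale separates the equilibrium fibers
  p <- model_params()
  fx <- fixture("backward_chem_like", seed = 4)
  set.seed(2)
  res <- integrate_network("chem1", fx$net, p, NULL,
                           init = list(V = rnorm(30, -35, 1)),
                           T = 3, dt = 2e-4)
  sg <- calibrate_sigma(res, fx$partition, window = 1)
  expect_lte(sg, 0.5)
  L <- los_matrix(res, window = 1, sigma = sg)
  expect_true(fibersync:::within_fiber_synchrony(L, fx$partition))
})
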