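# Independent oracles and fixture builders shared across the suite.

# random integer-weighted digraph (no self-loops unless asked)
random_net <- function(n, p = 0.3, max_w = 2, seed = 1, directed = TRUE,
                       self_loops = FALSE) {
  set.seed(seed)
  adj <- matrix(rbinom(n * n, 1, p) * sample(seq_len(max_w), n * n, TRUE), n)
  if (!self_loops) diag(adj) <- 0
  if (!directed) adj <- pmax(adj, t(adj))
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  network_from_adjacency(adj, directed = directed)
}

# all permutations of a vector (n <= 7)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# brute-force orbit partition: filter all n! permutations by adjacency
# preservation, then union-find over every automorphism's images
brute_orbits <- function(net) {
  nodes <- network_nodes(net)
  adj <- adjacency(net)
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(i) while (TRUE) {
    if (parent[i] == i) return(i)
    i <- parent[i]
  }
  autos <- 0L
  for (p in all_perms(seq_len(n))) {
    if (all(adj[p, p] == adj)) {
      autos <- autos + 1L
      for (w in seq_len(n)) {
        ri <- find(w); rj <- find(p[w])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  memb <- vapply(seq_len(n), find, 0L)
  list(partition = node_partition(setNames(memb, nodes)), n_autos = autos)
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(maxc + 1L)) rec(c(prefix, c), max(maxc, c))
  }
  rec(integer(0), 0L)
  out
}

# central finite-difference Jacobian of the model RHS at a state
fd_jacobian <- function(model, net, params, V_thr, h = 1e-6) {
  n <- n_nodes(net)
  x0 <- if (model == "chem2") c(V_thr, rep(params$s_eq, n)) else V_thr
  m <- length(x0)
  J <- matrix(0, m, m)
  for (k in seq_len(m)) {
    xp <- x0; xm <- x0
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    J[, k] <- (neuron_rhs(model, xp, 0, net, params, V_threshold = V_thr) -
                 neuron_rhs(model, xm, 0, net, params, V_threshold = V_thr)) /
      (2 * h)
  }
  J
}

# forward trail enumeration: walks over distinct edges counted whenever the
# walk currently ends at the root (independent of the reverse-DFS used by
# trail_count)
brute_trails <- function(net, root) {
  simple <- (adjacency(net) != 0) * 1
  nodes <- network_nodes(net)
  simple[match(root, nodes), ] <- 0
  idx <- which(simple != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  count <- 0L
  used <- logical(nrow(idx))
  step <- function(at) {
    for (e in which(idx[, 1] == at & !used)) {
      used[e] <<- TRUE
      if (nodes[idx[e, 2]] == root) count <<- count + 1L
      step(idx[e, 2])
      used[e] <<- FALSE
    }
  }
  for (s in seq_along(nodes)) step(s)
  count
}

# layer sizes by explicit matrix powers: a_i = 1' A^i e_root
powers_layer_sizes <- function(net, root, depth) {
  adj <- adjacency(net)
  e <- as.numeric(network_nodes(net) == root)
  out <- numeric(depth + 1L)
  v <- e
  out[1] <- sum(v)
  for (i in seq_len(depth)) {
    v <- as.vector(adj %*% v)
    out[i + 1L] <- sum(v)
  }
  out
}

# fixture: composite block — pair fiber with per-member regulators whose
# components are only bridged through outside nodes p, q
composite_fixture <- function() {
  net <- neuron_network(data.frame(
    tail = c("a1", "a2", "a1", "p", "a2", "q"),
    head = c("x1", "x2", "p", "a2", "q", "a1")
  ))
  part <- node_partition(c(x1 = "X", x2 = "X", a1 = "A", a2 = "A",
                           p = "P", q = "P"))
  list(net = net, partition = part)
}

# fixture: two-fiber loop whose circuit renders |1, 1> (+) |1, 2>
two_layer_loop_fixture <- function() {
  net <- neuron_network(data.frame(
    tail = c("r1", "r2", "m2", "m1", "t1", "t2"),
    head = c("m1", "m2", "r1", "r2", "r1", "r2")
  ))
  part <- minimal_balanced_coloring(net)
  list(net = net, partition = part)
}

# fixture: VA02-VA05 style sub-graph — four nodes fed equally by three
# source pairs, two of them sinks, outputs entangled so that only the
# simultaneous swap (VA02 VA03)(VA04 VA05) preserves adjacency
va_toy_fixture <- function() {
  vas <- c("VA02", "VA03", "VA04", "VA05")
  srcs <- c("S1a", "S1b", "S2a", "S2b", "S3a", "S3b")
  edges <- expand.grid(tail = srcs, head = vas, stringsAsFactors = FALSE)
  edges <- rbind(edges, data.frame(tail = c("VA02", "VA03"),
                                   head = c("VA05", "VA04")))
  neuron_network(edges)
}

expect_same_partition <- function(a, b) {
  expect_true(same_partition(a, b))
}
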