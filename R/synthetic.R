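#' Planted-fiber network specification
#'
#' Describes a random lift of a base multigraph: `k` cells with given sizes,
#' and a `k x k` base matrix `B` whose entry `B[j, i]` is the number of
#' in-edges every node of cell `i` receives from cell `j`. The lift is
#' balanced by construction; the spec is additionally required to have a base
#' whose own minimal balanced coloring is trivial, which guarantees the
#' lift's minimal balanced coloring equals the planted partition (input
#' trees lift through the fibration).
#'
#' @param sizes integer cell sizes.
#' @param base `k x k` non-negative integer matrix, `B[j, i]` = in-edges per
#'   cell-`i` node from cell `j`.
#' @param directed logical; undirected bases must satisfy the edge-count
#'   consistency `sizes[i] * B[j, i] == sizes[j] * B[i, j]`.
#' @param pair_cells indices of size-2 cells representing left-right
#'   interneuron pairs.
#' @param allow_multiplicity directed lifts may reuse a tail (multi-edge)
#'   when `B[j, i] > |cell j|`.
#' @export
planted_fiber_spec <- function(sizes, base, directed = TRUE,
                               pair_cells = integer(0),
                               allow_multiplicity = FALSE) {
  k <- length(sizes)
  stopifnot(is.matrix(base), nrow(base) == k, ncol(base) == k,
            all(base >= 0), all(base == round(base)), all(sizes >= 1))
  if (!directed) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (sizes[i] * base[j, i] != sizes[j] * base[i, j]) {
          stop(sprintf(
            "infeasible undirected spec: cell sizes %d*%d != %d*%d for pair (%d, %d)",
            sizes[i], base[j, i], sizes[j], base[i, j], i, j
          ))
        }
        if (j > i && base[j, i] > 0) {
          # cross-cell blocks are unions of rotation orbits on Z_si x Z_sj;
          # each orbit contributes sj/gcd to the cell-i degree
          g <- gcd2(sizes[i], sizes[j])
          per <- sizes[j] / g
          if (base[j, i] %% per != 0 || base[j, i] / per > g) {
            stop(sprintf(
              "infeasible undirected spec: degree %d between cells %d, %d is not realizable as aligned circulant orbits",
              base[j, i], i, j
            ))
          }
        }
      }
      d <- base[i, i]
      if (d >= sizes[i]) stop("within-cell degree must be below the cell size")
      if (d %% 2 == 1 && sizes[i] %% 2 == 1) {
        stop("odd within-cell degree needs an even cell size")
      }
    }
  } else if (!allow_multiplicity) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        avail <- sizes[j] - (i == j)
        if (base[j, i] > avail) {
          stop(sprintf(
            "infeasible spec: B[%d, %d] = %d exceeds available tails (%d) in cell %d",
            j, i, base[j, i], avail, j
          ))
        }
      }
    }
  }
  if (length(pair_cells) && any(sizes[pair_cells] != 2L)) {
    stop("pair cells must have size 2")
  }
  structure(list(sizes = as.integer(sizes), base = base, directed = directed,
                 pair_cells = as.integer(pair_cells),
                 allow_multiplicity = allow_multiplicity),
            class = "planted_fiber_spec")
}

#' Draw a network with a planted fiber partition
#'
#' Random lift of the base: every node of cell `i` receives exactly
#' `B[j, i]` in-edges from cell `j`, with tails chosen uniformly (directed
#' case) or via a randomized biregular pairing (undirected case). The draw
#' is certified before returning: the minimal balanced coloring of the lift
#' must equal the planted partition (resampled up to `max_retries`
#' otherwise).
#'
#' @param spec a [planted_fiber_spec()].
#' @param seed integer seed; the draw is deterministic per seed.
#' @param max_retries certification retry cap.
#' @return list with `net` (a [neuron_network()]) and `partition` (the
#'   planted [node_partition()]).
#' @export
planted_fiber_graph <- function(spec, seed = 1L, max_retries = 20L) {
  stopifnot(inherits(spec, "planted_fiber_spec"))
  for (attempt in seq_len(max_retries)) {
    set.seed(seed + (attempt - 1L) * 1009L)
    draw <- lift_once(spec)
    got <- minimal_balanced_coloring(draw$net)
    if (!same_partition(got, draw$partition)) next
    # undirected draws are additionally audited for orbit/fiber agreement,
    # the structure the gap-junction study networks exhibit
    if (!spec$directed &&
        !same_partition(orbit_partition(draw$net), draw$partition)) {
      next
    }
    return(draw)
  }
  stop("could not certify the planted partition; the base likely has a ",
       "non-trivial balanced coloring")
}

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

lift_once <- function(spec) {
  k <- length(spec$sizes)
  cells <- vector("list", k)
  for (i in seq_len(k)) {
    cells[[i]] <- sprintf("f%02dn%02d", i, seq_len(spec$sizes[i]))
  }
  nodes <- unlist(cells)
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (spec$directed) {
    for (i in seq_len(k)) {
      for (v in cells[[i]]) {
        for (j in seq_len(k)) {
          m <- spec$base[j, i]
          if (m == 0) next
          pool <- setdiff(cells[[j]], v)
          if (spec$allow_multiplicity && m > length(pool)) {
            tails <- sample(pool, m, replace = TRUE)
            for (tl in tails) adj[tl, v] <- adj[tl, v] + 1
          } else {
            tails <- sample(pool)[seq_len(m)]
            adj[tails, v] <- adj[tails, v] + 1
          }
        }
      }
    }
  } else {
    # Aligned circulant lift: index cell i by Z_{s_i}; edges are unions of
    # orbits of the simultaneous rotation x -> x + 1 (mod s) acting in every
    # cell. That rotation is then an automorphism acting transitively within
    # each cell, so the draw's orbit partition equals the planted fibers.
    # Randomness: random orbit offsets and a random relabelling per cell.
    perms <- lapply(seq_len(k), function(i) sample(cells[[i]]))
    for (i in seq_len(k)) {
      s <- spec$sizes[i]
      d <- spec$base[i, i]
      if (d > 0) {
        half <- if (s %% 2 == 0) s / 2 else (s - 1) / 2
        pool <- setdiff(seq_len(half), if (s %% 2 == 0) s / 2 else integer(0))
        n_off <- if (d %% 2 == 0) d / 2 else (d - 1) / 2
        offs <- if (n_off > 0) sample(pool)[seq_len(n_off)] else integer(0)
        if (d %% 2 == 1) offs <- c(offs, s / 2)
        for (a in seq_len(s)) {
          for (o in offs) {
            b <- ((a - 1 + o) %% s) + 1
            u <- perms[[i]][a]; v <- perms[[i]][b]
            if (o == s / 2 && a > b) next # matching edge once
            adj[u, v] <- adj[u, v] + 1
            adj[v, u] <- adj[v, u] + 1
          }
        }
      }
      for (j in seq_len(k)) {
        if (j <= i) next
        di <- spec$base[j, i] # degree of a cell-i node toward cell j
        if (di == 0) next
        sj <- spec$sizes[j]
        g <- gcd2(s, sj)
        n_orb <- di * g / sj
        cs <- sample(seq_len(g))[seq_len(n_orb)] - 1L # orbit labels in Z_g
        for (a in seq_len(s)) {
          for (cc in cs) {
            # orbit cc pairs (a, b) with b - a = cc (mod g)
            for (b0 in seq((a - 1L + cc) %% g, sj - 1L, by = g)) {
              u <- perms[[i]][a]; v <- perms[[j]][b0 + 1L]
              adj[u, v] <- adj[u, v] + 1
              adj[v, u] <- adj[v, u] + 1
            }
          }
        }
      }
    }
  }
  net <- network_from_adjacency(adj, directed = spec$directed)
  memb <- setNames(rep(seq_len(k), spec$sizes), nodes)
  list(net = net, partition = node_partition(memb))
}

#' Built-in fixture networks
#'
#' Worked-example graphs and planted-symmetry stand-ins at the study's
#' node/fiber counts:
#' * `cyan_multigraph` — the 3-node multigraph (root C, regulators M, P)
#'   whose input tree has layer sizes 1, 3, 11, 35, ... and branching ratio
#'   3.3723 (the real root of x^3 = 9x + 8).
#' * `two_regulator_hub` — a hub fed by two independent sources: |0, 2>.
#' * `bidirectional_square` — four nodes in an undirected square: one fiber,
#'   |2, 0>.
#' * `fibonacci_base` — parametric 2-node base with multiplicity matrix
#'   `rbind(c(a, b), c(c, d))`; `fibonacci_base(1, 1, 1, 0)` grows at the
#'   golden ratio.
#' * `forward_chem_like`, `backward_chem_like`, `forward_gap_like` (alias
#'   `gap_like`), `backward_gap_like` — planted-fiber draws at the study's
#'   scale (22 nodes/4 fibers, 30/10, 20/6, 29/6). These are synthetic
#'   stand-ins with the assumed symmetry structure (left-right interneuron
#'   pairs as their own size-2 fibers driving the rest), not connectome
#'   reconstructions.
#'
#' @param name fixture name.
#' @param seed seed for the planted draws.
#' @param a,b,c,d multiplicities for `fibonacci_base`.
#' @return list with `net`, `partition` (`NULL` where not defined) and
#'   `roles` (drive-target bookkeeping for the planted fixtures).
#' @export
fixture <- function(name, seed = 1L, a = 1, b = 1, c = 1, d = 0) {
  name <- match.arg(name, c(
    "cyan_multigraph", "two_regulator_hub", "bidirectional_square",
    "fibonacci_base", "forward_chem_like", "backward_chem_like",
    "gap_like", "forward_gap_like", "backward_gap_like"
  ))
  if (name == "cyan_multigraph") {
    net <- neuron_network(data.frame(
      tail = c("M", "P", "M", "P", "C", "C"),
      head = c("C", "C", "P", "M", "M", "P"),
      weight = c(1, 2, 2, 2, 1, 2)
    ), directed = TRUE)
    return(list(net = net, partition = NULL, roles = list(root = "C")))
  }
  if (name == "two_regulator_hub") {
    net <- neuron_network(data.frame(
      tail = c("R1", "R2"), head = c("H", "H"), weight = c(1, 1)
    ), directed = TRUE)
    # the two regulators play distinct upstream fibers, as in the worked
    # first-layer block (a hub driven by two different fiber classes)
    return(list(net = net,
                partition = node_partition(c(H = "hub", R1 = "srcA",
                                             R2 = "srcB")),
                roles = list(root = "H")))
  }
  if (name == "bidirectional_square") {
    net <- neuron_network(data.frame(
      tail = c("Q1", "Q2", "Q3", "Q4"),
      head = c("Q2", "Q3", "Q4", "Q1"),
      weight = 1
    ), directed = FALSE)
    part <- node_partition(setNames(rep("sq", 4), paste0("Q", 1:4)))
    return(list(net = net, partition = part, roles = list(root = "Q1")))
  }
  if (name == "fibonacci_base") {
    adjm <- rbind(c(a, b), c(c, d))
    dimnames(adjm) <- list(c("X", "Y"), c("X", "Y"))
    return(list(net = network_from_adjacency(adjm, directed = TRUE),
                partition = NULL, roles = list(root = "X")))
  }
  spec <- switch(name,
    forward_chem_like = planted_fiber_spec(
      sizes = c(2, 4, 6, 10),
      base = rbind(
        c(1, 2, 1, 1),
        c(0, 0, 1, 2),
        c(0, 1, 0, 1),
        c(0, 0, 0, 0)
      ),
      directed = TRUE, pair_cells = 1L
    ),
    backward_chem_like = planted_fiber_spec(
      sizes = c(2, 2, 2, 2, 2, 5, 5, 4, 4, 2),
      base = local({
        B <- matrix(0L, 10, 10)
        put <- function(B, j, i, m) { B[j, i] <- m; B }
        B <- put(B, 1, 1, 1); B <- put(B, 1, 2, 1); B <- put(B, 2, 2, 1)
        B <- put(B, 2, 3, 1); B <- put(B, 3, 3, 1)
        B <- put(B, 1, 4, 1); B <- put(B, 3, 4, 1); B <- put(B, 4, 4, 1)
        B <- put(B, 2, 5, 1); B <- put(B, 4, 5, 1); B <- put(B, 5, 5, 1)
        B <- put(B, 1, 6, 2); B <- put(B, 2, 6, 1)
        B <- put(B, 1, 7, 1); B <- put(B, 2, 7, 2)
        B <- put(B, 3, 8, 2); B <- put(B, 6, 8, 1)
        B <- put(B, 4, 9, 2); B <- put(B, 5, 9, 1); B <- put(B, 6, 9, 1)
        B <- put(B, 1, 10, 1); B <- put(B, 5, 10, 2); B <- put(B, 7, 10, 1)
        B
      }),
      directed = TRUE, pair_cells = 1:5
    ),
    gap_like = ,
    forward_gap_like = planted_fiber_spec(
      sizes = c(2, 2, 4, 4, 4, 4),
      base = rbind(
        c(1, 1, 1, 2, 0, 0),
        c(1, 1, 0, 0, 1, 0),
        c(2, 0, 0, 0, 1, 0),
        c(4, 0, 0, 0, 0, 1),
        c(0, 2, 1, 0, 0, 2),
        c(0, 0, 0, 1, 2, 0)
      ),
      directed = FALSE, pair_cells = 1:2
    ),
    backward_gap_like = planted_fiber_spec(
      sizes = c(2, 2, 5, 5, 5, 10),
      base = rbind(
        c(1, 1, 2, 0, 0, 0),
        c(1, 1, 0, 0, 0, 1),
        c(5, 0, 0, 1, 0, 0),
        c(0, 0, 1, 0, 2, 0),
        c(0, 0, 0, 2, 0, 1),
        c(0, 5, 0, 0, 2, 2)
      ),
      directed = FALSE, pair_cells = 1:2
    )
  )
  draw <- planted_fiber_graph(spec, seed = seed)
  roles <- list(
    interneurons = draw$partition$cells[["c1"]],
    motor = if (length(spec$pair_cells) > 1L) draw$partition$cells[["c2"]]
            else NULL
  )
  c(draw, list(roles = roles))
}

#' Perturb edge weights with Gaussian noise
#'
#' Every nonzero weight `w` becomes `w - N(0, std^2)` (independent draws;
#' undirected edges are perturbed once and mirrored). Models the
#' partial-information scenario: the symmetry structure is kept, the exact
#' multiplicities are not. Edge support is preserved.
#'
#' @param net a [neuron_network()].
#' @param std standard deviation of the perturbation (study grid: 0 to 0.1).
#' @param seed integer seed.
#' @export
perturb_weights <- function(net, std, seed = 1L) {
  if (std < 0) stop("std must be non-negative")
  if (std == 0) return(net)
  set.seed(seed)
  adj <- net$adj
  if (net$directed) {
    idx <- which(adj != 0)
    adj[idx] <- adj[idx] - rnorm(length(idx), 0, std)
  } else {
    idx <- which(adj != 0 & upper.tri(adj, diag = TRUE), arr.ind = TRUE)
    eps <- rnorm(nrow(idx), 0, std)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      adj[i, j] <- adj[i, j] - eps[r]
      if (i != j) adj[j, i] <- adj[i, j]
    }
  }
  new_neuron_network(adj, net$directed)
}
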