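#' Circuit of a fiber
#'
#' The circuit of a fiber is computed on the base graph (total space
#' collapsed under its minimal balanced coloring): it keeps the fiber's base
#' node plus every base node that can reach it, i.e. all fibers appearing in
#' its input tree.
#'
#' @param net a [neuron_network()] (total space).
#' @param part the minimal balanced coloring of `net`.
#' @param fiber a cell id of `part` (e.g. `"c2"`) or any member node.
#' @return the circuit as a `neuron_network` over base nodes (named by each
#'   cell's smallest member), with attribute `main_fiber` naming the root
#'   base node.
#' @export
extract_circuit <- function(net, part, fiber) {
  base <- quotient_graph(net, part)
  root <- base_node_of(base, part, fiber)
  keep <- names(which(reaches_root(adjacency(base), root)))
  out <- induced_subnetwork(base, keep)
  attr(out, "main_fiber") <- root
  attr(out, "cell_of") <- attr(base, "cell_of")[keep]
  out
}

# resolve a fiber reference (cell id or member node) to its base node name
base_node_of <- function(base, part, fiber) {
  cell_of <- attr(base, "cell_of")
  if (fiber %in% names(part$cells)) {
    reps <- names(cell_of)[cell_of == fiber]
    if (length(reps) != 1L) stop("unknown fiber id: ", fiber)
    return(reps)
  }
  hit <- vapply(part$cells, function(cl) fiber %in% cl, NA)
  if (!any(hit)) stop("unknown fiber id: ", fiber)
  names(cell_of)[cell_of == names(part$cells)[hit][1L]]
}

# logical vector: which nodes have a (possibly empty) walk to root
reaches_root <- function(adj, root) {
  nodes <- rownames(adj)
  seen <- setNames(logical(length(nodes)), nodes)
  seen[root] <- TRUE
  frontier <- root
  while (length(frontier) > 0) {
    pred <- nodes[rowSums(adj[, frontier, drop = FALSE] > 0) > 0]
    frontier <- pred[!seen[pred]]
    seen[frontier] <- TRUE
  }
  seen
}

#' Fiber building block of a fiber
#'
#' The FBB is the subgraph induced by (1) the fiber's nodes, (2) their
#' immediate in-neighbors ("regulators"), (3) the nodes of the shortest
#' non-self loop through a fiber node, and (4), if those rules leave the
#' subgraph weakly disconnected, the nodes of the shortest path bridging each
#' component pair ("composite" blocks). Ties in rules 3 and 4 are resolved by
#' including all shortest witnesses.
#'
#' @param net a [neuron_network()] — the total space, or a base graph with
#'   `part` its singleton partition for elementary blocks.
#' @param part a balanced [node_partition()] of `net`.
#' @param fiber cell id or member node.
#' @return object of class `fbb`: list with `net` (induced subnetwork),
#'   `fiber`, `regulators`, `composite`, `root` (representative fiber node).
#' @export
extract_fbb <- function(net, part, fiber) {
  nodes <- network_nodes(net)
  adj <- net$adj
  if (fiber %in% names(part$cells)) {
    fib <- part$cells[[fiber]]
  } else {
    hit <- vapply(part$cells, function(cl) fiber %in% cl, NA)
    if (!any(hit)) stop("unknown fiber id: ", fiber)
    fib <- part$cells[[which(hit)[1L]]]
  }
  # rule 2: immediate in-neighbors
  inn <- nodes[rowSums(adj[, fib, drop = FALSE] > 0) > 0]
  regulators <- sort(union(setdiff(inn, fib), intersect(inn, fib)))
  keep <- union(fib, inn)
  # rule 3: shortest non-self loop through a fiber node
  ig <- to_igraph(net, weighted = FALSE)
  d <- igraph::distances(ig, mode = "out", weights = NA)
  best <- Inf
  witnesses <- list()
  for (v in fib) {
    succ <- nodes[adj[v, ] > 0]
    for (w in setdiff(succ, v)) {
      len <- 1 + d[w, v]
      if (!is.finite(len) || len > best) next
      paths <- igraph::all_shortest_paths(ig, from = w, to = v,
                                          mode = "out", weights = NA)$vpaths
      pn <- unique(unlist(lapply(paths, function(p) names(p))))
      wit <- union(v, pn)
      if (len < best) {
        best <- len
        witnesses <- list(wit)
      } else {
        witnesses <- c(witnesses, list(wit))
      }
    }
  }
  keep <- union(keep, unlist(witnesses))
  # rule 4: bridge weakly disconnected components by shortest paths
  composite <- FALSE
  repeat {
    sub <- induced_subnetwork(net, keep)
    comp <- weak_components(adjacency(sub))
    if (max(comp) == 1L || n_nodes(sub) == 0L) break
    bridge <- shortest_bridges(ig, d, network_nodes(sub), comp)
    if (is.null(bridge)) break # disconnected even in the host graph
    composite <- TRUE
    keep <- union(keep, bridge)
  }
  sub <- induced_subnetwork(net, keep)
  structure(list(net = sub, fiber = sort(fib), regulators = regulators,
                 composite = composite, root = sort(fib)[1L],
                 membership = part$membership[network_nodes(sub)]),
            class = "fbb")
}

# base representation of a building block: quotient of its subgraph under
# the host partition restricted to it (refined minimally where the
# restriction is no longer balanced on the subgraph). Fiber numbers are
# defined on this base.
fbb_base <- function(fbb) {
  net <- fbb$net
  init <- fbb$membership
  if (is.null(init)) init <- setNames(network_nodes(net),
                                      network_nodes(net))
  colors <- coarsest_refinement(adjacency(net), unname(init))
  part <- node_partition(setNames(colors, network_nodes(net)))
  base <- quotient_graph(net, part)
  root <- network_nodes(net)[match(fbb$root, network_nodes(net))]
  # base nodes carry the smallest member's name; find the root's cell rep
  rep_root <- part$cells[[part$membership[[fbb$root]]]][1L]
  list(base = base, root = rep_root)
}

#' @export
print.fbb <- function(x, ...) {
  cat(sprintf("<fbb: fiber {%s}, %d regulator(s)%s>\n",
              paste(x$fiber, collapse = " "), length(x$regulators),
              if (x$composite) ", composite" else ""))
  if (!is.null(x$n)) {
    cat(" fiber numbers:", render_fiber_number(x$n, x$ell), "\n")
  }
  invisible(x)
}

weak_components <- function(adj) {
  und <- (adj + t(adj)) > 0
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nbr <- which(rowSums(und[, frontier, drop = FALSE]) > 0)
      frontier <- nbr[comp[nbr] == 0L]
      comp[frontier] <- cur
    }
  }
  comp
}

# all nodes on the shortest directed path(s) between the closest component
# pair (either direction), or NULL if none exists in the host graph
shortest_bridges <- function(ig, d, sub_nodes, comp) {
  groups <- split(sub_nodes, comp)
  best <- Inf
  pairs <- list()
  for (a in seq_along(groups)) {
    for (b in seq_along(groups)) {
      if (a == b) next
      dd <- d[groups[[a]], groups[[b]], drop = FALSE]
      m <- suppressWarnings(min(dd))
      if (!is.finite(m) || m > best) next
      idx <- which(dd == m, arr.ind = TRUE)
      hits <- lapply(seq_len(nrow(idx)), function(r) {
        c(groups[[a]][idx[r, 1]], groups[[b]][idx[r, 2]])
      })
      if (m < best) {
        best <- m
        pairs <- hits
      } else {
        pairs <- c(pairs, hits)
      }
    }
  }
  if (!is.finite(best)) return(NULL)
  out <- character(0)
  for (p in pairs) {
    paths <- igraph::all_shortest_paths(ig, from = p[1], to = p[2],
                                        mode = "out", weights = NA)$vpaths
    out <- union(out, unlist(lapply(paths, function(q) names(q))))
  }
  out
}

#' Branching ratio |n> of a building block
#'
#' The limiting ratio `a_{i+1}/a_i` of the input-tree layer sizes, computed
#' as the spectral radius of the multiplicity matrix restricted to the nodes
#' that can reach the root (0 when the input tree is finite), and
#' cross-validated against the empirical layer-size ratio at `max_depth`.
#'
#' @param x an `fbb` or a [neuron_network()].
#' @param root root node; defaults to the block's fiber representative.
#' @param max_depth depth for the empirical cross-check.
#' @param tol maximum allowed |spectral - empirical| disagreement.
#' @export
branching_ratio <- function(x, root = NULL, max_depth = 120L, tol = 1e-3) {
  net <- if (inherits(x, "fbb")) x$net else x
  if (is.null(root)) {
    if (!inherits(x, "fbb")) stop("root is required for a plain network")
    root <- x$root
  }
  adj <- net$adj
  keep <- names(which(reaches_root(adj, root)))
  sub <- adj[keep, keep, drop = FALSE]
  ev <- eigen(sub, only.values = TRUE)$values
  spectral <- max(Mod(ev))
  if (spectral < 1e-9) spectral <- 0
  # empirical check via layer sizes: sqrt of the two-step ratio damps
  # odd/even oscillation, and Richardson extrapolation (2 r(d) - r(d/2))
  # cancels the O(1/depth) bias of polynomially growing (defective
  # eigenvalue) trees
  a <- build_input_tree(net, root, max_depth)$layer_sizes
  if (a[length(a)] == 0) {
    empirical <- 0
  } else {
    r_at <- function(i) sqrt(a[i] / a[i - 2L])
    i <- length(a)
    h <- max(5L, i %/% 2L)
    empirical <- if (i >= 10L) 2 * r_at(i) - r_at(h) else r_at(i)
  }
  if (abs(spectral - empirical) > tol) {
    stop(sprintf(
      "branching ratio did not converge: spectral %.6f vs empirical %.6f at depth %d",
      spectral, empirical, max_depth
    ))
  }
  spectral
}

#' Trail count |l> of a building block
#'
#' The number of distinct edge-simple trails terminating at the root,
#' enumerated on the simple (multiplicity-ignored) graph with the root's
#' out-edges removed. Exhaustive depth-first enumeration; capped by edge
#' count.
#'
#' @inheritParams branching_ratio
#' @param max_edges enumeration cap; more edges raises a capability error.
#' @export
trail_count <- function(x, root = NULL, max_edges = 24L) {
  net <- if (inherits(x, "fbb")) x$net else x
  if (is.null(root)) {
    if (!inherits(x, "fbb")) stop("root is required for a plain network")
    root <- x$root
  }
  nodes <- network_nodes(net)
  simple <- (net$adj != 0) * 1
  simple[match(root, nodes), ] <- 0 # trails terminate at the root
  idx <- which(simple != 0, arr.ind = TRUE)
  if (nrow(idx) > max_edges) {
    stop(sprintf("trail enumeration capped at %d edges (got %d)",
                 max_edges, nrow(idx)))
  }
  if (nrow(idx) == 0L) return(0L)
  # reverse the edges and walk outward from the root: every partial walk is
  # one trail ending at the root in the original orientation
  efrom <- idx[, 2] # reversed tail
  eto <- idx[, 1] # reversed head
  by_from <- split(seq_len(nrow(idx)), efrom)
  used <- logical(nrow(idx))
  count_from <- function(v) {
    total <- 0L
    for (e in by_from[[as.character(v)]]) {
      if (used[e]) next
      used[e] <<- TRUE
      total <- total + 1L + count_from(eto[e])
      used[e] <<- FALSE
    }
    total
  }
  ri <- match(root, nodes)
  if (is.na(ri)) stop("unknown root node: ", root)
  if (is.null(by_from[[as.character(ri)]])) return(0L)
  count_from(ri)
}

#' Classify a building block from its fiber numbers
#'
#' `finite` blocks have branching ratio 0 (finite input tree); `n-loop`
#' blocks have an integer ratio `n >= 1`; blocks whose ratio is not within
#' tolerance of an integer are `Fibonacci` (nested loops of several
#' lengths). Blocks assembled through the bridging rule are `composite`
#' regardless of ratio.
#'
#' @param fbb an `fbb`, ideally from [fiber_numbers()].
#' @param tol relative integer-detection tolerance.
#' @export
classify_fbb <- function(fbb, tol = 1e-6) {
  if (isTRUE(fbb$composite)) return("composite")
  n <- fbb$n
  if (is.null(n)) stop("compute fiber numbers first (fiber_numbers())")
  if (n == 0) return("finite")
  if (abs(n - round(n)) <= tol * max(1, abs(n)) && round(n) >= 1) {
    return("n-loop")
  }
  "Fibonacci"
}

#' Fiber numbers |n, l> of a building block
#'
#' Attaches the branching ratio `n`, trail count `ell` and class label to an
#' `fbb`. Both numbers are defined on the block's base representation (its
#' subgraph collapsed under the host partition, minimally refined where the
#' restriction is unbalanced): `n` is the layer growth rate of the base
#' input tree, `ell` counts edge-simple trails in the base with edge
#' multiplicity ignored.
#'
#' @param fbb an `fbb`.
#' @param max_depth,tol passed to [branching_ratio()].
#' @param max_edges passed to [trail_count()].
#' @export
fiber_numbers <- function(fbb, max_depth = 120L, tol = 1e-3, max_edges = 24L) {
  bb <- fbb_base(fbb)
  fbb$n <- branching_ratio(bb$base, bb$root, max_depth = max_depth,
                           tol = tol)
  fbb$ell <- trail_count(bb$base, bb$root, max_edges = max_edges)
  fbb$class_label <- classify_fbb(fbb)
  fbb
}

render_fiber_number <- function(n, ell) {
  ns <- if (abs(n - round(n)) < 1e-9) format(round(n)) else sprintf("%.3f", n)
  sprintf("|%s, %d⟩", ns, as.integer(ell))
}

#' Multilayer composition signature of a fiber's circuit
#'
#' Layers the fibers of a circuit by backward breadth-first distance from the
#' main fiber in the base graph, each fiber appearing once at its shallowest
#' layer. Every listed fiber contributes the |n, l> pair of its elementary
#' building block in the base; pure-source fibers (|0, 0>) are regulators
#' inside other blocks and are not listed separately, except for the main
#' fiber which always opens the signature. Rendered with `⊕` between
#' layers and `+` within a layer.
#'
#' @inheritParams extract_circuit
#' @return object of class `multilayer_signature`: list of layers, each a
#'   data frame with columns `fiber`, `n`, `ell`.
#' @export
multilayer_signature <- function(net, part, fiber) {
  circ <- extract_circuit(net, part, fiber)
  main <- attr(circ, "main_fiber")
  adj <- adjacency(circ)
  nodes <- network_nodes(circ)
  # backward BFS distance from the main fiber
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[main] <- 0
  frontier <- main
  while (length(frontier) > 0) {
    pred <- nodes[rowSums(adj[, frontier, drop = FALSE] > 0) > 0]
    pred <- pred[!is.finite(dist[pred])]
    dist[pred] <- dist[frontier[1L]] + 1 # BFS: frontier is a single level
    frontier <- pred
  }
  sing <- singleton_partition(circ)
  layers <- list()
  for (lv in sort(unique(dist[is.finite(dist)]))) {
    members <- nodes[dist == lv]
    rows <- list()
    for (f in sort(members)) {
      blk <- fiber_numbers(extract_fbb(circ, sing, f))
      if (f != main && blk$n == 0 && blk$ell == 0) next # pure source
      rows[[length(rows) + 1L]] <- data.frame(fiber = f, n = blk$n,
                                              ell = blk$ell)
    }
    if (length(rows) > 0) {
      layers[[length(layers) + 1L]] <- do.call(rbind, rows)
    }
  }
  structure(list(layers = layers, main_fiber = main),
            class = "multilayer_signature")
}

#' @export
print.multilayer_signature <- function(x, ...) {
  cat(render_signature(x), "\n")
  invisible(x)
}

#' Render / parse a multilayer signature string
#'
#' @param sig a `multilayer_signature`.
#' @return `render_signature()`: a string such as
#'   `"|0, 2⟩ ⊕ |3.372, 6⟩"`. `parse_signature()` inverts it
#'   into a list of layers of `(n, ell)` pairs.
#' @export
render_signature <- function(sig) {
  paste(vapply(sig$layers, function(df) {
    paste(mapply(render_fiber_number, df$n, df$ell), collapse = " + ")
  }, ""), collapse = " ⊕ ")
}

#' @rdname render_signature
#' @param text a rendered signature string.
#' @export
parse_signature <- function(text) {
  layers <- strsplit(text, "⊕", fixed = TRUE)[[1]]
  lapply(layers, function(layer) {
    terms <- strsplit(layer, "+", fixed = TRUE)[[1]]
    do.call(rbind, lapply(terms, function(tm) {
      m <- regmatches(tm, regexec("\\|\\s*([0-9.]+),\\s*([0-9]+)\\s*⟩",
                                  tm))[[1]]
      if (length(m) != 3L) stop("cannot parse fiber number: ", tm)
      data.frame(n = as.numeric(m[2]), ell = as.integer(m[3]))
    }))
  })
}

#' Collapse a block onto its own minimal base, preserving the branching ratio
#'
#' Quotients the block under its own minimal balanced coloring and asserts
#' that the dominant eigenvalue (the common ratio) is unchanged — the defining
#' property of the two-node Fibonacci bases that irrational-ratio blocks
#' collapse onto.
#'
#' @param fbb an `fbb` (or a `neuron_network`).
#' @param tol eigenvalue preservation tolerance.
#' @export
fibonacci_base_collapse <- function(fbb, tol = 1e-6) {
  net <- if (inherits(fbb, "fbb")) fbb$net else fbb
  part <- minimal_balanced_coloring(net)
  if (part$k == n_nodes(net)) return(net) # already minimal
  base <- quotient_graph(net, part)
  r0 <- max(Mod(eigen(net$adj, only.values = TRUE)$values))
  r1 <- max(Mod(eigen(adjacency(base), only.values = TRUE)$values))
  if (abs(r0 - r1) > tol * max(1, r0)) {
    stop(sprintf("collapse changed the dominant eigenvalue: %.8f -> %.8f",
                 r0, r1))
  }
  base
}
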