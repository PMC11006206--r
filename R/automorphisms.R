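#' Automorphisms and orbit partitions
#'
#' An automorphism is a node permutation `sigma` with
#' `A[sigma(u), sigma(v)] = A[u, v]` for all node pairs — it preserves the
#' weighted adjacency in both directions (`P A P^-1 = A`). Orbits are the
#' equivalence classes of nodes under the full automorphism group; every
#' orbit is contained in a fiber, but not conversely.
#'
#' The search is an in-house backtracking over candidate images, pruned by a
#' joint in/out color refinement (any automorphism must map within those
#' classes). Orbits are found by searching, for each candidate node pair in
#' the same pruning class, for one witness automorphism mapping the first
#' node to the second, and closing the found images under union-find.
#' `automorphisms()` returns the witness permutations (a generating set for
#' the orbit structure) with the identity always included.
#'
#' @param net a [neuron_network()].
#' @param max_nodes capability cap for the backtracking search.
#' @return `automorphisms()`: object of class `automorphism_set`, a list of
#'   named node -> node maps. `orbit_partition()`: a [node_partition()].
#' @export
automorphisms <- function(net, max_nodes = 64L) {
  res <- aut_orbits(net, max_nodes)
  res$generators
}

#' @rdname automorphisms
#' @export
orbit_partition <- function(net, max_nodes = 64L) {
  res <- aut_orbits(net, max_nodes)
  res$orbits
}

#' @export
print.automorphism_set <- function(x, ...) {
  cat(sprintf("<automorphism_set: %d generator(s) incl. identity>\n",
              length(x)))
  invisible(x)
}

#' Check a node map against the adjacency-preservation condition
#' @param net a [neuron_network()].
#' @param sigma named character vector, node -> image node.
#' @export
is_automorphism <- function(net, sigma) {
  nodes <- network_nodes(net)
  if (!setequal(names(sigma), nodes) || !setequal(unname(sigma), nodes)) {
    return(FALSE)
  }
  adj <- net$adj
  img <- sigma[nodes]
  all(adj[img, img] == adj)
}

aut_orbits <- function(net, max_nodes = 64L) {
  n <- n_nodes(net)
  if (n > max_nodes) {
    stop(sprintf("automorphism search capped at %d nodes (got %d)",
                 max_nodes, n))
  }
  nodes <- network_nodes(net)
  adj <- net$adj
  classes <- joint_refine(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  gens <- list(setNames(nodes, nodes)) # identity
  if (n > 1L) {
    for (u in seq_len(n - 1L)) {
      for (v in seq((u + 1L), n)) {
        if (classes[u] != classes[v] || find(u) == find(v)) next
        sigma <- aut_search(adj, classes, fix_from = u, fix_to = v)
        if (!is.null(sigma)) {
          gens[[length(gens) + 1L]] <- setNames(nodes[sigma], nodes)
          for (w in seq_len(n)) union_(w, sigma[w])
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  orbits <- node_partition(setNames(roots, nodes))
  structure_set <- structure(gens, class = "automorphism_set")
  list(generators = structure_set, orbits = orbits)
}

# joint refinement on in- and out-multisets: automorphism-invariant classes
joint_refine <- function(adj) {
  n <- nrow(adj)
  colors <- rep(1L, n)
  repeat {
    keys <- character(n)
    for (v in seq_len(n)) {
      inn <- adj[, v]; out <- adj[v, ]
      ik <- which(inn > 0); ok <- which(out > 0)
      keys[v] <- paste(
        colors[v], adj[v, v],
        paste(sort(paste(colors[ik], inn[ik])), collapse = ","),
        "|",
        paste(sort(paste(colors[ok], out[ok])), collapse = ","),
        sep = ";"
      )
    }
    nxt <- match(keys, unique(keys))
    if (identical(nxt, colors)) break
    colors <- nxt
  }
  colors
}

# Backtracking search for one automorphism with sigma[fix_from] = fix_to
# (or any automorphism if both NULL). Returns an index permutation or NULL.
aut_search <- function(adj, classes, fix_from = NULL, fix_to = NULL) {
  n <- nrow(adj)
  sigma <- integer(n)      # 0 = unassigned
  used <- logical(n)
  order_nodes <- order(tabulate(classes)[classes], seq_len(n))
  if (!is.null(fix_from)) {
    order_nodes <- c(fix_from, setdiff(order_nodes, fix_from))
  }
  compatible <- function(v, c) {
    if (classes[v] != classes[c] || adj[v, v] != adj[c, c]) return(FALSE)
    assigned <- which(sigma > 0L)
    if (length(assigned) == 0L) return(TRUE)
    img <- sigma[assigned]
    all(adj[assigned, v] == adj[img, c]) && all(adj[v, assigned] == adj[c, img])
  }
  recurse <- function(pos) {
    if (pos > n) return(TRUE)
    v <- order_nodes[pos]
    cands <- if (!is.null(fix_from) && v == fix_from) fix_to else
      which(classes == classes[v] & !used)
    for (c in cands) {
      if (used[c] || !compatible(v, c)) next
      sigma[v] <<- c; used[c] <<- TRUE
      if (recurse(pos + 1L)) return(TRUE)
      sigma[v] <<- 0L; used[c] <<- FALSE
    }
    FALSE
  }
  if (recurse(1L)) sigma else NULL
}
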