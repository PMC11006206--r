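#' Input tree of a node
#'
#' The input tree `T(v)` is the rooted, layered tree of all walks terminating
#' at `v`: layer 0 is the root alone, and layer `i + 1` expands every entry of
#' layer `i` by its in-neighbors, with edge multiplicity. The layer-size
#' sequence `a_i` therefore counts the walks of length `i` ending at the root.
#' Layers are stored compactly as per-node occurrence counts; `a_i` is their
#' sum.
#'
#' @param net a [neuron_network()].
#' @param root node identifier.
#' @param depth number of layers to expand (>= 0).
#' @return object of class `input_tree` with fields `root`, `layer_sizes`
#'   (length `depth + 1`, starting at `a_0 = 1`) and `layer_counts` (list of
#'   named per-node occurrence counts per layer).
#' @export
build_input_tree <- function(net, root, depth) {
  nodes <- network_nodes(net)
  if (!root %in% nodes) stop("unknown root node: ", root)
  stopifnot(depth >= 0)
  adj <- net$adj
  w <- setNames(numeric(length(nodes)), nodes)
  w[root] <- 1
  layers <- vector("list", depth + 1L)
  sizes <- numeric(depth + 1L)
  layers[[1L]] <- w[w > 0]
  sizes[1L] <- 1
  for (i in seq_len(depth)) {
    # occurrences of node u at layer i+1 = sum_v adj[u, v] * occurrences of v
    w <- as.vector(adj %*% w)
    names(w) <- nodes
    layers[[i + 1L]] <- w[w > 0]
    sizes[i + 1L] <- sum(w)
  }
  structure(list(root = root, depth = depth, layer_sizes = sizes,
                 layer_counts = layers),
            class = "input_tree")
}

#' @export
print.input_tree <- function(x, ...) {
  cat(sprintf("<input_tree: root %s, depth %d>\n", x$root, x$depth))
  cat("layer sizes a_i:", format(x$layer_sizes, trim = TRUE), "\n")
  invisible(x)
}

# One round of in-neighborhood color refinement. Colors after k rounds from
# the uniform start classify nodes by depth-k input-tree isomorphism; the
# fixed point is the minimal balanced coloring.
refine_round <- function(adj, colors) {
  n <- nrow(adj)
  keys <- character(n)
  for (v in seq_len(n)) {
    m <- adj[, v]
    nz <- which(m > 0)
    if (length(nz) == 0L) {
      keys[v] <- ""
    } else {
      # sorted multiset of in-colors, repeated by edge multiplicity
      keys[v] <- paste(sort(rep(colors[nz], times = round(m[nz]))),
                       collapse = ",")
    }
  }
  match(keys, unique(keys))
}

refine_colors <- function(adj, rounds) {
  colors <- rep(1L, nrow(adj))
  for (i in seq_len(rounds)) {
    nxt <- refine_round(adj, colors)
    if (identical(nxt, colors)) break
    colors <- nxt
  }
  colors
}

#' Are the input trees of two nodes isomorphic?
#'
#' Two layered input trees are isomorphic when a layer-preserving bijection
#' of nodes and edges exists. This is decided by canonical-form colors built
#' bottom-up per layer (sorted multiset encoding of in-colors with
#' multiplicity); depth `n - 1` suffices to distinguish all non-isomorphic
#' input trees of an `n`-node graph.
#'
#' @param net a [neuron_network()].
#' @param u,v node identifiers.
#' @param depth comparison depth; default `n - 1`.
#' @export
input_trees_isomorphic <- function(net, u, v, depth = NULL) {
  nodes <- network_nodes(net)
  if (!u %in% nodes) stop("unknown node: ", u)
  if (!v %in% nodes) stop("unknown node: ", v)
  if (u == v) return(TRUE)
  if (is.null(depth)) depth <- max(n_nodes(net) - 1L, 0L)
  colors <- refine_colors(net$adj, depth)
  colors[match(u, nodes)] == colors[match(v, nodes)]
}
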