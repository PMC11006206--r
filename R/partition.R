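#' Node partition (coloring) of a network
#'
#' A `node_partition` assigns every node to exactly one cell. Cells are
#' relabelled deterministically (`c1`, `c2`, ... in order of their
#' lexicographically smallest member) so that two partitions with the same
#' cells compare `identical()`.
#'
#' @param membership named vector (node identifier -> cell label).
#' @return object of class `node_partition` with fields `membership` (named
#'   integer-coded vector), `cells` (named list of node-id vectors) and `k`.
#' @export
node_partition <- function(membership) {
  if (is.null(names(membership))) stop("membership must be named by node")
  nodes <- sort(names(membership))
  memb <- as.character(membership[nodes])
  if (anyNA(memb)) stop("every node needs a cell")
  first_seen <- !duplicated(memb)
  order_lab <- memb[first_seen] # cells in order of smallest member
  code <- match(memb, order_lab)
  labels <- sprintf("c%d", seq_along(order_lab))
  out <- setNames(labels[code], nodes)
  cells <- split(nodes, out)
  cells <- cells[order(as.integer(sub("^c", "", names(cells))))]
  structure(list(membership = out, cells = cells, k = length(cells)),
            class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("<node_partition: %d cells over %d nodes>\n",
              x$k, length(x$membership)))
  for (nm in names(x$cells)) {
    cat(" ", nm, ": ", paste(x$cells[[nm]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Partition with every node in its own cell
#' @param net a [neuron_network()].
#' @export
singleton_partition <- function(net) {
  ids <- network_nodes(net)
  node_partition(setNames(ids, ids))
}

#' Do two partitions have the same cells?
#' @param a,b `node_partition` objects over the same node set.
#' @export
same_partition <- function(a, b) {
  identical(node_partition(a$membership)$membership,
            node_partition(b$membership)$membership)
}

#' Read/write a two-column (node, color) TSV partition file
#' @param path file path.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("node", "color"),
                          colClasses = "character")
  node_partition(setNames(df$color, df$node))
}

#' @rdname read_partition
#' @param part a `node_partition`.
#' @export
write_partition <- function(part, path) {
  utils::write.table(
    data.frame(node = names(part$membership), color = part$membership),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Is a partition equitable (balanced)?
#'
#' A partition is equitable when, for every ordered pair of cells
#' `(C_j, C_i)`, all nodes of `C_i` receive the same in-multiplicity from
#' `C_j`. On failure the witness `(v, v2, cell_j)` is attached as attribute
#' `witness`.
#'
#' @param net a [neuron_network()].
#' @param part a [node_partition()] covering the network's nodes.
#' @export
is_equitable <- function(net, part) {
  nodes <- network_nodes(net)
  if (!setequal(nodes, names(part$membership))) {
    stop("partition must cover exactly the network's nodes")
  }
  adj <- net$adj
  for (cj in names(part$cells)) {
    src <- part$cells[[cj]]
    # in-multiplicity into each node from cell cj
    inm <- colSums(adj[src, , drop = FALSE])
    for (ci in names(part$cells)) {
      tgt <- part$cells[[ci]]
      vals <- inm[tgt]
      if (length(vals) > 1L && any(vals != vals[1L])) {
        bad <- tgt[which(vals != vals[1L])[1L]]
        res <- FALSE
        attr(res, "witness") <- list(v = tgt[1L], v2 = bad, cell_j = cj)
        return(res)
      }
    }
  }
  res <- TRUE
  attr(res, "witness") <- NULL
  res
}

#' Minimal balanced coloring (fiber partition)
#'
#' Computes the coarsest equitable partition by iterated recoloring: all
#' nodes start with one color and are recolored by the multiset of their
#' in-edge colors (with multiplicity in weighted mode, distinct colored
#' inputs in binary mode) until no recoloring changes the classes. Nodes in
#' the same cell have isomorphic input trees; each cell is one fiber of the
#' minimal graph fibration.
#'
#' @param net a [neuron_network()].
#' @param respect_weights count edge multiplicities (`TRUE`) or clamp the
#'   network to binary first (`FALSE`).
#' @return a [node_partition()].
#' @export
minimal_balanced_coloring <- function(net, respect_weights = TRUE) {
  if (n_nodes(net) == 0L) stop("network is empty")
  adj <- if (respect_weights) net$adj else (net$adj != 0) * 1
  colors <- refine_colors(adj, rounds = max(n_nodes(net), 1L))
  node_partition(setNames(colors, network_nodes(net)))
}

# coarsest balanced refinement of an initial coloring: recolor by
# (own color, in-color multiset) until stable. With a uniform start this is
# the minimal balanced coloring; with a finer start it returns the coarsest
# balanced partition refining it.
coarsest_refinement <- function(adj, init) {
  colors <- match(init, unique(init))
  n <- nrow(adj)
  for (r in seq_len(max(n, 1L))) {
    base <- refine_round(adj, colors)
    keys <- paste(colors, base)
    nxt <- match(keys, unique(keys))
    if (identical(nxt, colors)) break
    colors <- nxt
  }
  colors
}

#' Quotient (base) graph of a network under a balanced partition
#'
#' Collapses every cell onto one representative node. The multiplicity from
#' cell X to cell Y in the base is the in-multiplicity any single member of Y
#' receives from members of X — well defined exactly when the partition is
#' balanced, which is enforced. Base nodes are named after the
#' lexicographically smallest member of their cell. The base of an undirected
#' network is directed in general (cells of unequal size collapse
#' asymmetrically).
#'
#' @param net a [neuron_network()].
#' @param part a balanced [node_partition()].
#' @export
quotient_graph <- function(net, part) {
  ok <- is_equitable(net, part)
  if (!ok) {
    w <- attr(ok, "witness")
    stop(sprintf(
      "partition is not balanced: nodes %s and %s receive different in-multiplicity from cell %s",
      w$v, w$v2, w$cell_j
    ))
  }
  reps <- vapply(part$cells, `[[`, "", 1L) # smallest member (cells sorted)
  k <- length(reps)
  base <- matrix(0, k, k, dimnames = list(unname(reps), unname(reps)))
  adj <- net$adj
  for (j in seq_len(k)) {
    src <- part$cells[[j]]
    inm <- colSums(adj[src, , drop = FALSE])
    for (i in seq_len(k)) {
      base[j, i] <- inm[reps[i]]
    }
  }
  out <- network_from_adjacency(base, directed = TRUE)
  attr(out, "cell_of") <- setNames(names(part$cells), unname(reps))
  out
}
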