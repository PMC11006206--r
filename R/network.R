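#' Directed or undirected weighted neuron multigraph
#'
#' A `neuron_network` stores a set of neurons and a multiset of connections
#' between them as an integer-weighted adjacency matrix, `adj[u, v]` being the
#' multiplicity of the edge `u -> v`. Chemical-synapse networks are directed;
#' gap-junction networks are undirected, with every undirected edge stored as
#' two opposed directed edges of equal multiplicity.
#'
#' @param edges data frame with columns `tail`, `head` and optionally
#'   `weight` (default 1). Duplicate rows are summed with a warning. For an
#'   undirected network a row represents one undirected edge; if both
#'   orientations of the same pair are listed their multiplicities must agree
#'   (the maximum is kept, with a warning on mismatch).
#' @param nodes optional character vector of node identifiers; nodes with no
#'   edges are allowed. Defaults to the endpoints present in `edges`.
#' @param directed logical; `FALSE` for gap-junction (undirected) networks.
#' @param allow_real permit non-integer positive weights (used for
#'   weight-perturbed networks; symmetry analysis expects integers).
#' @return an object of class `neuron_network`.
#' @export
neuron_network <- function(edges = NULL, nodes = NULL, directed = TRUE,
                           allow_real = FALSE) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    ids <- sort(unique(as.character(nodes)))
    adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    return(new_neuron_network(adj, directed))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$weight)) edges$weight <- 1
  w <- as.numeric(edges$weight)
  if (anyNA(w) || any(w <= 0)) {
    stop("edge weights must be positive numbers")
  }
  if (!allow_real && any(abs(w - round(w)) > 1e-9)) {
    stop("edge weights must be positive integers (multiplicities)")
  }
  tl <- as.character(edges$tail)
  hd <- as.character(edges$head)
  ids <- sort(unique(c(tl, hd, as.character(nodes))))
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  key <- paste(tl, hd, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edge rows found; multiplicities summed")
  }
  agg <- rowsum(w, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  for (i in seq_along(parts)) {
    adj[parts[[i]][1L], parts[[i]][2L]] <- agg[i, 1L]
  }
  if (!directed) {
    m <- pmax(adj, t(adj))
    asym <- adj != 0 & t(adj) != 0 & adj != t(adj)
    if (any(asym)) {
      warning("inconsistent multiplicities for undirected edge(s); maximum kept")
    }
    adj <- m
  }
  if (!allow_real) adj <- round(adj)
  new_neuron_network(adj, directed)
}

new_neuron_network <- function(adj, directed) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (!directed && nrow(adj) > 0 && !isTRUE(all.equal(adj, t(adj)))) {
    stop("undirected network requires a symmetric multiplicity matrix")
  }
  structure(list(adj = adj, directed = directed), class = "neuron_network")
}

#' Build a network directly from a multiplicity matrix
#'
#' @param adj square numeric matrix with dimnames; `adj[u, v]` is the
#'   multiplicity of edge `u -> v`.
#' @inheritParams neuron_network
#' @export
network_from_adjacency <- function(adj, directed = TRUE, allow_real = FALSE) {
  if (is.null(dimnames(adj))) {
    ids <- sprintf("n%02d", seq_len(nrow(adj)))
    dimnames(adj) <- list(ids, ids)
  }
  if (any(adj < 0)) stop("multiplicities must be non-negative")
  if (!allow_real && any(abs(adj - round(adj)) > 1e-9)) {
    stop("multiplicities must be integers")
  }
  ord <- order(rownames(adj))
  new_neuron_network(adj[ord, ord, drop = FALSE], directed)
}

#' @export
print.neuron_network <- function(x, ...) {
  cat(sprintf(
    "<neuron_network: %d nodes, %s edges (%s), total multiplicity %s>\n",
    n_nodes(x), sum(x$adj != 0), if (x$directed) "directed" else "undirected",
    format(sum(x$adj))
  ))
  invisible(x)
}

#' Number of nodes in a network
#' @param net a `neuron_network`.
#' @export
n_nodes <- function(net) nrow(net$adj)

#' Node identifiers of a network
#' @param net a `neuron_network`.
#' @export
network_nodes <- function(net) rownames(net$adj)

#' Multiplicity (adjacency) matrix of a network
#' @param net a `neuron_network`.
#' @export
adjacency <- function(net) net$adj

#' Clamp all multiplicities to one (binary view of a multigraph)
#' @param net a `neuron_network`.
#' @export
as_binary <- function(net) {
  new_neuron_network((net$adj != 0) * 1, net$directed)
}

#' Induced subnetwork on a node subset
#' @param net a `neuron_network`.
#' @param nodes character vector of node identifiers to keep.
#' @export
induced_subnetwork <- function(net, nodes) {
  stopifnot(all(nodes %in% network_nodes(net)))
  nodes <- sort(unique(nodes))
  new_neuron_network(net$adj[nodes, nodes, drop = FALSE], net$directed)
}

#' Read a whitespace/TAB separated edge list
#'
#' Rows are `tail head weight`, with the weight optional (default 1). An
#' empty file yields an empty network.
#'
#' @param path file path.
#' @param directed logical; `FALSE` symmetrizes the input.
#' @param allow_real permit non-integer weights.
#' @export
read_edge_list <- function(path, directed = TRUE, allow_real = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(neuron_network(NULL, directed = directed))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L)) {
    stop("format error: each row must be 'tail head [weight]'")
  }
  tl <- vapply(parts, `[[`, "", 1L)
  hd <- vapply(parts, `[[`, "", 2L)
  w <- vapply(parts, function(p) {
    if (length(p) >= 3L) suppressWarnings(as.numeric(p[3L])) else 1
  }, 0)
  if (anyNA(w)) stop("format error: non-numeric weight")
  neuron_network(data.frame(tail = tl, head = hd, weight = w),
                 directed = directed, allow_real = allow_real)
}

#' Write a network as a TAB-separated edge list
#'
#' Undirected edges are written once (lexicographically smaller endpoint
#' first).
#'
#' @param net a `neuron_network`.
#' @param path file path.
#' @export
write_edge_list <- function(net, path) {
  adj <- net$adj
  idx <- which(adj != 0, arr.ind = TRUE)
  if (!net$directed && nrow(idx) > 0) {
    idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  }
  rows <- character(nrow(idx))
  if (nrow(idx) > 0) {
    rows <- sprintf("%s\t%s\t%s",
                    rownames(adj)[idx[, 1]], colnames(adj)[idx[, 2]],
                    format(adj[idx], trim = TRUE))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a network from GraphML
#'
#' Edge multiplicities are taken from a `weight` edge attribute when present,
#' otherwise parallel edges are counted.
#'
#' @param path file path.
#' @param directed override the directedness recorded in the file
#'   (default: keep it).
#' @export
read_graphml <- function(path, directed = NA) {
  ig <- igraph::read_graph(path, format = "graphml")
  if (is.na(directed)) directed <- igraph::is_directed(ig)
  nm <- igraph::vertex_attr(ig, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(ig)))
  el <- igraph::as_edgelist(ig, names = FALSE)
  w <- igraph::edge_attr(ig, "weight")
  if (is.null(w)) w <- rep(1, nrow(el))
  if (nrow(el) == 0L) {
    return(neuron_network(NULL, nodes = nm, directed = directed))
  }
  neuron_network(
    data.frame(tail = nm[el[, 1]], head = nm[el[, 2]], weight = w),
    nodes = nm, directed = directed
  )
}

#' Write a network to GraphML (weights stored as a `weight` edge attribute)
#' @param net a `neuron_network`.
#' @param path file path.
#' @export
write_graphml <- function(net, path) {
  ig <- to_igraph(net, weighted = TRUE)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

# igraph view; weighted = TRUE keeps multiplicities as E()$weight,
# FALSE drops them (simple graph for shortest-path work).
to_igraph <- function(net, weighted = TRUE) {
  mode <- if (net$directed) "directed" else "undirected"
  adj <- if (weighted) net$adj else (net$adj != 0) * 1
  igraph::graph_from_adjacency_matrix(adj, mode = mode, weighted = TRUE,
                                      diag = TRUE)
}
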