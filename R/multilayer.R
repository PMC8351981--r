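#' Construct a multilayer network from a tidy edge table
#'
#' A multilayer (multiplex) network is a single node universe connected by
#' several undirected, unweighted edge sets ("layers"). Nodes are opaque
#' string labels shared across layers: the node `"a"` in layer `L1` and the
#' node `"a"` in layer `L2` are counterpart replicas of the same entity, and
#' the coupling between them is computed (from neighbourhood similarity),
#' never stored as explicit inter-layer edges.
#'
#' @param edges Data frame with columns `layer`, `from`, `to` (one row per
#'   intra-layer edge). Duplicate rows and reversed duplicates collapse to a
#'   single undirected edge; self-loops are an error.
#' @param nodes Optional character vector fixing the node universe and its
#'   order. Must contain every edge endpoint; may add isolated nodes.
#' @param layers Optional character vector fixing layer names and order;
#'   must contain every layer mentioned in `edges`, and may add empty layers.
#' @param presence Optional data frame with columns `layer`, `node` marking
#'   nodes present-but-isolated in a layer (edge endpoints are always
#'   present). Use layer `"-"` to add a node to the universe only.
#'
#' @return An object of class `multilayer_network` with elements `nodes`,
#'   `layers`, `edges` (canonicalized tibble) and per-layer adjacency.
#' @examples
#' net <- multilayer_network(
#'   tibble::tibble(
#'     layer = c("L1", "L1", "L2"),
#'     from = c("a", "b", "a"),
#'     to = c("b", "c", "c")
#'   )
#' )
#' net
#' layer_neighbors(net, "b", "L1")
#' @export
multilayer_network <- function(edges, nodes = NULL, layers = NULL,
                               presence = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("layer", "from", "to") %in% names(edges))) {
    stop("`edges` must have columns layer, from, to", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)[, c("layer", "from", "to")]
  edges$layer <- as.character(edges$layer)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    bad <- which(edges$from == edges$to)[1]
    stop("self-loop edge (", edges$from[bad], ", ", edges$to[bad],
         ") is not allowed", call. = FALSE)
  }

  layer_names <- if (is.null(layers)) unique(edges$layer) else as.character(layers)
  if (!all(edges$layer %in% layer_names)) {
    stop("`layers` must include every layer used in `edges`", call. = FALSE)
  }
  if (anyDuplicated(layer_names)) stop("duplicate layer names", call. = FALSE)

  extra_nodes <- character()
  extra_presence <- NULL
  if (!is.null(presence)) {
    stopifnot(is.data.frame(presence), all(c("layer", "node") %in% names(presence)))
    presence <- tibble::as_tibble(presence)
    presence$layer <- as.character(presence$layer)
    presence$node <- as.character(presence$node)
    extra_nodes <- presence$node
    extra_presence <- presence[presence$layer != "-", , drop = FALSE]
    if (!all(extra_presence$layer %in% layer_names)) {
      stop("presence refers to unknown layer(s)", call. = FALSE)
    }
  }

  seen_nodes <- unique(c(rbind(edges$from, edges$to), extra_nodes))
  node_names <- if (is.null(nodes)) seen_nodes else as.character(nodes)
  if (anyDuplicated(node_names)) stop("duplicate node labels", call. = FALSE)
  if (!all(seen_nodes %in% node_names)) {
    stop("`nodes` must include every edge endpoint", call. = FALSE)
  }
  if (length(node_names) < 1) stop("network must have at least one node", call. = FALSE)
  if (length(layer_names) < 1) stop("network must have at least one layer", call. = FALSE)

  # canonical undirected form: lower node index first, one row per edge
  fi <- match(edges$from, node_names)
  ti <- match(edges$to, node_names)
  lo <- pmin(fi, ti)
  hi <- pmax(fi, ti)
  li <- match(edges$layer, layer_names)
  key <- paste(li, lo, hi)
  keep <- !duplicated(key)
  edges <- tibble::tibble(
    layer = layer_names[li[keep]],
    from = node_names[lo[keep]],
    to = node_names[hi[keep]]
  )
  edges <- edges[order(match(edges$layer, layer_names), lo[keep], hi[keep]), ]

  n <- length(node_names)
  adj <- lapply(layer_names, function(l) {
    sub <- edges[edges$layer == l, ]
    a <- vector("list", n)
    f <- match(sub$from, node_names)
    t2 <- match(sub$to, node_names)
    for (e in seq_along(f)) {
      a[[f[e]]] <- c(a[[f[e]]], t2[e])
      a[[t2[e]]] <- c(a[[t2[e]]], f[e])
    }
    lapply(a, function(v) if (is.null(v)) integer() else sort(v))
  })
  names(adj) <- layer_names

  pres <- lapply(layer_names, function(l) {
    idx <- which(vapply(adj[[l]], length, 1L) > 0)
    if (!is.null(extra_presence)) {
      idx <- sort(unique(c(idx, match(
        extra_presence$node[extra_presence$layer == l], node_names
      ))))
    }
    idx
  })
  names(pres) <- layer_names

  structure(
    list(nodes = node_names, layers = layer_names, edges = edges,
         adj = adj, presence = pres),
    class = "multilayer_network"
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  per_layer <- table(factor(x$edges$layer, levels = x$layers))
  cat("<multilayer_network> ", length(x$nodes), " nodes, ",
      length(x$layers), " layer(s), ", nrow(x$edges), " edges\n", sep = "")
  for (l in x$layers) {
    cat("  ", l, ": ", per_layer[[l]], " edges, ",
        length(x$presence[[l]]), " present nodes\n", sep = "")
  }
  invisible(x)
}

#' @export
format.multilayer_network <- function(x, ...) {
  paste0("<multilayer_network: ", length(x$nodes), " nodes, ",
         length(x$layers), " layers, ", nrow(x$edges), " edges>")
}

#' Number of nodes / layers
#' @param net A `multilayer_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_layers <- function(net) length(net$layers)

node_index <- function(net, node) {
  i <- match(node, net$nodes)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  i
}

layer_index <- function(net, layer) {
  l <- match(layer, net$layers)
  if (is.na(l)) stop("unknown layer: ", layer, call. = FALSE)
  l
}

#' Neighbours of a node within one layer
#'
#' Returns the set of nodes adjacent to `node` in layer `layer`. A node that
#' is isolated or absent in the layer has no neighbours there.
#'
#' @param net A `multilayer_network`.
#' @param node Node label.
#' @param layer Layer name.
#' @return Character vector of neighbour labels (possibly empty).
#' @export
layer_neighbors <- function(net, node, layer) {
  i <- node_index(net, node)
  l <- layer_index(net, layer)
  net$nodes[net$adj[[l]][[i]]]
}

#' Common-edge weight of a node pair
#'
#' The fraction of layers in which the undirected edge `(i, j)` is present:
#' \eqn{\omega(i,j) = \sum_l A_l(i,j) / k} for binary per-layer adjacency
#' \eqn{A_l} and layer count \eqn{k}. Edges recurring in many layers carry
#' weight near 1 and attract the biased walker; a pair connected in no layer
#' has weight 0. Symmetric in its node arguments and independent of layer.
#'
#' @param net A `multilayer_network`.
#' @param i,j Distinct node labels.
#' @return A value in `{0, 1/k, ..., 1}`.
#' @export
edge_weight <- function(net, i, j) {
  ii <- node_index(net, i)
  jj <- node_index(net, j)
  if (ii == jj) stop("edge weight is undefined for i == j", call. = FALSE)
  hits <- vapply(net$adj, function(a) jj %in% a[[ii]], logical(1))
  sum(hits) / length(net$layers)
}

#' Collapse a multilayer network into its aggregate single layer
#'
#' The aggregate is the union of all layer edge sets over the unchanged node
#' universe, in a single layer named `"aggregate"`. It is the standard
#' single-layer baseline: methods that cannot exploit layer structure run on
#' this graph.
#'
#' @param net A `multilayer_network`.
#' @return A single-layer `multilayer_network`.
#' @export
aggregate_layers <- function(net) {
  e <- net$edges
  fi <- match(e$from, net$nodes)
  ti <- match(e$to, net$nodes)
  keep <- !duplicated(paste(pmin(fi, ti), pmax(fi, ti)))
  agg <- tibble::tibble(layer = "aggregate", from = e$from[keep], to = e$to[keep])
  pres_all <- sort(unique(unlist(net$presence)))
  pres <- tibble::tibble(layer = "aggregate", node = net$nodes[pres_all])
  if (length(setdiff(seq_along(net$nodes), pres_all)) > 0) {
    pres <- rbind(pres, tibble::tibble(
      layer = "-", node = net$nodes[setdiff(seq_along(net$nodes), pres_all)]
    ))
  }
  multilayer_network(agg, nodes = net$nodes, layers = "aggregate", presence = pres)
}

#' Read / write multilayer edge lists
#'
#' The on-disk format is TSV with three columns `layer`, `node_a`, `node_b`
#' (optional header), one undirected edge per row. Lines starting with `#`
#' are comments, except three directives: `#layer<TAB><name>` fixes layer
#' order and records empty layers; `#node<TAB><label>` fixes node-universe
#' order and records isolated nodes; `#nodes<TAB><layer><TAB><label>`
#' declares a node present-but-isolated in a layer (layer `-` places the
#' node in the universe only). Duplicate and reversed rows collapse to one
#' edge. Files without directives are valid: layers and nodes are then
#' taken in order of first appearance.
#'
#' @param path Path to a TSV edge-list file.
#' @return For `read_multilayer_edgelist`, a `multilayer_network`;
#'   `write_multilayer_edgelist` returns `path` invisibly. Reading back a
#'   written file reproduces the original network exactly.
#' @export
read_multilayer_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  presence <- NULL
  layer_order <- character()
  node_order <- character()
  edge_rows <- list()
  lineno <- 0L
  first_data_row <- TRUE
  for (raw in lines) {
    lineno <- lineno + 1L
    line <- sub("\r$", "", raw)
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (identical(f[1], "#nodes")) {
        if (length(f) != 3) {
          stop("malformed #nodes directive at line ", lineno, call. = FALSE)
        }
        presence <- rbind(presence, tibble::tibble(layer = f[2], node = f[3]))
      } else if (identical(f[1], "#layer") && length(f) == 2) {
        layer_order <- c(layer_order, f[2])
      } else if (identical(f[1], "#node") && length(f) == 2) {
        node_order <- c(node_order, f[2])
      }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) {
      stop("malformed row at line ", lineno, ": expected 3 tab-separated ",
           "columns, got ", length(f), call. = FALSE)
    }
    if (first_data_row) {
      first_data_row <- FALSE
      if (identical(tolower(f[1]), "layer")) next
    }
    if (f[2] == f[3]) {
      stop("self-loop at line ", lineno, ": (", f[2], ", ", f[3], ")",
           call. = FALSE)
    }
    edge_rows[[length(edge_rows) + 1L]] <- f
  }
  if (length(edge_rows) == 0) stop("no edges in ", path, call. = FALSE)
  m <- do.call(rbind, edge_rows)
  pres_layers <- if (is.null(presence)) character() else {
    presence$layer[presence$layer != "-"]
  }
  pres_nodes <- if (is.null(presence)) character() else presence$node
  multilayer_network(
    tibble::tibble(layer = m[, 1], from = m[, 2], to = m[, 3]),
    nodes = unique(c(node_order, c(rbind(m[, 2], m[, 3])), pres_nodes)),
    layers = unique(c(layer_order, m[, 1], pres_layers)),
    presence = presence
  )
}

#' @rdname read_multilayer_edgelist
#' @param net A `multilayer_network` to serialize.
#' @export
write_multilayer_edgelist <- function(net, path) {
  stopifnot(inherits(net, "multilayer_network"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("layer\tnode_a\tnode_b", con)
  # directives make the read-back reproduce the exact data model: layer and
  # node order, empty layers, isolated and universe-only nodes
  writeLines(paste("#layer", net$layers, sep = "\t"), con)
  writeLines(paste("#node", net$nodes, sep = "\t"), con)
  for (l in net$layers) {
    deg <- vapply(net$adj[[l]], length, 1L)
    iso <- intersect(net$presence[[l]], which(deg == 0))
    for (i in iso) writeLines(paste("#nodes", l, net$nodes[i], sep = "\t"), con)
  }
  if (nrow(net$edges) > 0) {
    writeLines(paste(net$edges$layer, net$edges$from, net$edges$to, sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write ground-truth community files
#'
#' One community per line, tab-separated node labels.
#'
#' @param path File path.
#' @return `read_communities` returns a list of character vectors (one per
#'   community); `write_communities` returns `path` invisibly.
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no communities in ", path, call. = FALSE)
  comms <- lapply(strsplit(lines, "\t", fixed = TRUE), unique)
  if (any(lengths(comms) == 0)) stop("empty community line", call. = FALSE)
  comms
}

#' @rdname read_communities
#' @param communities List of character vectors of node labels.
#' @export
write_communities <- function(communities, path) {
  stopifnot(is.list(communities), all(lengths(communities) > 0))
  writeLines(vapply(communities, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.multilayer_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.multilayer_network <- function(x, ...) {
  agg <- aggregate_layers(x)
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_layers = length(x$layers),
    n_edges = nrow(x$edges),
    n_aggregate_edges = nrow(agg$edges)
  )
}

#' Test two networks for equality of node universe, layers and edge sets
#' @param a,b `multilayer_network` objects.
#' @return Logical scalar.
#' @export
same_network <- function(a, b) {
  identical(a$nodes, b$nodes) && identical(a$layers, b$layers) &&
    identical(a$edges, b$edges) && identical(a$presence, b$presence)
}
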