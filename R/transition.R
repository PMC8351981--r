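#' Unnormalized intra-layer move score between two nodes
#'
#' The biased walker prefers, within the current layer, neighbours that (1)
#' share many neighbours with the current node, (2) are not high-degree hubs
#' of other communities, and (3) are connected by an edge recurring across
#' layers. For nodes `i`, `j` in layer `l` with neighbour sets
#' \eqn{\Gamma_l(\cdot)} the score is
#' \deqn{P_l(i,j) = \frac{|\Gamma_l(i) \cap \Gamma_l(j)| + 1}{|\Gamma_l(i)| + 1}
#'   \times \frac{1}{|\Gamma_l(j)| + 1} \times \omega(i,j),}
#' where \eqn{\omega} is the common-edge weight ([edge_weight()]). The score
#' is symmetric in `i`, `j`, bounded by \eqn{\omega(i,j)}, and zero whenever
#' the pair is connected in no layer. Scores are unnormalized: they become
#' probabilities only when rescaled over the current node's move set at
#' move time ([move_distribution()]).
#'
#' @param net A `multilayer_network`.
#' @param i,j Distinct node labels.
#' @param l Layer name.
#' @param weight_fn Edge weighting function `(net, i, j) -> [0, 1]`;
#'   defaults to the common-edge fraction [edge_weight()]. Supplying another
#'   weighting (e.g. an entropy-based one) changes the bias but not the
#'   walk mechanics.
#' @return Nonnegative score.
#' @export
intra_layer_score <- function(net, i, j, l, weight_fn = edge_weight) {
  ii <- node_index(net, i)
  jj <- node_index(net, j)
  if (ii == jj) stop("intra-layer score undefined for i == j", call. = FALSE)
  ll <- layer_index(net, l)
  w <- weight_fn(net, i, j)
  if (w == 0) return(0)
  gi <- net$adj[[ll]][[ii]]
  gj <- net$adj[[ll]][[jj]]
  common <- length(intersect(gi, gj))
  (common + 1) / (length(gi) + 1) * 1 / (length(gj) + 1) * w
}

#' Inter-layer transition score of a node between two layers
#'
#' The probability weight for the walker at node `i` to switch from layer
#' `ls` to the counterpart node in layer `lt` grows with the similarity of
#' the node's neighbourhoods in the two layers, measured by an add-one
#' smoothed Jaccard index
#' \deqn{R_i(l_s, l_t) = \frac{|\Gamma_{l_s}(i) \cap \Gamma_{l_t}(i)| + 1}
#'   {|\Gamma_{l_s}(i) \cup \Gamma_{l_t}(i)| + 1}.}
#' The +1 smoothing keeps the value defined (and equal to 1) when the node
#' is isolated in both layers, so every layer always has positive switch
#' weight.
#'
#' @param net A `multilayer_network`.
#' @param i Node label.
#' @param ls,lt Layer names (source and target).
#' @return Score in `(0, 1]`; 1 iff the two neighbourhoods are equal.
#' @export
inter_layer_score <- function(net, i, ls, lt) {
  ii <- node_index(net, i)
  s <- layer_index(net, ls)
  t <- layer_index(net, lt)
  gs <- net$adj[[s]][[ii]]
  gt <- net$adj[[t]][[ii]]
  (length(intersect(gs, gt)) + 1) / (length(union(gs, gt)) + 1)
}

#' Precompute all transition scores of the biased walk
#'
#' Evaluates [intra_layer_score()] under every layer context for every edge
#' of the multilayer network (sparse: pairs connected in no layer score
#' zero and are not stored), and [inter_layer_score()] for every node and
#' layer pair. The stored move set of a node is its multilayer
#' neighbourhood — every counterpart connected to it in at least one
#' layer — while the current layer shapes the score through that layer's
#' neighbourhood overlap and degrees. The cost is O(k n^2) worst case for
#' the intra part — proportional to edge count in practice — and O(n k^2)
#' for the inter part.
#'
#' @param net A `multilayer_network`.
#' @param weight_fn Edge weighting function, see [intra_layer_score()].
#' @return An immutable `plcdm_transition_model` with elements
#'   `intra[[layer]][[node]]` = list(`nbrs` integer indices, `score`
#'   numeric) and `inter[[node]]` = k-by-k matrix of smoothed Jaccard
#'   scores (unit diagonal, symmetric).
#' @export
build_transition_model <- function(net, weight_fn = edge_weight) {
  n <- length(net$nodes)
  k <- length(net$layers)

  # omega for every pair that is an edge somewhere; the default weighting
  # (and any sane custom one) is zero elsewhere, so these pairs are exactly
  # the walker's possible moves
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  pair_key <- paste(pmin(fi, ti), pmax(fi, ti))
  upairs <- !duplicated(pair_key)
  omega <- vapply(which(upairs), function(e) {
    weight_fn(net, net$edges$from[e], net$edges$to[e])
  }, numeric(1))
  names(omega) <- pair_key[upairs]

  # the walker's move set is the multilayer neighbourhood {j : omega(i,j)>0};
  # the current layer enters through the neighbourhood terms of the score
  uadj <- lapply(seq_len(n), function(i) {
    sort(unique(unlist(lapply(net$adj, `[[`, i))))
  })
  intra <- lapply(seq_len(k), function(l) {
    a <- net$adj[[l]]
    deg1 <- vapply(a, length, 1L) + 1L
    lapply(seq_len(n), function(i) {
      nbrs <- uadj[[i]]
      if (length(nbrs) == 0) {
        return(list(nbrs = integer(), score = numeric()))
      }
      sc <- vapply(nbrs, function(j) {
        common <- length(intersect(a[[i]], a[[j]]))
        w <- omega[[paste(min(i, j), max(i, j))]]
        (common + 1) / deg1[i] / deg1[j] * w
      }, numeric(1))
      list(nbrs = nbrs, score = sc)
    })
  })
  names(intra) <- net$layers

  inter <- lapply(seq_len(n), function(i) {
    m <- diag(1, k)
    if (k > 1) {
      for (s in seq_len(k - 1)) {
        for (t in (s + 1):k) {
          gs <- net$adj[[s]][[i]]
          gt <- net$adj[[t]][[i]]
          r <- (length(intersect(gs, gt)) + 1) / (length(union(gs, gt)) + 1)
          m[s, t] <- r
          m[t, s] <- r
        }
      }
    }
    dimnames(m) <- list(net$layers, net$layers)
    m
  })
  names(inter) <- net$nodes

  structure(list(intra = intra, inter = inter, nodes = net$nodes,
                 layers = net$layers),
            class = "plcdm_transition_model")
}

#' @export
print.plcdm_transition_model <- function(x, ...) {
  nz <- sum(vapply(x$intra, function(l) sum(lengths(lapply(l, `[[`, "nbrs"))), 1))
  cat("<plcdm_transition_model> ", length(x$nodes), " nodes, ",
      length(x$layers), " layer(s), ", nz / 2, " scored edges per direction\n",
      sep = "")
  invisible(x)
}

#' One-step move distribution of the walker
#'
#' Restricts the layer-contextual move scores of `node` to its multilayer
#' neighbourhood and rescales them so they sum to one. A node connected to
#' nothing in any layer has no move distribution ("stuck"); the walker
#' resolves that by returning to the seed (see [run_plcdm()]).
#'
#' @param model A `plcdm_transition_model`.
#' @param node Node label.
#' @param layer Layer name.
#' @return Named numeric vector of probabilities over the neighbours.
#' @export
move_distribution <- function(model, node, layer) {
  i <- match(node, model$nodes)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  if (!layer %in% model$layers) stop("unknown layer: ", layer, call. = FALSE)
  entry <- model$intra[[layer]][[i]]
  if (length(entry$nbrs) == 0 || sum(entry$score) == 0) {
    stop("node ", node, " has no scorable neighbour (stuck)", call. = FALSE)
  }
  p <- entry$score / sum(entry$score)
  names(p) <- model$nodes[entry$nbrs]
  p
}

#' Layer-switch distribution of the walker at a node
#'
#' Probabilities over all layers proportional to the node's inter-layer
#' scores from the current layer. Strictly positive on every layer (the
#' smoothed Jaccard never vanishes); switching to the current layer is
#' allowed and is a no-op.
#'
#' @param model A `plcdm_transition_model`.
#' @param node Node label.
#' @param current_layer Layer the walker occupies.
#' @return Named numeric vector of probabilities over layers, summing to 1.
#' @export
layer_distribution <- function(model, node, current_layer) {
  i <- match(node, model$nodes)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  if (!current_layer %in% model$layers) {
    stop("unknown layer: ", current_layer, call. = FALSE)
  }
  row <- model$inter[[i]][current_layer, ]
  row / sum(row)
}
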