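# Shared fixtures, all built in code.

# Triangle 1-2-3 with pendant edge 3-4, one layer.
toy_pendant_net <- function() {
  multilayer_network(tibble::tibble(
    layer = "L1",
    from = c("1", "1", "2", "3"),
    to = c("2", "3", "3", "4")
  ))
}

# Two disjoint cliques of size `size`, replicated identically in `k` layers.
two_clique_net <- function(size = 4, k = 2) {
  cl <- function(prefix) {
    p <- utils::combn(paste0(prefix, seq_len(size)), 2)
    tibble::tibble(from = p[1, ], to = p[2, ])
  }
  base <- dplyr::bind_rows(cl("a"), cl("b"))
  edges <- dplyr::bind_rows(lapply(seq_len(k), function(l) {
    dplyr::mutate(base, layer = paste0("L", l))
  }))
  multilayer_network(edges[, c("layer", "from", "to")])
}

# Small random multilayer instance for property tests.
random_multilayer <- function(n = 8, k = 3, p = 0.4, seed = 1) {
  pairs <- utils::combn(n, 2)
  set.seed(seed)
  rows <- lapply(seq_len(k), function(l) {
    keep <- stats::runif(ncol(pairs)) < p
    tibble::tibble(layer = paste0("L", l),
                   from = paste0("n", pairs[1, keep]),
                   to = paste0("n", pairs[2, keep]))
  })
  multilayer_network(dplyr::bind_rows(rows),
                     nodes = paste0("n", seq_len(n)),
                     layers = paste0("L", seq_len(k)))
}

# Definition-level oracle for the intra-layer move score.
brute_intra_score <- function(net, i, j, l) {
  gi <- layer_neighbors(net, i, l)
  gj <- layer_neighbors(net, j, l)
  w <- edge_weight(net, i, j)
  (length(intersect(gi, gj)) + 1) / (length(gi) + 1) / (length(gj) + 1) * w
}

# Definition-level oracle for the inter-layer score.
brute_inter_score <- function(net, i, ls, lt) {
  gs <- layer_neighbors(net, i, ls)
  gt <- layer_neighbors(net, i, lt)
  (length(intersect(gs, gt)) + 1) / (length(union(gs, gt)) + 1)
}

# Independent NMI computation via the entropy identity
# I(Y;C) = H(Y) + H(C) - H(Y,C) on the binary membership labelings.
brute_nmi <- function(predicted, truth, universe) {
  y <- universe %in% predicted
  c_ <- universe %in% truth
  h <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  hy <- h(y)
  hc <- h(c_)
  if (hy == 0 || hc == 0) return(0)
  hyc <- h(paste(y, c_))
  2 * (hy + hc - hyc) / (hy + hc)
}
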