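#' Near-equal split of n nodes into m module sizes
#'
#' @param n_in_modules Total number of nodes to place in modules.
#' @param n_modules Number of modules.
#' @return Integer vector of module sizes summing to `n_in_modules`.
#' @export
equal_module_sizes <- function(n_in_modules, n_modules) {
  stopifnot(n_modules >= 1, n_in_modules >= n_modules)
  base <- n_in_modules %/% n_modules
  sizes <- rep(base, n_modules)
  extra <- n_in_modules %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  as.integer(sizes)
}

#' Generate a modular single-layer graph with planted communities
#'
#' Planted-partition (stochastic-block-style) model: the first
#' `sum(module_sizes)` nodes are split into consecutive modules; every
#' intra-module pair is connected independently with probability `p_in`,
#' every other pair (inter-module or involving background nodes) with
#' probability `p_out`. The planted modules are returned as ground truth
#' regardless of which edges the random draw realizes.
#'
#' @param n_nodes Total node count (node labels `"v1" ... "vn"`).
#' @param module_sizes Integer vector of planted module sizes
#'   (`sum <= n_nodes`); see [equal_module_sizes()].
#' @param p_in Intra-module edge probability.
#' @param p_out Inter-module / background edge probability (`p_out < p_in`).
#' @param rng_seed Integer seed; output is deterministic given it.
#' @return List with `network` (a single-layer `multilayer_network` whose
#'   layer is named `"base"`, universe of all `n_nodes` nodes preserved) and
#'   `ground_truth` (list of character vectors, the planted modules).
#' @examples
#' g <- generate_modular_graph(25, c(5, 5), p_in = 0.9, p_out = 0.05,
#'                             rng_seed = 1)
#' g$ground_truth
#' @export
generate_modular_graph <- function(n_nodes, module_sizes, p_in, p_out,
                                   rng_seed = 1L) {
  stopifnot(n_nodes >= 2, length(module_sizes) >= 1, all(module_sizes >= 1),
            sum(module_sizes) <= n_nodes,
            p_in > 0, p_in <= 1, p_out >= 0, p_out < p_in)
  nodes <- paste0("v", seq_len(n_nodes))
  membership <- integer(n_nodes)  # 0 = background
  stops <- cumsum(module_sizes)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  for (m in seq_along(module_sizes)) {
    membership[starts[m]:stops[m]] <- m
  }

  pairs <- utils::combn(n_nodes, 2)
  same <- membership[pairs[1, ]] != 0 &
    membership[pairs[1, ]] == membership[pairs[2, ]]
  prob <- ifelse(same, p_in, p_out)
  set.seed(rng_seed)
  keep <- stats::runif(ncol(pairs)) < prob
  edges <- tibble::tibble(
    layer = "base",
    from = nodes[pairs[1, keep]],
    to = nodes[pairs[2, keep]]
  )
  if (nrow(edges) == 0) {
    stop("random draw produced an empty graph; increase p_in/p_out or n",
         call. = FALSE)
  }
  net <- multilayer_network(edges, nodes = nodes, layers = "base")
  ground_truth <- lapply(seq_along(module_sizes), function(m) {
    nodes[membership == m]
  })
  list(network = net, ground_truth = ground_truth)
}

#' Simulate a multilayer network from a single-layer graph
#'
#' Each of `n_layers` layers independently retains every edge of the input
#' graph with probability `edge_selection_prob` (independent Bernoulli
#' draws per edge per layer, no coupling across layers). The node universe
#' is preserved in every layer, so dropped edges leave nodes isolated, not
#' removed. Because retention is probabilistic, the aggregate of the
#' simulated layers generally differs from the source graph: an edge
#' survives into the aggregate with probability
#' `1 - (1 - edge_selection_prob)^n_layers`.
#'
#' @param graph A single-layer `multilayer_network` (e.g. from
#'   [generate_modular_graph()]).
#' @param n_layers Number of layers to simulate (default 5).
#' @param edge_selection_prob Per-layer edge retention probability
#'   (default 0.5).
#' @param rng_seed Integer seed; output is deterministic given it.
#' @return A `multilayer_network` with layers `"L1" ... "Lk"`.
#' @export
simulate_multilayer <- function(graph, n_layers = 5,
                                edge_selection_prob = 0.5, rng_seed = 1L) {
  stopifnot(inherits(graph, "multilayer_network"))
  if (length(graph$layers) != 1) {
    stop("`graph` must be single-layer", call. = FALSE)
  }
  stopifnot(n_layers >= 1, edge_selection_prob > 0, edge_selection_prob <= 1)
  src <- graph$edges
  set.seed(rng_seed)
  layer_edges <- lapply(seq_len(n_layers), function(l) {
    keep <- stats::runif(nrow(src)) < edge_selection_prob
    tibble::tibble(layer = paste0("L", l), from = src$from[keep],
                   to = src$to[keep])
  })
  edges <- dplyr::bind_rows(layer_edges)
  layers <- paste0("L", seq_len(n_layers))
  # universe preserved in every layer: isolated nodes stay present
  presence <- tidyr::expand_grid(layer = layers, node = graph$nodes)
  multilayer_network(edges, nodes = graph$nodes, layers = layers,
                     presence = presence)
}

#' Configuration of the standard synthetic benchmark
#'
#' Bundles the generator settings of the standard synthetic multilayer
#' validation benchmark: 100 nodes in 5 planted modules of 20, 5 layers at
#' edge-selection probability 0.5, with edge densities solved so that the
#' expected multilayer edge count matches a target. The target counts
#' undirected intra-layer edges summed over layers, so with per-layer
#' retention `q` the expected number of source-graph edges is
#' \deqn{E_{src} = \frac{E_{target}}{k \, q},}
#' and given `p_in` the inter-module probability solves
#' \deqn{p_{out} = \frac{E_{src} - p_{in} \sum_m \binom{s_m}{2}}
#'   {\binom{n}{2} - \sum_m \binom{s_m}{2}}.}
#' The default `p_in = 0.6` with the 1526-edge target fixes `p_out` near
#' 0.010: roughly 93% of expected source edges fall inside planted
#' modules, a strongly modular graph whose modules are dense but far from
#' complete.
#'
#' @param n_nodes Node count (default 100).
#' @param n_modules Number of planted modules (default 5).
#' @param n_layers Number of layers (default 5).
#' @param edge_selection_prob Per-layer retention probability (default 0.5).
#' @param target_total_edges Expected undirected edge count summed over
#'   layers (default 1526).
#' @param p_in Intra-module probability (default 0.6).
#' @return List of resolved generator settings including the solved `p_out`.
#' @export
benchmark_config <- function(n_nodes = 100, n_modules = 5, n_layers = 5,
                             edge_selection_prob = 0.5,
                             target_total_edges = 1526, p_in = 0.6) {
  sizes <- equal_module_sizes(n_nodes, n_modules)
  intra_pairs <- sum(choose(sizes, 2))
  other_pairs <- choose(n_nodes, 2) - intra_pairs
  target_source_edges <- target_total_edges / (n_layers * edge_selection_prob)
  p_out <- (target_source_edges - p_in * intra_pairs) / other_pairs
  if (p_out < 0 || p_out >= p_in) {
    stop("infeasible density target for the given p_in", call. = FALSE)
  }
  list(n_nodes = n_nodes, module_sizes = sizes, n_layers = n_layers,
       edge_selection_prob = edge_selection_prob, p_in = p_in, p_out = p_out,
       target_total_edges = target_total_edges)
}

#' Generate one benchmark instance (modular graph + simulated layers)
#'
#' @param config A [benchmark_config()] list (or compatible).
#' @param rng_seed Integer seed.
#' @return List with `network` (multilayer), `source` (the single-layer
#'   modular graph) and `ground_truth`.
#' @export
generate_benchmark_instance <- function(config = benchmark_config(),
                                        rng_seed = 1L) {
  g <- generate_modular_graph(config$n_nodes, config$module_sizes,
                              config$p_in, config$p_out, rng_seed = rng_seed)
  ml <- simulate_multilayer(g$network, n_layers = config$n_layers,
                            edge_selection_prob = config$edge_selection_prob,
                            rng_seed = rng_seed + 1L)
  list(network = ml, source = g$network, ground_truth = g$ground_truth)
}
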