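#' Parameters of the biased random walk
#'
#' @param iteration_count Number of move steps `t`. `NULL` (default) resolves
#'   at run time to `max(1e5, 1000 * n)` for an `n`-node network, large
#'   enough for visit frequencies to stabilize on benchmark-sized graphs.
#' @param jump_prob Probability, after each move, of restarting at the seed
#'   (scoring it). Default 0.5: restarts frequent enough to keep the walk
#'   local while still reaching the seed's wider neighbourhood.
#' @param layer_change_prob Probability, after each move/jump, of resampling
#'   the layer from the current node's inter-layer scores. Default 0.5; it
#'   is ignored on single-layer networks, where the walker never switches.
#' @param rng_seed Integer seed; the entire walk is deterministic given it.
#' @return A `plcdm_walk_params` object.
#' @export
walk_params <- function(iteration_count = NULL, jump_prob = 0.5,
                        layer_change_prob = 0.5, rng_seed = 1L) {
  if (!is.null(iteration_count)) {
    iteration_count <- as.numeric(iteration_count)
    stopifnot(length(iteration_count) == 1, iteration_count >= 1,
              iteration_count == floor(iteration_count))
  }
  stopifnot(
    is.numeric(jump_prob), length(jump_prob) == 1,
    jump_prob >= 0, jump_prob <= 1,
    is.numeric(layer_change_prob), length(layer_change_prob) == 1,
    layer_change_prob >= 0, layer_change_prob <= 1,
    is.numeric(rng_seed), length(rng_seed) == 1
  )
  structure(
    list(iteration_count = iteration_count, jump_prob = jump_prob,
         layer_change_prob = layer_change_prob,
         rng_seed = as.integer(rng_seed)),
    class = "plcdm_walk_params"
  )
}

# Flatten the transition model into the arrays the C++ walker consumes.
walk_arrays <- function(model) {
  n <- length(model$nodes)
  k <- length(model$layers)
  ptr <- integer(n * k + 1)
  idx <- integer(0)
  cum <- numeric(0)
  idx_list <- vector("list", n * k)
  cum_list <- vector("list", n * k)
  for (l in seq_len(k)) {
    for (i in seq_len(n)) {
      seg <- (l - 1L) * n + i
      entry <- model$intra[[l]][[i]]
      idx_list[[seg]] <- entry$nbrs - 1L
      cum_list[[seg]] <- cumsum(entry$score)
    }
  }
  lens <- lengths(idx_list)
  ptr <- c(0L, cumsum(lens))
  inter <- numeric(n * k * k)
  for (i in seq_len(n)) {
    # node-major, source-layer rows
    inter[((i - 1) * k * k + 1):(i * k * k)] <- as.numeric(t(model$inter[[i]]))
  }
  list(ptr = as.integer(ptr), idx = unlist(idx_list, use.names = FALSE),
       cum = unlist(cum_list, use.names = FALSE), inter = inter)
}

#' Run the seed-centric biased walk and extract the local community
#'
#' Performs `iteration_count` move steps from `seed`: at each step the
#' walker moves to a node of its multilayer neighbourhood sampled from the
#' rescaled layer-contextual move scores and scores it; with probability
#' `jump_prob` it then restarts at the seed (scoring it); with probability
#' `layer_change_prob` it resamples the layer from the current node's
#' inter-layer scores. The initial layer is uniform at random and the seed
#' is scored once at the start. Visit counts are z-scored over the full node
#' universe and the community is the set of nodes with strictly positive
#' z-score.
#'
#' A node connected to nothing in any layer sends the walker back to the
#' seed, so a fully isolated seed yields the degenerate community `{seed}`
#' (with a warning).
#'
#' @param net A `multilayer_network`.
#' @param seed Seed node label.
#' @param params A [walk_params()] object.
#' @param model Optional prebuilt [build_transition_model()] for `net`;
#'   built on the fly when omitted.
#' @return A `plcdm_walk` object with fields `seed`, `params` (resolved),
#'   `raw_counts`, `z_scores`, `community`, `jumps`.
#' @examples
#' net <- multilayer_network(tibble::tibble(
#'   layer = "L1",
#'   from = c("a", "a", "b", "c"),
#'   to = c("b", "c", "c", "d")
#' ))
#' res <- run_plcdm(net, "a", walk_params(iteration_count = 1000, rng_seed = 7))
#' res$community
#' @export
run_plcdm <- function(net, seed, params = walk_params(), model = NULL) {
  stopifnot(inherits(net, "multilayer_network"),
            inherits(params, "plcdm_walk_params"))
  seed_i <- node_index(net, seed)
  if (is.null(model)) model <- build_transition_model(net)
  stopifnot(inherits(model, "plcdm_transition_model"),
            identical(model$nodes, net$nodes))
  n <- length(net$nodes)
  k <- length(net$layers)
  t_steps <- params$iteration_count
  if (is.null(t_steps)) t_steps <- max(1e5, 1000 * n)

  deg_any <- Reduce(`+`, lapply(net$adj, function(a) lengths(a)))
  if (deg_any[seed_i] == 0) {
    warning("seed '", seed, "' is isolated in every layer; ",
            "returning the degenerate community {seed}", call. = FALSE)
  }

  arr <- walk_arrays(model)
  set.seed(params$rng_seed)
  out <- .walk_cpp(n, k, seed_i - 1L, t_steps, params$jump_prob,
                   params$layer_change_prob, arr$ptr, arr$idx, arr$cum,
                   arr$inter)
  counts <- out$counts
  names(counts) <- net$nodes
  z <- zscore_transform(counts)
  community <- extract_community(z, seed)
  params$iteration_count <- t_steps
  structure(
    list(seed = seed, params = params, raw_counts = counts, z_scores = z,
         community = community, jumps = out$jumps),
    class = "plcdm_walk"
  )
}

#' @export
print.plcdm_walk <- function(x, ...) {
  cat("<plcdm_walk> seed '", x$seed, "', t = ",
      format(x$params$iteration_count, scientific = FALSE), ", ",
      x$jumps, " restarts\n", sep = "")
  cat("community (", length(x$community), " nodes): ",
      paste(utils::head(x$community, 12), collapse = " "),
      if (length(x$community) > 12) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Standardize visit counts to z-scores
#'
#' Centers and scales counts by their mean and population standard
#' deviation over the whole population (the node universe), so counts above
#' the average become positive and counts below it negative. A constant
#' count vector (zero deviation) maps to all-zero scores.
#'
#' @param raw_counts Named numeric vector of visit counts.
#' @return Named numeric vector of z-scores (mean zero unless degenerate).
#' @export
zscore_transform <- function(raw_counts) {
  stopifnot(length(raw_counts) > 0)
  m <- mean(raw_counts)
  s <- sqrt(mean((raw_counts - m)^2))
  if (s == 0) {
    z <- rep(0, length(raw_counts))
    names(z) <- names(raw_counts)
    return(z)
  }
  (raw_counts - m) / s
}

#' Extract the community from z-scores
#'
#' The community is every node with strictly positive z-score; when no
#' score is positive (constant counts), it degenerates to the seed alone.
#'
#' @param z_scores Named numeric vector of z-scores.
#' @param seed Seed node label (degenerate fallback).
#' @return Character vector of community members.
#' @export
extract_community <- function(z_scores, seed) {
  comm <- names(z_scores)[z_scores > 0]
  if (length(comm) == 0) comm <- seed
  comm
}

#' Exact long-run visit distribution of the walk
#'
#' Builds the one-iteration Markov kernel on states (node, layer) implied by
#' the sampling rules of [run_plcdm()] — move, possible restart, possible
#' layer change, including the forced-layer-change handling of stuck
#' walkers — solves for its stationary distribution by dense eigenanalysis,
#' and returns the per-step node-scoring distribution marginalized over
#' layers. Serves as a closed-form oracle for the simulated walk: empirical
#' visit frequencies converge to it as the iteration count grows.
#'
#' @param net A `multilayer_network` with at most ~500 (node, layer) states.
#' @param seed Seed node label.
#' @param jump_prob,layer_change_prob Walk probabilities as in
#'   [walk_params()].
#' @param model Optional prebuilt transition model.
#' @return Named probability vector over nodes (sums to 1).
#' @export
expected_visit_distribution <- function(net, seed, jump_prob = 0.5,
                                        layer_change_prob = 0.5,
                                        model = NULL) {
  stopifnot(inherits(net, "multilayer_network"))
  n <- length(net$nodes)
  k <- length(net$layers)
  if (n * k > 500) stop("state space too large for the dense oracle",
                        call. = FALSE)
  seed_i <- node_index(net, seed)
  if (is.null(model)) model <- build_transition_model(net)

  ns <- n * k
  state <- function(i, l) (l - 1L) * n + i

  # move phase: state -> state, with forced layer change when stuck
  M <- matrix(0, ns, ns)
  has_nbr <- vapply(seq_len(k), function(l) {
    vapply(model$intra[[l]], function(e) length(e$nbrs) > 0, logical(1))
  }, logical(n))  # n x k
  for (l in seq_len(k)) {
    for (i in seq_len(n)) {
      s <- state(i, l)
      entry <- model$intra[[l]][[i]]
      if (length(entry$nbrs) > 0) {
        p <- entry$score / sum(entry$score)
        M[s, state(entry$nbrs, l)] <- p
      } else {
        cand <- which(has_nbr[i, ])
        if (length(cand) > 0) {
          w <- model$inter[[i]][l, cand]
          w <- w / sum(w)
          for (ci in seq_along(cand)) {
            lt <- cand[ci]
            e2 <- model$intra[[lt]][[i]]
            p <- e2$score / sum(e2$score)
            M[s, state(e2$nbrs, lt)] <- M[s, state(e2$nbrs, lt)] + w[ci] * p
          }
        } else {
          M[s, state(seed_i, l)] <- 1
        }
      }
    }
  }

  # restart phase
  J <- diag(1 - jump_prob, ns)
  for (l in seq_len(k)) {
    J[state(seq_len(n), l), state(seed_i, l)] <-
      J[state(seq_len(n), l), state(seed_i, l)] + jump_prob
  }

  # layer-change phase (no-op on single-layer networks)
  if (k > 1 && layer_change_prob > 0) {
    C <- diag(1 - layer_change_prob, ns)
    for (i in seq_len(n)) {
      rows <- model$inter[[i]] / rowSums(model$inter[[i]])
      for (l in seq_len(k)) {
        C[state(i, l), state(i, seq_len(k))] <-
          C[state(i, l), state(i, seq_len(k))] + layer_change_prob * rows[l, ]
      }
    }
  } else {
    C <- diag(1, ns)
  }

  T_full <- M %*% J %*% C

  # restrict to states reachable from the start (seed node, any layer)
  reach <- rep(FALSE, ns)
  frontier <- state(seed_i, seq_len(k))
  reach[frontier] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(T_full[frontier, , drop = FALSE] > 1e-300) > 0)
    frontier <- nxt[!reach[nxt]]
    reach[frontier] <- TRUE
  }
  ridx <- which(reach)
  Tr <- T_full[ridx, ridx, drop = FALSE]

  ev <- eigen(t(Tr))
  pick <- which.min(abs(ev$values - 1))
  if (abs(ev$values[pick] - 1) > 1e-8) {
    stop("stationary distribution not found (no unit eigenvalue)",
         call. = FALSE)
  }
  pi_r <- Re(ev$vectors[, pick])
  if (sum(pi_r) < 0) pi_r <- -pi_r
  if (min(pi_r) < -1e-8 * max(abs(pi_r))) {
    stop("stationary solve produced a signed eigenvector; ",
         "the chain may have several recurrent classes", call. = FALSE)
  }
  pi_r[pi_r < 0] <- 0
  pi_r <- pi_r / sum(pi_r)
  resid <- max(abs(drop(pi_r %*% Tr) - pi_r))
  if (resid > 1e-8) stop("stationary residual too large: ", resid,
                         call. = FALSE)

  # per-step scoring: the move landing plus the restart mass on the seed
  land_state <- drop(pi_r %*% M[ridx, , drop = FALSE])
  land_node <- numeric(n)
  for (l in seq_len(k)) {
    land_node <- land_node + land_state[state(seq_len(n), l)]
  }
  score <- land_node
  score[seed_i] <- score[seed_i] + jump_prob
  score <- score / (1 + jump_prob)
  names(score) <- net$nodes
  score
}

#' @exportS3Method generics::tidy
tidy.plcdm_walk <- function(x, ...) {
  tibble::tibble(
    node = names(x$raw_counts),
    raw_count = as.numeric(x$raw_counts),
    z_score = as.numeric(x$z_scores),
    in_community = names(x$raw_counts) %in% x$community
  )
}

#' @exportS3Method generics::glance
glance.plcdm_walk <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    community_size = length(x$community),
    iteration_count = x$params$iteration_count,
    jump_prob = x$params$jump_prob,
    layer_change_prob = x$params$layer_change_prob,
    rng_seed = x$params$rng_seed,
    jumps = x$jumps,
    total_scored = sum(x$raw_counts)
  )
}

#' Plot the z-scored visit profile of a walk
#'
#' Nodes ordered by z-score, coloured by community membership, with the
#' zero line that separates community from background.
#'
#' @param object A `plcdm_walk`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plcdm_walk <- function(object, ...) {
  d <- tidy(object)
  d$node <- stats::reorder(d$node, d$z_score)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$z_score,
                                  fill = .data$in_community)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "z-scored visit count",
                  fill = "in community",
                  title = paste0("Local community of seed '", object$seed, "'")) +
    ggplot2::theme_minimal()
}

#' Write a walk result with provenance header
#'
#' TSV columns `node`, `raw_count`, `z_score`, `in_community`, preceded by
#' `#`-prefixed metadata lines (parameters, RNG seed, network fingerprint).
#'
#' @param result A `plcdm_walk`.
#' @param net The network the walk ran on (for the fingerprint).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_walk_result <- function(result, net, path) {
  stopifnot(inherits(result, "plcdm_walk"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  p <- result$params
  writeLines(c(
    paste0("# plcdm ", as.character(utils::packageVersion("plcdm"))),
    paste0("# seed\t", result$seed),
    paste0("# iteration_count\t", format(p$iteration_count, scientific = FALSE)),
    paste0("# jump_prob\t", p$jump_prob),
    paste0("# layer_change_prob\t", p$layer_change_prob),
    paste0("# rng_seed\t", p$rng_seed),
    paste0("# network_hash\t", rlang::hash(list(net$nodes, net$layers, net$edges))),
    "node\traw_count\tz_score\tin_community"
  ), con)
  d <- tidy(result)
  writeLines(paste(d$node, format(d$raw_count, scientific = FALSE),
                   formatC(d$z_score, digits = 10, format = "g"),
                   as.integer(d$in_community), sep = "\t"), con)
  invisible(path)
}
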