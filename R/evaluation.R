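#' Node-level contingency table of a predicted community
#'
#' Confusion counts of the predicted community against the ground-truth
#' community over the node universe: `tp = |predicted n truth|`,
#' `fp = |predicted \\ truth|`, `fn = |truth \\ predicted|`, and `tn` the
#' remaining nodes. The four counts always sum to the universe size.
#'
#' @param predicted Character vector, the detected community.
#' @param truth Character vector, the ground-truth community.
#' @param universe Character vector, the node universe (both sets must be
#'   subsets of it).
#' @return One-row tibble with columns `tp`, `fp`, `fn`, `tn`,
#'   `universe_size`.
#' @examples
#' contingency(c("v1", "v2", "v3", "v6", "v7"),
#'             c("v1", "v2", "v3", "v4", "v5"),
#'             paste0("v", 1:12))
#' @export
contingency <- function(predicted, truth, universe) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  universe <- unique(as.character(universe))
  if (!all(predicted %in% universe)) {
    stop("`predicted` is not a subset of `universe`", call. = FALSE)
  }
  if (!all(truth %in% universe)) {
    stop("`truth` is not a subset of `universe`", call. = FALSE)
  }
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 universe_size = length(universe))
}

#' Set-based evaluation metrics from a contingency table
#'
#' Computes specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, recall
#' `tp/(tp+fn)`, accuracy `(tp+tn)/N`, `F1 = 2tp/(2tp+fp+fn)`, the Matthews
#' correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))` and the false
#' discovery rate `fp/(fp+tp)`. A ratio with zero denominator (and MCC with
#' any zero factor) is reported as 0 and the row is flagged `degenerate` so
#' aggregation can exclude it.
#'
#' @param table One-row data frame with columns `tp`, `fp`, `fn`, `tn` (as
#'   from [contingency()]).
#' @return One-row tibble of the seven metrics plus `degenerate`.
#' @export
compute_metrics <- function(table) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(table)),
            nrow(table) == 1)
  tp <- as.numeric(table$tp); fp <- as.numeric(table$fp)
  fn <- as.numeric(table$fn); tn <- as.numeric(table$tn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n <- tp + fp + fn + tn

  safe_ratio <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- (tn + fp == 0) || (tp + fp == 0) || (tp + fn == 0) ||
    (tn + fn == 0)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble::tibble(
    specificity = safe_ratio(tn, tn + fp),
    precision = safe_ratio(tp, tp + fp),
    recall = safe_ratio(tp, tp + fn),
    accuracy = safe_ratio(tp + tn, n),
    f1 = safe_ratio(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den),
    fdr = safe_ratio(fp, fp + tp),
    degenerate = degenerate
  )
}

#' Normalized mutual information of two node sets
#'
#' Treats each set as a binary labelling of the universe (member /
#' non-member) and computes `NMI(Y, C) = 2 I(Y; C) / (H(Y) + H(C))` with
#' natural-log entropies from the 2x2 joint membership counts. Equals 1 for
#' identical non-trivial labelings and 0 when either labelling is constant
#' (zero entropy) or the sets are independent.
#'
#' @inheritParams contingency
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(predicted, truth, universe) {
  ct <- contingency(predicted, truth, universe)
  n <- ct$universe_size
  if (n == 0) stop("empty universe", call. = FALSE)
  joint <- matrix(c(ct$tp, ct$fp, ct$fn, ct$tn), 2, 2) / n
  py <- rowSums(joint)  # predicted in/out
  pc <- colSums(joint)  # truth in/out
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  hy <- ent(py)
  hc <- ent(pc)
  if (hy == 0 || hc == 0) return(0)
  mi <- 0
  for (a in 1:2) {
    for (b in 1:2) {
      if (joint[a, b] > 0) {
        mi <- mi + joint[a, b] * log(joint[a, b] / (py[a] * pc[b]))
      }
    }
  }
  max(0, min(1, 2 * mi / (hy + hc)))
}

#' Per-seed benchmark of community recovery against ground truth
#'
#' The evaluation protocol: every node of every ground-truth community is
#' used as a seed, [run_plcdm()] detects its local community, and the
#' result is scored against that seed's own community with the full metric
#' set (contingency counts, the seven set metrics and NMI). Replicates
#' repeat the whole sweep with shifted RNG seeds. Aggregates report both
#' mean and median per metric across seeds and replicates.
#'
#' @param net A `multilayer_network`.
#' @param ground_truth List of character vectors (the known communities).
#' @param params A [walk_params()] object; its `rng_seed` is shifted
#'   deterministically per seed node and replicate.
#' @param replicates Number of independent repetitions of the seed sweep.
#' @param model Optional prebuilt transition model for `net`.
#' @return A `plcdm_benchmark` object: `per_seed` tibble (one row per seed
#'   x replicate) and `summary` tibble (mean, median, sd per metric).
#' @export
plcdm_benchmark <- function(net, ground_truth, params = walk_params(),
                            replicates = 1, model = NULL) {
  stopifnot(inherits(net, "multilayer_network"), is.list(ground_truth),
            length(ground_truth) > 0, all(lengths(ground_truth) > 0),
            replicates >= 1)
  if (!all(unlist(ground_truth) %in% net$nodes)) {
    stop("ground-truth communities must be subsets of the node universe",
         call. = FALSE)
  }
  if (is.null(model)) model <- build_transition_model(net)

  grid <- tidyr::expand_grid(
    replicate = seq_len(replicates),
    community_id = seq_along(ground_truth)
  )
  rows <- purrr::pmap(grid, function(replicate, community_id) {
    comm <- ground_truth[[community_id]]
    purrr::imap(comm, function(seed, pos) {
      p <- params
      p$rng_seed <- params$rng_seed + 7919L * (replicate - 1L) +
        101L * (community_id - 1L) + (pos - 1L)
      res <- run_plcdm(net, seed, p, model = model)
      ct <- contingency(res$community, comm, net$nodes)
      dplyr::bind_cols(
        tibble::tibble(replicate = replicate, community_id = community_id,
                       seed = seed, community_size = length(res$community),
                       truth_size = length(comm)),
        ct[, c("tp", "fp", "fn", "tn")],
        compute_metrics(ct),
        tibble::tibble(nmi = nmi(res$community, comm, net$nodes))
      )
    })
  })
  per_seed <- dplyr::bind_rows(purrr::flatten(rows))

  metric_cols <- c("specificity", "precision", "recall", "accuracy", "f1",
                   "mcc", "fdr", "nmi")
  summary <- per_seed |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      median = stats::median(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, metric_cols))

  structure(list(per_seed = per_seed, summary = summary,
                 params = params, replicates = replicates),
            class = "plcdm_benchmark")
}

#' @export
print.plcdm_benchmark <- function(x, ...) {
  cat("<plcdm_benchmark> ", nrow(x$per_seed), " seed runs (",
      x$replicates, " replicate(s))\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.plcdm_benchmark <- function(x, ...) x$per_seed

#' @exportS3Method generics::glance
glance.plcdm_benchmark <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(tibble::as_tibble(wide),
                   tibble::tibble(n_runs = nrow(x$per_seed),
                                  replicates = x$replicates))
}

#' Boxplots of per-seed evaluation metrics
#'
#' One box per metric over all seed runs, mirroring how per-seed benchmark
#' distributions are usually displayed.
#'
#' @param object A `plcdm_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plcdm_benchmark <- function(object, ...) {
  metric_cols <- c("specificity", "precision", "recall", "accuracy", "f1",
                   "mcc", "fdr", "nmi")
  d <- object$per_seed |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric, levels = metric_cols))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "per-seed value",
                  title = "Community recovery across ground-truth seeds") +
    ggplot2::theme_minimal()
}

#' Write per-seed and aggregate benchmark tables
#'
#' @param bench A `plcdm_benchmark`.
#' @param per_seed_path,summary_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_benchmark <- function(bench, per_seed_path, summary_path) {
  stopifnot(inherits(bench, "plcdm_benchmark"))
  utils::write.table(bench$per_seed, per_seed_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bench$summary, summary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(per_seed_path, summary_path))
}
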