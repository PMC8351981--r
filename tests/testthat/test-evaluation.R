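test_that("contingency counts follow the set definitions", {
  universe <- paste0("v", 1:12)
  ct <- contingency(paste0("v", c(1, 2, 3, 6, 7)), paste0("v", 1:5), universe)
  expect_equal(ct$tp, 3)
  expect_equal(ct$fp, 2)
  expect_equal(ct$fn, 2)
  expect_equal(ct$tn, 5)
  expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, ct$universe_size)

  exact <- contingency(c("a", "b"), c("a", "b"), c("a", "b", "c"))
  expect_equal(c(exact$fp, exact$fn), c(0, 0))
  none <- contingency(character(0), c("a", "b"), c("a", "b", "c"))
  expect_equal(c(none$tp, none$fp, none$fn), c(0, 0, 2))
  expect_error(contingency("zz", "a", c("a", "b")), "subset")
})

test_that("set metrics match their formulas on the worked contingency", {
  ct <- tibble::tibble(tp = 3, fp = 2, fn = 2, tn = 5)
  m <- compute_metrics(ct)
  expect_equal(m$f1, 0.6)
  expect_equal(m$fdr, 0.4)
  expect_equal(m$mcc, 11 / 35)
  expect_equal(m$precision, 0.6)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 5 / 7)
  expect_equal(m$accuracy, 8 / 12)
  expect_false(m$degenerate)
})

test_that("perfect and degenerate predictions hit the metric boundaries", {
  perfect <- compute_metrics(tibble::tibble(tp = 5, fp = 0, fn = 0, tn = 7))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$fdr, 0)

  noisy <- compute_metrics(tibble::tibble(tp = 0, fp = 4, fn = 2, tn = 6))
  expect_equal(noisy$precision, 0)
  expect_equal(noisy$fdr, 1)

  empty_pred <- compute_metrics(tibble::tibble(tp = 0, fp = 0, fn = 3, tn = 9))
  expect_equal(empty_pred$precision, 0)
  expect_equal(empty_pred$fdr, 0)
  expect_true(empty_pred$degenerate)
})

test_that("metric identities hold on randomized contingency tables", {
  set.seed(14)
  for (rep in 1:25) {
    universe <- paste0("u", 1:30)
    predicted <- sample(universe, sample(1:20, 1))
    truth <- sample(universe, sample(1:20, 1))
    ct <- contingency(predicted, truth, universe)
    m <- compute_metrics(ct)
    # F1 is the harmonic mean of precision and recall when both defined
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
    # MCC is invariant under swapping prediction and truth
    swapped <- compute_metrics(contingency(truth, predicted, universe))
    expect_equal(m$mcc, swapped$mcc)
    expect_true(all(unlist(m[c("specificity", "precision", "recall",
                               "accuracy", "f1", "fdr")]) >= 0))
    expect_true(all(unlist(m[c("specificity", "precision", "recall",
                               "accuracy", "f1", "fdr")]) <= 1))
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
    # NMI agrees with the entropy-identity oracle and is symmetric
    v <- nmi(predicted, truth, universe)
    expect_equal(v, brute_nmi(predicted, truth, universe), tolerance = 1e-9)
    expect_equal(v, nmi(truth, predicted, universe))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("NMI boundary behaviour: identity, constancy, independence", {
  universe <- paste0("u", 1:12)
  expect_equal(nmi(universe[1:5], universe[1:5], universe), 1)
  # constant labelling (everything predicted) carries no information
  expect_equal(nmi(universe, universe[1:5], universe), 0)
  expect_equal(nmi(character(0), universe[1:5], universe), 0)
  # independent-looking split has low NMI
  expect_lt(nmi(universe[c(1, 3, 5, 7, 9, 11)], universe[1:6], universe), 0.05)
})

test_that("the per-seed protocol scores every ground-truth node against its module", {
  net <- two_clique_net(size = 5, k = 3)
  truth <- list(paste0("a", 1:5), paste0("b", 1:5))
  bench <- plcdm_benchmark(net, truth,
                           walk_params(iteration_count = 3000, rng_seed = 2))
  expect_equal(nrow(bench$per_seed), 10)
  # fully separable cliques: exact recovery from every seed
  expect_true(all(bench$per_seed$f1 == 1))
  expect_equal(bench$summary$mean[bench$summary$metric == "f1"], 1)
  expect_equal(bench$summary$median[bench$summary$metric == "fdr"], 0)
  expect_setequal(bench$per_seed$seed, unlist(truth))
  # replicates rerun the sweep with shifted seeds
  b2 <- plcdm_benchmark(net, truth,
                        walk_params(iteration_count = 3000, rng_seed = 2),
                        replicates = 2)
  expect_equal(nrow(b2$per_seed), 20)
  expect_equal(sort(unique(b2$per_seed$replicate)), 1:2)
  # glance exposes the mean profile
  g <- glance(bench)
  expect_equal(g$f1, 1)
  expect_equal(g$n_runs, 10)
})

test_that("the aggregated single-layer network runs through the same protocol", {
  net <- two_clique_net(size = 4, k = 3)
  truth <- list(paste0("a", 1:4), paste0("b", 1:4))
  agg <- aggregate_layers(net)
  bench <- plcdm_benchmark(agg, truth,
                           walk_params(iteration_count = 2000, rng_seed = 9))
  expect_equal(nrow(bench$per_seed), 8)
  expect_true(all(c("specificity", "precision", "recall", "accuracy", "f1",
                    "mcc", "fdr", "nmi") %in% bench$summary$metric))
  expect_true(all(bench$per_seed$f1 == 1))
})
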