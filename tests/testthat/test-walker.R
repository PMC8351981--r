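test_that("every scored step is accounted for: sum(counts) = 1 + t + jumps", {
  grid <- expand.grid(jump = c(0, 0.3, 1), change = c(0, 0.5), seed = c(1, 42))
  net <- random_multilayer(n = 10, k = 3, p = 0.35, seed = 2)
  model <- build_transition_model(net)
  for (r in seq_len(nrow(grid))) {
    res <- run_plcdm(net, "n1",
                     walk_params(iteration_count = 500,
                                 jump_prob = grid$jump[r],
                                 layer_change_prob = grid$change[r],
                                 rng_seed = grid$seed[r]),
                     model = model)
    expect_identical(sum(res$raw_counts), 1 + 500 + res$jumps)
    expect_gte(res$raw_counts[["n1"]], 1)
    expect_setequal(res$community, names(res$z_scores)[res$z_scores > 0])
  }
})

test_that("identical inputs and rng seed reproduce the walk exactly", {
  net <- random_multilayer(n = 12, k = 2, p = 0.3, seed = 8)
  p <- walk_params(iteration_count = 2000, rng_seed = 99)
  a <- run_plcdm(net, "n4", p)
  b <- run_plcdm(net, "n4", p)
  expect_identical(a$raw_counts, b$raw_counts)
  expect_identical(a$community, b$community)
  c <- run_plcdm(net, "n4", walk_params(iteration_count = 2000, rng_seed = 100))
  expect_false(identical(a$raw_counts, c$raw_counts))
})

test_that("the walker never leaves the seed's connected component", {
  net <- two_clique_net(size = 4, k = 2)
  res <- run_plcdm(net, "a1", walk_params(iteration_count = 5000, rng_seed = 5))
  bs <- paste0("b", 1:4)
  expect_true(all(res$raw_counts[bs] == 0))
  expect_true(all(res$community %in% paste0("a", 1:4)))
  expect_setequal(res$community, paste0("a", 1:4))
})

test_that("z-score transform matches hand arithmetic and is mean-zero", {
  counts <- c(a = 4, b = 2, c = 0, d = 0)
  z <- zscore_transform(counts)
  expect_equal(unname(z), c(1.5076, 0.3015, -0.9045, -0.9045),
               tolerance = 1e-4)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  # constant counts: all zero
  expect_equal(unname(zscore_transform(c(a = 3, b = 3))), c(0, 0))
  # mean-zero property on random count vectors
  set.seed(1)
  for (i in 1:5) {
    v <- stats::setNames(rpois(20, 5), paste0("x", 1:20))
    expect_equal(mean(zscore_transform(v)), 0, tolerance = 1e-9)
  }
})

test_that("community extraction selects positive scores with seed fallback", {
  z <- c(a = 1.5, b = 0.3, c = -0.9, d = -0.9)
  expect_setequal(extract_community(z, "a"), c("a", "b"))
  expect_equal(extract_community(c(a = 0, b = 0), "b"), "b")
  expect_equal(extract_community(c(a = -1, b = 2, c = -1), "a"), "b")
})

test_that("a seed isolated in every layer degenerates to itself with a warning", {
  net <- multilayer_network(
    tibble::tibble(layer = "L1", from = "a", to = "b"),
    nodes = c("a", "b", "lone"),
    presence = tibble::tibble(layer = "L1", node = "lone")
  )
  expect_warning(
    res <- run_plcdm(net, "lone", walk_params(iteration_count = 100,
                                              rng_seed = 1)),
    "isolated"
  )
  expect_equal(res$community, "lone")
  expect_identical(sum(res$raw_counts), 1 + 100 + res$jumps)
})

test_that("single-layer runs ignore the layer-change probability entirely", {
  net <- toy_pendant_net()
  a <- run_plcdm(net, "1", walk_params(iteration_count = 1000,
                                       layer_change_prob = 0, rng_seed = 7))
  b <- run_plcdm(net, "1", walk_params(iteration_count = 1000,
                                       layer_change_prob = 0.9, rng_seed = 7))
  expect_identical(a$raw_counts, b$raw_counts)
})

test_that("the closed-form oracle reproduces simple limiting cases", {
  # two nodes, no restart: scoring alternates between the endpoints
  pair <- multilayer_network(tibble::tibble(layer = "L1", from = "a", to = "b"))
  expect_equal(unname(expected_visit_distribution(pair, "a", jump_prob = 0)),
               c(0.5, 0.5))
  # restart probability one: the seed dominates every other node
  net <- random_multilayer(n = 8, k = 2, p = 0.4, seed = 4)
  d <- expected_visit_distribution(net, "n2", jump_prob = 1)
  expect_true(all(d["n2"] > d[setdiff(names(d), "n2")]))
  # raising the restart probability never lowers the seed's share
  shares <- vapply(c(0.1, 0.3, 0.5, 0.8), function(pj) {
    expected_visit_distribution(net, "n2", jump_prob = pj)[["n2"]]
  }, numeric(1))
  expect_true(all(diff(shares) > -1e-12))
})

test_that("empirical visit frequencies converge to the oracle", {
  net <- random_multilayer(n = 15, k = 2, p = 0.3, seed = 6)
  oracle <- expected_visit_distribution(net, "n1")
  res <- run_plcdm(net, "n1", walk_params(iteration_count = 2e5, rng_seed = 21))
  emp <- res$raw_counts / sum(res$raw_counts)
  tv <- 0.5 * sum(abs(emp - oracle[names(emp)]))
  expect_lt(tv, 0.02)
})

test_that("walk results serialize with provenance and tidy round-trip", {
  net <- toy_pendant_net()
  res <- run_plcdm(net, "1", walk_params(iteration_count = 500, rng_seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_walk_result(res, net, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# rng_seed\t3$", lines)))
  d <- utils::read.delim(f, comment.char = "#")
  expect_equal(as.character(d$node), tidy(res)$node)
  expect_equal(d$raw_count, unname(res$raw_counts))
  g <- glance(res)
  expect_equal(g$community_size, length(res$community))
  expect_equal(g$total_scored, sum(res$raw_counts))
})
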