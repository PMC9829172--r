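test_that("pool generation hits the specified distributions", {
  spec <- single_species_pool(n = 100000)
  pool <- generate_pool(spec, seed = 2)
  g <- pool$g_max_1
  K <- pool$K_1
  expect_lt(abs(mean(g) - 1.0), 3 * 0.03 / sqrt(length(g)))
  expect_lt(abs(sd(g) - 0.03), 0.002)
  # log-normal: median at 4, sd of logs 0.5
  se_med <- 1.2533 * 0.5 / sqrt(length(K))   # asymptotic SE of median of logs
  expect_lt(abs(median(log(K)) - log(4)), 3 * se_med)
  expect_lt(abs(sd(log(K)) - 0.5), 0.01)
  expect_true(all(g > 0) && all(K > 0))
})

test_that("zero-variance specs collapse onto the means and medians", {
  spec <- pool_spec(species_spec(5, g_mean = 0.8, g_sd = 0,
                                 K_meanlog = log(2), K_sdlog = 0),
                    resource_count = 1)
  pool <- generate_pool(spec, seed = 1)
  expect_true(all(pool$g_max_1 == 0.8))
  expect_true(all(pool$K_1 == 2))
})

test_that("pool generation is deterministic given the seed", {
  spec <- two_species_pool(n = 10, x_sd = 0.1)
  expect_identical(generate_pool(spec, seed = 7), generate_pool(spec, seed = 7))
  expect_false(identical(generate_pool(spec, seed = 7),
                         generate_pool(spec, seed = 8)))
  # and leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_pool(spec, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("two-species pools carry the Methods co-utilization structure", {
  pool <- generate_pool(two_species_pool(), seed = 3)
  expect_equal(nrow(pool), 100)
  I <- pool[pool$species == "I", ]
  II <- pool[pool$species == "II", ]
  expect_equal(I$x_1, rep(0.2, 50))
  expect_equal(I$x_2, rep(0.8, 50))
  expect_equal(II$x_1, rep(0.7, 50))
  expect_equal(II$x_2, rep(0.3, 50))
  expect_equal(pool$x_1 + pool$x_2, rep(1, 100))
  # per-strain g shared across resources
  expect_identical(pool$g_max_1, pool$g_max_2)
})

test_that("pareto front contains exactly the non-dominated strains", {
  two <- rbind(strain("weak", 0.5, 5), strain("strong", 1.0, 0.5))
  expect_equal(pareto_front(two), "strong")
  expect_setequal(pareto_front(pair_AB()), c("A", "B"))
  withr::with_seed(111, {
    pool <- generate_pool(single_species_pool(n = 50), seed = 12)
    front <- pareto_front(pool)
    g <- pool$g_max_1; K <- pool$K_1
    for (i in seq_len(nrow(pool))) {
      dominated <- any(g >= g[i] & K <= K[i] & (g > g[i] | K < K[i]))
      expect_equal(pool$id[i] %in% front, !dominated)
    }
  })
})

test_that("small ensembles reproduce survivor-count structure and determinism", {
  env <- std_env()
  ens <- run_ensemble(single_species_pool(), env, n_pools = 12,
                      base_seed = 5)
  expect_equal(ens$n_pools, 12)
  counts <- ens$records$n_survivors
  expect_true(all(counts >= 1 & counts <= 3))
  expect_equal(sum(ens$survivor_count_histogram), 1)
  # survivors lie on (or at) the Pareto front in the typical pool
  on_front <- vapply(seq_len(12), function(i) {
    pool <- generate_pool(single_species_pool(), seed = ens$records$seed[i])
    surv <- strsplit(ens$records$survivors[i], "\\+")[[1]]
    all(surv %in% pareto_front(pool))
  }, logical(1))
  expect_gte(mean(on_front), 0.9)
  ens2 <- run_ensemble(single_species_pool(), env, n_pools = 12,
                       base_seed = 5)
  expect_identical(ens$records, ens2$records)
})

test_that("two-species ensembles report joint and marginal histograms", {
  env <- dilution_env(c0 = c(10, 10))
  ens <- run_ensemble(two_species_pool(n = 25), env, n_pools = 6,
                      base_seed = 11)
  expect_equal(sum(ens$joint_species_histogram), 1)
  expect_named(ens$species_histograms, c("I", "II"))
  expect_true(all(ens$records$n_I >= 1) || all(ens$records$n_II >= 1))
  expect_equal(ens$records$n_survivors,
               ens$records$n_I + ens$records$n_II)
})
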