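test_that("a near-zero-K strain converts all supplied resource (conservation)", {
  env <- std_env()
  s <- strain("s", g_max = 1, K = 1e-9)
  end <- integrate_cycle(s, cycle_state(N = 1, c = 10), env)
  expect_equal(end$N, 11, tolerance = 1e-6)
  expect_lt(end$c, 1e-6)
})

test_that("total material is conserved within a cycle (yield 1, single resource)", {
  env <- std_env()
  end <- integrate_cycle(pair_AB(), cycle_state(N = c(1, 1), c = 10), env)
  expect_equal(sum(end$N) + end$c, 12, tolerance = 1e-8)
  withr::with_seed(21, {
    for (rep in 1:5) {
      strains <- random_strain_set(4)
      N0 <- runif(4, 0.2, 2)
      end <- integrate_cycle(strains, cycle_state(N = N0, c = 10), env)
      budget0 <- sum(N0) + 10
      expect_equal(sum(end$N) + end$c, budget0,
                   tolerance = 1e-8 * budget0)
      expect_true(all(end$N >= N0))       # abundances nondecreasing
      expect_lte(end$c, 10)               # resource nonincreasing
    }
  })
})

test_that("the RK45 core agrees with an independent lsoda reference", {
  env <- std_env()
  withr::with_seed(31, {
    for (rep in 1:5) {
      strains <- random_strain_set(3)
      N0 <- runif(3, 0.5, 2)
      mine <- integrate_cycle(strains, cycle_state(N = N0, c = 10), env)
      ref <- lsoda_cycle(strains, N0, 10, env$T)
      expect_equal(mine$N, ref$N, tolerance = 1e-6)
    }
  })
  # two co-utilized resources, unequal yields
  two <- rbind(strain("I_1", c(1, 1), c(4, 5), x = c(0.2, 0.8),
                      species = "I"),
               strain("II_1", c(0.55, 0.55), c(0.05, 0.03), x = c(0.7, 0.3),
                      species = "II"))
  env2 <- dilution_env(c0 = c(10, 10))
  mine <- integrate_cycle(two, cycle_state(N = c(1, 1), c = c(10, 10)), env2)
  ref <- lsoda_cycle(two, c(1, 1), c(10, 10), env2$T)
  expect_equal(mine$N, ref$N, tolerance = 1e-6)
  expect_equal(mine$c, ref$c, tolerance = 1e-4)
})

test_that("per-resource budgets decompose in the multi-resource case", {
  # with yield 1, total biomass gain equals total resource drain
  env2 <- dilution_env(c0 = c(10, 10))
  two <- rbind(strain("a", c(1, 1), c(4, 5), x = c(0.2, 0.8)),
               strain("b", c(0.55, 0.55), c(0.05, 0.03), x = c(0.7, 0.3),
                      species = "II"))
  end <- integrate_cycle(two, cycle_state(N = c(1, 1), c = c(10, 10)), env2)
  gain <- sum(end$N) - 2
  drain <- sum(20 - sum(end$c))
  expect_equal(gain, drain, tolerance = 1e-8 * 20)
})

test_that("with equal K the larger-g strain achieves the larger fold change", {
  env <- std_env()
  strains <- rbind(strain("slow", 0.6, 2), strain("fast", 0.9, 2))
  end <- integrate_cycle(strains, cycle_state(N = c(1, 1), c = 10), env)
  expect_gt(end$N[2], end$N[1])
})

test_that("invalid cycle inputs are rejected", {
  env <- std_env()
  expect_error(cycle_state(N = -1, c = 10), ">= 0")
  expect_error(integrate_cycle(pair_AB(), cycle_state(N = 1, c = 10), env),
               "abundances")
  expect_error(integrate_cycle(pair_AB(),
                               cycle_state(N = c(1, 1), c = 10, t = 2), env),
               "t = 0")
})

test_that("the step-model event solver reproduces closed-form solutions", {
  env <- std_env()
  # one strain: grows until c = K at e^t = 10, i.e. t = ln 10
  end <- integrate_cycle_step(step_strain("s", 1, 1),
                              cycle_state(N = 1, c = 10), env)
  expect_equal(end$N, 10, tolerance = 1e-10)
  expect_equal(end$c, 1, tolerance = 1e-10)
  # threshold above supply: never grows
  end2 <- integrate_cycle_step(step_strain("s", 1, 11),
                               cycle_state(N = 1, c = 10), env)
  expect_equal(end2$N, 1)
  expect_equal(end2$c, 10)
  # two strains: first crossing from 12 - 2 e^t = 5 (equal g), order checked
  two <- step_strain(c("hiK", "loK"), g = c(1, 1), K = c(5, 1))
  t1 <- log(7 / 2)
  end3 <- integrate_cycle_step(two, cycle_state(N = c(1, 1), c = 10), env)
  expect_equal(end3$N[1], exp(t1), tolerance = 1e-9)   # frozen at crossing
  expect_equal(end3$c, 1, tolerance = 1e-9)            # final c = smallest K
  # conservation throughout
  expect_equal(sum(end3$N) + end3$c, 12, tolerance = 1e-9)
})

test_that("the event solver matches a steep-Hill ODE surrogate", {
  env <- std_env()
  withr::with_seed(41, {
    for (rep in 1:4) {
      st <- random_step_set(3)
      N0 <- runif(3, 0.5, 2)
      exact <- integrate_cycle_step(st, cycle_state(N = N0, c = 10), env)
      monod_form <- do.call(rbind, lapply(seq_len(3), function(i)
        strain(st$id[i], g_max = st$g[i], K = st$K[i])))
      ref <- lsoda_cycle(monod_form, N0, 10, env$T, hill = 2000)
      expect_equal(exact$N, ref$N, tolerance = 1e-3)
    }
  })
})
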