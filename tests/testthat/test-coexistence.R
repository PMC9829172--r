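test_that("the leftover-resource equation matches the simulated single-strain steady state", {
  env <- std_env()
  res <- run_to_steady_state(strain_B(), env)
  c_f <- solve_final_resource(strain_B(), env)
  expect_lt(abs(res$final_state$c - c_f) / c_f, 1e-4)
  # complete-depletion limit: K -> 0 with gT >> log D
  tiny <- solve_final_resource(strain("t", 1.0, 1e-6), env)
  expect_lt(attr(tiny, "log_c_f"), -100)
  # washout: cannot replace dilution losses even at saturation
  expect_error(solve_final_resource(strain("w", 0.09, 1),
                                    std_env()), "non-persistent")
})

test_that("total material follows (D c0 - c_f)/(D - 1) and the simulated fixed point", {
  env <- std_env()
  expect_equal(total_material(0, env), 100 / 9)
  expect_equal(total_material(10 - 1e-12, env), 10, tolerance = 1e-9)
  expect_error(total_material(10, env), "c_f")
  res <- run_to_steady_state(strain_B(), env)
  c_f <- solve_final_resource(strain_B(), env)
  expect_equal(total_material(c_f, env), sum(res$start_N) + env$c0,
               tolerance = 1e-4)
  # c_tot always between c0 and D c0/(D-1)
  withr::with_seed(71, {
    for (rep in 1:10) {
      cf <- runif(1, 0, 10)
      ct <- total_material(cf, env)
      expect_gt(ct, env$c0)
      expect_lt(ct, env$D * env$c0 / (env$D - 1) + 1e-12)
    }
  })
})

test_that("leftover resource decreases with cycle length and growth rate", {
  base <- strain("s", 0.4, 2)
  envs <- list(dilution_env(T = 10), dilution_env(T = 14), dilution_env(T = 20))
  cfs <- sapply(envs, function(e) attr(solve_final_resource(base, e), "log_c_f"))
  expect_true(all(diff(cfs) < 0))
  gs <- c(0.3, 0.4, 0.6)
  cfg <- sapply(gs, function(g)
    attr(solve_final_resource(strain("s", g, 2), dilution_env(T = 10)),
         "log_c_f"))
  expect_true(all(diff(cfg) < 0))
})

test_that("pairwise bounds bracket the canonical coexisting pair and degenerate to 1", {
  env <- std_env()
  b <- pair_coexistence_bounds(strain_A(), strain_B(), env)
  expect_true(b$feasible)
  expect_lt(b$ratio_lower, 1.0 / 0.55)
  expect_gt(b$ratio_upper, 1.0 / 0.55)
  expect_true(b$predicted_coexistence)
  # identical strains: zero-width region at ratio 1
  same <- pair_coexistence_bounds(strain("A", 0.7, 2),
                                  strain("B", 0.7, 2), env)
  expect_equal(same$ratio_lower, 1, tolerance = 1e-9)
  expect_equal(same$ratio_upper, 1, tolerance = 1e-9)
  expect_error(pair_coexistence_bounds(strain_B(), strain_A(), env),
               "low-K")
})

test_that("bound feasibility matches brute-force assembly away from the boundary", {
  env <- std_env()
  A <- strain_A()
  withr::with_seed(81, {
    K_Bs <- exp(runif(8, log(0.1), log(5)))
    for (K_B in K_Bs) {
      b <- pair_coexistence_bounds(A, strain("B", 1, K_B), env)
      width <- b$ratio_upper - b$ratio_lower
      # probe clearly inside and clearly outside the band
      for (frac in c(-0.2, 0.5, 1.2)) {
        ratio <- b$ratio_lower + frac * width
        g_B <- 0.55 * ratio
        if (g_B <= 0.1) next
        res <- run_to_steady_state(rbind(A, strain("B", g_B, K_B)), env,
                                   max_cycles = 4000)
        sim_coexist <- setequal(survivor_ids(res, "trend"), c("A", "B"))
        expect_equal(sim_coexist, frac > 0 && frac < 1)
      }
    }
  })
})

test_that("the asymptotic coexistence width behaves as derived", {
  env <- std_env()
  A <- strain("A", 0.55, 0.2)
  expect_equal(coexistence_width(A, 0.2, env)$delta_g, 0)
  expect_equal(coexistence_width(A, 0.2, env, "quadratic")$delta_g, 0)
  # inverse linear dependence on c0
  w1 <- coexistence_width(A, 0.3, dilution_env(c0 = 10))$delta_g
  w2 <- coexistence_width(A, 0.3, dilution_env(c0 = 20))$delta_g
  expect_equal(w1 / w2, 2, tolerance = 1e-12)
  # quadratic and generalized variants agree for small K_B - K_A
  wq <- coexistence_width(A, 0.202, env, "quadratic")$delta_g
  wg <- coexistence_width(A, 0.202, env, "generalized")$delta_g
  expect_equal(wq, wg, tolerance = 0.01)
  # against the exact bounds in the asymptotic regime (K << c0, long T)
  envL <- dilution_env(c0 = 10, D = 10, T = 200)
  A2 <- strain("A", 0.55, 0.05)
  for (ratio in c(1.05, 1.2, 1.5)) {
    K_B <- 0.05 * ratio
    b <- pair_coexistence_bounds(A2, strain("B", 0.6, K_B), envL)
    exact <- 0.55 * (b$ratio_upper - b$ratio_lower)
    approx <- coexistence_width(A2, K_B, envL)$delta_g
    expect_lt(abs(approx - exact) / exact, 0.3)
  }
})

test_that("invasion fitness is zero for the resident and signs reproduce the analytic bounds", {
  env <- std_env()
  resident <- strain("R", 0.7, 1.5)
  expect_equal(invasion_fitness(strain("R2", 0.7, 1.5), resident, env), 0,
               tolerance = 1e-5)
  expect_gt(invasion_fitness(strain("up", 0.75, 1.5), resident, env), 0)
  withr::with_seed(91, {
    for (rep in 1:8) {
      gA <- runif(1, 0.4, 0.8); KA <- exp(runif(1, log(0.05), log(1)))
      KB <- KA * exp(runif(1, 0.2, 2))
      A <- strain("A", gA, KA)
      b <- pair_coexistence_bounds(A, strain("B", 1, KB), env)
      ratio <- runif(1, 0.8 * b$ratio_lower, 1.2 * b$ratio_upper)
      B <- strain("B", gA * ratio, KB)
      fB <- invasion_fitness(B, A, env)   # B invades resident A
      fA <- invasion_fitness(A, B, env)   # A invades resident B
      expect_equal(fB > 0, ratio > b$ratio_lower)
      expect_equal(fA > 0, ratio < b$ratio_upper)
    }
  })
})

test_that("environment scans recover coexistence at the standard point and exclusion at D -> 1+", {
  grid <- scan_environment(strain_A(), strain_B(), c0_grid = 10,
                           D_grid = c(1.05, 10),
                           env_template = std_env(), max_cycles = 6000)
  std <- grid[grid$D == 10, ]
  expect_gt(std$rel_abundance_B, 0)
  expect_lt(std$rel_abundance_B, 1)
  expect_equal(std$n_survivors, 2)
  low <- grid[grid$D == 1.05, ]
  expect_equal(low$n_survivors, 1)
})

test_that("triple coexistence is a strict subset of the pairwise shadow intersection", {
  env <- std_env()
  A <- strain_A(); B <- strain_B()
  g_grid <- seq(0.6, 0.7, length.out = 5)
  K_grid <- seq(0.25, 1.05, length.out = 5)
  scan <- scan_invader_region(A, B, g_grid, K_grid, env, max_cycles = 4000)
  # C dominated by both at a corner: A and B persist
  corner <- scan[scan$g_C == 0.6 & scan$K_C == 1.05, ]
  expect_equal(corner$survivors, "A+B")
  expect_true(any(scan$n_survivors == 3))
  inside_both <- function(margin) vapply(seq_len(nrow(scan)), function(i) {
    C <- strain("C", scan$g_C[i], scan$K_C[i])
    bAC <- pair_coexistence_bounds(A, C, env)
    bCB <- pair_coexistence_bounds(C, B, env)
    rAC <- scan$g_C[i] / 0.55
    rCB <- 1.0 / scan$g_C[i]
    (bAC$ratio_lower / margin < rAC && rAC < bAC$ratio_upper * margin) &&
      (bCB$ratio_lower / margin < rCB && rCB < bCB$ratio_upper * margin)
  }, logical(1))
  triple <- scan$n_survivors == 3
  # triple coexistence implies both pairwise shadows, up to a thin
  # higher-order rescue band along the pairwise boundary (2% on the ratio)
  expect_true(all(inside_both(1.02)[triple]))
  # the converse fails: pairwise shadows do not guarantee triple coexistence
  expect_true(any(inside_both(1.0) & !triple))
})
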