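#' Leftover resource at a single-strain steady state
#'
#' At the steady state of the serial-dilution protocol a lone strain grows
#' exactly `D`-fold per cycle.  Integrating the within-cycle Monod dynamics
#' with conservation (`yield = 1`) gives an implicit equation for the
#' leftover concentration `c_f` at the end of each steady-state cycle:
#' \deqn{\frac{1}{g}\left[\log D +
#'   \frac{(D-1)K}{D c_0 - c_f}\,\log\frac{D c_0}{c_f}\right] = T.}
#' The left-hand side is monotone decreasing in `c_f`, so the root in
#' `(0, c0)` is unique.  The solve is performed in `log c_f`, which keeps
#' full relative precision even in the deep-depletion regime where `c_f`
#' is many orders of magnitude below `c0` (for long cycles it can drop
#' below the smallest representable double; the returned value then
#' underflows to 0 but the `"log_c_f"` attribute remains exact).
#'
#' @param strain a one-row, single-resource strain table with `yield = 1`.
#' @param env a single-resource [dilution_env()].
#' @return the leftover concentration `c_f` (a.u.), with attribute
#'   `"log_c_f"` carrying `log(c_f)`.
#' @examples
#' solve_final_resource(strain("B", 1.0, 4.0), dilution_env())
#' @export
solve_final_resource <- function(strain, env) {
  stopifnot(inherits(env, "dilution_env"))
  p <- analytic_params(strain, env)
  g <- p$g; K <- p$K; c0 <- env$c0; D <- env$D; T <- env$T
  # value of the cycle-duration expression at log(c_f) = v
  lhs <- function(v)
    (log(D) + (D - 1) * K * (log(D * c0) - v) / (D * c0 - exp(v))) / g
  v_hi <- log(c0) + log1p(-1e-12)
  if (lhs(v_hi) > T)
    stop("non-persistent strain: it cannot grow D-fold in T hours even ",
         "with negligible depletion (g T too close to log D)")
  # bracket: ignore exp(v) against D c0 to bound the root from below
  v_lo <- log(D * c0) - (g * T - log(D)) * D * c0 / ((D - 1) * K) - 10
  root <- stats::uniroot(function(v) lhs(v) - T, lower = v_lo, upper = v_hi,
                         tol = 1e-13, maxiter = 2000)
  structure(exp(root$root), log_c_f = root$root)
}

#' Total material concentration at a single-strain steady state
#'
#' Cells plus nutrients, in the shared units that yield 1 makes possible:
#' `c_tot = (D c0 - c_f) / (D - 1)`.  It always lies in
#' `(c0, D c0/(D-1))`.
#'
#' @param c_f leftover concentration, in `[0, c0)`.
#' @param env a single-resource [dilution_env()].
#' @return `c_tot` (a.u.).
#' @export
total_material <- function(c_f, env) {
  stopifnot(inherits(env, "dilution_env"))
  if (any(c_f < 0) || any(c_f >= env$c0))
    stop("c_f must lie in [0, c0)")
  as.numeric((env$D * env$c0 - c_f) / (env$D - 1))
}

#' Analytic pairwise coexistence bounds
#'
#' Two strains coexist under serial dilution iff each can invade the other's
#' single-strain steady state.  Writing the invasion integrals in closed
#' form (via the same change of variables that yields the leftover-resource
#' equation) gives a lower and an upper bound on the growth-rate ratio
#' `g_B/g_A` in terms of the leftover concentrations `c_f` and total
#' material `c_tot` of the two single-strain steady states:
#' \deqn{\frac{(c^{tot}_A+K_B)\log D}{(c^{tot}_A+K_A)\log D +
#'   (K_A-K_B)\log\frac{c_0+K_B}{c^f_A+K_B}} < \frac{g_B}{g_A} <
#'   \frac{(c^{tot}_B+K_B)\log D - (K_A-K_B)\log\frac{c_0+K_A}{c^f_B+K_A}}
#'        {(c^{tot}_B+K_A)\log D}.}
#' By convention `A` is the low-`K` strategist (`K_A <= K_B`).  The lower
#' bound is B's invasion condition against resident A; the upper bound is
#' A's against resident B.
#'
#' @param A,B one-row single-resource strain tables with yield 1; requires
#'   `K_A <= K_B`.
#' @param env a single-resource [dilution_env()].
#' @return an object of class `pair_coexistence_bounds`: list with
#'   `ratio_lower`, `ratio_upper`, the intermediate `c_f_A`, `c_f_B`,
#'   `c_tot_A`, `c_tot_B`, `feasible` (`ratio_lower < ratio_upper`),
#'   `ratio` (the actual `g_B/g_A`) and `predicted_coexistence`.
#' @examples
#' env <- dilution_env()
#' b <- pair_coexistence_bounds(strain("A", 0.55, 0.01),
#'                              strain("B", 1.0, 4.0), env)
#' b$feasible; b$ratio_lower; b$ratio; b$ratio_upper
#' @export
pair_coexistence_bounds <- function(A, B, env) {
  stopifnot(inherits(env, "dilution_env"))
  pA <- analytic_params(A, env)
  pB <- analytic_params(B, env)
  if (pA$K > pB$K)
    stop("convention: A must be the low-K strategist (K_A <= K_B)")
  logD <- log(env$D)
  c0 <- env$c0
  c_f_A <- as.numeric(solve_final_resource(A, env))
  c_f_B <- as.numeric(solve_final_resource(B, env))
  c_tot_A <- total_material(c_f_A, env)
  c_tot_B <- total_material(c_f_B, env)
  KA <- pA$K; KB <- pB$K
  lower <- (c_tot_A + KB) * logD /
    ((c_tot_A + KA) * logD + (KA - KB) * log((c0 + KB) / (c_f_A + KB)))
  upper <- ((c_tot_B + KB) * logD -
              (KA - KB) * log((c0 + KA) / (c_f_B + KA))) /
    ((c_tot_B + KA) * logD)
  ratio <- pB$g / pA$g
  structure(list(ratio_lower = lower, ratio_upper = upper,
                 c_f_A = c_f_A, c_f_B = c_f_B,
                 c_tot_A = c_tot_A, c_tot_B = c_tot_B,
                 feasible = lower < upper, ratio = ratio,
                 predicted_coexistence = lower < ratio && ratio < upper),
            class = "pair_coexistence_bounds")
}

#' @export
print.pair_coexistence_bounds <- function(x, ...) {
  cat("Pairwise coexistence bounds on g_B/g_A:\n")
  cat(sprintf("  %.6g < g_B/g_A < %.6g  (actual ratio %.6g)\n",
              x$ratio_lower, x$ratio_upper, x$ratio))
  cat("  coexistence predicted:", x$predicted_coexistence, "\n")
  invisible(x)
}

#' Approximate width of the coexistence region
#'
#' Asymptotic width `g_B^(max) - g_B^(min)` of the band of growth rates
#' that lets a strain with affinity `K_B` coexist with a focal strain `A`,
#' in the regime `K << c0`, `c_f << c0` (long cycles, `T >> log D / g`):
#' \deqn{\Delta g_{coexist} = g_A\,\frac{(K_B-K_A)\log(K_B/K_A)}{c_0}\,
#'       \frac{D-1}{D\log D}}
#' (`variant = "generalized"`), which for `K_B - K_A << K_A` reduces to the
#' quadratic form with `(K_B-K_A)^2/K_A` in place of the log factor.  The
#' width depends only logarithmically on `D` but inversely on `c0`.
#'
#' @param A one-row single-resource strain table (the focal strain).
#' @param K_B affinity of the candidate partner (a.u.).
#' @param env a single-resource [dilution_env()].
#' @param variant `"generalized"` or `"quadratic"`.
#' @return list with `delta_g` (hr^-1) and `variant`.
#' @export
coexistence_width <- function(A, K_B, env,
                              variant = c("generalized", "quadratic")) {
  stopifnot(inherits(env, "dilution_env"))
  variant <- match.arg(variant)
  p <- analytic_params(A, env)
  envfac <- (env$D - 1) / (env$D * log(env$D)) / env$c0
  shape <- switch(variant,
                  quadratic = (K_B - p$K)^2 / p$K,
                  generalized = (K_B - p$K) * log(K_B / p$K))
  list(delta_g = p$g * envfac * shape, variant = variant)
}

#' Invasion fitness of a rare strain against a resident community
#'
#' Per-cycle log growth of an infinitesimally rare invader evaluated on the
#' resident community's steady-state resource trajectory, minus `log D`:
#' \deqn{F = \int_0^T g_{inv}\,\frac{c(t)}{c(t)+K_{inv}}\,dt - \log D.}
#' Positive means the invader increases when rare.  The residents are first
#' run to steady state; the invader is then added at a vanishing abundance
#' (1e-30 of the community) for one cycle, which leaves the resource
#' trajectory unperturbed to machine precision.
#'
#' @param invader a one-row strain table.
#' @param residents a strain table of the resident community.
#' @param env a [dilution_env()].
#' @param resident_result optionally, a precomputed `assembly_result` for
#'   the residents (saves re-running the assembly in scans).
#' @param ... passed to [run_to_steady_state()].
#' @return invasion fitness (dimensionless, per cycle).
#' @examples
#' env <- dilution_env()
#' A <- strain("A", 0.55, 0.01)
#' invasion_fitness(strain("B", 1.0, 4.0), A, env)   # > 0: B invades A
#' @export
invasion_fitness <- function(invader, residents, env,
                             resident_result = NULL, ...) {
  stopifnot(inherits(env, "dilution_env"))
  if (is.null(resident_result))
    resident_result <- run_to_steady_state(residents, env, ...)
  if (!resident_result$converged)
    warning("resident community did not converge; invasion fitness is ",
            "evaluated on its final cycle")
  keep <- residents$id %in% resident_result$survivors
  res_strains <- residents[keep, , drop = FALSE]
  inv <- invader
  inv$id <- ".invader."
  all_strains <- rbind(res_strains, inv)
  N_rare <- 1e-30 * sum(resident_result$start_N)
  start <- cycle_state(N = c(resident_result$start_N, N_rare), c = env$c0)
  ends <- integrate_cycle(all_strains, start, env)
  inv_i <- length(ends$N)
  log(ends$N[inv_i] / N_rare) - log(env$D)
}

#' Scan environments for the steady-state composition of a strain pair
#'
#' For every combination of supply concentration and dilution factor, runs
#' the pair to steady state and records the relative abundance of strain B
#' (0 = excluded, 1 = alone, interior = coexistence).
#'
#' @param A,B one-row single-resource strain tables.
#' @param c0_grid,D_grid numeric grids of environments.
#' @param env_template a [dilution_env()] providing the cycle length `T`.
#' @param max_cycles,trend_cut steady-state controls; non-converged runs are
#'   classified with the `"trend"` rule of [survivor_ids()].
#' @param ... passed to [run_to_steady_state()].
#' @return a data.frame with columns `c0`, `D`, `n_survivors`, `survivors`,
#'   `rel_abundance_B`, `converged`.  Rows are independent of evaluation
#'   order.
#' @export
scan_environment <- function(A, B, c0_grid, D_grid, env_template,
                             max_cycles = 2000, trend_cut = 1e-4, ...) {
  stopifnot(inherits(env_template, "dilution_env"))
  AB <- rbind(A, B)
  grid <- expand.grid(c0 = c0_grid, D = D_grid, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    env <- dilution_env(c0 = grid$c0[k], D = grid$D[k], T = env_template$T)
    res <- run_to_steady_state(AB, env, max_cycles = max_cycles, ...)
    ids <- survivor_ids(res, "trend", trend_cut)
    relB <- if (B$id %in% ids) {
      if (length(ids) == 1) 1 else {
        ab <- res$relative_abundance[ids]
        unname(ab[B$id] / sum(ab))
      }
    } else 0
    data.frame(c0 = grid$c0[k], D = grid$D[k], n_survivors = length(ids),
               survivors = paste(ids, collapse = "+"),
               rel_abundance_B = relB, converged = res$converged)
  })
  do.call(rbind, out)
}

#' Scan the growth parameters of an invading third strain
#'
#' Fixes a coexisting pair A, B and assembles the three-strain community for
#' every `(g_C, K_C)` on a grid, recording how many strains persist and
#' which.  The region where all three coexist is a strict subset of the
#' intersection of the two pairwise coexistence regions ("shadows"):
#' pairwise coexistence of every pair does not guarantee triple coexistence.
#'
#' @param A,B one-row single-resource strain tables (a coexisting pair).
#' @param g_C_grid,K_C_grid numeric grids for the third strain.
#' @param env a [dilution_env()].
#' @param max_cycles,trend_cut steady-state controls, as in
#'   [scan_environment()].
#' @param ... passed to [run_to_steady_state()].
#' @return a data.frame with columns `g_C`, `K_C`, `n_survivors`,
#'   `survivors`, `converged`.
#' @export
scan_invader_region <- function(A, B, g_C_grid, K_C_grid, env,
                                max_cycles = 2000, trend_cut = 1e-4, ...) {
  stopifnot(inherits(env, "dilution_env"))
  grid <- expand.grid(g_C = g_C_grid, K_C = K_C_grid, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    C <- strain("C", g_max = grid$g_C[k], K = grid$K_C[k])
    res <- run_to_steady_state(rbind(A, B, C), env,
                               max_cycles = max_cycles, ...)
    ids <- survivor_ids(res, "trend", trend_cut)
    data.frame(g_C = grid$g_C[k], K_C = grid$K_C[k],
               n_survivors = length(ids),
               survivors = paste(sort(ids), collapse = "+"),
               converged = res$converged)
  })
  do.call(rbind, out)
}

# internal: extract (g, K) of a one-row single-resource strain with yield 1,
# for the closed-form machinery (which assumes yield 1 throughout)
analytic_params <- function(s, env) {
  if (env$resource_count != 1)
    stop("the closed-form coexistence machinery is single-resource")
  m <- strain_matrices(s)
  if (m$S != 1L || m$R != 1L)
    stop("expected a one-row, single-resource strain table")
  if (abs(m$yield - 1) > 1e-12)
    stop("the coexistence analytics assume yield = 1")
  list(g = m$g[1, 1], K = m$K[1, 1])
}
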