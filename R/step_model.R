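#' Exact n-strain fixed point of the step-growth serial-dilution map
#'
#' Under the step growth law the within-cycle dynamics are piecewise
#' exponential and the steady state can be written down exactly.  Order the
#' strains by decreasing threshold, `K_1 > K_2 > ... > K_n`.  Strain `i`
#' grows at rate `g_i` until the concentration reaches its threshold at its
#' crossing time `t_i`; replacing dilution losses each cycle forces
#' `g_i t_i = log D`, so the crossing times are fixed by the growth rates
#' alone and the ordering is consistent only if `g` decreases along the
#' `K`-ordering (the high-threshold strain must finish its `D`-fold growth
#' first).  Substituting the crossing times into the resource budget at each
#' crossing gives a linear system for the start-of-cycle abundances:
#' \deqn{\sum_{i<j}(D-1)N_i + \sum_{i\ge j}(D^{g_i/g_j}-1)N_i = c_0 - K_j,
#'       \quad j = 1..n.}
#' The configuration is feasible iff all solved abundances are positive,
#' every threshold is below `c0`, the crossing order is consistent, and the
#' last crossing happens within the cycle (`log D / min(g) <= T`).
#'
#' @param strains a step-strain table ([step_strain()] rows) with distinct
#'   thresholds.
#' @param env a single-resource [dilution_env()].
#' @return an object of class `step_fixed_point`: list with `survivors`
#'   (ids ordered by decreasing `K`), `start_abundances`, `crossing_times`,
#'   `c_f` (leftover concentration, equal to the smallest threshold) and
#'   `feasible`.  Infeasible configurations are flagged, not errors.
#' @examples
#' env <- dilution_env()
#' step_fixed_point(step_strain("s", g = 1, K = 1), env)
#' @export
step_fixed_point <- function(strains, env) {
  stopifnot(inherits(env, "dilution_env"))
  if (env$resource_count != 1)
    stop("the step model supports a single resource")
  o <- order(strains$K, decreasing = TRUE)
  g <- strains$g[o]
  K <- strains$K[o]
  id <- strains$id[o]
  n <- length(g)
  t_cross <- log(env$D) / g
  infeasible <- function() structure(
    list(survivors = id, start_abundances = rep(NA_real_, n),
         crossing_times = t_cross, c_f = K[n], feasible = FALSE),
    class = "step_fixed_point")
  if (anyDuplicated(K) || any(diff(g) >= 0) || K[1] >= max(env$c0) ||
      t_cross[n] > env$T)
    return(infeasible())
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (j > 1) A[j, seq_len(j - 1)] <- env$D - 1
    i <- j:n
    A[j, i] <- env$D^(g[i] / g[j]) - 1
  }
  N <- tryCatch(solve(A, env$c0 - K), error = function(e) NULL)
  if (is.null(N) || any(N <= 0)) return(infeasible())
  structure(list(survivors = id, start_abundances = N,
                 crossing_times = t_cross, c_f = K[n], feasible = TRUE),
            class = "step_fixed_point")
}

#' @export
print.step_fixed_point <- function(x, ...) {
  cat("Step-model fixed point:",
      if (x$feasible) "feasible\n" else "infeasible\n")
  df <- data.frame(id = x$survivors, start_N = x$start_abundances,
                   crossing_time_hr = x$crossing_times)
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' Closed-form probability that n random strains all coexist (step model)
#'
#' For strains with growth rates and thresholds drawn uniformly at random
#' (thresholds across the full supply range, rates from an interval starting
#' at zero; cycles long enough that every strain can complete its growth),
#' the probability that all `n` strains admit a feasible step-model fixed
#' point is
#' \deqn{P_n = \frac{1}{n!}\left(\frac{D}{D-1} -
#'       \frac{1}{\log D}\right)^{n-1}.}
#' Since the base is below 1 for every `D > 1`, the coexistence volume
#' shrinks faster than exponentially with `n`.
#'
#' @param n number of strains, >= 1.
#' @param D dilution factor, > 1.
#' @return `P_n`, dimensionless; `P_1 = 1`.
#' @examples
#' coexistence_probability(2, 10)   # ~0.3384
#' coexistence_probability(3, 10)   # ~0.0763
#' @export
coexistence_probability <- function(n, D) {
  if (any(D <= 1)) stop("D must be > 1")
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer")
  (D / (D - 1) - 1 / log(D))^(n - 1) / factorial(n)
}

#' Monte-Carlo estimate of the n-strain coexistence probability
#'
#' Samples `n`-strain sets with `g ~ U(g_interval)` and `K ~ U(K_interval)`,
#' tests each for feasibility of the exact step-model fixed point, and
#' returns the feasible fraction with its binomial standard error.  The
#' defaults (`K` uniform over the full supply range `(0, c0)`, `g` uniform
#' from zero, unbounded cycles) are the sampling regime under which the
#' closed form [coexistence_probability()] is exact: narrowing the `K`
#' interval well below `c0` inflates the estimate towards `1/n!` because
#' the abundance-positivity constraint almost never binds there.
#'
#' @param n number of strains per draw.
#' @param D dilution factor.
#' @param g_interval,K_interval uniform sampling intervals for `g` (hr^-1)
#'   and `K` (a.u.).
#' @param samples number of Monte-Carlo draws.
#' @param seed optional integer seed (restores the RNG state on exit).
#' @param c0 supply concentration (a.u.).
#' @param T cycle duration; `Inf` (default) removes the crossing-time
#'   constraint, matching the closed form.
#' @return list with `estimate`, `se`, `samples`.
#' @examples
#' mc <- mc_coexistence_probability(2, 10, samples = 2000, seed = 1)
#' abs(mc$estimate - coexistence_probability(2, 10)) < 3 * mc$se
#' @export
mc_coexistence_probability <- function(n, D, g_interval = c(0, 1),
                                       K_interval = NULL, samples = 10000,
                                       seed = NULL, c0 = 10, T = Inf) {
  if (D <= 1) stop("D must be > 1")
  if (is.null(K_interval)) K_interval <- c(0, c0)
  if (!is.null(seed)) local_seed(seed)
  logD <- log(D)
  hits <- 0L
  for (s in seq_len(samples)) {
    g <- stats::runif(n, g_interval[1], g_interval[2])
    K <- stats::runif(n, K_interval[1], K_interval[2])
    if (step_feasible(g, K, D, logD, c0, T)) hits <- hits + 1L
  }
  p <- hits / samples
  list(estimate = p, se = sqrt(p * (1 - p) / samples), samples = samples)
}

# internal lean feasibility kernel (same construction as step_fixed_point)
step_feasible <- function(g, K, D, logD, c0, T) {
  o <- order(K, decreasing = TRUE)
  g <- g[o]
  K <- K[o]
  n <- length(g)
  if (n > 1 && any(diff(g) >= 0)) return(FALSE)
  if (K[1] >= c0) return(FALSE)
  if (logD / g[n] > T) return(FALSE)
  if (n == 1) return(TRUE)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (j > 1) A[j, seq_len(j - 1)] <- D - 1
    i <- j:n
    A[j, i] <- D^(g[i] / g[j]) - 1
  }
  N <- tryCatch(solve(A, c0 - K), error = function(e) NULL)
  !is.null(N) && all(N > 0)
}

# set the RNG seed for the calling function's scope, restoring the previous
# RNG state when the caller exits (so seeded helpers do not perturb the
# caller's random stream)
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restore <- if (is.null(old))
    quote(rm(".Random.seed", envir = globalenv()))
  else
    bquote(assign(".Random.seed", .(old), globalenv()))
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(NULL)
}
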