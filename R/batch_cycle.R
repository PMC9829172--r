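#' Boom-and-bust environment parameters
#'
#' The serial-dilution protocol: every cycle starts with each resource at its
#' supply concentration `c0`, the community grows in batch for `T` hours, and
#' is then diluted by a factor `D` into fresh medium.
#'
#' @param c0 supplied concentration per resource, a.u. (componentwise > 0).
#'   Length sets the number of resources.
#' @param D dilution factor, > 1.
#' @param T cycle duration in hours, > 0.
#' @return an object of class `dilution_env`.
#' @examples
#' dilution_env()            # the standard protocol: c0 = 10, D = 10, T = 24
#' dilution_env(c0 = c(10, 10))  # two supplied resources
#' @export
dilution_env <- function(c0 = 10, D = 10, T = 24) {
  if (any(c0 <= 0)) stop("c0 must be > 0 for every resource")
  if (length(D) != 1 || D <= 1) stop("D must be a scalar > 1")
  if (length(T) != 1 || T <= 0) stop("T must be a scalar > 0")
  structure(list(c0 = as.numeric(c0), D = as.numeric(D), T = as.numeric(T),
                 resource_count = length(c0)),
            class = "dilution_env")
}

#' @export
print.dilution_env <- function(x, ...) {
  cat("Serial-dilution environment: c0 =", paste(x$c0, collapse = ", "),
      "a.u.; D =", x$D, "; T =", x$T, "hr;", x$resource_count,
      "resource(s)\n")
  invisible(x)
}

#' Instantaneous state within a growth cycle
#'
#' @param N abundance per strain, a.u. (componentwise >= 0).
#' @param c concentration per resource, a.u. (componentwise >= 0).
#' @param t time since the start of the cycle, hours.
#' @return an object of class `cycle_state`.
#' @export
cycle_state <- function(N, c, t = 0) {
  if (any(N < 0)) stop("abundances must be >= 0")
  if (any(c < 0)) stop("concentrations must be >= 0")
  structure(list(N = as.numeric(N), c = as.numeric(c), t = as.numeric(t)),
            class = "cycle_state")
}

#' @export
print.cycle_state <- function(x, ...) {
  cat("Cycle state at t =", format(x$t), "hr\n  N:",
      paste(signif(x$N, 6), collapse = ", "), "\n  c:",
      paste(signif(x$c, 6), collapse = ", "), "\n")
  invisible(x)
}

# internal floor for log concentrations (exp(-745) underflows to ~5e-324)
LOG_FLOOR <- -745

#' Integrate one batch growth cycle under Monod kinetics
#'
#' Solves the within-cycle consumer-resource dynamics from inoculation to
#' `t = T`: each strain grows at its (possibly multi-resource, co-utilized)
#' Monod rate, and each Monod term drains its own resource at the same rate
#' divided by the strain's yield, so that for yield 1 total biomass plus
#' total resource is conserved.
#'
#' The solver is an adaptive Dormand-Prince RK45 working on
#' `(log N, log c)`.  In log coordinates the depletion phase, where `c`
#' drops far below every `K`, is not stiff (log c decays linearly), and the
#' leftover concentration retains full relative precision however close to
#' zero it gets.  Tolerances default to rtol 1e-10 / atol 1e-12 because
#' coexistence margins can be a ~1e-3 fraction of the growth rates and
#' competitive outcomes are sensitive to integration error.
#'
#' @param strains a strain table ([strain()]); one row per strain.
#' @param start a [cycle_state()] with `t = 0`; abundances of length
#'   `nrow(strains)` and concentrations matching the environment.
#' @param env a [dilution_env()].
#' @param rtol,atol relative and absolute integration tolerances (applied in
#'   log coordinates).
#' @return a [cycle_state()] at `t = T`.
#' @examples
#' env <- dilution_env()
#' AB <- strain_table(strain("A", 0.55, 0.01), strain("B", 1.0, 4.0))
#' integrate_cycle(AB, cycle_state(N = c(1, 1), c = 10), env)
#' @export
integrate_cycle <- function(strains, start, env, rtol = 1e-10,
                            atol = 1e-12) {
  stopifnot(inherits(start, "cycle_state"), inherits(env, "dilution_env"))
  validate_strains(strains, env$resource_count)
  m <- strain_matrices(strains)
  if (length(start$N) != m$S)
    stop("start state has ", length(start$N), " abundances for ", m$S,
         " strains")
  if (length(start$c) != env$resource_count)
    stop("start state has ", length(start$c), " concentrations for ",
         env$resource_count, " resources")
  if (start$t != 0) stop("start state must be at t = 0")
  live <- start$N > 0
  N_end <- start$N
  logc <- pmax(log(start$c), LOG_FLOOR)
  if (any(live)) {
    res <- .cycle_cpp(log(start$N[live]), logc,
                      m$g[live, , drop = FALSE], m$K[live, , drop = FALSE],
                      m$x[live, , drop = FALSE], m$yield[live],
                      env$T, rtol, atol)
    N_end[live] <- exp(res$logN)
    logc <- res$logc
  }
  cycle_state(N = N_end, c = exp(logc), t = env$T)
}

#' Integrate one batch cycle under the step growth law, exactly
#'
#' Event-driven exact solution for the single-resource step model: while the
#' concentration exceeds a strain's threshold the strain grows exponentially
#' at its rate `g`; the concentration follows from conservation
#' (`c = c_tot - sum(N)`, yield 1); and each time `c` reaches the largest
#' remaining threshold, that strain is frozen.  Crossing times are found by
#' root-solving a sum of exponentials, largest threshold first; strains with
#' exactly equal thresholds are frozen together.
#'
#' @param strains a step-strain table ([step_strain()] rows).
#' @param start a [cycle_state()] with `t = 0` and a single resource.
#' @param env a single-resource [dilution_env()].
#' @return a [cycle_state()] at `t = T`.
#' @examples
#' env <- dilution_env()
#' s <- step_strain("s", g = 1, K = 1)
#' integrate_cycle_step(s, cycle_state(N = 1, c = 10), env)  # N = 10, c = 1
#' @export
integrate_cycle_step <- function(strains, start, env) {
  stopifnot(inherits(start, "cycle_state"), inherits(env, "dilution_env"))
  if (env$resource_count != 1 || length(start$c) != 1)
    stop("the step model supports a single resource")
  if (start$t != 0) stop("start state must be at t = 0")
  g <- strains$g
  K <- strains$K
  N <- start$N
  if (length(N) != length(g))
    stop("start state has ", length(N), " abundances for ", length(g),
         " strains")
  c_now <- start$c
  ctot <- sum(N) + c_now
  t_now <- 0
  active <- which(K < c_now & N > 0)
  while (length(active) > 0 && t_now < env$T) {
    frozen_mass <- sum(N[-active])
    Kmax <- max(K[active])
    Na <- N[active]
    ga <- g[active]
    conc <- function(dt) ctot - frozen_mass - sum(Na * exp(ga * dt))
    dt_left <- env$T - t_now
    if (conc(dt_left) > Kmax) {
      # no further crossing before the cycle ends
      N[active] <- Na * exp(ga * dt_left)
      c_now <- conc(dt_left)
      t_now <- env$T
      break
    }
    root <- stats::uniroot(function(dt) conc(dt) - Kmax,
                           lower = 0, upper = dt_left,
                           tol = .Machine$double.eps^0.9, maxiter = 2000)
    dt <- root$root
    N[active] <- Na * exp(ga * dt)
    t_now <- t_now + dt
    c_now <- Kmax
    active <- active[K[active] < Kmax]
  }
  cycle_state(N = N, c = max(c_now, 0), t = env$T)
}
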