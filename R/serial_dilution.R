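#' Dilute an end-of-cycle state into fresh medium
#'
#' Abundances are divided by the dilution factor `D`; every resource is
#' reset to exactly its supply concentration `c0`; leftover resource is
#' discarded, not carried over.  The discard convention is what makes the
#' steady-state budget `c_tot = (D c0 - c_f)/(D - 1)` hold: carrying
#' leftovers over would give a total material concentration independent of
#' the leftover `c_f`.
#'
#' @param end_state a [cycle_state()] at the end of a growth cycle.
#' @param env a [dilution_env()].
#' @return a [cycle_state()] at `t = 0`, the start of the next cycle.
#' @examples
#' dilute(cycle_state(N = 10, c = 1, t = 24), dilution_env())
#' @export
dilute <- function(end_state, env) {
  stopifnot(inherits(end_state, "cycle_state"), inherits(env, "dilution_env"))
  if (length(end_state$c) != env$resource_count)
    stop("state and environment disagree on the number of resources")
  cycle_state(N = end_state$N / env$D, c = env$c0, t = 0)
}

#' Run growth-dilution cycles to steady state
#'
#' Iterates [integrate_cycle()] and [dilute()] from equal (or given) initial
#' abundances until the community displays reproducible cycle dynamics: the
#' start-of-cycle abundance vector of the remaining strains changes by less
#' than `tol` in maximum absolute log difference between consecutive cycles.
#' A strain whose start-of-cycle abundance falls below `extinction` times
#' the total is declared extinct and removed permanently (the continuous
#' dynamics never reach zero, so a cutoff is mandatory; the default 1e-9 is
#' far below any reported relative abundance).
#'
#' At a converged steady state every survivor's within-cycle fold change
#' equals `D`, so the community exactly replaces its dilution losses.
#'
#' @param strains a strain table.
#' @param env a [dilution_env()].
#' @param initial_N starting abundance per strain (scalar recycled; default
#'   1 a.u. for every strain).
#' @param max_cycles cycle budget; if reached without convergence the result
#'   is returned with `converged = FALSE` rather than an error.
#' @param tol convergence tolerance on max |delta log N| between consecutive
#'   cycle starts.
#' @param extinction relative extinction threshold.
#' @param rtol,atol integration tolerances, see [integrate_cycle()].
#' @return an object of class `assembly_result`: a list with elements
#'   `survivors` (ids), `relative_abundance` (named, summing to 1 over
#'   survivors, measured at cycle start), `cycles_run`, `converged`,
#'   `final_state` (end-of-cycle [cycle_state()] of the survivors),
#'   `per_cycle_fold_change` (named; ~`D` at convergence), `delta_log`
#'   (named last inter-cycle change in log abundance, NA right after an
#'   extinction), and the `strains`/`env`/settings used.
#' @examples
#' env <- dilution_env()
#' AB <- strain_table(strain("A", 0.55, 0.01), strain("B", 1.0, 4.0))
#' res <- run_to_steady_state(AB, env)
#' res$survivors                  # both strains coexist
#' @export
run_to_steady_state <- function(strains, env, initial_N = 1,
                                max_cycles = 1000, tol = 1e-6,
                                extinction = 1e-9, rtol = 1e-10,
                                atol = 1e-12) {
  stopifnot(inherits(env, "dilution_env"))
  validate_strains(strains, env$resource_count)
  m <- strain_matrices(strains)
  N0 <- rep_len(as.numeric(initial_N), m$S)
  if (any(N0 <= 0)) stop("initial abundances must be > 0")
  res <- .assemble_cpp(log(N0), m$g, m$K, m$x, m$yield, env$c0, env$D,
                       env$T, as.integer(max_cycles), tol, extinction,
                       rtol, atol)
  ids <- m$id[res$alive]
  N_start <- exp(res$start_logN)
  rel <- if (length(N_start)) N_start / sum(N_start) else numeric(0)
  names(rel) <- ids
  fold <- exp(res$log_fold)
  names(fold) <- ids
  delta <- res$delta_log
  names(delta) <- ids
  structure(list(
    survivors = ids,
    relative_abundance = rel,
    cycles_run = res$cycles,
    converged = res$converged,
    final_state = cycle_state(N = exp(res$end_logN), c = exp(res$end_logc),
                              t = env$T),
    start_N = N_start,
    per_cycle_fold_change = fold,
    delta_log = delta,
    species = m$species[res$alive],
    strains = strains,
    env = env,
    settings = list(initial_N = initial_N, max_cycles = max_cycles,
                    tol = tol, extinction = extinction, rtol = rtol,
                    atol = atol)
  ), class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Serial-dilution assembly:", length(x$survivors), "survivor(s) after",
      x$cycles_run, "cycles",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  if (length(x$survivors)) {
    df <- data.frame(id = x$survivors, species = x$species,
                     relative_abundance = signif(x$relative_abundance, 5),
                     fold_change = signif(x$per_cycle_fold_change, 6))
    rownames(df) <- NULL
    print(df)
  }
  invisible(x)
}

#' Count surviving strains of an assembly
#'
#' @param result an `assembly_result` from [run_to_steady_state()].
#' @param by_species if `TRUE`, return a per-species count table instead of
#'   a single integer.
#' @return integer count of strains above the extinction threshold, or a
#'   named per-species count vector.
#' @export
count_survivors <- function(result, by_species = FALSE) {
  stopifnot(inherits(result, "assembly_result"))
  if (by_species) {
    tab <- table(factor(result$species,
                        levels = sort(unique(result$strains$species))))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
  } else {
    length(result$survivors)
  }
}

#' Survivor ids, optionally discounting strains still in steady decline
#'
#' For a converged assembly the survivors are simply the strains above the
#' extinction threshold.  When the cycle budget runs out first, strains that
#' are being excluded slowly (a steady per-cycle loss of log abundance that
#' has not yet reached the extinction cutoff) are still above threshold; the
#' `"trend"` rule classifies a strain as a survivor only if its last
#' inter-cycle change in log abundance exceeds `-trend_cut`, which separates
#' persisting strains (change -> 0) from slowly dying ones (change -> a
#' negative constant equal to their invasion-fitness deficit).
#'
#' @param result an `assembly_result`.
#' @param rule `"threshold"` (all strains above the extinction cutoff) or
#'   `"trend"`.
#' @param trend_cut per-cycle log-abundance loss beyond which a strain is
#'   considered on its way out (default 1e-4).
#' @return character vector of survivor ids.
#' @export
survivor_ids <- function(result, rule = c("threshold", "trend"),
                         trend_cut = 1e-4) {
  stopifnot(inherits(result, "assembly_result"))
  rule <- match.arg(rule)
  if (rule == "threshold" || result$converged) return(result$survivors)
  keep <- is.na(result$delta_log) | result$delta_log > -trend_cut
  result$survivors[keep]
}
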