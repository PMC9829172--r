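#' Specify the sampling distributions of a random strain pool
#'
#' A pool is a set of species, each contributing `n` mutant strains whose
#' growth parameters are drawn independently: maximal growth rates from a
#' normal distribution (a single `g` per strain, shared across resources),
#' substrate affinities per resource from log-normal distributions, and --
#' optionally -- the co-utilization weight on resource 1 from a normal
#' distribution truncated to `[0, 1]` (weight on resource 2 is the
#' complement).  `species_spec()` describes one species;  `pool_spec()`
#' bundles them.
#'
#' The shipped defaults are the two study designs:
#' `single_species_pool()` gives 100 strains on one resource with
#' `g ~ N(1.0, 0.03^2)` hr^-1 and `K ~ logNormal(log 4, 0.5^2)` a.u.;
#' `two_species_pool()` gives 50 + 50 strains of two species on two
#' co-utilized resources, species I with `g ~ N(1.0, 0.03^2)`,
#' `K1 ~ logNormal(log 4, 0.3^2)`, `K2 ~ logNormal(log 5, 0.3^2)` and
#' fixed weight `x = 0.2` on resource 1, species II with
#' `g ~ N(0.55, 0.03^2)`, `K1 ~ logNormal(log 0.05, 0.3^2)`,
#' `K2 ~ logNormal(log 0.03, 0.3^2)` and `x = 0.7`.
#'
#' @param n_strains strains contributed by the species.
#' @param g_mean,g_sd normal parameters for the maximal growth rate
#'   (hr^-1); non-positive draws (vanishingly rare at the defaults) are
#'   rejected and resampled.
#' @param K_meanlog,K_sdlog per-resource log-normal parameters for the
#'   affinities (a.u.); vectors of length `resource_count` (`K_sdlog` is
#'   recycled).
#' @param x mean co-utilization weight on resource 1 (ignored with one
#'   resource).
#' @param x_sd standard deviation of the weight; 0 (default) fixes it at
#'   `x`, positive values draw per-strain weights from a normal truncated
#'   to `[0, 1]`.
#' @param species species label.
#' @return `species_spec()`: a list; `pool_spec()`: an object of class
#'   `pool_spec`.
#' @examples
#' generate_pool(single_species_pool(), seed = 1)[1:3, ]
#' @export
species_spec <- function(n_strains, g_mean, g_sd, K_meanlog, K_sdlog, x = 1,
                         x_sd = 0, species = "I") {
  stopifnot(n_strains >= 1, g_sd >= 0, all(K_sdlog >= 0), x_sd >= 0,
            x >= 0, x <= 1)
  list(n_strains = as.integer(n_strains), g_mean = g_mean, g_sd = g_sd,
       K_meanlog = K_meanlog, K_sdlog = K_sdlog, x = x, x_sd = x_sd,
       species = species)
}

#' @rdname species_spec
#' @param ... `species_spec()` entries.
#' @param resource_count number of supplied resources (1 or 2 in the
#'   shipped designs; the machinery is general).
#' @param seed default seed used by [generate_pool()].
#' @export
pool_spec <- function(..., resource_count = 1, seed = NULL) {
  species <- list(...)
  for (sp in species) {
    if (length(sp$K_meanlog) != resource_count)
      stop("K_meanlog must have one entry per resource")
  }
  structure(list(species = species, resource_count = resource_count,
                 seed = seed),
            class = "pool_spec")
}

#' @rdname species_spec
#' @export
single_species_pool <- function(n = 100, g_mean = 1.0, g_sd = 0.03,
                                K_meanlog = log(4), K_sdlog = 0.5) {
  pool_spec(species_spec(n, g_mean, g_sd, K_meanlog, K_sdlog,
                         species = "II"),
            resource_count = 1)
}

#' @rdname species_spec
#' @param fix_growth if `TRUE`, suppress all variation in the Monod
#'   parameters (every strain gets its species' mean `g` and median `K`),
#'   isolating the effect of variable resource allocation; combine with
#'   `x_sd > 0`.
#' @export
two_species_pool <- function(n = 50, x_sd = 0, fix_growth = FALSE) {
  g_sd <- if (fix_growth) 0 else 0.03
  K_sdlog <- if (fix_growth) 0 else 0.3
  pool_spec(
    species_spec(n, g_mean = 1.0, g_sd = g_sd,
                 K_meanlog = log(c(4, 5)), K_sdlog = K_sdlog,
                 x = 0.2, x_sd = x_sd, species = "I"),
    species_spec(n, g_mean = 0.55, g_sd = g_sd,
                 K_meanlog = log(c(0.05, 0.03)), K_sdlog = K_sdlog,
                 x = 0.7, x_sd = x_sd, species = "II"),
    resource_count = 2
  )
}

#' Draw a random strain pool
#'
#' Deterministic given the seed: the same seed always yields the identical
#' pool, and the caller's RNG state is left untouched.
#'
#' @param spec a [pool_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a validated strain table with one row per strain.
#' @export
generate_pool <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "pool_spec"))
  if (!is.null(seed)) local_seed(seed)
  R <- spec$resource_count
  pools <- lapply(spec$species, function(sp) {
    g <- stats::rnorm(sp$n_strains, sp$g_mean, sp$g_sd)
    bad <- which(g <= 0)
    while (length(bad)) {
      g[bad] <- stats::rnorm(length(bad), sp$g_mean, sp$g_sd)
      bad <- bad[g[bad] <= 0]
    }
    K <- sapply(seq_len(R), function(r)
      stats::rlnorm(sp$n_strains, sp$K_meanlog[r], rep_len(sp$K_sdlog, R)[r]))
    K <- matrix(K, nrow = sp$n_strains)
    if (R == 1) {
      x <- matrix(1, sp$n_strains, 1)
    } else if (R == 2) {
      x1 <- if (sp$x_sd > 0) {
        v <- stats::rnorm(sp$n_strains, sp$x, sp$x_sd)
        bad <- which(v < 0 | v > 1)
        while (length(bad)) {
          v[bad] <- stats::rnorm(length(bad), sp$x, sp$x_sd)
          bad <- bad[v[bad] < 0 | v[bad] > 1]
        }
        v
      } else rep(sp$x, sp$n_strains)
      x <- cbind(x1, 1 - x1)
    } else {
      stop("shipped pool generation covers 1 or 2 resources")
    }
    out <- data.frame(id = paste0(sp$species, "_", seq_len(sp$n_strains)),
                      species = sp$species, yield = 1,
                      stringsAsFactors = FALSE)
    for (r in seq_len(R)) {
      out[[paste0("g_max_", r)]] <- g
      out[[paste0("K_", r)]] <- K[, r]
      out[[paste0("x_", r)]] <- x[, r]
    }
    out
  })
  validate_strains(do.call(rbind, pools))
}

#' Assemble an ensemble of independent random pools
#'
#' Generates `n_pools` independent pools (pool `i` uses seed
#' `base_seed + i - 1`), assembles each by serial dilution with every strain
#' inoculated at 1 a.u., and summarises the survivor-count statistics.
#'
#' Survivors are counted with the `"trend"` rule of [survivor_ids()]: in a
#' pool that has not fully converged within the cycle budget, a strain that
#' is still above the extinction threshold but declining steadily (by more
#' than `trend_cut` in log abundance per cycle) is classified as on its way
#' to exclusion rather than as a survivor.  This removes the bias that
#' plain exclusion of non-converged pools would introduce: the pools that
#' converge slowly are precisely those resolving a close competition, so
#' dropping them would distort the survivor-count histogram.  Pools still
#' non-converged at the budget are reported via `n_converged` and flagged
#' per record.
#'
#' @param spec a [pool_spec()].
#' @param env a [dilution_env()] whose resource count matches the spec.
#' @param n_pools number of independent pools.
#' @param base_seed seed of the first pool.
#' @param max_cycles cycle budget per pool.  The default is deliberately
#'   large: the expensive early cycles (many strains) are over quickly,
#'   while the long tail of cycles needed to resolve a close competitive
#'   exclusion involves only the last few contenders and is cheap, so a
#'   generous budget resolves most close calls outright.
#' @param trend_cut per-cycle log-abundance decline separating a slowly
#'   excluded strain from a persisting one, see [survivor_ids()].
#' @param tol,extinction,rtol,atol passed to [run_to_steady_state()].
#' @param progress print a line every `progress` pools (0 = silent).
#' @return an object of class `ensemble_summary`: list with `n_pools`,
#'   `n_converged`, `survivor_count_histogram` (fractions over all pools),
#'   `species_histograms` (per-species marginal fractions),
#'   `joint_species_histogram` (two-species designs: fraction per
#'   (count_I, count_II) pair), and `records`, a per-pool data.frame with
#'   seed, counts, survivor ids and relative abundances.
#' @examples
#' \donttest{
#' env <- dilution_env()
#' ens <- run_ensemble(single_species_pool(), env, n_pools = 10,
#'                     base_seed = 1)
#' ens$survivor_count_histogram
#' }
#' @export
run_ensemble <- function(spec, env, n_pools, base_seed = 1,
                         max_cycles = 20000, trend_cut = 1e-4, tol = 1e-6,
                         extinction = 1e-9, rtol = 1e-10, atol = 1e-12,
                         progress = 0) {
  stopifnot(inherits(spec, "pool_spec"), inherits(env, "dilution_env"),
            n_pools >= 1)
  if (spec$resource_count != env$resource_count)
    stop("pool spec and environment disagree on the number of resources")
  species_levels <- vapply(spec$species, `[[`, "", "species")
  records <- vector("list", n_pools)
  for (i in seq_len(n_pools)) {
    seed_i <- base_seed + i - 1
    pool <- generate_pool(spec, seed = seed_i)
    res <- run_to_steady_state(pool, env, max_cycles = max_cycles,
                               tol = tol, extinction = extinction,
                               rtol = rtol, atol = atol)
    ids <- survivor_ids(res, "trend", trend_cut)
    keep <- res$survivors %in% ids
    counts <- table(factor(res$species[keep], levels = species_levels))
    rel <- res$relative_abundance[keep]
    rec <- data.frame(pool = i, seed = seed_i,
                      n_survivors = length(ids),
                      converged = res$converged,
                      cycles = res$cycles_run,
                      survivors = paste(ids, collapse = "+"),
                      relative_abundance = paste(
                        signif(rel / sum(rel), 6), collapse = "+"),
                      stringsAsFactors = FALSE)
    for (sp in species_levels)
      rec[[paste0("n_", sp)]] <- as.integer(counts[[sp]])
    records[[i]] <- rec
    if (progress > 0 && i %% progress == 0)
      message("pool ", i, "/", n_pools, ": ", rec$n_survivors,
              " survivor(s) in ", rec$cycles, " cycles")
  }
  records <- do.call(rbind, records)
  n_bad <- sum(!records$converged)
  if (n_bad > 0)
    message(n_bad, " of ", n_pools, " pools had not fully converged after ",
            max_cycles, " cycles; their survivors are classified by the ",
            "declining-trend rule")
  hist_of <- function(v) {
    tab <- table(v)
    fr <- as.numeric(tab) / length(v)
    names(fr) <- names(tab)
    fr
  }
  joint <- NULL
  species_hists <- NULL
  if (length(species_levels) > 1) {
    cols <- paste0("n_", species_levels)
    joint <- hist_of(do.call(paste, c(records[cols], sep = ",")))
    species_hists <- lapply(cols, function(cl) hist_of(records[[cl]]))
    names(species_hists) <- species_levels
  }
  structure(list(
    n_pools = n_pools, n_converged = sum(records$converged),
    survivor_count_histogram = hist_of(records$n_survivors),
    species_histograms = species_hists,
    joint_species_histogram = joint,
    records = records,
    spec = spec, env = env, base_seed = base_seed,
    settings = list(max_cycles = max_cycles, trend_cut = trend_cut,
                    tol = tol, extinction = extinction)
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Strain-pool ensemble:", x$n_converged, "converged of", x$n_pools,
      "pools\n")
  cat("Survivor-count fractions:\n")
  print(round(x$survivor_count_histogram, 4))
  if (!is.null(x$joint_species_histogram)) {
    cat("Joint (", paste(names(x$species_histograms), collapse = ", "),
        ") survivor-count fractions:\n", sep = "")
    print(round(x$joint_species_histogram, 4))
  }
  invisible(x)
}

#' Pareto frontier of a strain pool
#'
#' Strains not dominated in the (higher `g`, lower `K`) sense on the chosen
#' resource: no other strain is at least as good in both coordinates and
#' strictly better in one.  Assembly survivors concentrate on (or adjacent
#' to) this front.
#'
#' @param strains a strain table.
#' @param resource which resource's `(g, K)` plane to use.
#' @return character vector of frontier strain ids.
#' @export
pareto_front <- function(strains, resource = 1) {
  m <- strain_matrices(strains)
  g <- m$g[, resource]
  K <- m$K[, resource]
  n <- length(g)
  dominated <- vapply(seq_len(n), function(i)
    any(g >= g[i] & K <= K[i] & (g > g[i] | K < K[i])), logical(1))
  m$id[!dominated]
}
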