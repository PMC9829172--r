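#' Load and validate a run configuration
#'
#' Configurations are YAML with up to four blocks: `environment` (`c0`,
#' `D`, `T`, all defaulting to the standard protocol values 10, 10 and
#' 24 hr), exactly one of `strains` (inline strain rows or a `csv` path) or
#' `pool` (mirroring [pool_spec()]), an optional `run` block (`max_cycles`,
#' `tol`, `extinction`, `seed`, `n_pools`) and an optional `output` block
#' (paths).  Schema violations raise an error naming the offending field.
#'
#' @param path YAML file path.
#' @return an object of class `run_config` with `environment` expanded to a
#'   [dilution_env()], `strains` (a strain table) or `pool` (a
#'   [pool_spec()]), and `run`/`output` lists with defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("environment", "strains", "pool", "run", "output")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config block: ", paste(bad, collapse = ", "))
  has_strains <- !is.null(raw$strains)
  has_pool <- !is.null(raw$pool)
  if (has_strains == has_pool)
    stop("config must contain exactly one of the blocks 'strains' / 'pool'")
  eb <- raw$environment
  if (!is.null(eb)) {
    bad <- setdiff(names(eb), c("c0", "D", "T"))
    if (length(bad))
      stop("unknown field in environment block: ",
           paste(bad, collapse = ", "))
  }
  resource_count <- if (has_pool && !is.null(raw$pool$resource_count))
    raw$pool$resource_count else length(eb$c0 %||% 10)
  c0 <- eb$c0 %||% rep(10, resource_count)
  env <- dilution_env(c0 = c0, D = eb$D %||% 10, T = eb$T %||% 24)
  strains <- NULL
  pool <- NULL
  if (has_strains) {
    sb <- raw$strains
    strains <- if (is.character(sb$csv %||% NULL)) {
      p <- sb$csv
      if (!file.exists(p)) stop("strains.csv path not resolvable: ", p)
      read_strain_table(p)
    } else {
      do.call(strain_table, lapply(sb, function(row) do.call(strain, row)))
    }
    validate_strains(strains, env$resource_count)
  } else {
    pb <- raw$pool
    bad <- setdiff(names(pb), c("species", "resource_count", "seed"))
    if (length(bad))
      stop("unknown field in pool block: ", paste(bad, collapse = ", "))
    if (is.null(pb$species)) stop("pool block requires a species list")
    specs <- lapply(pb$species, function(sp) do.call(species_spec, sp))
    pool <- do.call(pool_spec,
                    c(specs, list(resource_count = env$resource_count,
                                  seed = pb$seed %||% NULL)))
  }
  run_defaults <- list(max_cycles = 1000, tol = 1e-6, extinction = 1e-9,
                       seed = 1, n_pools = 1)
  rb <- raw$run %||% list()
  bad <- setdiff(names(rb), names(run_defaults))
  if (length(bad))
    stop("unknown field in run block: ", paste(bad, collapse = ", "))
  run <- utils::modifyList(run_defaults, rb)
  structure(list(environment = env, strains = strains, pool = pool,
                 run = run, output = raw$output %||% list(),
                 source = normalizePath(path)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration back to YAML
#'
#' Writes the effective configuration (defaults filled in) so that any run
#' is reproducible from its config echo plus seed alone; `load_config()` of
#' the written file gives back an equivalent `run_config`.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  env <- config$environment
  out <- list(environment = list(c0 = env$c0, D = env$D, T = env$T))
  if (!is.null(config$strains)) {
    rows <- lapply(seq_len(nrow(config$strains)), function(i) {
      m <- strain_matrices(config$strains[i, , drop = FALSE])
      list(id = m$id, species = m$species, yield = m$yield,
           g_max = as.numeric(m$g), K = as.numeric(m$K),
           x = as.numeric(m$x))
    })
    names(rows) <- NULL
    out$strains <- rows
  } else {
    out$pool <- list(
      species = lapply(config$pool$species, function(sp)
        sp[c("n_strains", "g_mean", "g_sd", "K_meanlog", "K_sdlog", "x", "x_sd",
             "species")]),
      resource_count = config$pool$resource_count)
    if (!is.null(config$pool$seed)) out$pool$seed <- config$pool$seed
  }
  out$run <- config$run
  if (length(config$output)) out$output <- config$output
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write analysis results to disk
#'
#' Single runs are written as JSON, grids and ensembles as CSV (with a JSON
#' summary for ensembles).  Every output embeds the seed(s), the tool
#' version and enough of the configuration to reproduce the run; numbers
#' are serialized at full precision and field order is deterministic.
#'
#' @param x an `assembly_result`, `ensemble_summary`, or a grid
#'   `data.frame` from the scan functions.
#' @param path output path (`.json` for single runs, `.csv` for grids; an
#'   ensemble written to `foo.json` also writes its per-pool table to
#'   `foo_pools.csv`).
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

result_header <- function() {
  list(tool = "boombust",
       version = as.character(utils::packageVersion("boombust")))
}

#' @export
write_results.assembly_result <- function(x, path, ...) {
  env <- x$env
  out <- c(result_header(), list(
    environment = list(c0 = env$c0, D = env$D, T = env$T),
    settings = x$settings,
    survivors = as.list(x$survivors),
    relative_abundance = as.list(x$relative_abundance),
    per_cycle_fold_change = as.list(x$per_cycle_fold_change),
    cycles_run = x$cycles_run,
    converged = x$converged
  ))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_results.ensemble_summary <- function(x, path, ...) {
  env <- x$env
  out <- c(result_header(), list(
    environment = list(c0 = env$c0, D = env$D, T = env$T),
    base_seed = x$base_seed,
    n_pools = x$n_pools,
    n_converged = x$n_converged,
    survivor_count_histogram = as.list(x$survivor_count_histogram),
    joint_species_histogram = as.list(x$joint_species_histogram)
  ))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  pools_csv <- sub("\\.json$", "_pools.csv", path)
  write_grid_csv(x$records, pools_csv)
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, ...) {
  write_grid_csv(x, path)
  invisible(path)
}

# full-precision CSV so that a reload reproduces the in-memory grid exactly
write_grid_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) {
    ifelse(v == round(v) & abs(v) < 2^31, format(v, scientific = FALSE),
           formatC(v, digits = 17, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a grid CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return a data.frame with numeric columns restored.
#' @export
read_grid_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
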