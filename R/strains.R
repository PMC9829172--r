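#' Construct a strain parameter table
#'
#' A strain is described by its Monod growth parameters on each supplied
#' resource: a maximal growth rate `g_max` (hr^-1), a half-saturation
#' (substrate affinity) constant `K` (concentration, a.u.), and, when several
#' substitutable resources are co-utilized, a set of co-utilization weights
#' `x` that sum to 1 across resources.  The biomass yield per unit resource
#' defaults to 1, which makes abundance and concentration commensurable.
#'
#' @param id strain label (character scalar).
#' @param g_max maximal growth rate per resource, hr^-1.  A scalar is
#'   recycled across resources.
#' @param K half-saturation concentration per resource, a.u.
#' @param x co-utilization weights per resource; must be non-negative and sum
#'   to 1.  Defaults to equal weights.
#' @param yield biomass produced per unit resource consumed (default 1).
#' @param species species label, used to group strains in multi-species
#'   pools.
#' @return A one-row `data.frame` with columns `id`, `species`, `yield` and
#'   per-resource columns `g_max_r`, `K_r`, `x_r`.  Combine strains with
#'   [rbind()] or [strain_table()].
#' @seealso [monod_rate()], [multi_resource_rate()], [read_strain_table()]
#' @examples
#' A <- strain("A", g_max = 0.55, K = 0.01)
#' B <- strain("B", g_max = 1.0, K = 4.0)
#' strain_table(A, B)
#' @export
strain <- function(id, g_max, K, x = NULL, yield = 1, species = "I") {
  R <- max(length(g_max), length(K), length(x))
  g_max <- rep_len(as.numeric(g_max), R)
  K <- rep_len(as.numeric(K), R)
  if (is.null(x)) x <- rep(1 / R, R)
  x <- rep_len(as.numeric(x), R)
  out <- data.frame(id = as.character(id), species = as.character(species),
                    yield = as.numeric(yield), stringsAsFactors = FALSE)
  for (r in seq_len(R)) {
    out[[paste0("g_max_", r)]] <- g_max[r]
    out[[paste0("K_", r)]] <- K[r]
    out[[paste0("x_", r)]] <- x[r]
  }
  validate_strains(out)
  out
}

#' @rdname strain
#' @param ... strain rows created by [strain()], or data frames of them.
#' @export
strain_table <- function(...) {
  out <- do.call(rbind, list(...))
  validate_strains(out)
  out
}

#' Validate a strain table
#'
#' Checks the invariants every strain table must satisfy: positive `g_max`,
#' `K` and `yield`, non-negative co-utilization weights summing to 1 per
#' strain, consistent per-resource column sets and unique ids.
#'
#' @param strains a strain `data.frame` as built by [strain()].
#' @param n_resources if given, additionally require this many resources.
#' @return the table, invisibly, on success; otherwise an error.
#' @export
validate_strains <- function(strains, n_resources = NULL) {
  stopifnot(is.data.frame(strains))
  need <- c("id", "species", "yield")
  if (!all(need %in% names(strains)))
    stop("strain table must have columns: ", paste(need, collapse = ", "))
  R <- n_strain_resources(strains)
  cols <- as.vector(outer(c("g_max_", "K_", "x_"), seq_len(R), paste0))
  if (!all(cols %in% names(strains)))
    stop("strain table is missing per-resource columns: ",
         paste(setdiff(cols, names(strains)), collapse = ", "))
  if (!is.null(n_resources) && R != n_resources)
    stop("strain table has ", R, " resources, expected ", n_resources)
  m <- strain_matrices(strains)
  if (any(m$g <= 0)) stop("all g_max must be > 0")
  if (any(m$K <= 0)) stop("all K must be > 0")
  if (any(m$x < 0)) stop("co-utilization weights must be >= 0")
  if (any(abs(rowSums(m$x) - 1) > 1e-8))
    stop("co-utilization weights must sum to 1 for every strain")
  if (any(m$yield <= 0)) stop("yield must be > 0")
  if (anyDuplicated(strains$id)) stop("strain ids must be unique")
  invisible(strains)
}

n_strain_resources <- function(strains) {
  sum(grepl("^g_max_[0-9]+$", names(strains)))
}

# internal: strain table -> parameter matrices (S x R)
strain_matrices <- function(strains) {
  R <- n_strain_resources(strains)
  S <- nrow(strains)
  pick <- function(prefix)
    matrix(unlist(strains[paste0(prefix, seq_len(R))]), nrow = S)
  list(g = pick("g_max_"), K = pick("K_"), x = pick("x_"),
       yield = strains$yield, id = strains$id, species = strains$species,
       R = R, S = S)
}

#' Monod growth rate
#'
#' Per-capita growth rate under Monod kinetics, `g_max * c / (c + K)`:
#' saturating at `g_max` for `c >> K` and dropping to half-maximum at
#' `c = K`.
#'
#' @param params a one-row strain table ([strain()]) or a list with elements
#'   `g_max` and `K` (single resource).
#' @param c resource concentration (a.u.), scalar or vector; must be >= 0.
#' @return per-capita growth rate(s), hr^-1.
#' @examples
#' monod_rate(strain("B", 1.0, 4.0), c = 4.0)  # 0.5: half-maximum at c = K
#' @export
monod_rate <- function(params, c) {
  p <- single_resource_params(params)
  if (any(c < 0)) stop("negative resource concentration is not a valid state")
  p$g_max * c / (c + p$K)
}

single_resource_params <- function(params) {
  if (is.data.frame(params)) {
    m <- strain_matrices(params)
    if (m$R != 1L || m$S != 1L)
      stop("expected a single strain with a single resource")
    list(g_max = m$g[1, 1], K = m$K[1, 1])
  } else {
    list(g_max = params$g_max, K = params$K)
  }
}

#' Step-approximation growth parameters and rate
#'
#' In the step simplification of Monod's law a strain grows at a constant
#' rate `g` while the resource concentration exceeds its threshold `K`, and
#' not at all below it.  At exactly `c == K` the rate is defined as 0 (the
#' depleted side), so the event-driven cycle solver is unambiguous: a strain
#' stops the instant the concentration reaches its threshold.
#'
#' @param id strain label.
#' @param g growth rate above threshold, hr^-1 (> 0).
#' @param K threshold concentration, a.u. (> 0).
#' @return `step_strain()` returns a one-row `data.frame` with columns `id`,
#'   `g`, `K`; combine rows with `rbind()`.
#' @examples
#' s <- step_strain("s", g = 1, K = 1)
#' step_rate(s, c(0.5, 1, 2))  # 0, 0, 1
#' @export
step_strain <- function(id, g, K) {
  if (any(g <= 0)) stop("g must be > 0")
  if (any(K <= 0)) stop("K must be > 0")
  data.frame(id = as.character(id), g = as.numeric(g), K = as.numeric(K),
             stringsAsFactors = FALSE)
}

#' @rdname step_strain
#' @param params a one-row step-strain table or list with `g` and `K`.
#' @param c resource concentration (>= 0), scalar or vector.
#' @export
step_rate <- function(params, c) {
  if (any(c < 0)) stop("negative resource concentration is not a valid state")
  ifelse(c > params$K, params$g, 0)
}

#' Multi-resource co-utilization growth rate
#'
#' Total per-capita growth rate when several substitutable resources are
#' consumed simultaneously: the weighted sum of per-resource Monod terms,
#' `sum_r x_r g_max_r c_r / (c_r + K_r)`.  With a single resource and
#' `x = 1` this reduces to [monod_rate()].
#'
#' @param params a one-row strain table with as many resources as `c`.
#' @param c vector of resource concentrations (componentwise >= 0).
#' @return per-capita growth rate, hr^-1.
#' @export
multi_resource_rate <- function(params, c) {
  m <- strain_matrices(params)
  if (m$S != 1L) stop("expected a single strain")
  if (length(c) != m$R)
    stop("concentration vector has length ", length(c), ", strain has ",
         m$R, " resources")
  if (any(c < 0)) stop("negative resource concentration is not a valid state")
  sum(m$x[1, ] * m$g[1, ] * c / (c + m$K[1, ]))
}

#' Read or write a strain table as CSV
#'
#' The on-disk format has a mandatory header with columns `id`, `species`,
#' `yield` and per-resource columns `g_max_r`, `K_r`, `x_r` (r = 1..R);
#' rates in hr^-1, concentrations in a.u.
#'
#' @param path file path.
#' @return `read_strain_table()` returns a validated strain `data.frame`.
#' @export
read_strain_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$id <- as.character(out$id)
  out$species <- as.character(out$species)
  validate_strains(out)
  out
}

#' @rdname read_strain_table
#' @param strains a validated strain table.
#' @export
write_strain_table <- function(strains, path) {
  validate_strains(strains)
  utils::write.csv(strains, path, row.names = FALSE)
  invisible(path)
}
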