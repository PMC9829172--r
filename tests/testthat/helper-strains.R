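# Shared fixtures: the standard environment and the canonical K-strategist /
# r-strategist pair, plus small random-instance generators.

std_env <- function() dilution_env(c0 = 10, D = 10, T = 24)

strain_A <- function() strain("A", g_max = 0.55, K = 0.01)
strain_B <- function() strain("B", g_max = 1.0, K = 4.0)
pair_AB <- function() rbind(strain_A(), strain_B())

random_strain_set <- function(n, g_range = c(0.3, 1.5),
                              K_range = c(0.05, 6)) {
  strains <- lapply(seq_len(n), function(i)
    strain(paste0("s", i), g_max = stats::runif(1, g_range[1], g_range[2]),
           K = exp(stats::runif(1, log(K_range[1]), log(K_range[2])))))
  do.call(rbind, strains)
}

random_step_set <- function(n, g_range = c(0.2, 1.5), K_range = c(0.1, 8)) {
  step_strain(paste0("s", seq_len(n)),
              g = stats::runif(n, g_range[1], g_range[2]),
              K = exp(stats::runif(n, log(K_range[1]), log(K_range[2]))))
}

# Reference integrator for the within-cycle Monod dynamics, independent of
# the package's RK45 core: deSolve::lsoda on the linear-space system.
lsoda_cycle <- function(strains, N0, c0, T, hill = 1) {
  m <- boombust:::strain_matrices(strains)
  S <- m$S; R <- length(c0)
  rhs <- function(t, y, parms) {
    N <- y[seq_len(S)]
    cc <- pmax(y[S + seq_len(R)], 0)
    dN <- numeric(S); dc <- numeric(R)
    for (r in seq_len(R)) {
      # c^h/(c^h + K^h) computed in log space so steep exponents don't
      # overflow
      mon <- if (cc[r] == 0) rep(0, S) else
        stats::plogis(hill * (log(cc[r]) - log(m$K[, r])))
      per <- m$x[, r] * m$g[, r] * mon
      dN <- dN + per * N
      dc[r] <- -sum(per * N / m$yield)
    }
    list(c(dN, dc))
  }
  out <- deSolve::lsoda(c(N0, c0), c(0, T), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  y <- out[nrow(out), -1]
  list(N = unname(y[seq_len(S)]), c = unname(pmax(y[S + seq_len(R)], 0)))
}
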