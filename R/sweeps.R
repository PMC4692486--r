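#' Gain sweep of the attractor landscape
#'
#' Runs the sampling-based attractor search at each gain value and summarizes
#' the landscape: attractor count, density range, empirical entropy and (for
#' static thresholds) potential values.  Counts are estimates and need not be
#' monotone in G.
#'
#' @param w a normalized `"connectome"`.
#' @param cfg a `"model_config"` template (its `G` is overridden).
#' @param G_values gain grid.
#' @param density_grid,n_per_density,seed,cap_ms passed to
#'   [sample_attractors()].
#' @param keep_sets retain the full per-G attractor sets (memory heavy).
#' @return list with `summary` (one row per G) and, when `keep_sets`, `sets`.
#' @export
sweep_gain <- function(w, cfg, G_values,
                       density_grid = seq(0.02, 0.98, by = 0.03),
                       n_per_density = 100, seed = 1, cap_ms = 1000,
                       keep_sets = FALSE) {
  stopifnot(length(G_values) >= 1)
  rows <- vector("list", length(G_values))
  sets <- if (keep_sets) vector("list", length(G_values)) else NULL
  for (gi in seq_along(G_values)) {
    cfg$G <- G_values[gi]
    set <- sample_attractors(w, cfg, density_grid, n_per_density,
                             seed = seed + gi - 1, cap_ms = cap_ms)
    mv <- NA_real_
    if (cfg$variant != "DG" && nrow(set$patterns) > 0) {
      mv <- min(apply(set$patterns, 1, function(p)
        lyapunov_value(p, w, cfg)))
    }
    rows[[gi]] <- data.frame(
      G = G_values[gi], n_attractors = nrow(set$patterns),
      n_equilibrated = set$n_samples, n_failed = set$n_failed,
      mean_density = if (length(set$density)) mean(set$density) else NA_real_,
      entropy_bits = if (length(set$cardinality))
        empirical_entropy(set$cardinality) else NA_real_,
      min_V = mv)
    if (keep_sets) sets[[gi]] <- set
  }
  out <- list(summary = do.call(rbind, rows))
  if (keep_sets) out$sets <- sets
  out
}

#' First bifurcation detected by a gain sweep
#'
#' The smallest swept gain at which more than one attractor is found.  For
#' the SL model with P = 1 the analytic prediction is G_c = 2 / lambda_max(W).
#'
#' @param sweep result of [sweep_gain()].
#' @return the gain value, or `NA` if the sweep never leaves monostability.
#' @export
first_bifurcation <- function(sweep) {
  s <- sweep$summary
  hit <- which(s$n_attractors > 1)
  if (!length(hit)) return(NA_real_)
  s$G[hit[1]]
}

#' Analytic instability gain of the central SL equilibrium
#'
#' For SL with P = 1 the symmetric equilibrium x = W 1/2 loses stability when
#' (G/2) lambda_max(W) > 1, i.e. at G_c = 2 / lambda_max(W).
#'
#' @param w a normalized `"connectome"`.
#' @return G_c.
#' @export
critical_gain_sl <- function(w) {
  2 / matrix_norm(w$weights, "spectral")
}

#' Scaling-factor x initial-density sweep
#'
#' Maps attractor count, mean final density and empirical entropy over a
#' (P, f0) grid, each cell sampled with `n_per_cell` random initial patterns
#' at that single density.
#'
#' @param w a normalized `"connectome"`.
#' @param cfg a `"model_config"` template (its `P` is overridden).
#' @param P_values scaling-factor grid.
#' @param f0_values initial-density grid.
#' @param n_per_cell relaxations per (P, f0) cell.
#' @param seed root seed.
#' @param cap_ms equilibrium cap per relaxation.
#' @return data.frame with one row per cell: P, f0, n_attractors,
#'   mean_density (of the attractors), mean_final_density (cardinality
#'   weighted), entropy_bits, n_failed.
#' @export
sweep_P_density <- function(w, cfg, P_values, f0_values, n_per_cell = 100,
                            seed = 1, cap_ms = 1000) {
  rows <- list()
  cell <- 0L
  for (P in P_values) {
    for (f0 in f0_values) {
      cell <- cell + 1L
      cfg$P <- P
      set <- sample_attractors(w, cfg, density_grid = f0,
                               n_per_density = n_per_cell,
                               seed = seed + cell, cap_ms = cap_ms)
      m <- nrow(set$patterns)
      rows[[cell]] <- data.frame(
        P = P, f0 = f0, n_attractors = m,
        mean_density = if (m) mean(set$density) else NA_real_,
        mean_final_density = if (m)
          sum(set$density * set$cardinality) / sum(set$cardinality)
          else NA_real_,
        entropy_bits = if (m) empirical_entropy(set$cardinality) else NA_real_,
        n_equilibrated = set$n_samples, n_failed = set$n_failed)
    }
  }
  do.call(rbind, rows)
}
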