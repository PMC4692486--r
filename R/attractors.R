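#' Pearson similarity between two patterns
#'
#' Standard Pearson correlation, with the zero-variance case defined as 0
#' (with a warning) so that constant patterns such as the all-up/all-down
#' states can still be compared.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @export
pearson_similarity <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) {
    warning("zero-variance pattern; Pearson similarity defined as 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Euclidean similarity between two patterns
#'
#' 1 / (1 + Euclidean distance), in (0, 1], equal to 1 only for identical
#' patterns.
#'
#' @param x,y numeric vectors of equal length.
#' @return similarity in (0, 1\].
#' @export
euclidean_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  1 / (1 + sqrt(sum((x - y)^2)))
}

#' Create an empty attractor set
#'
#' An attractor set stores deduplicated relaxed patterns, each annotated with
#' its density (mean activity) and cardinality (number of sampled initial
#' conditions that relaxed onto it, a proxy for basin width).
#'
#' @param n node count.
#' @param sim_threshold double-dissimilarity threshold: a pattern is novel iff
#'   both its Pearson and its Euclidean similarity to every stored attractor
#'   are below this value (default 0.9).
#' @param provenance free-form list recorded with the set.
#' @return an object of class `"attractor_set"`.
#' @export
attractor_set <- function(n, sim_threshold = 0.9, provenance = list()) {
  structure(list(patterns = matrix(numeric(0), nrow = 0, ncol = n),
                 cardinality = integer(0), density = numeric(0),
                 n_samples = 0L, n_failed = 0L,
                 sim_threshold = sim_threshold, provenance = provenance),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf(
    "<attractor_set> %d attractors from %d equilibrated samples (%d failed)\n",
    nrow(x$patterns), x$n_samples, x$n_failed))
  invisible(x)
}

#' @export
length.attractor_set <- function(x) nrow(x$patterns)

#' Absorb a relaxed pattern into an attractor set or add it as new
#'
#' The double-dissimilarity rule: the pattern is stored as a new attractor iff
#' against every stored attractor both the Pearson correlation and the
#' Euclidean similarity are below the threshold (default 0.9).  Otherwise the
#' cardinality of the best-matching attractor is incremented, where the match
#' score is max(Pearson, Euclidean similarity) and ties go to the lowest
#' attractor index.
#'
#' @param pattern equilibrated final pattern.
#' @param set an `"attractor_set"`.
#' @return the updated set.
#' @export
absorb_or_add <- function(pattern, set) {
  pattern <- as.numeric(pattern)
  m <- nrow(set$patterns)
  if (m > 0) {
    sims <- pattern_similarities(pattern, set$patterns)
    novel <- all(sims$pearson < set$sim_threshold &
                 sims$euclid < set$sim_threshold)
    if (!novel) {
      score <- pmax(sims$pearson, sims$euclid)
      best <- which.max(score)   # which.max takes the lowest index on ties
      set$cardinality[best] <- set$cardinality[best] + 1L
      set$n_samples <- set$n_samples + 1L
      return(set)
    }
  }
  set$patterns <- rbind(set$patterns, pattern, deparse.level = 0)
  set$cardinality <- c(set$cardinality, 1L)
  set$density <- c(set$density, mean(pattern))
  set$n_samples <- set$n_samples + 1L
  set
}

# vectorized Pearson + Euclidean similarity of one pattern against the rows
# of a matrix; zero-variance rows or pattern give Pearson 0 (no warning here:
# the all-up/all-down states make this a routine case inside the search loop)
pattern_similarities <- function(pattern, mat) {
  d2 <- rowSums(sweep(mat, 2, pattern)^2)
  euclid <- 1 / (1 + sqrt(d2))
  pc <- pattern - mean(pattern)
  sp <- sqrt(sum(pc^2))
  mc <- mat - rowMeans(mat)
  sm <- sqrt(rowSums(mc^2))
  pear <- as.vector(mc %*% pc)
  denom <- sm * sp
  pear <- ifelse(denom > 0, pear / denom, 0)
  list(pearson = pear, euclid = euclid)
}

#' Relax one initial pattern to its attractor
#'
#' Deterministic run with the equilibrium stop rule and a 1 s cap.
#'
#' @param a0 initial binary pattern.
#' @param cfg a `"model_config"` (noise ignored: a deterministic copy is
#'   used).
#' @param w a normalized `"connectome"`.
#' @param cap_ms search cap (default 1000 ms).
#' @return list with the final output pattern `A`, final potentials `x` and
#'   an `equilibrated` flag.
#' @export
relax_pattern <- function(a0, cfg, w, cap_ms = 1000) {
  dcfg <- cfg
  dcfg$sigma_x <- 0; dcfg$sigma_theta <- 0
  traj <- simulate_net(a0, dcfg, w, duration = cap_ms,
                       record_stride = as.integer(round(cap_ms / dcfg$dt)),
                       stop_at_equilibrium = TRUE)
  A <- activation(traj$x,
                  if (dcfg$variant == "SL") traj$theta else traj$theta[1],
                  dcfg$G, dcfg$P)
  list(A = A, x = traj$x, equilibrated = traj$equilibrated)
}

#' Random sampling-based attractor search
#'
#' For each density of the grid, draws `n_per_density` random binary initial
#' patterns, relaxes each deterministically (equilibrium stop rule, 1 s cap),
#' and feeds every equilibrated final output pattern through
#' [absorb_or_add()].  Non-equilibrated runs are counted in `n_failed` and
#' excluded.  For the DG variant the threshold time constant is forced equal
#' to the potential time constant during the search.
#'
#' @param w a normalized `"connectome"`.
#' @param cfg a `"model_config"`.
#' @param density_grid initial-density grid (default 0.02 to 0.98 in steps of
#'   0.03, i.e. 33 densities).
#' @param n_per_density relaxations per density.
#' @param seed root seed; per-run seeds are derived from it.
#' @param cap_ms equilibrium search cap (default 1000 ms).
#' @return an `"attractor_set"` whose provenance records the per-density
#'   attractor counts (`density_counts`).
#' @export
sample_attractors <- function(w, cfg, density_grid = seq(0.02, 0.98, by = 0.03),
                              n_per_density = 100, seed = 1, cap_ms = 1000) {
  if (!w$normalized) stop("connectome must be normalized")
  if (cfg$variant == "DG") cfg$tau_theta <- cfg$tau_x
  n <- nrow(w$weights)
  set <- attractor_set(n, provenance = list(
    variant = cfg$variant, G = cfg$G, P = cfg$P,
    density_grid = density_grid, n_per_density = n_per_density,
    seed = seed))
  per_density <- integer(length(density_grid))
  run <- 0L
  for (di in seq_along(density_grid)) {
    f0 <- density_grid[di]
    before <- attractor_set(n)
    local_ids <- integer(0)
    for (k in seq_len(n_per_density)) {
      run <- run + 1L
      a0 <- random_initial_pattern(n, f0,
              seed = (as.numeric(seed) * 1000003 + run) %% 2147483647)
      res <- relax_pattern(a0, cfg, w, cap_ms = cap_ms)
      if (!res$equilibrated) {
        set$n_failed <- set$n_failed + 1L
        next
      }
      m_before <- nrow(set$patterns)
      set <- absorb_or_add(res$A, set)
      # track which attractors this density touched (soft per-density count)
      if (nrow(set$patterns) > m_before) {
        local_ids <- c(local_ids, nrow(set$patterns))
      } else {
        sims <- pattern_similarities(res$A, set$patterns)
        local_ids <- c(local_ids, which.max(pmax(sims$pearson, sims$euclid)))
      }
    }
    per_density[di] <- length(unique(local_ids))
  }
  set$provenance$density_counts <- data.frame(f0 = density_grid,
                                              n_attractors = per_density)
  set
}

#' Potential (Lyapunov) value of a state
#'
#' Evaluates the scalar potential of the static-threshold dynamics at a
#' vector of node potentials x:
#' V(x) = 1/2 sum_i \[ x_i^2 - x_i sum_j W_ij
#'        - x_i sum_(j != i) W_ij tanh(G (P x_j - theta_j))
#'        - W_ii (1/(G P)) ln cosh(G (P x_i - theta_i)) \].
#' For a zero diagonal the ln-cosh self-coupling term vanishes.  Exact as a
#' Lyapunov function for N = 1 (or diagonal W); for general symmetric W it is
#' evaluated verbatim as an energy proxy.
#'
#' @param x potential vector.
#' @param w a `"connectome"`.
#' @param cfg a `"model_config"` with static thresholds (SL or SG).
#' @return scalar V.
#' @export
lyapunov_value <- function(x, w, cfg) {
  if (cfg$variant == "DG")
    stop("the potential function is defined for static thresholds (SL/SG)")
  W <- w$weights
  th <- static_thresholds(w, cfg$variant)
  if (cfg$variant == "SG") th <- rep(th, length(x))
  tg <- tanh(cfg$G * (cfg$P * x - th))
  Wo <- W; diag(Wo) <- 0
  interact <- x * as.vector(Wo %*% tg)
  selfterm <- diag(W) * (1 / (cfg$G * cfg$P)) *
    log(cosh(cfg$G * (cfg$P * x - th)))
  0.5 * sum(x^2 - x * rowSums(W) - interact - selfterm)
}

#' Ising energy of a binary pattern
#'
#' E = -1/2 sum_ij W_ij A_i A_j - sum_i theta_i A_i, the spin-network energy
#' of the high-gain (Heaviside) limit.
#'
#' @param a binary pattern (0/1 vector).
#' @param w a `"connectome"`.
#' @param theta threshold state (vector or scalar, broadcast).
#' @return scalar energy.
#' @export
ising_energy <- function(a, w, theta) {
  a <- as.numeric(a)
  stopifnot(all(a %in% c(0, 1)))
  -0.5 * sum(a * as.vector(w$weights %*% a)) - sum(theta * a)
}

#' Boltzmann-Gibbs distribution over attractor energies
#'
#' p_alpha = exp(-beta E_alpha) / Z with a max-shift for numerical stability.
#'
#' @param energies vector of energies E_alpha.
#' @param beta inverse temperature (>= 0).
#' @return probability vector summing to 1.
#' @export
boltzmann_distribution <- function(energies, beta) {
  stopifnot(length(energies) > 0, is.finite(energies), beta >= 0)
  z <- -beta * energies
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

#' Entropy of the Boltzmann distribution
#'
#' H = -sum p log p over the Boltzmann-Gibbs weights; natural log by default.
#'
#' @inheritParams boltzmann_distribution
#' @param base logarithm base (default `exp(1)`).
#' @return scalar entropy.
#' @export
boltzmann_entropy <- function(energies, beta, base = exp(1)) {
  p <- boltzmann_distribution(energies, beta)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Empirical entropy of an attractor cardinality distribution
#'
#' H = -sum p_i log2 p_i with p_i = n_i / n.  Base 2 (bits): with an alphabet
#' of 3,300 equiprobable attractors the upper bound is log2(3300) = 11.69.
#'
#' @param cardinalities vector of positive integer cardinalities.
#' @param base logarithm base (default 2).
#' @return entropy in bits (for the default base).
#' @export
empirical_entropy <- function(cardinalities, base = 2) {
  stopifnot(length(cardinalities) >= 1, all(cardinalities > 0))
  p <- cardinalities / sum(cardinalities)
  -sum(p * log(p)) / log(base)
}

#' Write an attractor set as TSV + JSON provenance
#'
#' One row per attractor: density, cardinality, optional V and E columns,
#' then the pattern values.
#'
#' @param set an `"attractor_set"`.
#' @param path output TSV path; provenance goes to `paste0(path, ".json")`.
#' @param w,cfg optionally annotate each attractor with its potential value
#'   (SL/SG) and Ising energy of the binarized pattern.
#' @return `path`, invisibly.
#' @export
write_attractor_set <- function(set, path, w = NULL, cfg = NULL) {
  m <- nrow(set$patterns)
  df <- data.frame(id = seq_len(m), density = set$density,
                   cardinality = set$cardinality)
  if (!is.null(w) && !is.null(cfg)) {
    if (cfg$variant != "DG")
      df$V <- apply(set$patterns, 1, lyapunov_value, w = w, cfg = cfg)
    th <- if (cfg$variant == "DG") set$density else
      static_thresholds(w, cfg$variant)
    df$E <- vapply(seq_len(m), function(i) {
      ising_energy(as.numeric(set$patterns[i, ] > 0.5), w,
                   if (cfg$variant == "DG") set$density[i] else th)
    }, numeric(1))
  }
  df <- cbind(df, as.data.frame(set$patterns))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(set$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
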