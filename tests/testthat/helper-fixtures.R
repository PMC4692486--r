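# shared fixtures, built in code at test time

# single self-coupled node: W = [[1]], SL threshold 0.5; spectral norm is 1
# so normalization leaves it unchanged
one_node <- function() {
  normalize_connectome(
    connectome(matrix(1, 1, 1), allow_self_coupling = TRUE), "spectral")
}

# small normalized synthetic net (memoised per (n, seed))
small_net <- local({
  cache <- list()
  function(n = 30, seed = 4, n_modules = 3, p_intra = 0.4, p_inter = 0.05) {
    key <- paste(n, seed, n_modules, p_intra, p_inter)
    if (is.null(cache[[key]]))
      cache[[key]] <<- normalize_connectome(
        synthetic_connectome(n, n_modules, p_intra, p_inter, seed = seed))
    cache[[key]]
  }
})

# relax every binary corner of an N-node net (brute-force attractor oracle)
brute_force_attractors <- function(w, cfg) {
  n <- nrow(w$weights)
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  set <- attractor_set(n)
  for (i in seq_len(nrow(corners))) {
    r <- relax_pattern(corners[i, ], cfg, w)
    if (r$equilibrated) set <- absorb_or_add(r$A, set)
  }
  set
}

# best similarity (max of Pearson/Euclidean) of each row of `a` against the
# rows of `b`
best_match_sims <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    s <- hopscape:::pattern_similarities(a[i, ], b)
    max(pmax(s$pearson, s$euclid))
  }, numeric(1))
}

bp <- function(active, n_total = 10) binary_pattern(active, n_total)
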