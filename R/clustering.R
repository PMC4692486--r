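#' Binary activation pattern
#'
#' A pattern is the set of active nodes out of `n_total`.  Indices are
#' 1-based, following R convention.
#'
#' @param active integer vector of active node indices.
#' @param n_total total node count.
#' @return an object of class `"binary_pattern"`.
#' @export
binary_pattern <- function(active, n_total) {
  active <- sort(unique(as.integer(active)))
  if (length(active) && (min(active) < 1 || max(active) > n_total))
    stop("active indices must lie in 1..n_total")
  structure(list(active = active, n_total = as.integer(n_total)),
            class = "binary_pattern")
}

#' @export
print.binary_pattern <- function(x, ...) {
  cat(sprintf("<binary_pattern> %d/%d active\n", length(x$active), x$n_total))
  invisible(x)
}

#' Threshold a graded pattern into a binary one
#'
#' Nodes with activity strictly above the threshold are active; activity
#' exactly at the threshold is inactive.
#'
#' @param pattern numeric vector in \[0,1\]^N.
#' @param threshold activity cut (default 0.5).
#' @return a `"binary_pattern"`.
#' @export
binarize <- function(pattern, threshold = 0.5) {
  binary_pattern(which(pattern > threshold), length(pattern))
}

#' Inclusion match
#'
#' incl(A, B) = |A intersect B| / |A|, an asymmetric overlap; defined as 0
#' when A is empty.
#'
#' @param a,b `"binary_pattern"`s over the same node count.
#' @return value in \[0,1\].
#' @export
inclusion <- function(a, b) {
  stopifnot(a$n_total == b$n_total)
  if (length(a$active) == 0) return(0)
  length(intersect(a$active, b$active)) / length(a$active)
}

#' Symmetrized inclusion similarity
#'
#' sim_incl(A, B) = max(incl(A, B), incl(B, A)); equals 1 iff one non-empty
#' set contains the other.
#'
#' @inheritParams inclusion
#' @return value in \[0,1\].
#' @export
sim_incl <- function(a, b) {
  max(inclusion(a, b), inclusion(b, a))
}

# reference pattern of a cluster (member indices into `patterns`)
# rule "max_inclusion_score": the member maximizing the summed sim_incl with
# the other members (ties -> lowest member index);
# rule "majority": nodes active in strictly more than half of the members.
cluster_reference <- function(members, patterns,
                              rule = c("max_inclusion_score", "majority")) {
  rule <- match.arg(rule)
  n_total <- patterns[[members[1]]]$n_total
  if (rule == "majority") {
    counts <- integer(n_total)
    for (m in members) counts[patterns[[m]]$active] <-
        counts[patterns[[m]]$active] + 1L
    return(binary_pattern(which(counts > length(members) / 2), n_total))
  }
  if (length(members) == 1) return(patterns[[members[1]]])
  scores <- vapply(members, function(i) {
    sum(vapply(setdiff(members, i), function(j)
      sim_incl(patterns[[i]], patterns[[j]]), numeric(1)))
  }, numeric(1))
  patterns[[members[which.max(scores)]]]
}

# core agglomeration over an initial partition; `init` is a list of member
# index vectors, references computed with `rule`.
agglomerate_engine <- function(init, patterns, k, rule) {
  members <- init
  refs <- lapply(members, cluster_reference, patterns = patterns, rule = rule)
  nc <- length(members)
  if (nc == 1) return(list(members = members, refs = refs))
  S <- matrix(-Inf, nc, nc)
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc)
    S[i, j] <- sim_incl(refs[[i]], refs[[j]])
  alive <- rep(TRUE, nc)
  repeat {
    if (sum(alive) < 2) break
    mx <- max(S)  # dead rows/cols are -Inf
    if (mx <= k) break
    # lexicographically first maximal pair (lowest i, then lowest j)
    hit <- which(S == mx, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    e <- hit[1, 1]; f <- hit[1, 2]
    merged <- c(members[[e]], members[[f]])
    members[[e]] <- merged
    refs[[e]] <- cluster_reference(merged, patterns, rule)
    alive[f] <- FALSE
    S[f, ] <- -Inf; S[, f] <- -Inf
    for (j in which(alive)) {
      if (j == e) next
      s <- sim_incl(refs[[e]], refs[[j]])
      if (j > e) S[e, j] <- s else S[j, e] <- s
    }
  }
  list(members = members[alive], refs = refs[alive])
}

#' Greedy inclusion-match agglomeration
#'
#' Starts from singleton clusters and repeatedly merges the pair of clusters
#' whose reference patterns are most similar (symmetrized inclusion match),
#' until the maximal similarity drops to `k` or below.  Argmax ties are
#' broken by the lexicographically lowest cluster-index pair.
#'
#' @param patterns list of `"binary_pattern"`s.
#' @param k similarity threshold in (0, 1\].
#' @param reference_rule how cluster references are computed after a merge:
#'   `"max_inclusion_score"` picks the member with the highest summed
#'   similarity to the other members; `"majority"` takes the nodes active in
#'   more than 50% of members.
#' @return list of clusters, each a list with `members` (indices into
#'   `patterns`), `reference`, `size`.
#' @export
agglomerate <- function(patterns, k,
                        reference_rule = c("max_inclusion_score",
                                           "majority")) {
  reference_rule <- match.arg(reference_rule)
  stopifnot(k > 0, k <= 1, length(patterns) >= 1)
  res <- agglomerate_engine(as.list(seq_along(patterns)), patterns, k,
                            reference_rule)
  mapply(function(m, r) list(members = sort(m), reference = r,
                             size = length(m)),
         res$members, res$refs, SIMPLIFY = FALSE)
}

#' Double-pass inclusion-match clustering
#'
#' Pass 1 agglomerates the raw patterns with max-inclusion-score references,
#' grouping patterns that share a common core.  Pass 2 is a smoothing pass:
#' the pass-1 clusters are re-agglomerated using their majority patterns as
#' references, merging clusters that coincide on average.  Clusters are
#' returned sorted by descending size; clusters whose members are all empty
#' are dropped with a warning.
#'
#' @inheritParams agglomerate
#' @return list of clusters as in [agglomerate()].
#' @export
double_pass_cluster <- function(patterns, k) {
  p1 <- agglomerate(patterns, k, "max_inclusion_score")
  res <- agglomerate_engine(lapply(p1, `[[`, "members"), patterns, k,
                            "majority")
  out <- mapply(function(m, r) list(members = sort(m), reference = r,
                                    size = length(m)),
                res$members, res$refs, SIMPLIFY = FALSE)
  empty <- vapply(out, function(cl)
    all(vapply(cl$members, function(i) length(patterns[[i]]$active) == 0,
               logical(1))), logical(1))
  if (any(empty)) {
    warning("dropping ", sum(empty), " cluster(s) with all-empty members")
    out <- out[!empty]
  }
  out[order(vapply(out, `[[`, integer(1), "size"), decreasing = TRUE)]
}

#' Cluster core: the most frequently active nodes
#'
#' Ranks nodes by their activation frequency across the cluster's members and
#' keeps the top `round(fraction * n_total)`; frequency ties go to the lower
#' node index.
#'
#' @param cluster a cluster from [agglomerate()] / [double_pass_cluster()].
#' @param patterns the pattern list the cluster indexes into.
#' @param fraction fraction of all nodes to keep (0, 1\].
#' @return a `"binary_pattern"`.
#' @export
cluster_core <- function(cluster, patterns, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  n_total <- patterns[[cluster$members[1]]]$n_total
  counts <- integer(n_total)
  for (m in cluster$members)
    counts[patterns[[m]]$active] <- counts[patterns[[m]]$active] + 1L
  keep <- round(fraction * n_total)
  ord <- order(-counts, seq_len(n_total))
  binary_pattern(ord[seq_len(keep)], n_total)
}

#' Match fraction and t-statistic between a core and a reference set
#'
#' m = |core intersect reference| / |core|; under the null of an independent
#' random core the match probability is p = |reference| / n_total, giving
#' t = (m - p) sqrt(n_core / (p (1 - p))).  Qualitative bands: significant
#' (t > 3), good (t > 6), strong (t > 9).
#'
#' @param core,reference non-empty `"binary_pattern"`s.
#' @param n_total total node count (defaults to the patterns' own).
#' @return list with `m`, `t`, `p`, `band`.
#' @export
match_t_statistic <- function(core, reference, n_total = core$n_total) {
  stopifnot(length(core$active) > 0, length(reference$active) > 0)
  n_core <- length(core$active)
  p <- length(reference$active) / n_total
  m <- length(intersect(core$active, reference$active)) / n_core
  t <- (m - p) * sqrt(n_core / (p * (1 - p)))
  band <- if (t > 9) "strong" else if (t > 6) "good" else
    if (t > 3) "significant" else "none"
  list(m = m, t = t, p = p, band = band)
}

#' Planted-prototype pattern fixture
#'
#' Generates `n_prototypes` disjoint prototype sets of `n_active` nodes each,
#' plus `n_copies` noisy copies per prototype in which a fraction
#' `flip_frac` of the active nodes is swapped for random inactive nodes.
#' Used to validate clustering recovery.
#'
#' @param n_prototypes number of planted prototypes.
#' @param n_active active nodes per prototype.
#' @param n_copies noisy copies per prototype.
#' @param flip_frac fraction of active nodes flipped per copy (default 0.1).
#' @param n_total total node count.
#' @param seed integer seed.
#' @return list with `patterns` (noisy copies), `prototypes`, and
#'   `truth` (prototype index per pattern).
#' @export
planted_patterns <- function(n_prototypes, n_active, n_copies,
                             flip_frac = 0.1, n_total = 1000, seed = 1) {
  stopifnot(n_prototypes * n_active <= n_total)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pool <- sample.int(n_total, n_prototypes * n_active)
  protos <- lapply(seq_len(n_prototypes), function(i)
    binary_pattern(pool[((i - 1) * n_active + 1):(i * n_active)], n_total))
  n_flip <- round(flip_frac * n_active)
  patterns <- list(); truth <- integer(0)
  for (i in seq_len(n_prototypes)) {
    for (k in seq_len(n_copies)) {
      act <- protos[[i]]$active
      drop <- sample(act, n_flip)
      add <- sample(setdiff(seq_len(n_total), act), n_flip)
      patterns[[length(patterns) + 1]] <-
        binary_pattern(c(setdiff(act, drop), add), n_total)
      truth <- c(truth, i)
    }
  }
  list(patterns = patterns, prototypes = protos, truth = truth)
}
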