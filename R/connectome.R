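#' Construct a connectome object
#'
#' A connectome is a square, symmetric, non-negative weighted coupling matrix
#' between brain parcels (regions of interest), optionally annotated with node
#' labels and hemisphere tags.
#'
#' @param weights square numeric matrix, symmetric and non-negative.
#' @param labels optional character vector of node identifiers.
#' @param hemisphere optional character vector of tags in `"L"`, `"R"`,
#'   `"other"`.
#' @param normalized logical; `TRUE` when `weights` already has unit norm.
#' @param norm the matrix norm the `normalized` flag refers to.
#' @param allow_self_coupling permit non-zero diagonal entries (needed for
#'   single-node analytic tests); empirical connectomes have zero diagonals.
#' @return an object of class `"connectome"`.
#' @export
connectome <- function(weights, labels = NULL, hemisphere = NULL,
                       normalized = FALSE, norm = "frobenius",
                       allow_self_coupling = FALSE) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("hopscape_nonsquare: weights matrix must be square, got ",
         n, "x", ncol(weights), call. = FALSE)
  if (!is.numeric(weights) || anyNA(weights))
    stop("hopscape_nonnumeric: weights must be numeric and free of NA",
         call. = FALSE)
  if (any(weights < 0))
    stop("hopscape_negative: connectome weights must be non-negative",
         call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("hopscape_asymmetric: weights matrix is not symmetric within 1e-12; ",
         "refusing to symmetrize silently", call. = FALSE)
  if (!allow_self_coupling && any(diag(weights) != 0))
    stop("hopscape_diagonal: diagonal entries must be zero ",
         "(set allow_self_coupling = TRUE to permit them)", call. = FALSE)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  if (length(labels) != n)
    stop("hopscape_sidecar_mismatch: got ", length(labels),
         " labels for ", n, " nodes", call. = FALSE)
  if (!is.null(hemisphere)) {
    if (length(hemisphere) != n)
      stop("hopscape_sidecar_mismatch: got ", length(hemisphere),
           " hemisphere tags for ", n, " nodes", call. = FALSE)
    bad <- setdiff(unique(hemisphere), c("L", "R", "other"))
    if (length(bad))
      stop("hopscape_sidecar_mismatch: invalid hemisphere tag(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(weights = unname(weights), labels = as.character(labels),
         hemisphere = hemisphere, normalized = isTRUE(normalized),
         norm = norm, allow_self_coupling = allow_self_coupling),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %d nodes, %d edges, density %.3f, %s\n",
              n, ne, ne / (n * (n - 1) / 2),
              if (x$normalized) paste0("normalized (", x$norm, ")")
              else "unnormalized"))
  invisible(x)
}

#' @export
dim.connectome <- function(x) dim(x$weights)

#' Read a connectome from a plain-text matrix file
#'
#' The matrix file holds newline-separated rows of whitespace- or
#' tab-separated numeric fields (scientific notation accepted).  An optional
#' JSON sidecar supplies `"labels"` and `"hemisphere"` arrays.  Asymmetric
#' input is rejected, never silently symmetrized.
#'
#' @param path path to the matrix file.
#' @param sidecar optional path to a JSON sidecar.
#' @inheritParams connectome
#' @return a `"connectome"` with `normalized = FALSE`.
#' @export
read_connectome <- function(path, sidecar = NULL, allow_self_coupling = FALSE) {
  if (!file.exists(path))
    stop("hopscape_missing_file: no such file: ", path, call. = FALSE)
  rows <- strsplit(trimws(readLines(path, warn = FALSE)), "[ \t]+")
  rows <- rows[vapply(rows, function(r) length(r) > 0 && any(nzchar(r)),
                      logical(1))]
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L || lens[1] != length(rows))
    stop("hopscape_nonsquare: file does not hold a square matrix (",
         length(rows), " rows, widths ", paste(unique(lens), collapse = "/"),
         ")", call. = FALSE)
  w <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(w))
    stop("hopscape_nonnumeric: non-numeric field in ", path, call. = FALSE)
  labels <- NULL; hemi <- NULL
  if (!is.null(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    labels <- sc$labels
    hemi <- sc$hemisphere
  }
  connectome(w, labels = labels, hemisphere = hemi, normalized = FALSE,
             allow_self_coupling = allow_self_coupling)
}

#' Write a connectome and its sidecar
#'
#' @param c a `"connectome"`.
#' @param path output path for the matrix (TSV).
#' @param sidecar optional output path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(c, path, sidecar = NULL) {
  utils::write.table(c$weights, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(
      list(labels = c$labels, hemisphere = c$hemisphere),
      sidecar, auto_unbox = FALSE, null = "null")
  }
  invisible(path)
}

matrix_norm <- function(w, norm = c("frobenius", "spectral", "max_row_sum")) {
  norm <- match.arg(norm)
  switch(norm,
         frobenius   = sqrt(sum(w^2)),
         spectral    = max(abs(eigen(w, symmetric = TRUE,
                                     only.values = TRUE)$values)),
         max_row_sum = max(rowSums(abs(w))))
}

#' Normalize a connectome to unit matrix norm
#'
#' Coupling matrices enter the dynamics as W = C / ||C||.  The default norm is
#' Frobenius; spectral and maximum-row-sum norms are selectable.
#'
#' @param c a `"connectome"` with at least one non-zero entry.
#' @param norm which matrix norm to scale by.
#' @return a normalized `"connectome"` (idempotent).
#' @export
normalize_connectome <- function(c, norm = c("frobenius", "spectral",
                                             "max_row_sum")) {
  norm <- match.arg(norm)
  nv <- matrix_norm(c$weights, norm)
  if (nv == 0)
    stop("hopscape_zero_matrix: cannot normalize an all-zero connectome",
         call. = FALSE)
  c$weights <- c$weights / nv
  c$normalized <- TRUE
  c$norm <- norm
  c
}

#' Degree-preserving randomization (Maslov-Sneppen edge switching)
#'
#' Repeatedly proposes a switch of two non-null edges (a-b, c-d) into
#' (a-d, c-b); the switch is applied only when all four nodes are distinct and
#' neither target edge already exists, so the binary degree sequence is
#' preserved exactly.  Weights travel with their original source node:
#' w(a,d) <- w(a,b), w(c,b) <- w(c,d).  Rejected proposals are retried up to
#' `max_attempts` total proposals.
#'
#' @param c a symmetric `"connectome"`.
#' @param n_swaps number of successful switches to perform (>= 1).
#' @param seed integer seed for proposal draws.
#' @param max_attempts cap on total proposals; if reached before any swap
#'   succeeds the input is returned unchanged with a warning.
#' @return a randomized `"connectome"` with identical node count, degree
#'   sequence and weight multiset.
#' @export
maslov_sneppen_randomize <- function(c, n_swaps, seed,
                                     max_attempts = 100 * n_swaps) {
  stopifnot(n_swaps >= 1)
  w <- c$weights
  n <- nrow(w)
  edges <- which(upper.tri(w) & w > 0, arr.ind = TRUE)  # i < j
  ne <- nrow(edges)
  if (ne < 2) {
    warning("fewer than 2 edges; returning input unchanged")
    return(c)
  }
  done <- 0L; attempts <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  while (done < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx <- sample.int(ne, 2L)
    a <- edges[idx[1], 1]; b <- edges[idx[1], 2]
    cc <- edges[idx[2], 1]; d <- edges[idx[2], 2]
    # randomly orient the second edge so (a-d, c-b) covers both pairings
    if (stats::runif(1) < 0.5) { tmp <- cc; cc <- d; d <- tmp }
    if (length(unique(c(a, b, cc, d))) < 4) next
    if (w[a, d] > 0 || w[cc, b] > 0) next
    wab <- w[a, b]; wcd <- w[cc, d]
    w[a, b] <- w[b, a] <- 0
    w[cc, d] <- w[d, cc] <- 0
    w[a, d] <- w[d, a] <- wab     # weight follows source node a
    w[cc, b] <- w[b, cc] <- wcd   # weight follows source node c
    edges[idx[1], ] <- c(min(a, d), max(a, d))
    edges[idx[2], ] <- c(min(cc, b), max(cc, b))
    done <- done + 1L
  }
  if (done == 0L) {
    warning("no valid degree-preserving swap found after ", attempts,
            " attempts; returning input unchanged")
    return(c)
  }
  out <- c
  out$weights <- w
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Generate a synthetic modular connectome
#'
#' Emulates the gross statistics of an empirical structural connectome: a
#' sparse, symmetric, positively weighted graph with modular block structure.
#' Nodes are split into `n_modules` contiguous modules; within-module edges
#' appear with probability `p_intra`, between-module edges with `p_inter`.
#' Hemisphere tags split each module half/half.
#'
#' @param n node count (>= 2).
#' @param n_modules number of modules.
#' @param p_intra,p_inter within-/between-module edge probabilities with
#'   `0 <= p_inter <= p_intra <= 1`.
#' @param weight_law `"uniform"` (weights on (0,1]) or `"lognormal"`
#'   (meanlog 0, sdlog 1, heavy-tailed like tract-strength distributions).
#' @param seed integer seed; output is reproducible.
#' @return a `"connectome"` with zero diagonal.
#' @export
synthetic_connectome <- function(n, n_modules = 4, p_intra = 0.3,
                                 p_inter = 0.02,
                                 weight_law = c("uniform", "lognormal"),
                                 seed = 1) {
  weight_law <- match.arg(weight_law)
  stopifnot(n >= 2, n_modules >= 1,
            p_inter >= 0, p_intra <= 1, p_inter <= p_intra)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  module <- sort(rep(seq_len(n_modules), length.out = n))
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  same <- module[ut[, 1]] == module[ut[, 2]]
  p <- ifelse(same, p_intra, p_inter)
  present <- stats::runif(nrow(ut)) < p
  ne <- sum(present)
  wt <- if (weight_law == "uniform") stats::runif(ne)
        else stats::rlnorm(ne)
  idx <- ut[present, , drop = FALSE]
  w[idx] <- wt
  w[idx[, c(2, 1), drop = FALSE]] <- wt
  # hemisphere: first half of each module L, second half R
  hemi <- unlist(lapply(split(seq_len(n), module), function(ix) {
    h <- rep("R", length(ix)); h[seq_len(ceiling(length(ix) / 2))] <- "L"; h
  }), use.names = FALSE)
  connectome(w, hemisphere = hemi)
}
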