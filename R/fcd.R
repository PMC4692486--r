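#' Balloon/Windkessel hemodynamic kernel
#'
#' Damped sinusoid H(t) = exp(-t / (2 tau_s)) sin(omega t) / omega with
#' omega = sqrt(1/tau_f - 1/(4 tau_s T_param)) (the alternative reading
#' omega^2 = 1/tau_f - 1/(4 tau_s^2) is selectable), sampled at `dt` on
#' \[0, support\].  At the default support of 15 s the envelope is below
#' 1e-4, justifying truncation.
#'
#' @param dt sampling step in seconds.
#' @param tau_s,tau_f signal decay / feedback time constants (s).
#' @param T_param dimensionless damping parameter (default 10).
#' @param support kernel length in seconds (default 15).
#' @param normalize scale the kernel to unit area (default TRUE).
#' @param omega_form `"T"` for 1/(4 tau_s T_param), `"tau_s_sq"` for
#'   1/(4 tau_s^2).
#' @return numeric kernel vector.
#' @export
balloon_kernel <- function(dt, tau_s = 0.8, tau_f = 0.4, T_param = 10,
                           support = 15, normalize = TRUE,
                           omega_form = c("T", "tau_s_sq")) {
  omega_form <- match.arg(omega_form)
  stopifnot(dt > 0, tau_s > 0, tau_f > 0, support > 0)
  w2 <- if (omega_form == "T") 1 / tau_f - 1 / (4 * tau_s * T_param)
        else 1 / tau_f - 1 / (4 * tau_s^2)
  if (w2 <= 0) stop("omega^2 = ", w2, " <= 0: kernel is not oscillatory")
  omega <- sqrt(w2)
  t <- seq(0, support, by = dt)
  h <- exp(-0.5 * t / tau_s) * sin(omega * t) / omega
  if (normalize) h <- h / (sum(h) * dt)
  h
}

#' BOLD-like series container
#'
#' @param values T x N matrix of detrended samples.
#' @param rate sampling rate in Hz.
#' @param labels optional node labels.
#' @return an object of class `"bold_series"`.
#' @export
bold_series <- function(values, rate, labels = NULL) {
  values <- as.matrix(values)
  structure(list(values = values, rate = rate,
                 labels = labels %||% paste0("n", seq_len(ncol(values)))),
            class = "bold_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d nodes, %d samples at %g Hz (%.1f min)\n",
              ncol(x$values), nrow(x$values), x$rate,
              nrow(x$values) / x$rate / 60))
  invisible(x)
}

#' Reconstruct a BOLD-like signal from a trajectory
#'
#' Per node: block-average the recorded signal to 100 Hz, convolve causally
#' with the Balloon/Windkessel kernel, discard one kernel support (15 s) of
#' warm-up so the zero-initial-condition transient never reaches the output,
#' decimate to 0.5 Hz by strided sampling (convolution has already low-passed
#' the signal), and remove the temporal mean.  Record the trajectory with
#' `record = "mean_output"` so the neural signal is the bounded output A;
#' instantaneous potential recordings are accepted too.
#'
#' @param traj a `"trajectory"`.
#' @param out_rate final sampling rate in Hz (default 0.5).
#' @param ... passed to [balloon_kernel()].
#' @return a `"bold_series"`.
#' @export
simulate_bold <- function(traj, out_rate = 0.5, ...) {
  x <- traj$states
  if (nrow(x) < 2) stop("trajectory too short")
  dt_ms <- traj$dt * traj$record_stride
  # bring to 100 Hz (10 ms sampling) by block averaging if recorded finer
  if (dt_ms < 10 - 1e-9) {
    per <- as.integer(round(10 / dt_ms))
    nb <- nrow(x) %/% per
    if (nb < 2) stop("trajectory too short")
    grp <- rep(seq_len(nb), each = per)
    x <- apply(x[seq_len(nb * per), , drop = FALSE], 2,
               function(col) tapply(col, grp, mean))
  } else if (dt_ms > 10 + 1e-9) {
    stop("record the trajectory at 10 ms resolution or finer (got ",
         dt_ms, " ms)")
  }
  h <- balloon_kernel(dt = 0.01, ...)
  conv <- apply(x, 2, function(col) {
    stats::convolve(col, rev(h), type = "open")[seq_along(col)] * 0.01
  })
  # drop the convolution warm-up (one kernel support) so the output carries
  # no zero-initial-condition transient
  warm <- length(h) - 1L
  if (nrow(conv) <= warm + 1L) stop("trajectory too short")
  conv <- conv[-seq_len(warm), , drop = FALSE]
  stride <- as.integer(round(100 / out_rate))
  keep <- seq(1L, nrow(conv), by = stride)
  if (length(keep) < 2) stop("trajectory too short")
  dec <- conv[keep, , drop = FALSE]
  dec <- sweep(dec, 2, colMeans(dec))
  bold_series(dec, rate = out_rate)
}

#' Sliding-window functional connectivity
#'
#' For each window position, the N x N Pearson correlation matrix over the
#' window's samples.  A 1-minute window at 0.5 Hz spans 30 samples; a series
#' of duration D yields floor((D - window) * rate / step) + 1 positions.
#' Zero-variance nodes yield 0 entries (with one warning per call).
#'
#' @param bold a `"bold_series"`.
#' @param window_min window length in minutes (default 1).
#' @param step step between window starts, in samples (default 1).
#' @return list of FC matrices with attribute `"window_samples"`.
#' @export
sliding_fc <- function(bold, window_min = 1, step = 1) {
  ws <- as.integer(round(window_min * 60 * bold$rate))
  nt <- nrow(bold$values)
  if (ws > nt) stop("window longer than the series")
  starts <- seq(1L, nt - ws + 1L, by = step)
  warned <- FALSE
  fcs <- lapply(starts, function(s) {
    seg <- bold$values[s:(s + ws - 1L), , drop = FALSE]
    sds <- apply(seg, 2, stats::sd)
    fc <- suppressWarnings(stats::cor(seg))
    if (any(sds == 0)) {
      if (!warned) {
        warning("zero-variance node(s) in a window; FC entries set to 0")
        warned <<- TRUE
      }
      fc[is.na(fc)] <- 0
    }
    diag(fc) <- 1
    fc
  })
  attr(fcs, "window_samples") <- ws
  attr(fcs, "step") <- step
  attr(fcs, "rate") <- bold$rate
  fcs
}

#' Functional connectivity dynamics matrix
#'
#' Each window's FC matrix is vectorized over the (optionally masked) upper
#' triangle; FCD(t1, t2) is the Pearson correlation between the vectors at
#' t1 and t2.  Symmetric with unit diagonal by construction.
#'
#' @param fc_sequence list of FC matrices from [sliding_fc()].
#' @param node_subset optional integer vector of node indices to restrict the
#'   upper triangle to.
#' @return an object of class `"fcd_matrix"` (a plain matrix with window
#'   metadata attributes).
#' @export
fcd_matrix <- function(fc_sequence, node_subset = NULL) {
  if (length(fc_sequence) < 2) stop("need at least 2 window positions")
  vecs <- vapply(fc_sequence, function(fc) {
    if (!is.null(node_subset)) fc <- fc[node_subset, node_subset]
    fc[upper.tri(fc)]
  }, numeric(sum(upper.tri(
    if (is.null(node_subset)) fc_sequence[[1]]
    else fc_sequence[[1]][node_subset, node_subset]))))
  fcd <- suppressWarnings(stats::cor(vecs))
  fcd[is.na(fcd)] <- 0
  fcd <- (fcd + t(fcd)) / 2
  diag(fcd) <- 1
  structure(fcd, class = c("fcd_matrix", "matrix", "array"),
            window = attr(fc_sequence, "window_samples"),
            step = attr(fc_sequence, "step"))
}

#' @export
print.fcd_matrix <- function(x, ...) {
  cat(sprintf("<fcd_matrix> %d x %d window positions\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Attractor-based functional connectivity
#'
#' Pearson correlation between nodes across the attractor set (attractors as
#' observations), by default weighting each attractor by its cardinality so
#' that wide basins count for the time the noisy dynamics would spend there.
#' Nodes constant across the set get zero rows/columns with a warning.
#'
#' @param set an `"attractor_set"` with at least 2 attractors.
#' @param weighted weight attractors by cardinality (default TRUE).
#' @return N x N correlation matrix with unit diagonal.
#' @export
attractor_fc <- function(set, weighted = TRUE) {
  m <- nrow(set$patterns)
  if (m < 2) stop("need at least 2 attractors")
  X <- set$patterns
  wgt <- if (weighted) set$cardinality else rep(1, m)
  wgt <- wgt / sum(wgt)
  mu <- colSums(X * wgt)
  Xc <- sweep(X, 2, mu)
  cv <- t(Xc * wgt) %*% Xc
  sds <- sqrt(diag(cv))
  zero <- sds == 0
  denom <- outer(sds, sds)
  fc <- ifelse(denom > 0, cv / denom, 0)
  if (any(zero))
    warning(sum(zero), " node(s) constant across the attractor set; ",
            "rows/columns set to 0")
  diag(fc) <- ifelse(zero, 0, 1)
  fc
}

#' Correlate two FC matrices over a hemispheric mask
#'
#' Pearson correlation over the off-diagonal upper-triangle entries, possibly
#' restricted to intra- or inter-hemispheric node pairs.
#'
#' @param a,b square matrices of matching size.
#' @param mask `"all"`, `"intra_hemispheric"` or `"inter_hemispheric"`.
#' @param hemisphere character vector of `"L"`/`"R"`/`"other"` tags, required
#'   for the hemispheric masks.
#' @return Pearson correlation.
#' @export
compare_fc <- function(a, b, mask = c("all", "intra_hemispheric",
                                      "inter_hemispheric"),
                       hemisphere = NULL) {
  mask <- match.arg(mask)
  stopifnot(all(dim(a) == dim(b)))
  sel <- upper.tri(a)
  if (mask != "all") {
    if (is.null(hemisphere)) stop("hemisphere tags required for mask ", mask)
    same <- outer(hemisphere, hemisphere, `==`)
    sel <- sel & (if (mask == "intra_hemispheric") same else !same)
  }
  if (!any(sel)) stop("empty mask")
  stats::cor(a[sel], b[sel])
}
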