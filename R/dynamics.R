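#' Model configuration for the graded-response network
#'
#' Bundles the model variant and every dynamical parameter.  Variants differ
#' in how the activation threshold is built: `SL` uses a static local
#' threshold per node (half the node's coupling row sum), `SG` a single
#' static global threshold (the mean of the SL thresholds), and `DG` a single
#' dynamic global threshold relaxing toward the mean network output, which
#' acts as a density control.
#'
#' @param variant `"SL"`, `"SG"` or `"DG"`.
#' @param G gain (node excitability, inverse spin-glass temperature), > 0.
#' @param P scaling factor (excitation/inhibition ratio), >= 0.
#' @param tau_x potential time constant in ms (default 10).
#' @param tau_theta threshold time constant in ms (default 80 for noisy runs;
#'   set equal to `tau_x` during deterministic attractor search).
#' @param sigma_x,sigma_theta noise strengths (0 = deterministic).
#' @param dt Euler step in ms (default 0.1).
#' @param noise_scaling `"tau"` reads sigma as the diffusion strength of the
#'   tau-scaled stochastic equation, giving increments (sigma/tau) sqrt(dt) xi;
#'   `"plain"` uses sigma sqrt(dt) xi.
#' @return an object of class `"model_config"`.
#' @export
model_config <- function(variant = c("SL", "SG", "DG"), G = 900, P = 1,
                         tau_x = 10, tau_theta = tau_x,
                         sigma_x = 0, sigma_theta = 0, dt = 0.1,
                         noise_scaling = c("tau", "plain")) {
  variant <- match.arg(variant)
  noise_scaling <- match.arg(noise_scaling)
  stopifnot(G > 0, P >= 0, tau_x > 0, tau_theta > 0, dt > 0,
            sigma_x >= 0, sigma_theta >= 0)
  structure(list(variant = variant, G = G, P = P, tau_x = tau_x,
                 tau_theta = tau_theta, sigma_x = sigma_x,
                 sigma_theta = sigma_theta, dt = dt,
                 noise_scaling = noise_scaling),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config> %s  G=%g P=%g tau_x=%g tau_theta=%g sigma=(%g,%g) dt=%g\n",
    x$variant, x$G, x$P, x$tau_x, x$tau_theta, x$sigma_x, x$sigma_theta,
    x$dt))
  invisible(x)
}

variant_code <- function(variant) match(variant, c("SL", "SG", "DG")) - 1L

#' Sigmoid activation
#'
#' A_i = (1 + tanh(G (P x_i - theta_i))) / 2, bounded in \[0, 1\] and monotone
#' in x.  `theta` is either a length-N vector (SL) or a scalar (SG/DG,
#' broadcast).
#'
#' @param x potential vector.
#' @param theta threshold state.
#' @param G gain.
#' @param P scaling factor.
#' @return output vector in \[0,1\]^N.
#' @export
activation <- function(x, theta, G, P) {
  0.5 * (1 + tanh(G * (P * x - theta)))
}

#' Static activation thresholds
#'
#' SL: theta_i = half the i-th row sum of W.  SG: the mean of the SL vector.
#'
#' @param w a normalized `"connectome"`.
#' @param variant `"SL"` or `"SG"`.
#' @return numeric vector (SL, length N) or scalar (SG).
#' @export
static_thresholds <- function(w, variant = c("SL", "SG")) {
  variant <- match.arg(variant)
  th <- 0.5 * rowSums(w$weights)
  if (variant == "SG") mean(th) else th
}

initial_threshold <- function(w, cfg, a0) {
  switch(cfg$variant,
         SL = static_thresholds(w, "SL"),
         SG = static_thresholds(w, "SG"),
         DG = mean(a0))
}

base_threshold <- function(w, cfg) {
  switch(cfg$variant,
         SL = static_thresholds(w, "SL"),
         SG = static_thresholds(w, "SG"),
         DG = 0)   # unused by the DG update
}

#' Random binary initial pattern
#'
#' Each node is independently active with probability `f0` (binomial draw),
#' so the realized density fluctuates around `f0`.
#'
#' @param n node count.
#' @param f0 target density in (0,1).
#' @param seed integer seed.
#' @return a 0/1 vector of length `n`.
#' @export
random_initial_pattern <- function(n, f0, seed = NULL) {
  stopifnot(f0 > 0, f0 < 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  as.numeric(stats::runif(n) < f0)
}

#' Single Euler(-Maruyama) step (reference implementation)
#'
#' Pure-R update used as the cross-check oracle for the compiled integrator.
#' With zero noise the update is exactly deterministic Euler.
#'
#' @param state list with `x` (potentials), `theta` (threshold state),
#'   `t` (elapsed ms).
#' @param cfg a `"model_config"`.
#' @param w a normalized `"connectome"`.
#' @param theta_base static thresholds the SL/SG noisy thresholds revert to
#'   (computed from `w` when `NULL`).
#' @return the updated state list.
#' @export
step_state <- function(state, cfg, w, theta_base = NULL) {
  x <- state$x; theta <- state$theta
  A <- activation(x, theta, cfg$G, cfg$P)
  sc <- if (cfg$noise_scaling == "tau") {
    c(cfg$sigma_x / cfg$tau_x, cfg$sigma_theta / cfg$tau_theta)
  } else c(cfg$sigma_x, cfg$sigma_theta)
  sq <- sqrt(cfg$dt)
  dx <- (cfg$dt / cfg$tau_x) * (-x + as.vector(w$weights %*% A))
  if (cfg$sigma_x > 0) dx <- dx + sc[1] * sq * stats::rnorm(length(x))
  if (cfg$variant == "DG") {
    dth <- (cfg$dt / cfg$tau_theta) * (-theta + mean(A))
    if (cfg$sigma_theta > 0) dth <- dth + sc[2] * sq * stats::rnorm(1)
  } else {
    if (is.null(theta_base))
      theta_base <- static_thresholds(w, cfg$variant)
    dth <- (cfg$dt / cfg$tau_theta) * (theta_base - theta)
    if (cfg$sigma_theta > 0)
      dth <- dth + sc[2] * sq * stats::rnorm(length(theta))
  }
  x <- x + dx
  if (any(!is.finite(x)))
    stop("non-finite potential at node ", which(!is.finite(x))[1],
         call. = FALSE)
  list(x = x, theta = theta + dth, t = state$t + cfg$dt)
}

#' Integrate the network dynamics
#'
#' Explicit Euler (Euler-Maruyama when noisy) integration of the chosen model
#' variant.  The initial binary pattern `x0` is assigned directly to the node
#' potentials; SL/SG thresholds start at their static values and the DG
#' threshold starts at `mean(x0)`.
#'
#' @param x0 initial pattern in \[0,1\]^N (potentials).
#' @param cfg a `"model_config"`.
#' @param w a normalized `"connectome"`.
#' @param duration simulated time in ms (>= `cfg$dt`).
#' @param record_stride record every `record_stride`-th step.
#' @param record `"sample"` records instantaneous potentials;
#'   `"mean_output"` records block means of the output A over each stride
#'   (used for hemodynamic downsampling).
#' @param stop_at_equilibrium apply the equilibrium stop rule (see
#'   [detect_equilibrium()]); the 1 s search cap is expressed by passing
#'   `duration = 1000`.
#' @param eq_T,eq_eps averaging window (ms) and relative tolerance of the
#'   stop rule.
#' @param seed optional integer seed for the noise stream.
#' @return a `"trajectory"`: `times` (ms), `states` (recorded x, or block-mean
#'   A), `theta_states`, final `x`/`theta`, `equilibrated` flag and `steps`
#'   taken.
#' @export
simulate_net <- function(x0, cfg, w, duration, record_stride = 10L,
                         record = c("sample", "mean_output"),
                         stop_at_equilibrium = FALSE,
                         eq_T = 100, eq_eps = 1e-6, seed = NULL) {
  record <- match.arg(record)
  stopifnot(duration >= cfg$dt)
  if (!w$normalized)
    warning("connectome is not normalized; thresholds assume ||W|| = 1")
  n <- nrow(w$weights)
  stopifnot(length(x0) == n)
  theta0 <- initial_threshold(w, cfg, x0)
  thbase <- base_threshold(w, cfg)
  if (cfg$variant != "SL") { theta0 <- theta0[1]; thbase <- thbase[1] }
  n_steps <- as.integer(round(duration / cfg$dt))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  res <- cpp_simulate(
    w$weights, as.numeric(x0), as.numeric(theta0), as.numeric(thbase),
    variant_code(cfg$variant), cfg$G, cfg$P, cfg$tau_x, cfg$tau_theta,
    cfg$sigma_x, cfg$sigma_theta, cfg$dt,
    n_steps, as.integer(record_stride),
    if (record == "mean_output") 1L else 0L,
    stop_at_equilibrium, eq_T, eq_eps, 10L,
    if (cfg$noise_scaling == "tau") 0L else 1L)
  structure(
    list(times = as.numeric(res$times), states = res$states,
         theta_states = res$theta_states, x = as.numeric(res$x),
         theta = as.numeric(res$theta), equilibrated = res$equilibrated,
         steps = res$steps, dt = cfg$dt, record_stride = record_stride,
         record = record, cfg = cfg),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d nodes, %d records over %.1f ms (%s)%s\n",
              ncol(x$states), nrow(x$states),
              x$steps * x$dt, x$record,
              if (x$equilibrated) ", equilibrated" else ""))
  invisible(x)
}

#' Equilibrium criterion on a mean-potential window
#'
#' Fires when the node-averaged potential has stopped moving:
#' |mean_T(xbar) - xbar(t)| / max(|xbar(t)|, 1e-6) < eps, where mean_T is the
#' trailing average over the last `T_ms` of simulated time.
#'
#' @param xbar vector of mean potentials sampled every `dt` ms, most recent
#'   last, spanning at least `T_ms`.
#' @param dt sample spacing in ms.
#' @param T_ms averaging window (default 100 ms).
#' @param eps relative tolerance (default 1e-6).
#' @return logical.
#' @export
detect_equilibrium <- function(xbar, dt, T_ms = 100, eps = 1e-6) {
  win <- max(1L, as.integer(round(T_ms / dt)))
  if (length(xbar) < win) stop("window spans less than T_ms of time")
  recent <- xbar[(length(xbar) - win + 1):length(xbar)]
  now <- xbar[length(xbar)]
  abs(mean(recent) - now) / max(abs(now), 1e-6) < eps
}

#' Export a trajectory as TSV
#'
#' One time column (ms) plus one column per node.
#' @param traj a `"trajectory"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_ms = traj$times, traj$states)
  names(df) <- c("time_ms", paste0("n", seq_len(ncol(traj$states))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
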