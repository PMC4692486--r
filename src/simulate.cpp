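// Euler / Euler-Maruyama integration of the graded-response Hopfield model
// with static-local (SL), static-global (SG) or dynamic-global (DG)
// activation thresholds.  Kept in C++ because attractor-landscape sweeps
// need 10^3..10^5 relaxations of up to 10^4 steps each.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec activation_cpp(const arma::vec& x, const arma::vec& theta,
                                       double G, double P) {
  // theta has length N (SL) or length 1 (SG/DG, broadcast)
  if (theta.n_elem == x.n_elem) {
    return 0.5 * (1.0 + arma::tanh(G * (P * x - theta)));
  }
  return 0.5 * (1.0 + arma::tanh(G * (P * x - theta(0))));
}

// variant: 0 = SL, 1 = SG, 2 = DG
// record_mode: 0 = instantaneous x samples every record_stride steps
//              1 = block means of the output A over record_stride-step blocks
// noise_scaling: 0 = increments (sigma/tau)*sqrt(dt)*xi  (tau-scaled SDE)
//                1 = increments  sigma*sqrt(dt)*xi
// [[Rcpp::export]]
List cpp_simulate(const arma::mat& W, const arma::vec& x0,
                  const arma::vec& theta_init, const arma::vec& theta_base,
                  int variant, double G, double P,
                  double tau_x, double tau_theta,
                  double sigma_x, double sigma_theta, double dt,
                  int n_steps, int record_stride, int record_mode,
                  bool stop_at_equilibrium, double eq_T, double eq_eps,
                  int eq_check_every, int noise_scaling) {
  const int N = x0.n_elem;
  arma::vec x = x0;
  arma::vec theta = theta_init;

  const double ax = dt / tau_x;
  const double at = dt / tau_theta;
  const double sqdt = std::sqrt(dt);
  const double nx = (noise_scaling == 0 ? sigma_x / tau_x : sigma_x) * sqdt;
  const double nt = (noise_scaling == 0 ? sigma_theta / tau_theta : sigma_theta) * sqdt;
  const bool noisy_x = sigma_x > 0.0;
  const bool noisy_t = sigma_theta > 0.0;

  // equilibrium detection: running window of the mean potential
  const int win = std::max(1, (int) std::lround(eq_T / dt));
  std::vector<double> xbar_buf(win, 0.0);
  double xbar_sum = 0.0;
  int buf_fill = 0, buf_pos = 0;

  const int n_rec = n_steps / record_stride + (record_mode == 0 ? 1 : 0);
  arma::mat rec(n_rec, N, arma::fill::zeros);
  arma::mat rec_theta(n_rec, theta.n_elem, arma::fill::zeros);
  arma::vec rec_times(n_rec, arma::fill::zeros);
  arma::vec block_acc(N, arma::fill::zeros);
  arma::vec theta_acc(theta.n_elem, arma::fill::zeros);
  int rec_i = 0;

  if (record_mode == 0 && n_rec > 0) {
    rec.row(0) = x.t();
    rec_theta.row(0) = theta.t();
    rec_times(0) = 0.0;
    rec_i = 1;
  }

  RNGScope scope;
  bool equilibrated = false;
  int step = 0;

  for (step = 1; step <= n_steps; ++step) {
    arma::vec A = activation_cpp(x, theta, G, P);

    // drift
    arma::vec dx = ax * (-x + W * A);
    if (noisy_x) {
      for (int i = 0; i < N; ++i) dx(i) += nx * norm_rand();
    }

    // threshold update (Euler on Eqs for SL/SG reversion, DG mean-output drive)
    if (variant == 2) {               // DG
      double drive = arma::mean(A);
      double dth = at * (-theta(0) + drive);
      if (noisy_t) dth += nt * norm_rand();
      theta(0) += dth;
    } else if (variant == 1) {        // SG
      double dth = at * (-theta(0) + theta_base(0));
      if (noisy_t) dth += nt * norm_rand();
      theta(0) += dth;
    } else {                          // SL
      if (noisy_t) {
        for (int i = 0; i < N; ++i)
          theta(i) += at * (-theta(i) + theta_base(i)) + nt * norm_rand();
      } else {
        theta += at * (theta_base - theta);
      }
    }

    x += dx;

    if (!x.is_finite()) {
      arma::uword bad = 0;
      for (arma::uword i = 0; i < x.n_elem; ++i)
        if (!std::isfinite(x(i))) { bad = i; break; }
      stop("non-finite potential at node %d after step %d", (int) bad + 1, step);
    }

    // recording
    if (record_mode == 1) {
      block_acc += activation_cpp(x, theta, G, P);
      theta_acc += theta;
      if (step % record_stride == 0 && rec_i < n_rec) {
        rec.row(rec_i) = (block_acc / record_stride).t();
        rec_theta.row(rec_i) = (theta_acc / record_stride).t();
        rec_times(rec_i) = step * dt;
        block_acc.zeros();
        theta_acc.zeros();
        ++rec_i;
      }
    } else if (step % record_stride == 0 && rec_i < n_rec) {
      rec.row(rec_i) = x.t();
      rec_theta.row(rec_i) = theta.t();
      rec_times(rec_i) = step * dt;
      ++rec_i;
    }

    // equilibrium stop rule on the node-averaged potential
    if (stop_at_equilibrium) {
      double xbar = arma::mean(x);
      if (buf_fill < win) {
        xbar_buf[buf_pos] = xbar; xbar_sum += xbar;
        ++buf_fill;
      } else {
        xbar_sum += xbar - xbar_buf[buf_pos];
        xbar_buf[buf_pos] = xbar;
      }
      buf_pos = (buf_pos + 1) % win;
      if (buf_fill == win && step % eq_check_every == 0) {
        double denom = std::max(std::fabs(xbar), 1e-6);
        if (std::fabs(xbar_sum / win - xbar) / denom < eq_eps) {
          equilibrated = true;
          break;
        }
      }
    }
  }
  if (step > n_steps) step = n_steps;

  return List::create(
    _["x"] = x, _["theta"] = theta,
    _["times"] = rec_times.head(rec_i),
    _["states"] = rec.head_rows(rec_i),
    _["theta_states"] = rec_theta.head_rows(rec_i),
    _["n_recorded"] = rec_i,
    _["steps"] = step,
    _["equilibrated"] = equilibrated);
}
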