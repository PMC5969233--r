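// Stochastic Euler-Maruyama integrator for the delayed corticothalamic
// mean-field network. Each region holds four populations (cortical
// excitatory/inhibitory, thalamic relay/reticular) whose membrane potentials
// are filtered by a second-order synapto-dendritic operator
//   (1/(alpha*beta)) V'' + (1/alpha + 1/beta) V' + V = input,
// and an excitatory field phi_e obeying second-order damping at rate gamma.
// Delayed quantities (phi_e for network and corticothalamic terms, Q_s for
// the corticothalamic feedback onto cortex) are kept in ring buffers.
// Gaussian white noise enters only the relay population's equation, scaled
// by sqrt(dt) (Euler-Maruyama); R's RNG is used so set.seed() in R makes
// runs bit-identical.
#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoidQ(double V, double Qmax, double theta, double sigma) {
  return Qmax / (1.0 + std::exp(-(V - theta) / sigma));
}

// [[Rcpp::export(name = ".integrate_ct")]]
List integrate_ct(NumericMatrix nu,        // n x 11: ee ei es ie ii is se sr re rs n
                  double Qmax, double theta, double sigma,
                  double alpha, double beta, double gamma_,
                  double epsilon, double sigma_n, double phi_n0, double dt,
                  IntegerVector edge_src,  // 0-based source region per directed edge
                  IntegerVector edge_dst,  // 0-based receiving region
                  NumericVector edge_w,    // structural weight A[dst, src]
                  IntegerVector edge_lag,  // delay in steps
                  int lag_ct,              // corticothalamic delay in steps
                  int n_steps, int n_transient, int decim,
                  NumericMatrix init,      // n x 10 initial state
                  NumericVector phi_hist)  // n, history value of phi_e for t <= 0
{
  const int n = nu.nrow();
  const int n_edges = edge_src.size();
  int max_lag = lag_ct;
  for (int e = 0; e < n_edges; ++e) max_lag = std::max(max_lag, edge_lag[e]);
  const int depth = max_lag + 1;

  // state: Ve We Vi Wi Vs Ws Vr Wr phi psi  (columns of `st`)
  NumericMatrix st(n, 10);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < 10; ++k) st(j, k) = init(j, k);

  // ring buffers over time slots [0, depth)
  NumericMatrix phi_buf(n, depth);
  NumericMatrix qs_buf(n, depth);
  for (int s = 0; s < depth; ++s)
    for (int j = 0; j < n; ++j) {
      phi_buf(j, s) = phi_hist[j];
      qs_buf(j, s) = sigmoidQ(init(j, 4), Qmax, theta, sigma);
    }

  const int n_keep = n_steps - n_transient;
  const int n_out = n_keep / decim;
  NumericMatrix out(n, n_out);
  std::vector<double> acc(n, 0.0);

  const double ab = alpha * beta;
  const double apb = alpha + beta;
  const double g2 = gamma_ * gamma_;
  const double sqdt = std::sqrt(dt);
  const double inv_n = 1.0 / n;

  std::vector<double> coupling(n);
  RNGScope scope;

  int out_col = 0, acc_count = 0;
  for (int t = 0; t < n_steps; ++t) {
    // slot arithmetic: lag <= max_lag < depth, so (slot_now - lag + depth) is
    // non-negative and (t - lag) mod depth indexes the right ring-buffer cell
    const int slot_now = t % depth;
    const int slot_ct2 = (slot_now - lag_ct + depth) % depth;

    std::fill(coupling.begin(), coupling.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      const int slot = (slot_now - edge_lag[e] + depth) % depth;
      coupling[edge_dst[e]] += edge_w[e] * phi_buf(edge_src[e], slot);
    }

    for (int j = 0; j < n; ++j) {
      const double Ve = st(j, 0), We = st(j, 1);
      const double Vi = st(j, 2), Wi = st(j, 3);
      const double Vs = st(j, 4), Ws = st(j, 5);
      const double Vr = st(j, 6), Wr = st(j, 7);
      const double phi = st(j, 8), psi = st(j, 9);

      const double Qi = sigmoidQ(Vi, Qmax, theta, sigma);
      const double Qsv = sigmoidQ(Vs, Qmax, theta, sigma);
      const double Qr = sigmoidQ(Vr, Qmax, theta, sigma);
      const double Qe = sigmoidQ(Ve, Qmax, theta, sigma);

      const double qs_del = qs_buf(j, slot_ct2);
      const double phi_del = phi_buf(j, slot_ct2);

      const double in_e = nu(j, 0) * phi + nu(j, 1) * Qi + nu(j, 2) * qs_del +
                          epsilon * inv_n * coupling[j];
      const double in_i = nu(j, 3) * phi + nu(j, 4) * Qi + nu(j, 5) * qs_del;
      const double in_s = nu(j, 6) * phi_del + nu(j, 7) * Qr + nu(j, 10) * phi_n0;
      const double in_r = nu(j, 8) * phi_del + nu(j, 9) * Qsv;

      double nVe = Ve + dt * We;
      double nWe = We + dt * (ab * (in_e - Ve) - apb * We);
      double nVi = Vi + dt * Wi;
      double nWi = Wi + dt * (ab * (in_i - Vi) - apb * Wi);
      double nVs = Vs + dt * Ws;
      double nWs = Ws + dt * (ab * (in_s - Vs) - apb * Ws);
      if (sigma_n > 0.0)
        nWs += ab * nu(j, 10) * sigma_n * ab * sqdt * norm_rand();
      double nVr = Vr + dt * Wr;
      double nWr = Wr + dt * (ab * (in_r - Vr) - apb * Wr);
      double nphi = phi + dt * psi;
      double npsi = psi + dt * (g2 * (Qe - phi) - 2.0 * gamma_ * psi);

      st(j, 0) = nVe; st(j, 1) = nWe; st(j, 2) = nVi; st(j, 3) = nWi;
      st(j, 4) = nVs; st(j, 5) = nWs; st(j, 6) = nVr; st(j, 7) = nWr;
      st(j, 8) = nphi; st(j, 9) = npsi;
    }

    // push time t+1 values into the buffers
    const int slot_next = (t + 1) % depth;
    for (int j = 0; j < n; ++j) {
      phi_buf(j, slot_next) = st(j, 8);
      qs_buf(j, slot_next) = sigmoidQ(st(j, 4), Qmax, theta, sigma);
    }

    if ((t & 1023) == 0) {
      double chk = 0.0;
      for (int j = 0; j < n; ++j) chk += st(j, 0) + st(j, 8);
      if (!std::isfinite(chk))
        stop("numerical blow-up: non-finite state at step %d (t = %g s)", t, t * dt);
    }

    if (t >= n_transient && out_col < n_out) {
      for (int j = 0; j < n; ++j) acc[j] += st(j, 8);
      if (++acc_count == decim) {
        for (int j = 0; j < n; ++j) {
          out(j, out_col) = acc[j] / decim;
          acc[j] = 0.0;
        }
        acc_count = 0;
        ++out_col;
      }
    }
  }

  double chk = 0.0;
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < 10; ++k) chk += st(j, k);
  if (!std::isfinite(chk))
    stop("numerical blow-up: non-finite state at final step %d", n_steps);

  return List::create(_["phi"] = out, _["final_state"] = st);
}
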