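// Training core for the (SU)PINN estimators.
//
// A branch is a small dense network t -> S_hat(t): two tanh hidden layers,
// one input (time, rescaled by t_max) and one output, with the initial
// condition S(0)=0 enforced by an output factor tanh(t/t_c). The loss per
// branch is mean squared ODE residual at collocation points plus
// gamma * weighted mean squared data misfit; a multi-branch fit sums branch
// losses and shares a single T1b across branches. All gradients (including
// through the network's input derivative in the ODE residual) are analytic;
// optimisation is Adam with a three-tier schedule and box projection of the
// kinetic parameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

struct Net {
  vec w1, b1;
  mat W2;
  vec b2, w3;
  double b3;
};

static Net net_from_list(const List& l) {
  Net n;
  n.w1 = Rcpp::as<vec>(l["w1"]);
  n.b1 = Rcpp::as<vec>(l["b1"]);
  n.W2 = Rcpp::as<mat>(l["W2"]);
  n.b2 = Rcpp::as<vec>(l["b2"]);
  n.w3 = Rcpp::as<vec>(l["w3"]);
  n.b3 = Rcpp::as<double>(l["b3"]);
  return n;
}

static List net_to_list(const Net& n) {
  return List::create(Rcpp::Named("w1") = n.w1, Rcpp::Named("b1") = n.b1,
                      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
                      Rcpp::Named("w3") = n.w3, Rcpp::Named("b3") = n.b3);
}

static Net net_zeros_like(const Net& n) {
  Net z;
  z.w1 = zeros<vec>(n.w1.n_elem);
  z.b1 = zeros<vec>(n.b1.n_elem);
  z.W2 = zeros<mat>(n.W2.n_rows, n.W2.n_cols);
  z.b2 = zeros<vec>(n.b2.n_elem);
  z.w3 = zeros<vec>(n.w3.n_elem);
  z.b3 = 0.0;
  return z;
}

// Forward pass caches on a fixed set of time points.
struct Cache {
  rowvec t, x, a, adot;        // times, scaled input, IC factor and its rate
  mat H1, D1, H2, D2;          // activations and tanh' per layer
  mat H1x, Z2x, H2x;           // input-derivative chain
  rowvec N, Nx;                // raw output and its d/dx
};

static void cache_times(Cache& c, const rowvec& t, double t_max, double t_c) {
  c.t = t;
  c.x = t / t_max;
  c.a = tanh(t / t_c);
  c.adot = (1.0 - square(c.a)) / t_c;
}

static void forward(const Net& net, Cache& c, bool need_deriv) {
  mat Z1 = net.w1 * c.x;
  Z1.each_col() += net.b1;
  c.H1 = tanh(Z1);
  c.D1 = 1.0 - square(c.H1);
  mat Z2 = net.W2 * c.H1;
  Z2.each_col() += net.b2;
  c.H2 = tanh(Z2);
  c.D2 = 1.0 - square(c.H2);
  c.N = net.w3.t() * c.H2 + net.b3;
  if (need_deriv) {
    c.H1x = c.D1.each_col() % net.w1;
    c.Z2x = net.W2 * c.H1x;
    c.H2x = c.D2 % c.Z2x;
    c.Nx = net.w3.t() * c.H2x;
  }
}

// Accumulate d(sum_i p_i * N_i)/d(weights) into g.
static void backprop_N(const Net& net, const Cache& c, const rowvec& p,
                       Net& g) {
  g.b3 += accu(p);
  g.w3 += c.H2 * p.t();
  mat GZ2 = (net.w3 * p) % c.D2;
  g.b2 += sum(GZ2, 1);
  g.W2 += GZ2 * c.H1.t();
  mat GZ1 = (net.W2.t() * GZ2) % c.D1;
  g.b1 += sum(GZ1, 1);
  g.w1 += GZ1 * c.x.t();
}

// Accumulate d(sum_i s_i * Nx_i)/d(weights) into g, where Nx = dN/dx.
static void backprop_Nx(const Net& net, const Cache& c, const rowvec& s,
                        Net& g) {
  mat dd2 = -2.0 * (c.H2 % c.D2);
  mat dd1 = -2.0 * (c.H1 % c.D1);
  g.w3 += c.H2x * s.t();
  mat M1 = c.D2.each_col() % net.w3;  // w3 . d2 per point
  mat M2 = dd2 % c.Z2x;               // w3 . dd2 . z2x per point
  M2.each_col() %= net.w3;
  g.W2 += (M1.each_row() % s) * c.H1x.t() + (M2.each_row() % s) * c.H1.t();
  g.b2 += M2 * s.t();
  mat V = net.W2.t() * M1;
  mat Q = net.W2.t() * M2;
  mat T2 = V % (dd1.each_col() % net.w1) + c.D1 % Q;  // dNx/dz1 per point
  g.b1 += T2 * s.t();
  g.w1 += (V % c.D1) * s.t() + T2 * (s % c.x).t();
}

// Smoothed three-branch ODE right-hand side and its parameter gradients.
static void rhs_terms(const rowvec& t, double cbf, double at, double t1b,
                      double tau, double k, rowvec& f, rowvec& dcbf,
                      rowvec& dat, rowvec& dt1b) {
  rowvec decay = exp(-t / t1b);
  rowvec fdur = cbf * decay % (1.0 - (t - at) / t1b);
  rowvec faft = -(cbf * tau / t1b) * decay;
  rowvec th1 = tanh(k * (t - at));
  rowvec th2 = tanh(k * (t - at - tau));
  rowvec g1 = 0.5 * (1.0 + th1);
  rowvec g2 = 0.5 * (1.0 + th2);
  rowvec g1p = 0.5 * k * (1.0 - square(th1));
  rowvec g2p = 0.5 * k * (1.0 - square(th2));
  f = g1 % (1.0 - g2) % fdur + g2 % faft;
  dcbf = f / cbf;
  rowvec ddur_at = (cbf / t1b) * decay;
  dat = -g1p % (1.0 - g2) % fdur + g1 % g2p % fdur - g2p % faft +
        g1 % (1.0 - g2) % ddur_at;
  rowvec ddur_t1b =
      cbf * decay %
      ((t / (t1b * t1b)) % (1.0 - (t - at) / t1b) + (t - at) / (t1b * t1b));
  rowvec daft_t1b = -(cbf * tau / (t1b * t1b * t1b)) * (decay % (t - t1b));
  dt1b = g1 % (1.0 - g2) % ddur_t1b + g2 % daft_t1b;
}

struct BranchData {
  rowvec y, w;       // scaled data values, data-confidence weights
  Cache col, dat;    // collocation and data-time caches
};

struct BranchGrad {
  Net g;
  double cbf = 0.0, at = 0.0, t1b = 0.0;
};

// One branch's loss contributions and gradients at the current state.
static void branch_pass(const Net& net, BranchData& bd, double cbf, double at,
                        double t1b, double tau, double steepness,
                        double gamma, double t_max, double s_scale,
                        bool want_grads, bool want_param_grads,
                        double& l_ode, double& l_data, BranchGrad& out) {
  forward(net, bd.col, true);
  forward(net, bd.dat, false);
  const double inv_tmax = 1.0 / t_max;
  const uword n = bd.col.t.n_elem, nd = bd.dat.t.n_elem;

  rowvec f, dcbf, dat_g, dt1b;
  rhs_terms(bd.col.t, cbf, at, t1b, tau, steepness, f, dcbf, dat_g, dt1b);
  f /= s_scale;
  rowvec St = bd.col.adot % bd.col.N + bd.col.a % (bd.col.Nx * inv_tmax);
  rowvec r = St - f;
  l_ode = mean(square(r));

  rowvec Sd = bd.dat.a % bd.dat.N;
  rowvec e = Sd - bd.y;
  l_data = mean(bd.w % square(e));

  if (!want_grads) return;
  rowvec uvec = (2.0 / n) * r;
  backprop_N(net, bd.col, uvec % bd.col.adot, out.g);
  backprop_Nx(net, bd.col, (uvec % bd.col.a) * inv_tmax, out.g);
  backprop_N(net, bd.dat, (2.0 * gamma / nd) * (bd.w % e % bd.dat.a), out.g);
  if (want_param_grads) {
    out.cbf = -dot(uvec, dcbf) / s_scale;
    out.at = -dot(uvec, dat_g) / s_scale;
    out.t1b = -dot(uvec, dt1b) / s_scale;
  }
}

// Adam state mirrors the trainable structure.
struct AdamNet {
  Net m, v;
};

static void adam_step_inplace(double& x, double g, double& m, double& v,
                              double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * g * g;
  x -= lr * (m / bc1) / (std::sqrt(v / bc2) + 1e-8);
}

template <typename T>
static void adam_step_arma(T& x, const T& g, T& m, T& v, double lr,
                           double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  x -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}

static void adam_step_net(Net& n, const Net& g, AdamNet& s, double lr,
                          double bc1, double bc2) {
  adam_step_arma(n.w1, g.w1, s.m.w1, s.v.w1, lr, bc1, bc2);
  adam_step_arma(n.b1, g.b1, s.m.b1, s.v.b1, lr, bc1, bc2);
  adam_step_arma(n.W2, g.W2, s.m.W2, s.v.W2, lr, bc1, bc2);
  adam_step_arma(n.b2, g.b2, s.m.b2, s.v.b2, lr, bc1, bc2);
  adam_step_arma(n.w3, g.w3, s.m.w3, s.v.w3, lr, bc1, bc2);
  adam_step_inplace(n.b3, g.b3, s.m.b3, s.v.b3, lr, bc1, bc2);
}

static double clamp(double x, double lo, double hi) {
  return std::min(std::max(x, lo), hi);
}

// [[Rcpp::export]]
List supinn_train_cpp(List branches, arma::rowvec colloc, double tau,
                      double steepness, double gamma, double t_max,
                      double t_c, double s_scale, arma::vec cbf0,
                      arma::vec at0, double t1b0, arma::vec lower,
                      arma::vec upper, arma::ivec tier_iters,
                      arma::vec tier_lr, bool train_params, int log_every) {
  const int nb = branches.size();
  std::vector<Net> nets(nb);
  std::vector<BranchData> bd(nb);
  for (int b = 0; b < nb; ++b) {
    List br = branches[b];
    nets[b] = net_from_list(br["net"]);
    bd[b].y = Rcpp::as<rowvec>(br["values"]) / s_scale;
    bd[b].w = Rcpp::as<rowvec>(br["weights"]);
    cache_times(bd[b].col, colloc, t_max, t_c);
    cache_times(bd[b].dat, Rcpp::as<rowvec>(br["times"]), t_max, t_c);
  }
  vec cbf = cbf0, at = at0;
  double t1b = t1b0;

  std::vector<double> hist_it, hist_l, hist_lode, hist_ldata, hist_cbf,
      hist_at, hist_t1b;
  bool diverged = false;
  int it_total = 0;
  double l_tot = 0.0, lode_tot = 0.0, ldata_tot = 0.0;

  auto log_state = [&](int iter) {
    hist_it.push_back(iter);
    hist_l.push_back(l_tot);
    hist_lode.push_back(lode_tot);
    hist_ldata.push_back(ldata_tot);
    hist_cbf.push_back(cbf(0));
    hist_at.push_back(at(0));
    hist_t1b.push_back(t1b);
  };

  for (int tier = 0; tier < 3 && !diverged; ++tier) {
    const bool upd_params = train_params && tier >= 1;
    const double lr = tier_lr(tier);
    // fresh optimiser moments whenever the trainable set changes
    std::vector<AdamNet> st(nb);
    for (int b = 0; b < nb; ++b) {
      st[b].m = net_zeros_like(nets[b]);
      st[b].v = net_zeros_like(nets[b]);
    }
    vec m_cbf = zeros<vec>(nb), v_cbf = zeros<vec>(nb);
    vec m_at = zeros<vec>(nb), v_at = zeros<vec>(nb);
    double m_t1b = 0.0, v_t1b = 0.0;

    const int iters = tier_iters(tier);
    for (int it = 0; it < iters; ++it) {
      l_tot = lode_tot = ldata_tot = 0.0;
      std::vector<BranchGrad> gr(nb);
      double g_t1b = 0.0;
      for (int b = 0; b < nb; ++b) {
        gr[b].g = net_zeros_like(nets[b]);
        double lo = 0.0, ld = 0.0;
        branch_pass(nets[b], bd[b], cbf(b), at(b), t1b, tau, steepness,
                    gamma, t_max, s_scale, true, upd_params, lo, ld, gr[b]);
        lode_tot += lo;
        ldata_tot += ld;
        g_t1b += gr[b].t1b;
      }
      l_tot = lode_tot + gamma * ldata_tot;
      if (!std::isfinite(l_tot)) {
        diverged = true;
        log_state(it_total);
        break;
      }
      if (it_total % log_every == 0) log_state(it_total);

      const double bc1 = 1.0 - std::pow(0.9, it + 1);
      const double bc2 = 1.0 - std::pow(0.999, it + 1);
      for (int b = 0; b < nb; ++b) {
        adam_step_net(nets[b], gr[b].g, st[b], lr, bc1, bc2);
      }
      if (upd_params) {
        for (int b = 0; b < nb; ++b) {
          adam_step_inplace(cbf(b), gr[b].cbf, m_cbf(b), v_cbf(b), lr, bc1,
                            bc2);
          adam_step_inplace(at(b), gr[b].at, m_at(b), v_at(b), lr, bc1, bc2);
          cbf(b) = clamp(cbf(b), lower(0), upper(0));
          at(b) = clamp(at(b), lower(1), upper(1));
        }
        adam_step_inplace(t1b, g_t1b, m_t1b, v_t1b, lr, bc1, bc2);
        t1b = clamp(t1b, lower(2), upper(2));
      }
      ++it_total;
    }
  }

  // final loss at the trained state
  if (!diverged) {
    l_tot = lode_tot = ldata_tot = 0.0;
    for (int b = 0; b < nb; ++b) {
      BranchGrad dummy;
      double lo = 0.0, ld = 0.0;
      branch_pass(nets[b], bd[b], cbf(b), at(b), t1b, tau, steepness, gamma,
                  t_max, s_scale, false, false, lo, ld, dummy);
      lode_tot += lo;
      ldata_tot += ld;
    }
    l_tot = lode_tot + gamma * ldata_tot;
    log_state(it_total);
  }

  List out_nets(nb);
  for (int b = 0; b < nb; ++b) out_nets[b] = net_to_list(nets[b]);
  mat history(hist_it.size(), 7);
  for (uword i = 0; i < hist_it.size(); ++i) {
    history(i, 0) = hist_it[i];
    history(i, 1) = hist_l[i];
    history(i, 2) = hist_lode[i];
    history(i, 3) = hist_ldata[i];
    history(i, 4) = hist_cbf[i];
    history(i, 5) = hist_at[i];
    history(i, 6) = hist_t1b[i];
  }
  return List::create(
      Rcpp::Named("cbf") = cbf, Rcpp::Named("at") = at,
      Rcpp::Named("t1b") = t1b, Rcpp::Named("nets") = out_nets,
      Rcpp::Named("history") = history, Rcpp::Named("diverged") = diverged,
      Rcpp::Named("loss") = l_tot, Rcpp::Named("loss_ode") = lode_tot,
      Rcpp::Named("loss_data") = ldata_tot,
      Rcpp::Named("iterations") = it_total);
}

// Loss components and full analytic gradient for one branch at a fixed
// state; used to validate the gradients against finite differences.
// [[Rcpp::export]]
List pinn_loss_grad_cpp(List net_list, arma::rowvec times, arma::rowvec values,
                        arma::rowvec weights, arma::rowvec colloc, double cbf,
                        double at, double t1b, double tau, double steepness,
                        double gamma, double t_max, double t_c,
                        double s_scale) {
  Net net = net_from_list(net_list);
  BranchData bdx;
  bdx.y = values / s_scale;
  bdx.w = weights;
  cache_times(bdx.col, colloc, t_max, t_c);
  cache_times(bdx.dat, times, t_max, t_c);
  BranchGrad g;
  g.g = net_zeros_like(net);
  double lo = 0.0, ld = 0.0;
  branch_pass(net, bdx, cbf, at, t1b, tau, steepness, gamma, t_max, s_scale,
              true, true, lo, ld, g);
  return List::create(
      Rcpp::Named("loss") = lo + gamma * ld, Rcpp::Named("loss_ode") = lo,
      Rcpp::Named("loss_data") = ld, Rcpp::Named("grad_net") = net_to_list(g.g),
      Rcpp::Named("grad_cbf") = g.cbf, Rcpp::Named("grad_at") = g.at,
      Rcpp::Named("grad_t1b") = g.t1b);
}

// Network prediction with the hard initial condition, plus dS/dt; used by
// the R-level predict path so compiled and interpreted forward passes agree.
// [[Rcpp::export]]
List pinn_forward_cpp(List net_list, arma::rowvec t, double t_max, double t_c,
                      double s_scale) {
  Net net = net_from_list(net_list);
  Cache c;
  cache_times(c, t, t_max, t_c);
  forward(net, c, true);
  rowvec S = (c.a % c.N) * s_scale;
  rowvec St = (c.adot % c.N + c.a % (c.Nx / t_max)) * s_scale;
  return List::create(Rcpp::Named("value") = S, Rcpp::Named("deriv") = St);
}
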