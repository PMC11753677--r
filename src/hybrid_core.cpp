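// Core numerics for the hybrid dynamical system x' = a*x + NN(x):
// a tiny tanh MLP, its Jacobians w.r.t. state and weights, and fixed-step
// RK4 integration with forward-mode sensitivities (discretize-then-optimize:
// gradients are exact derivatives of the discrete solution).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct MLP {
  std::vector<mat> W;
  std::vector<vec> b;
  int d;       // input = output dimension
  int nlayers; // number of weight layers
};

// theta packing: for each layer l: W_l column-major, then b_l
MLP unpack(const vec& theta, const Rcpp::IntegerVector& layers) {
  MLP m;
  m.nlayers = layers.size() - 1;
  m.d = layers[0];
  int pos = 0;
  for (int l = 0; l < m.nlayers; ++l) {
    int in = layers[l], out = layers[l + 1];
    m.W.push_back(reshape(theta.subvec(pos, pos + in * out - 1), out, in));
    pos += in * out;
    m.b.push_back(theta.subvec(pos, pos + out - 1));
    pos += out;
  }
  return m;
}

int n_params(const Rcpp::IntegerVector& layers) {
  int p = 0;
  for (int l = 0; l + 1 < layers.size(); ++l)
    p += layers[l] * layers[l + 1] + layers[l + 1];
  return p;
}

// forward pass; hidden activations (tanh outputs) cached in hs
vec mlp_forward(const MLP& m, const vec& x, std::vector<vec>& hs) {
  hs.clear();
  vec h = x;
  for (int l = 0; l < m.nlayers - 1; ++l) {
    h = tanh(m.W[l] * h + m.b[l]);
    hs.push_back(h);
  }
  return m.W[m.nlayers - 1] * h + m.b[m.nlayers - 1];
}

// Jacobian of the network output w.r.t. its input, given cached activations
mat mlp_jac_x(const MLP& m, const std::vector<vec>& hs) {
  mat J = m.W[m.nlayers - 1];
  for (int l = m.nlayers - 2; l >= 0; --l) {
    J = J * diagmat(1.0 - square(hs[l]));
    J = J * m.W[l];
  }
  return J;
}

// Jacobian of the network output w.r.t. the packed weights (d x P)
mat mlp_jac_theta(const MLP& m, const vec& x, const std::vector<vec>& hs,
                  int P) {
  int d = m.d;
  mat J(d, P, fill::zeros);
  // G_l: sensitivity of output to post-activation of layer l
  // built top-down; for the output layer the weight gradients are direct
  std::vector<mat> G(m.nlayers); // G[l] = d out / d z_l (pre-activation), hidden layers only
  // positions of each layer's block in theta
  std::vector<int> wpos(m.nlayers), bpos(m.nlayers);
  {
    int pos = 0;
    for (int l = 0; l < m.nlayers; ++l) {
      int in = (l == 0) ? d : (int)hs[l - 1].n_elem;
      int out = (l == m.nlayers - 1) ? d : (int)hs[l].n_elem;
      wpos[l] = pos; pos += in * out;
      bpos[l] = pos; pos += out;
    }
  }
  // output layer: out = W h + b
  {
    int l = m.nlayers - 1;
    const vec& input = hs[l - 1];
    int in = input.n_elem;
    for (int j = 0; j < in; ++j)
      for (int i = 0; i < d; ++i)
        J(i, wpos[l] + j * d + i) = input(j);
    for (int i = 0; i < d; ++i) J(i, bpos[l] + i) = 1.0;
  }
  // hidden layers
  mat chain = m.W[m.nlayers - 1]; // d out / d h_{L-1}
  for (int l = m.nlayers - 2; l >= 0; --l) {
    mat Gl = chain * diagmat(1.0 - square(hs[l])); // d out / d z_l
    const vec input = (l == 0) ? x : hs[l - 1];
    int in = input.n_elem, out = hs[l].n_elem;
    for (int j = 0; j < in; ++j)
      for (int k = 0; k < out; ++k)
        for (int i = 0; i < d; ++i)
          J(i, wpos[l] + j * out + k) = Gl(i, k) * input(j);
    for (int k = 0; k < out; ++k)
      for (int i = 0; i < d; ++i)
        J(i, bpos[l] + k) = Gl(i, k);
    if (l > 0) chain = Gl * m.W[l];
  }
  return J;
}

// hybrid RHS and its Jacobians
inline vec hybrid_f(const MLP& m, const vec& a, const vec& x,
                    std::vector<vec>& hs) {
  return a % x + mlp_forward(m, x, hs);
}

const double STATE_BOUND = 1e6;

// one RK4 step of the state, optionally with forward sensitivities
// returns false on numerical blow-up
bool rk4_step(const MLP& m, const vec& a, double h, vec& x, mat* S, int P) {
  std::vector<vec> hs;
  auto eval = [&](const vec& xi, vec& fi, mat& Jxi, mat& Jti) {
    fi = hybrid_f(m, a, xi, hs);
    if (S) {
      Jxi = diagmat(a) + mlp_jac_x(m, hs);
      Jti = mlp_jac_theta(m, xi, hs, P);
    }
  };
  vec k1, k2, k3, k4;
  mat Jx1, Jt1, Jx2, Jt2, Jx3, Jt3, Jx4, Jt4;
  eval(x, k1, Jx1, Jt1);
  vec x2 = x + 0.5 * h * k1;
  mat S2;
  if (S) S2 = *S + 0.5 * h * (Jx1 * (*S) + Jt1);
  eval(x2, k2, Jx2, Jt2);
  vec x3 = x + 0.5 * h * k2;
  mat S3;
  if (S) S3 = *S + 0.5 * h * (Jx2 * S2 + Jt2);
  eval(x3, k3, Jx3, Jt3);
  vec x4 = x + h * k3;
  mat S4;
  if (S) S4 = *S + h * (Jx3 * S3 + Jt3);
  eval(x4, k4, Jx4, Jt4);
  x += (h / 6.0) * (k1 + 2 * k2 + 2 * k3 + k4);
  if (S)
    *S += (h / 6.0) * ((Jx1 * (*S) + Jt1) + 2 * (Jx2 * S2 + Jt2) +
                       2 * (Jx3 * S3 + Jt3) + (Jx4 * S4 + Jt4));
  return x.is_finite() && max(abs(x)) < STATE_BOUND;
}

} // namespace

// Evaluate NN(x) on rows of X
// [[Rcpp::export]]
arma::mat cpp_nn_eval(const arma::vec& theta, const Rcpp::IntegerVector& layers,
                      const arma::mat& X) {
  MLP m = unpack(theta, layers);
  mat out(X.n_rows, m.d);
  std::vector<vec> hs;
  for (uword i = 0; i < X.n_rows; ++i)
    out.row(i) = mlp_forward(m, X.row(i).t(), hs).t();
  return out;
}

// Simulate the hybrid system on a time grid (fixed-step RK4 with
// `substeps` steps per grid interval). Returns list(states, ok).
// [[Rcpp::export]]
Rcpp::List cpp_sim_hybrid(const arma::vec& theta,
                          const Rcpp::IntegerVector& layers,
                          const arma::vec& a, const arma::vec& x0,
                          const arma::vec& times, int substeps) {
  MLP m = unpack(theta, layers);
  int T = times.n_elem;
  mat states(T, m.d, fill::value(datum::nan));
  vec x = x0;
  states.row(0) = x.t();
  bool ok = x.is_finite();
  for (int j = 1; j < T && ok; ++j) {
    double h = (times(j) - times(j - 1)) / substeps;
    for (int s = 0; s < substeps && ok; ++s)
      ok = rk4_step(m, a, h, x, nullptr, 0);
    if (ok) states.row(j) = x.t();
  }
  return Rcpp::List::create(Rcpp::Named("states") = states,
                            Rcpp::Named("ok") = ok);
}

// Mean loss and gradient over a batch of windows.
// Y: cube (w x d x n_windows), all windows share the relative time grid.
// Each window is simulated from its own first observed row; loss is the
// MSE over all w points and d species, batch loss the mean over windows.
// Windows that blow up are skipped (counted in n_failed).
// [[Rcpp::export]]
Rcpp::List cpp_batch_grad(const arma::vec& theta,
                          const Rcpp::IntegerVector& layers,
                          const arma::vec& a, const arma::vec& times,
                          const arma::cube& Y, int substeps) {
  MLP m = unpack(theta, layers);
  int P = n_params(layers);
  int w = Y.n_rows, d = Y.n_cols, nw = Y.n_slices;
  vec grad(P, fill::zeros);
  double loss = 0;
  int nfail = 0;
  for (int s = 0; s < nw; ++s) {
    vec x = Y.slice(s).row(0).t();
    mat S(d, P, fill::zeros);
    vec g(P, fill::zeros);
    double l = 0;
    bool ok = x.is_finite();
    for (int j = 1; j < w && ok; ++j) {
      double h = (times(j) - times(j - 1)) / substeps;
      for (int st = 0; st < substeps && ok; ++st)
        ok = rk4_step(m, a, h, x, &S, P);
      if (!ok) break;
      vec r = x - Y.slice(s).row(j).t();
      l += dot(r, r);
      g += (2.0 / (w * d)) * (S.t() * r);
    }
    if (!ok || !g.is_finite()) { ++nfail; continue; }
    loss += l / (w * d);
    grad += g;
  }
  int used = nw - nfail;
  if (used > 0) { loss /= used; grad /= used; }
  else { loss = datum::inf; grad.zeros(); }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("n_failed") = nfail);
}

// Mean per-sample MSE over validation trajectories (cube T x d x n).
// Each sample is simulated from its own first observation over the full
// grid; failed simulations contribute +Inf.
// [[Rcpp::export]]
double cpp_val_loss(const arma::vec& theta, const Rcpp::IntegerVector& layers,
                    const arma::vec& a, const arma::vec& times,
                    const arma::cube& Y, int substeps) {
  MLP m = unpack(theta, layers);
  int T = Y.n_rows, d = Y.n_cols, n = Y.n_slices;
  double total = 0;
  for (int s = 0; s < n; ++s) {
    vec x = Y.slice(s).row(0).t();
    double l = 0;
    bool ok = x.is_finite();
    for (int j = 1; j < T && ok; ++j) {
      double h = (times(j) - times(j - 1)) / substeps;
      for (int st = 0; st < substeps && ok; ++st)
        ok = rk4_step(m, a, h, x, nullptr, 0);
      if (!ok) break;
      vec r = x - Y.slice(s).row(j).t();
      l += dot(r, r);
    }
    if (!ok) return datum::inf;
    total += l / (T * d);
  }
  return total / n;
}
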