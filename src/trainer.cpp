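// Training loop for the Lipschitz-constrained critic network.
//
// Architecture: fully connected layers, GroupSort activations between them,
// spectral normalization of every weight matrix (power iteration with
// persistent left vectors, refreshed every epoch). The loss is
//   L = L_m + lambda * L_b,
//   L_m = -sum_mu w f + sum_nu w f            (metric loss, -L_m -> rho_F)
//   L_b = sum_k p_k max(|f_k| - M, 0)^2,      p_k = w_k / ||its measure||_TV
// optimized with Adam. Training runs in chunks; the adaptive lambda protocol
// lives in R (adapt_lambda) and calls back between chunks, so the schedule
// has a single implementation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;

static void groupsort_inplace(arma::mat& H, arma::imat& perm, int gs) {
  const int h = H.n_rows, n = H.n_cols;
  if (gs <= 1) { for (int c = 0; c < n; ++c) for (int r = 0; r < h; ++r) perm(r, c) = r; return; }
  std::vector<int> idx(gs);
  for (int c = 0; c < n; ++c) {
    double* col = H.colptr(c);
    for (int g0 = 0; g0 < h; g0 += gs) {
      if (gs == 2) {
        if (col[g0] > col[g0 + 1]) {
          std::swap(col[g0], col[g0 + 1]);
          perm(g0, c) = g0 + 1; perm(g0 + 1, c) = g0;
        } else { perm(g0, c) = g0; perm(g0 + 1, c) = g0 + 1; }
      } else {
        for (int k = 0; k < gs; ++k) idx[k] = g0 + k;
        std::sort(idx.begin(), idx.end(),
                  [&](int a, int b) { return col[a] < col[b]; });
        double tmp[64];
        for (int k = 0; k < gs; ++k) tmp[k] = col[idx[k]];
        for (int k = 0; k < gs; ++k) { col[g0 + k] = tmp[k]; perm(g0 + k, c) = idx[k]; }
      }
    }
  }
}

struct AdamState {
  arma::mat m, v;
  void init(const arma::mat& shape) {
    m.zeros(shape.n_rows, shape.n_cols);
    v.zeros(shape.n_rows, shape.n_cols);
  }
};

static void adam_step(arma::mat& theta, const arma::mat& g, AdamState& st,
                      double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.m = b1 * st.m + (1 - b1) * g;
  st.v = b2 * st.v + (1 - b2) * (g % g);
  double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  theta -= lr * (st.m / c1) / (arma::sqrt(st.v / c2) + eps);
}

// [[Rcpp::export]]
List train_chunk_cpp(List net, const arma::mat& X, const arma::vec& w,
                     const arma::ivec& memb, double tv0, double tv1,
                     double lambda, double M, const arma::vec& lrs,
                     int batch, int group_size, bool use_bound, int seed) {
  List Wl = net["W"], bl = net["b"], ul = net["u"];
  List mWl = net["mW"], vWl = net["vW"], mbl = net["mb"], vbl = net["vb"];
  int t_adam = as<int>(net["t"]);
  const int L = Wl.size();
  std::vector<arma::mat> W(L);
  std::vector<arma::vec> b(L), u(L);
  std::vector<AdamState> aW(L), ab(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(Wl[l]);
    b[l] = as<arma::vec>(bl[l]);
    u[l] = as<arma::vec>(ul[l]);
    aW[l].m = as<arma::mat>(mWl[l]); aW[l].v = as<arma::mat>(vWl[l]);
    ab[l].m = as<arma::mat>(mbl[l]); ab[l].v = as<arma::mat>(vbl[l]);
  }

  const int n = X.n_cols;
  const int epochs = lrs.n_elem;
  const bool full_batch = (batch <= 0 || batch >= n);
  std::mt19937 rng(static_cast<unsigned>(seed));

  arma::mat trace(epochs, 2);
  std::vector<arma::mat> What(L), H(L + 1);
  std::vector<arma::vec> vvec(L);
  std::vector<double> sigma(L);
  std::vector<arma::imat> perm(L);
  arma::uvec all_idx = arma::regspace<arma::uvec>(0, n - 1);

  for (int ep = 0; ep < epochs; ++ep) {
    // spectral normalization: two power-iteration refreshes per epoch
    for (int l = 0; l < L; ++l) {
      for (int it = 0; it < 2; ++it) {
        arma::vec vv = W[l].t() * u[l];
        double nv = arma::norm(vv); if (nv > 0) vv /= nv;
        arma::vec uu = W[l] * vv;
        double nu_ = arma::norm(uu); if (nu_ > 0) uu /= nu_;
        u[l] = uu; vvec[l] = vv;
      }
      sigma[l] = arma::as_scalar(u[l].t() * W[l] * vvec[l]);
      What[l] = (sigma[l] > 1e-12) ? W[l] / sigma[l] : W[l];
    }

    // batch selection
    arma::uvec idx;
    if (full_batch) idx = all_idx;
    else {
      idx.set_size(batch);
      std::uniform_int_distribution<int> unif(0, n - 1);
      for (int k = 0; k < batch; ++k) idx[k] = unif(rng); // with replacement
    }
    const int nb = idx.n_elem;

    // per-measure scaling keeps the minibatch integral estimates unbiased:
    // each integral is total_mass * weighted mean of f over the batch draw
    double bw0 = 0, bw1 = 0;
    for (int k = 0; k < nb; ++k) (memb[idx[k]] == 0 ? bw0 : bw1) += w[idx[k]];
    double s0 = (bw0 > 0) ? tv0 / bw0 : 0.0;
    double s1 = (bw1 > 0) ? tv1 / bw1 : 0.0;

    // forward
    H[0] = X.cols(idx);
    for (int l = 0; l < L; ++l) {
      H[l + 1] = What[l] * H[l];
      H[l + 1].each_col() += b[l];
      if (l < L - 1) {
        perm[l].set_size(H[l + 1].n_rows, nb);
        groupsort_inplace(H[l + 1], perm[l], group_size);
      }
    }
    arma::rowvec f = H[L].row(0);

    // losses and gradient w.r.t. f
    double Lm = 0, Lb = 0;
    arma::rowvec G(nb);
    for (int k = 0; k < nb; ++k) {
      int j = idx[k];
      double scale = (memb[j] == 0) ? s0 : s1;
      double sign_m = (memb[j] == 0) ? -1.0 : 1.0;
      double cw = sign_m * w[j] * scale;
      Lm += cw * f[k];
      double g = cw;
      if (use_bound) {
        double tv = (memb[j] == 0) ? tv0 : tv1;
        if (tv > 0) {
          double ex = std::fabs(f[k]) - M;
          if (ex > 0) {
            double pk = w[j] * scale / tv;
            Lb += pk * ex * ex;
            g += lambda * pk * 2.0 * ex * (f[k] > 0 ? 1.0 : -1.0);
          }
        }
      }
      G[k] = g;
    }
    if (!std::isfinite(Lm) || !std::isfinite(Lb))
      stop("training diverged: non-finite loss at epoch %d", ep + 1);
    trace(ep, 0) = Lm;
    trace(ep, 1) = Lb;

    // backward
    arma::mat Gm = arma::mat(G);
    ++t_adam;
    std::vector<arma::mat> gW(L);
    std::vector<arma::vec> gb(L);
    for (int l = L - 1; l >= 0; --l) {
      gW[l] = Gm * H[l].t();
      gb[l] = arma::sum(Gm, 1);
      if (l > 0) {
        Gm = What[l].t() * Gm;
        // route gradients through the GroupSort permutation of layer l-1
        arma::mat Gr(Gm.n_rows, Gm.n_cols);
        for (arma::uword c = 0; c < Gm.n_cols; ++c)
          for (arma::uword r = 0; r < Gm.n_rows; ++r)
            Gr(perm[l - 1](r, c), c) = Gm(r, c);
        Gm = Gr;
      }
    }
    // gradient through the normalization: What = W / sigma, dsigma = u v^T
    for (int l = 0; l < L; ++l) {
      arma::mat g = gW[l];
      if (sigma[l] > 1e-12) {
        double inner = arma::accu(g % What[l]);
        g = (g - inner * (u[l] * vvec[l].t())) / sigma[l];
      }
      adam_step(W[l], g, aW[l], lrs[ep], t_adam);
      arma::mat bmat(b[l].memptr(), b[l].n_elem, 1, false);
      arma::mat gbm(gb[l].memptr(), gb[l].n_elem, 1, false);
      adam_step(bmat, gbm, ab[l], lrs[ep], t_adam);
    }
  }

  // final f on the full data with the current (power-iteration) normalization
  arma::mat Hf = X;
  for (int l = 0; l < L; ++l) {
    Hf = What[l] * Hf;
    Hf.each_col() += b[l];
    if (l < L - 1) {
      arma::imat pm(Hf.n_rows, Hf.n_cols);
      groupsort_inplace(Hf, pm, group_size);
    }
  }

  for (int l = 0; l < L; ++l) {
    Wl[l] = W[l]; bl[l] = b[l]; ul[l] = u[l];
    mWl[l] = aW[l].m; vWl[l] = aW[l].v; mbl[l] = ab[l].m; vbl[l] = ab[l].v;
  }
  net["W"] = Wl; net["b"] = bl; net["u"] = ul;
  net["mW"] = mWl; net["vW"] = vWl; net["mb"] = mbl; net["vb"] = vbl;
  net["t"] = t_adam;
  return List::create(_["net"] = net, _["trace"] = trace,
                      _["f_full"] = arma::vec(Hf.row(0).t()));
}
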