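// Minibatch ADAM training loop for the fully-connected tanh surrogate.
// Hot path only: forward, backprop, ADAM update and validation scoring.
// Layer layout matches the R side (W[k]: n_in x n_out, bias row-added),
// so nets trained here are consumed directly by net_forward() and the
// R-level backprop used for inverse-problem gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Layers {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

arma::mat forward(const Layers& L, const arma::mat& X,
                  std::vector<arma::mat>* cache = nullptr) {
  arma::mat H = X;
  const int nl = static_cast<int>(L.W.size());
  if (cache) { cache->clear(); cache->push_back(H); }
  for (int k = 0; k < nl; ++k) {
    H = H * L.W[k];
    H.each_row() += L.b[k].t();
    if (k < nl - 1) H = arma::tanh(H);
    if (cache) cache->push_back(H);
  }
  return H;
}

// mean relative error (%) in raw stress space
double val_rel_err(const Layers& L, const arma::mat& Xval,
                   const arma::mat& rawYval, const arma::vec& out_mean,
                   const arma::vec& out_sd) {
  arma::mat ys = forward(L, Xval);
  ys.each_row() %= out_sd.t();
  ys.each_row() += out_mean.t();
  arma::mat pred = arma::exp10(ys);
  return 100.0 * arma::accu(arma::abs(pred - rawYval) / arma::abs(rawYval)) /
         static_cast<double>(rawYval.n_elem);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".rp_mlp_train_cpp")]]
List rp_mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                      const arma::mat& Xval, const arma::mat& rawYval,
                      const arma::vec& out_mean, const arma::vec& out_sd,
                      List W0, List b0,
                      double lr0, double l2, int n_epochs, int batch_size,
                      double beta1, double beta2,
                      double lr_decay, int lr_decay_every,
                      int patience, unsigned int shuffle_seed,
                      bool restore_best, bool verbose) {
  const int n = X.n_rows;
  const int nl = W0.size();
  Layers L, best;
  std::vector<arma::mat> mW(nl), vW(nl);
  std::vector<arma::vec> mb(nl), vb(nl);
  for (int k = 0; k < nl; ++k) {
    L.W.push_back(as<arma::mat>(W0[k]));
    L.b.push_back(as<arma::vec>(b0[k]));
    mW[k].zeros(L.W[k].n_rows, L.W[k].n_cols);
    vW[k].zeros(L.W[k].n_rows, L.W[k].n_cols);
    mb[k].zeros(L.b[k].n_elem);
    vb[k].zeros(L.b[k].n_elem);
  }
  best = L;
  std::mt19937 rng(shuffle_seed);
  arma::uvec ord = arma::regspace<arma::uvec>(0, n - 1);
  double best_val = arma::datum::inf;
  int stall = 0;
  long t = 0;
  std::vector<double> hist_loss, hist_val;
  std::vector<arma::mat> H;
  for (int ep = 0; ep < n_epochs; ++ep) {
    const double lr = lr0 * std::pow(lr_decay, ep / lr_decay_every);
    std::shuffle(ord.begin(), ord.end(), rng);
    double ep_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n) - 1;
      arma::uvec idx = ord.subvec(start, stop);
      arma::mat Xb = X.rows(idx);
      arma::mat Yb = Y.rows(idx);
      forward(L, Xb, &H);
      arma::mat resid = H.back() - Yb;
      const double loss = arma::accu(arma::square(resid)) / resid.n_elem;
      if (!std::isfinite(loss))
        return List::create(_["diverged"] = true);
      ep_loss += loss;
      ++nb;
      arma::mat delta = (2.0 / resid.n_elem) * resid;
      ++t;
      const double c1 = 1.0 - std::pow(beta1, t);
      const double c2 = 1.0 - std::pow(beta2, t);
      for (int k = nl - 1; k >= 0; --k) {
        arma::mat gW = H[k].t() * delta;
        if (l2 > 0) gW += (2.0 * l2) * L.W[k];
        arma::vec gb = arma::sum(delta, 0).t();
        if (k > 0)
          delta = (delta * L.W[k].t()) % (1.0 - arma::square(H[k]));
        mW[k] = beta1 * mW[k] + (1.0 - beta1) * gW;
        vW[k] = beta2 * vW[k] + (1.0 - beta2) * arma::square(gW);
        L.W[k] -= lr * (mW[k] / c1) / (arma::sqrt(vW[k] / c2) + 1e-8);
        mb[k] = beta1 * mb[k] + (1.0 - beta1) * gb;
        vb[k] = beta2 * vb[k] + (1.0 - beta2) * arma::square(gb);
        L.b[k] -= lr * (mb[k] / c1) / (arma::sqrt(vb[k] / c2) + 1e-8);
      }
    }
    const double ve = val_rel_err(L, Xval, rawYval, out_mean, out_sd);
    hist_loss.push_back(ep_loss / nb);
    hist_val.push_back(ve);
    if (std::isfinite(ve) && ve < best_val - 1e-10) {
      best_val = ve;
      best = L;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
    if (verbose && (ep + 1) % 5 == 0)
      Rcout << "  epoch " << (ep + 1) << ": loss " << ep_loss / nb
            << ", val rel err " << ve << "%\n";
    Rcpp::checkUserInterrupt();
  }
  const Layers& ret = restore_best ? best : L;
  List Wout(nl), bout(nl);
  for (int k = 0; k < nl; ++k) {
    Wout[k] = wrap(ret.W[k]);
    bout[k] = wrap(ret.b[k]);
  }
  return List::create(_["diverged"] = false, _["W"] = Wout, _["b"] = bout,
                      _["val_err"] = best_val,
                      _["loss_history"] = hist_loss,
                      _["val_history"] = hist_val);
}
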