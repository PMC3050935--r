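// Scaled (normalized-alpha) forward-backward, Viterbi and multi-sequence
// Baum-Welch for discrete-emission HMMs. Observations arrive 0-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Scaled forward pass. Fills alpha (T x N, row-normalized) and c (length T,
// per-step normalizers). Returns false if some step has zero total mass
// (sequence impossible under the model).
static bool forward_scaled(const arma::mat& A, const arma::mat& B,
                           const arma::vec& pi, const arma::ivec& obs,
                           arma::mat& alpha, arma::vec& c) {
  const arma::uword T = obs.n_elem, N = A.n_rows;
  alpha.set_size(T, N);
  c.set_size(T);
  arma::rowvec a = pi.t() % B.col(obs[0]).t();
  c[0] = arma::accu(a);
  if (c[0] <= 0.0) return false;
  a /= c[0];
  alpha.row(0) = a;
  for (arma::uword t = 1; t < T; ++t) {
    a = (a * A) % B.col(obs[t]).t();
    c[t] = arma::accu(a);
    if (c[t] <= 0.0) return false;
    a /= c[t];
    alpha.row(t) = a;
  }
  return true;
}

// [[Rcpp::export(name = ".loglik_cpp")]]
double loglik_cpp(const arma::mat& A, const arma::mat& B,
                  const arma::vec& pi, const arma::ivec& obs) {
  arma::mat alpha;
  arma::vec c;
  if (!forward_scaled(A, B, pi, obs, alpha, c)) return R_NegInf;
  return arma::accu(arma::log(c));
}

// Scaled backward pass given the forward normalizers.
static void backward_scaled(const arma::mat& A, const arma::mat& B,
                            const arma::ivec& obs, const arma::vec& c,
                            arma::mat& beta) {
  const arma::uword T = obs.n_elem, N = A.n_rows;
  beta.set_size(T, N);
  beta.row(T - 1).ones();
  for (arma::uword t = T - 1; t > 0; --t) {
    arma::vec b = A * (B.col(obs[t]) % beta.row(t).t());
    beta.row(t - 1) = b.t() / c[t];
  }
}

// [[Rcpp::export(name = ".forward_backward_cpp")]]
List forward_backward_cpp(const arma::mat& A, const arma::mat& B,
                          const arma::vec& pi, const arma::ivec& obs) {
  const arma::uword T = obs.n_elem, N = A.n_rows;
  arma::mat alpha, beta;
  arma::vec c;
  if (!forward_scaled(A, B, pi, obs, alpha, c))
    return List::create(_["ok"] = false);
  backward_scaled(A, B, obs, c, beta);
  arma::mat gamma = alpha % beta;  // rows already sum to 1 under this scaling
  arma::cube xi(N, N, T > 1 ? T - 1 : 0);
  for (arma::uword t = 0; t + 1 < T; ++t) {
    arma::mat x = (alpha.row(t).t() * (B.col(obs[t + 1]) % beta.row(t + 1).t()).t()) % A;
    xi.slice(t) = x / c[t + 1];
  }
  return List::create(_["ok"] = true, _["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = arma::accu(arma::log(c)));
}

// Viterbi with ties broken toward the lower state index.
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(const arma::mat& A, const arma::mat& B,
                 const arma::vec& pi, const arma::ivec& obs) {
  const arma::uword T = obs.n_elem, N = A.n_rows;
  arma::mat delta(T, N);
  arma::umat psi(T, N, arma::fill::zeros);
  delta.row(0) = arma::log(pi.t() % B.col(obs[0]).t());
  arma::mat logA = arma::log(A);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < N; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      arma::uword arg = 0;
      for (arma::uword i = 1; i < N; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }  // strict: lowest index wins ties
      }
      delta(t, j) = best + std::log(B(j, obs[t]));
      psi(t, j) = arg;
    }
  }
  double best = delta(T - 1, 0);
  arma::uword arg = 0;
  for (arma::uword i = 1; i < N; ++i)
    if (delta(T - 1, i) > best) { best = delta(T - 1, i); arg = i; }
  if (!std::isfinite(best))
    return List::create(_["ok"] = false);
  arma::ivec path(T);
  path[T - 1] = static_cast<int>(arg);
  for (arma::uword t = T - 1; t > 0; --t) {
    arg = psi(t, arg);
    path[t - 1] = static_cast<int>(arg);
  }
  return List::create(_["ok"] = true, _["path"] = path, _["score"] = best);
}

// Multi-sequence Baum-Welch. Sufficient statistics are pooled over all
// sequences; pi is re-estimated from position-1 posteriors. Exact zeros in
// the re-estimated emission rows are floored at floor_eps and the row
// renormalized, so no emission probability becomes absorbing.
// [[Rcpp::export(name = ".baum_welch_cpp")]]
List baum_welch_cpp(arma::mat A, arma::mat B, arma::vec pi,
                    const List& obs_list, double tol, int max_iter,
                    double floor_eps) {
  const arma::uword N = A.n_rows, M = B.n_cols;
  const int S = obs_list.size();
  std::vector<arma::ivec> seqs(S);
  for (int s = 0; s < S; ++s) seqs[s] = as<arma::ivec>(obs_list[s]);

  std::vector<double> traj;
  traj.reserve(std::min(max_iter + 1, 1024));
  bool converged = false;
  int n_floor = 0;
  double ll_prev = R_NegInf;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    arma::mat trans_num(N, N, arma::fill::zeros);
    arma::mat emit_num(N, M, arma::fill::zeros);
    arma::vec pi_num(N, arma::fill::zeros);
    arma::vec occ(N, arma::fill::zeros);       // sum gamma over t = 1..T-1
    arma::vec occ_all(N, arma::fill::zeros);   // sum gamma over all t
    double ll = 0.0;

    for (int s = 0; s < S; ++s) {
      const arma::ivec& obs = seqs[s];
      const arma::uword T = obs.n_elem;
      arma::mat alpha, beta;
      arma::vec c;
      if (!forward_scaled(A, B, pi, obs, alpha, c))
        stop("a training sequence has zero probability under the current model");
      backward_scaled(A, B, obs, c, beta);
      ll += arma::accu(arma::log(c));
      arma::mat gamma = alpha % beta;
      pi_num += gamma.row(0).t();
      for (arma::uword t = 0; t < T; ++t) {
        emit_num.col(obs[t]) += gamma.row(t).t();
        occ_all += gamma.row(t).t();
        if (t + 1 < T) occ += gamma.row(t).t();
      }
      for (arma::uword t = 0; t + 1 < T; ++t) {
        arma::mat x = (alpha.row(t).t() * (B.col(obs[t + 1]) % beta.row(t + 1).t()).t()) % A;
        trans_num += x / c[t + 1];
      }
    }

    traj.push_back(ll);
    if (it > 1 && std::abs(ll - ll_prev) < tol * std::abs(ll_prev)) {
      converged = true;
      break;  // keep the parameters that produced this log-likelihood
    }
    ll_prev = ll;

    // M-step
    for (arma::uword i = 0; i < N; ++i) {
      if (occ[i] > 0.0) A.row(i) = trans_num.row(i) / occ[i];
      // a state with zero expected occupancy keeps its previous row
      if (occ_all[i] > 0.0) {
        arma::rowvec b = emit_num.row(i) / occ_all[i];
        arma::uvec z = arma::find(b <= 0.0);
        if (z.n_elem > 0) {
          n_floor += static_cast<int>(z.n_elem);
          b.elem(z).fill(floor_eps);
          b /= arma::accu(b);
        }
        B.row(i) = b;
      }
      A.row(i) /= arma::accu(A.row(i));
    }
    pi = pi_num / arma::accu(pi_num);
  }

  if (!converged) {
    // one more forward pass so the trajectory ends at the returned model
    double ll = 0.0;
    arma::mat alpha;
    arma::vec c;
    for (int s = 0; s < S; ++s) {
      if (!forward_scaled(A, B, pi, seqs[s], alpha, c))
        stop("a training sequence has zero probability under the current model");
      ll += arma::accu(arma::log(c));
    }
    traj.push_back(ll);
  }

  return List::create(_["A"] = A, _["B"] = B, _["pi"] = pi,
                      _["loglik_trajectory"] = traj,
                      _["n_iter"] = std::min(it, max_iter),
                      _["converged"] = converged,
                      _["n_floored"] = n_floor);
}
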