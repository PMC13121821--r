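// Streaming TSNA/TASNA engine: one pass over a response matrix, updating
// every item's stochastic Newton state per arriving examinee and scoring
// the examinee by EAP under the just-updated averaged parameters.
//
// Mirrors the R reference path (process_examinee / update_item) exactly;
// an equivalence test in the package holds the two to ~1e-12.

#include <RcppArmadillo.h>

using namespace arma;

static inline vec sigmoid_clip(const vec& eta) {
  vec p = 1.0 / (1.0 + exp(-eta));
  p.clamp(1e-12, 1.0 - 1e-12);
  return p;
}

// posterior node weights from an M x J probability matrix and a response
// row (non-finite entries = masked items, skipped)
static vec posterior_weights(const mat& P, const rowvec& y,
                             const vec& logw) {
  vec lp = logw;
  for (uword j = 0; j < P.n_cols; ++j) {
    const double yj = y(j);
    if (!std::isfinite(yj)) continue;
    if (yj > 0.5) lp += log(P.col(j));
    else          lp += log1p(-P.col(j));
  }
  lp -= lp.max();
  vec post = exp(lp);
  return post / accu(post);
}

// [[Rcpp::export(name = ".stream_fit_cpp")]]
Rcpp::List stream_fit_cpp(const arma::mat& Y,        // N x J responses (NaN = masked)
                          const arma::mat& nodes,    // M x Q
                          const arma::vec& weights,  // M
                          arma::mat B_cur,           // (Q+1) x J start values
                          arma::mat B_avg,
                          const arma::umat& freemask,// (Q+1) x J
                          Rcpp::List S_init,         // per item: free x free matrix
                          const double gamma, const double c_nu, const double n0,
                          const double c_lambda, const double alpha_lambda,
                          const int avg_mode,        // 0 none, 1 uniform, 2 log-weighted
                          const double avg_w,
                          const int gradient_at,     // 0 current, 1 averaged
                          const int n_start,         // examinees already processed
                          const double cum_omega_start,
                          const arma::ivec& checkpoints) {
  const uword N = Y.n_rows, J = Y.n_cols, M = nodes.n_rows, Q = nodes.n_cols;
  if (B_cur.n_cols != J || B_cur.n_rows != Q + 1)
    Rcpp::stop("parameter matrix shape does not match responses/grid");

  const mat Xaug = join_rows(nodes, ones<vec>(M));
  const vec logw = log(weights);

  std::vector<uvec> freeidx(J);
  std::vector<mat> S(J);
  for (uword j = 0; j < J; ++j) {
    freeidx[j] = find(freemask.col(j));
    S[j] = Rcpp::as<mat>(S_init[j]);
    if (S[j].n_rows != freeidx[j].n_elem)
      Rcpp::stop("S_init[%d] does not match the item's free-entry count", (int)(j + 1));
  }

  mat eap(N, Q, fill::zeros);
  const uword ncp = checkpoints.n_elem;
  cube cp_avg(Q + 1, J, ncp, fill::zeros);
  uword cp_next = 0;

  double cum_omega = cum_omega_start;

  for (uword i = 0; i < N; ++i) {
    const int n = n_start + (int)i + 1;
    const rowvec y = Y.row(i);

    const double nu  = c_nu * std::pow((double)n + n0, -gamma);
    const double lam = c_lambda * std::pow((double)n + 1.0, -alpha_lambda);

    double tau = 1.0;
    if (avg_mode == 1) tau = 1.0 / ((double)n + 1.0);
    else if (avg_mode == 2) {
      const double om = std::pow(std::log1p((double)n), avg_w);
      cum_omega += om;
      tau = om / cum_omega;
    }

    // response probabilities and posteriors at the two parameter sets
    mat P_avg(M, J);
    for (uword j = 0; j < J; ++j) P_avg.col(j) = sigmoid_clip(Xaug * B_avg.col(j));
    const vec post_avg = posterior_weights(P_avg, y, logw);

    mat P_g;
    vec post_g;
    if (gradient_at == 0) {
      P_g.set_size(M, J);
      for (uword j = 0; j < J; ++j) P_g.col(j) = sigmoid_clip(Xaug * B_cur.col(j));
      post_g = posterior_weights(P_g, y, logw);
    } else {
      P_g = P_avg;
      post_g = post_avg;
    }

    for (uword j = 0; j < J; ++j) {
      const uvec& fi = freeidx[j];
      if (fi.n_elem == 0) continue;          // fully anchored item
      const double yj = y(j);
      if (!std::isfinite(yj)) continue;      // masked: no information, no update

      const mat Xf = Xaug.cols(fi);
      const vec r = post_g % (yj - P_g.col(j));
      const vec g = -(Xf.t() * r);

      const vec pq = P_avg.col(j) % (1.0 - P_avg.col(j));
      const vec w = post_avg % clamp(pq, lam, datum::inf);
      const mat Phi = Xf.t() * (Xf.each_col() % w);

      const mat Hbar = S[j] / (double)n;
      vec delta;
      if (!solve(delta, Hbar, g, solve_opts::likely_sympd + solve_opts::no_approx))
        Rcpp::stop("singular scaled Hessian for item %d at examinee %d", (int)(j + 1), n);

      vec bc = B_cur.col(j);
      bc(fi) -= nu * delta;
      B_cur.col(j) = bc;

      S[j] += Phi;

      vec ba = B_avg.col(j);
      ba(fi) = (1.0 - tau) * ba(fi) + tau * bc(fi);
      B_avg.col(j) = ba;
    }

    // EAP under the just-updated averaged item parameters
    mat P_new(M, J);
    for (uword j = 0; j < J; ++j) P_new.col(j) = sigmoid_clip(Xaug * B_avg.col(j));
    const vec post_new = posterior_weights(P_new, y, logw);
    eap.row(i) = (nodes.t() * post_new).t();

    if (cp_next < ncp && n == checkpoints(cp_next)) {
      cp_avg.slice(cp_next) = B_avg;
      ++cp_next;
    }
  }

  Rcpp::List S_out(J);
  for (uword j = 0; j < J; ++j) S_out[j] = S[j];

  return Rcpp::List::create(
    Rcpp::Named("B_current") = B_cur,
    Rcpp::Named("B_avg") = B_avg,
    Rcpp::Named("S") = S_out,
    Rcpp::Named("eap") = eap,
    Rcpp::Named("n") = n_start + (int)N,
    Rcpp::Named("cum_omega") = cum_omega,
    Rcpp::Named("checkpoint_avg") = cp_avg);
}
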