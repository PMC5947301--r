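// Online motor-babbling trainer: the inner loop of train().
//
// One iteration = sample a uniform command, move the arm (clipping at the
// joint limits), encode command and vision as cosine-tuned populations, one
// forward pass of the recurrent forward network, and — when the post-movement
// observation is available — one backprop step of each network. Runs on R's
// global RNG so the stream is shared with (and reproducible from) R code;
// draw order per iteration: d_alpha, d_beta, availability of y(t+1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// truncated-cosine place-code activation, product over the two dimensions;
// indices of nonzero units are collected so downstream products can skip
// the silent majority of the population
void encode_pop(const mat& pref, const vec& hw, double v1, double v2,
                vec& out, uvec& nz, uword& n_nz) {
  n_nz = 0;
  const double w1 = hw[0], w2 = hw[1];
  for (uword i = 0; i < pref.n_rows; ++i) {
    double d1 = std::fabs(v1 - pref(i, 0));
    double d2 = std::fabs(v2 - pref(i, 1));
    double a = 0.0;
    if (d1 < w1 && d2 < w2) {
      a = std::cos(M_PI_2 * d1 / w1) * std::cos(M_PI_2 * d2 / w2);
      if (a != 0.0) nz[n_nz++] = i;
    }
    out[i] = a;
  }
}

inline void logistic_inplace(vec& x) {
  for (uword i = 0; i < x.n_elem; ++i) x[i] = 1.0 / (1.0 + std::exp(-x[i]));
}

// W -= eta * d * s.t() without a temporary, skipping zero columns
inline void rank1_update(mat& W, const vec& d, const vec& s, double eta) {
  for (uword j = 0; j < s.n_elem; ++j) {
    double f = eta * s[j];
    if (f != 0.0) W.unsafe_col(j) -= f * d;
  }
}

inline void rank1_update_sparse(mat& W, const vec& d, const vec& s,
                                const uvec& nz, uword n_nz, double eta) {
  for (uword k = 0; k < n_nz; ++k) {
    uword j = nz[k];
    W.unsafe_col(j) -= (eta * s[j]) * d;
  }
}

// net += M * s over the nonzero entries of s
inline void accum_sparse(vec& net, const mat& M, const vec& s,
                         const uvec& nz, uword n_nz) {
  for (uword k = 0; k < n_nz; ++k) {
    uword j = nz[k];
    net += s[j] * M.unsafe_col(j);
  }
}

inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_chunk(Rcpp::List weights, arma::vec h,
                           double alpha, double beta, bool y_avail,
                           const arma::mat& motor_pref,
                           const arma::vec& motor_hw,
                           const arma::mat& vis_pref,
                           const arma::vec& vis_hw,
                           int n_steps, double eta, double avail_rate,
                           double cmd_range, double joint_min,
                           double joint_max, double seg_len) {
  mat W_mu = Rcpp::as<mat>(weights["W_mu"]);
  mat W_vy = Rcpp::as<mat>(weights["W_vy"]);
  mat W_hh = Rcpp::as<mat>(weights["W_hh"]);
  mat W_hy = Rcpp::as<mat>(weights["W_hy"]);
  mat V_y  = Rcpp::as<mat>(weights["V_y"]);
  mat V_h  = Rcpp::as<mat>(weights["V_h"]);
  mat V_u  = Rcpp::as<mat>(weights["V_u"]);

  const uword n_motor = motor_pref.n_rows;
  const uword n_vis   = vis_pref.n_rows;

  vec u_code(n_motor), y_code(n_vis), teach(n_vis);
  uvec u_nz(n_motor), y_nz(n_vis), t_nz(n_vis);
  uword u_nnz = 0, y_nnz = 0, t_nnz = 0;
  vec h_new(h.n_elem), d_out(n_vis), d_hid(h.n_elem);
  vec h_inv(h.n_elem), u_post(n_motor), du_out(n_motor), du_hid(h.n_elem);
  int bad_iter = -1;

  for (int t = 0; t < n_steps; ++t) {
    // pre-movement hand position (needed only if vision was available)
    double x0 = 0.0, y0 = 0.0;
    if (y_avail) {
      double a = alpha * M_PI / 180.0;
      double f = (alpha + 180.0 - beta) * M_PI / 180.0;
      x0 = seg_len * (std::cos(a) + std::cos(f));
      y0 = seg_len * (std::sin(a) + std::sin(f));
    }

    double du = R::runif(-cmd_range, cmd_range);
    double db = R::runif(-cmd_range, cmd_range);
    bool avail_next = R::unif_rand() < avail_rate;

    alpha = clip(alpha + du, joint_min, joint_max);
    beta  = clip(beta + db, joint_min, joint_max);

    encode_pop(motor_pref, motor_hw, du, db, u_code, u_nz, u_nnz);

    // forward pass: h_new = logistic(W_mu u + W_vy y + W_hh h)
    h_new = W_hh * h;
    accum_sparse(h_new, W_mu, u_code, u_nz, u_nnz);
    if (y_avail) {
      double r0 = std::sqrt(x0 * x0 + y0 * y0);
      double th0 = std::atan2(x0, y0) * 180.0 / M_PI;
      encode_pop(vis_pref, vis_hw, r0, th0, y_code, y_nz, y_nnz);
      accum_sparse(h_new, W_vy, y_code, y_nz, y_nnz);
    }
    logistic_inplace(h_new);

    if (avail_next) {
      // post-movement observation: teacher for the forward net, input and
      // teacher source for the inverse net
      double a1 = alpha * M_PI / 180.0;
      double f1 = (alpha + 180.0 - beta) * M_PI / 180.0;
      double x1 = seg_len * (std::cos(a1) + std::cos(f1));
      double y1 = seg_len * (std::sin(a1) + std::sin(f1));
      double r1 = std::sqrt(x1 * x1 + y1 * y1);
      double th1 = std::atan2(x1, y1) * 180.0 / M_PI;
      encode_pop(vis_pref, vis_hw, r1, th1, teach, t_nz, t_nnz);

      vec y_pred = W_hy * h_new;
      logistic_inplace(y_pred);

      // forward update; delta through the pre-update W_hy
      d_out = (y_pred - teach) % y_pred % (1.0 - y_pred);
      d_hid = (W_hy.t() * d_out) % h_new % (1.0 - h_new);
      rank1_update(W_hy, d_out, h_new, eta);
      rank1_update_sparse(W_mu, d_hid, u_code, u_nz, u_nnz, eta);
      if (y_avail) rank1_update_sparse(W_vy, d_hid, y_code, y_nz, y_nnz, eta);
      rank1_update(W_hh, d_hid, h, eta);

      // inverse pass + update; inputs are the encoded post-movement
      // position and the pre-step hidden state (the Elman context, which
      // represents the situation before the command) — feeding the
      // post-command hidden would let the net read the command straight
      // back out of its state input instead of learning vision-to-motor.
      // This matches the reaching loop, where the inverse consumes the
      // state settled before the command it generates.
      h_inv = V_h * h;
      accum_sparse(h_inv, V_y, teach, t_nz, t_nnz);
      logistic_inplace(h_inv);
      u_post = V_u * h_inv;
      logistic_inplace(u_post);
      du_out = (u_post - u_code) % u_post % (1.0 - u_post);
      du_hid = (V_u.t() * du_out) % h_inv % (1.0 - h_inv);
      rank1_update(V_u, du_out, h_inv, eta);
      rank1_update_sparse(V_y, du_hid, teach, t_nz, t_nnz, eta);
      rank1_update(V_h, du_hid, h, eta);
    }

    h = h_new;
    y_avail = avail_next;

    if (!h.is_finite()) { bad_iter = t + 1; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = Rcpp::List::create(
      Rcpp::Named("W_mu") = W_mu, Rcpp::Named("W_vy") = W_vy,
      Rcpp::Named("W_hh") = W_hh, Rcpp::Named("W_hy") = W_hy,
      Rcpp::Named("V_y") = V_y, Rcpp::Named("V_h") = V_h,
      Rcpp::Named("V_u") = V_u),
    Rcpp::Named("h") = h,
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("y_avail") = y_avail,
    Rcpp::Named("bad_iter") = bad_iter);
}
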