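// Forward dynamics and backpropagation-through-time for the two-stream
// horizontal-product network.  One call processes one teacher-forced
// sequence; the epoch/sequence loops live in R (R/training.R, R/modes.R).
//
// Conventions (must stay in lock-step with the R forward pass in
// R/network.R, which is tested for exact agreement):
//   - hidden state at t = 0 is the zero vector;
//   - output units are linear; s_o = x_d (.) x_v (horizontal product);
//   - transfer f(y) = 1.7159 * tanh(2/3 * y) on hidden and PB units;
//   - PB activations are constant over the sequence (recomputed from rho
//     only when rho is updated, outside this kernel);
//   - delta_pb is the NEGATIVE gradient of the cost w.r.t. rho, per step,
//     so that rho <- rho + gamma * sum_t(delta_pb) descends the cost.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double A = 1.7159;
static const double B = 2.0 / 3.0;

// f'(y) expressed through s = f(y): A*B*(1 - tanh^2) = B*(A - s^2/A)
static inline vec dtransfer_from_act(const vec& s) {
  return B * (A - square(s) / A);
}

// [[Rcpp::export(name = ".cpp_seq_grad")]]
Rcpp::List cpp_seq_grad(const arma::mat& w_d, const arma::mat& w_v,
                        const arma::mat& v_d, const arma::mat& v_v,
                        const arma::mat& wbar_d, const arma::mat& wbar_v,
                        const arma::mat& u_d, const arma::mat& u_v,
                        const arma::vec& rho1, const arma::vec& rho2,
                        const arma::mat& x,  // T x n_in, normalized
                        const bool want_grads) {
  const uword T = x.n_rows;
  if (T < 2) Rcpp::stop("sequence must have at least 2 time steps");
  const uword Tm1 = T - 1;
  const uword n_d = w_d.n_rows, n_v = w_v.n_rows, n_out = u_d.n_rows;

  // PB activations, constant over the sequence
  const vec act1 = A * tanh(B * rho1);  // enters the ventral stream
  const vec act2 = A * tanh(B * rho2);  // enters the dorsal stream

  mat S_d(n_d, Tm1), S_v(n_v, Tm1);
  mat Xd(n_out, Tm1), Xv(n_out, Tm1), Err(n_out, Tm1);
  double cost = 0.0;

  vec sd_prev(n_d, fill::zeros), sv_prev(n_v, fill::zeros);
  for (uword t = 0; t < Tm1; ++t) {
    const vec in = x.row(t).t();
    const vec sd = A * tanh(B * (w_d * in + v_d * sd_prev + wbar_d * act2));
    const vec sv = A * tanh(B * (w_v * in + v_v * sv_prev + wbar_v * act1));
    const vec xd = u_d * sd;
    const vec xv = u_v * sv;
    const vec err = x.row(t + 1).t() - xd % xv;  // target - output
    cost += 0.5 * dot(err, err);
    S_d.col(t) = sd; S_v.col(t) = sv;
    Xd.col(t) = xd; Xv.col(t) = xv; Err.col(t) = err;
    sd_prev = sd; sv_prev = sv;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("cost") = cost,
      Rcpp::Named("outputs") = mat((Xd % Xv).t()));
  if (!want_grads) return out;

  mat g_wd(size(w_d), fill::zeros), g_wv(size(w_v), fill::zeros);
  mat g_vd(size(v_d), fill::zeros), g_vv(size(v_v), fill::zeros);
  mat g_wbd(size(wbar_d), fill::zeros), g_wbv(size(wbar_v), fill::zeros);
  mat g_ud(size(u_d), fill::zeros), g_uv(size(u_v), fill::zeros);
  mat d_pb1(rho1.n_elem, Tm1), d_pb2(rho2.n_elem, Tm1);
  const vec fp_rho1 = dtransfer_from_act(act1);
  const vec fp_rho2 = dtransfer_from_act(act2);

  vec carry_d(n_d, fill::zeros), carry_v(n_v, fill::zeros);
  for (uword ti = Tm1; ti-- > 0;) {
    const vec dso = -Err.col(ti);               // dC/ds_o
    const vec dxd = dso % Xv.col(ti);           // dC/dx_d
    const vec dxv = dso % Xd.col(ti);
    g_ud += dxd * S_d.col(ti).t();
    g_uv += dxv * S_v.col(ti).t();
    const vec dsd = u_d.t() * dxd + carry_d;
    const vec dsv = u_v.t() * dxv + carry_v;
    const vec dyd = dsd % dtransfer_from_act(S_d.col(ti));
    const vec dyv = dsv % dtransfer_from_act(S_v.col(ti));
    const vec in = x.row(ti).t();
    g_wd += dyd * in.t();
    g_wv += dyv * in.t();
    const vec sdp = (ti == 0) ? vec(n_d, fill::zeros) : vec(S_d.col(ti - 1));
    const vec svp = (ti == 0) ? vec(n_v, fill::zeros) : vec(S_v.col(ti - 1));
    g_vd += dyd * sdp.t();
    g_vv += dyv * svp.t();
    g_wbd += dyd * act2.t();
    g_wbv += dyv * act1.t();
    // negative gradient back-propagated to the PB internal values
    d_pb2.col(ti) = -(wbar_d.t() * dyd) % fp_rho2;
    d_pb1.col(ti) = -(wbar_v.t() * dyv) % fp_rho1;
    carry_d = v_d.t() * dyd;
    carry_v = v_v.t() * dyv;
  }

  out["grads"] = Rcpp::List::create(
      Rcpp::Named("w_d") = g_wd, Rcpp::Named("w_v") = g_wv,
      Rcpp::Named("v_d") = g_vd, Rcpp::Named("v_v") = g_vv,
      Rcpp::Named("wbar_d") = g_wbd, Rcpp::Named("wbar_v") = g_wbv,
      Rcpp::Named("u_d") = g_ud, Rcpp::Named("u_v") = g_uv);
  out["delta_pb1"] = d_pb1;  // n_pb1 x (T-1), negative gradient per step
  out["delta_pb2"] = d_pb2;
  return out;
}
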