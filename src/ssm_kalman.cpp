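// Linear-Gaussian state space message passing for chromatin state features.
//
// Model per chain of G bins:
//   y_g     = Z a_g + eps_g,  eps_g ~ N(0, I_E)
//   a_{g+1} = T a_g + v_g,    v_g   ~ N(0, I_K),  a_1 ~ N(0, I_K)
//
// Noise covariances are fixed at identity and never re-estimated; per-track
// scale heterogeneity is absorbed by the arcsinh transform upstream.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// symmetric PD inverse with jitter fallback
static mat inv_spd(const mat& M) {
  mat S = 0.5 * (M + M.t());
  mat out;
  if (inv_sympd(out, S)) return out;
  S.diag() += 1e-9;
  if (inv_sympd(out, S)) return out;
  return pinv(S);
}

static double logdet_spd(const mat& M) {
  mat S = 0.5 * (M + M.t());
  double val;
  if (log_det_sympd(val, S)) return val;
  S.diag() += 1e-9;
  if (log_det_sympd(val, S)) return val;
  double sign;
  log_det(val, sign, S);
  return val;
}

static vec clamp_nonneg(vec a) {
  a.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return a;
}

// Euclidean projection onto {a >= 0, sum(a) <= 1}: clamp, then (if the sum
// still exceeds one) project onto the probability simplex by the usual
// sort-and-threshold rule.
static vec project_capped_simplex(vec a) {
  a = clamp_nonneg(a);
  double s = accu(a);
  if (s <= 1.0) return a;
  vec u = sort(a, "descend");
  const uword K = a.n_elem;
  double css = 0.0, theta = 0.0;
  for (uword j = 0; j < K; ++j) {
    css += u(j);
    double t = (css - 1.0) / double(j + 1);
    if (u(j) > t) theta = t;
  }
  vec out = a - theta;
  return clamp_nonneg(out);
}

static vec apply_projection(const vec& a, int project) {
  if (project == 1) return clamp_nonneg(a);
  if (project == 2) return project_capped_simplex(a);
  return a;
}

// One chain: forward filter, optional RTS smoother, sufficient statistics.
//
// project: 0 none, 1 nonneg, 2 capped simplex (sum-to-one variant).
// projected_stats: use projected smoothed means in the sufficient statistics.
// keep_moments: return full per-position moment arrays (tests, annotation);
//   otherwise only log-likelihood and accumulated statistics.
// [[Rcpp::export]]
Rcpp::List ssm_kalman_cpp(const arma::mat& Y, const arma::mat& Z,
                          const arma::mat& T, int project, bool smooth,
                          bool projected_stats, bool keep_moments) {
  const uword G = Y.n_rows, E = Y.n_cols, K = Z.n_cols;
  const mat IK = eye(K, K), IE = eye(E, E);

  mat mu_pred(K, G), mu_filt(K, G);
  cube P_pred(K, K, G), P_filt(K, K, G);
  double loglik = 0.0;

  for (uword g = 0; g < G; ++g) {
    vec m_p;
    mat P_p;
    if (g == 0) {
      m_p = zeros<vec>(K);
      P_p = IK;
    } else {
      m_p = T * mu_filt.col(g - 1);
      P_p = T * P_filt.slice(g - 1) * T.t() + IK;
      P_p = 0.5 * (P_p + P_p.t());
    }
    vec y = Y.row(g).t();
    vec e = y - Z * m_p;                       // pre-projection innovation
    mat S = Z * P_p * Z.t() + IE;
    mat Sinv = inv_spd(S);
    loglik += -0.5 * (double(E) * LOG2PI + logdet_spd(S) +
                      as_scalar(e.t() * Sinv * e));
    mat Kg = P_p * Z.t() * Sinv;
    vec m_f = m_p + Kg * e;
    mat P_f = P_p - Kg * Z * P_p;
    P_f = 0.5 * (P_f + P_f.t());
    if (project != 0) m_f = apply_projection(m_f, project);
    mu_pred.col(g) = m_p;
    P_pred.slice(g) = P_p;
    mu_filt.col(g) = m_f;
    P_filt.slice(g) = P_f;
  }

  Rcpp::List out;
  out["loglik"] = loglik;
  out["G"] = double(G);

  mat mu_sm(K, G);
  cube P_sm(K, K, G), C_lag(K, K, G, fill::zeros);  // slice g: Cov(a_g, a_{g-1})

  if (smooth) {
    mu_sm.col(G - 1) = mu_filt.col(G - 1);
    P_sm.slice(G - 1) = P_filt.slice(G - 1);
    for (uword gi = G - 1; gi > 0; --gi) {
      uword g = gi - 1;                        // smooth position g from g+1
      mat J = P_filt.slice(g) * T.t() * inv_spd(P_pred.slice(g + 1));
      mu_sm.col(g) = mu_filt.col(g) + J * (mu_sm.col(g + 1) - mu_pred.col(g + 1));
      mat P = P_filt.slice(g) +
              J * (P_sm.slice(g + 1) - P_pred.slice(g + 1)) * J.t();
      P_sm.slice(g) = 0.5 * (P + P.t());
      // exact lag-one smoothed cross-covariance: Cov(a_{g+1}, a_g | Y)
      C_lag.slice(g + 1) = P_sm.slice(g + 1) * J.t();
    }
  } else {
    mu_sm = mu_filt;
    P_sm = P_filt;
  }

  // means entering stats and outputs honour the variant's constraint
  mat mu_out = mu_sm;
  if (smooth && project != 0) {
    for (uword g = 0; g < G; ++g)
      mu_out.col(g) = apply_projection(mu_sm.col(g), project);
  }
  const mat& mu_stat = projected_stats ? mu_out : mu_sm;

  mat S_aa(K, K, fill::zeros), S_cross(K, K, fill::zeros),
      S_prev(K, K, fill::zeros);
  mat S_ya(E, K, fill::zeros), S_yy(E, E, fill::zeros);
  for (uword g = 0; g < G; ++g) {
    S_aa += P_sm.slice(g) + mu_stat.col(g) * mu_stat.col(g).t();
    S_ya += Y.row(g).t() * mu_stat.col(g).t();
    S_yy += Y.row(g).t() * Y.row(g);
    if (g > 0) {
      S_cross += C_lag.slice(g) + mu_stat.col(g) * mu_stat.col(g - 1).t();
      S_prev += P_sm.slice(g - 1) + mu_stat.col(g - 1) * mu_stat.col(g - 1).t();
    }
  }
  out["S_aa"] = S_aa;
  out["S_cross"] = S_cross;
  out["S_prev"] = S_prev;
  out["S_ya"] = S_ya;
  out["S_yy"] = S_yy;
  out["mu_smooth"] = mu_out.t();               // G x K

  if (keep_moments) {
    out["mu_pred"] = mu_pred.t();
    out["mu_filt"] = mu_filt.t();
    out["P_pred"] = P_pred;
    out["P_filt"] = P_filt;
    out["P_smooth"] = P_sm;
    out["C_lag"] = C_lag;
    out["mu_smooth_raw"] = mu_sm.t();
  }
  return out;
}

// fast elementwise projections used by simulation and annotation paths
// [[Rcpp::export]]
arma::vec project_nonneg_cpp(const arma::vec& a) { return clamp_nonneg(a); }

// [[Rcpp::export]]
arma::vec project_sumone_cpp(const arma::vec& a) {
  return project_capped_simplex(a);
}
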