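// Joint posterior density, gradient and NUTS transition for the
// flux-balance genomic prediction model, in the standardized flux space.
//
// Parameter vector layout (unconstrained):
//   [0] log a'   [1] log b'   [2] log s2e   [3] log s2eps  [4] log Seps
//   [5 .. 5+J-1]      log s2V_j
//   [5+J .. 5+2J-1]   log s2U_j
//   [ .. +NJ]         z: non-centered genetic effects (column major,
//                     N x J); U'_{,j} = mU_j + sqrt(s2U_j) * G^{1/2} z_j
//   [ .. +NJ]         V'' raw: identity for reversible reactions,
//                     alpha_j + exp(raw) for irreversible ones.
// The density includes the log-Jacobians of all transforms, so NUTS
// explores an unconstrained space while every retained draw satisfies the
// truncation V''_{ij} > alpha_j for irreversible reactions. The genetic
// effects are non-centered to avoid the variance/effect funnel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Model {
  arma::vec Y;            // N phenotypes (NA allowed for test genotypes)
  arma::uvec train;       // indices (0-based) of training genotypes
  arma::cube Mdelta;      // K x J x N, genotype stoichiometry * delta_j
  arma::mat lhs;          // N x K constraint left-hand side (incl. jitter)
  arma::vec alpha;        // J
  arma::uvec irrev;       // J, 1 = irreversible (truncated)
  arma::mat Qg;           // N x N eigenvectors of G
  arma::vec lamg;         // N eigenvalues (floored positive)
  arma::vec mU;           // J prior means of U' columns
  double W;
  double hc_e, hc_ab, hc_v, hc_u, g_shape, g_rate;
  int N, K, J, tj;        // tj: 0-based target reaction
};

static Model unpack(const List& m) {
  Model M;
  M.Y = as<arma::vec>(m["Y"]);
  M.train = as<arma::uvec>(m["train"]);
  M.Mdelta = as<arma::cube>(m["Mdelta"]);
  M.lhs = as<arma::mat>(m["lhs"]);
  M.alpha = as<arma::vec>(m["alpha"]);
  M.irrev = as<arma::uvec>(m["irrev"]);
  M.Qg = as<arma::mat>(m["Qg"]);
  M.lamg = as<arma::vec>(m["lamg"]);
  M.mU = as<arma::vec>(m["mU"]);
  M.W = as<double>(m["W"]);
  M.hc_e = as<double>(m["hc_e"]);   M.hc_ab = as<double>(m["hc_ab"]);
  M.hc_v = as<double>(m["hc_v"]);   M.hc_u = as<double>(m["hc_u"]);
  M.g_shape = as<double>(m["g_shape"]); M.g_rate = as<double>(m["g_rate"]);
  M.N = M.lhs.n_rows; M.K = M.lhs.n_cols; M.J = M.alpha.n_elem;
  M.tj = as<int>(m["tj"]) - 1;
  return M;
}

// log half-Cauchy density (x > 0) and d/dx
static inline double lhc(double x, double s) {
  return std::log(2.0 / M_PI) - std::log(s) - std::log1p((x / s) * (x / s));
}
static inline double dlhc(double x, double s) {
  return -2.0 * x / (s * s + x * x);
}

static const double LOG2PI = std::log(2.0 * M_PI);
static const double HALF_LOG2PI = 0.918938533204672741780329736406;

// log Phi(t) via erfc, with the asymptotic expansion far in the lower
// tail (erfc underflows near t = -37)
static inline double log_phi(double t) {
  if (t > -30.0)
    return std::log(0.5 * std::erfc(-t * 0.707106781186547524401));
  double t2 = t * t;
  return -0.5 * t2 - std::log(-t) - HALF_LOG2PI +
         std::log1p(-1.0 / t2 + 3.0 / (t2 * t2));
}
// inverse Mills ratio phi(t)/Phi(t)
static inline double mills_ratio(double t, double lphi) {
  return std::exp(-0.5 * t * t - HALF_LOG2PI - lphi);
}

// log posterior (with transform Jacobians) and gradient in theta space
static double lp_grad(const Model& M, const arma::vec& theta,
                      arma::vec& grad) {
  const int N = M.N, K = M.K, J = M.J;
  const int oV = 5, oU = 5 + J, oUp = 5 + 2 * J, oVp = 5 + 2 * J + N * J;
  grad.zeros(theta.n_elem);

  // theta(0) is the intercept a' itself (unconstrained, symmetric
  // Cauchy prior); the remaining scalars are log-transformed positives
  const double a = theta(0), lb = theta(1), lse = theta(2),
               lsE = theta(3), lS = theta(4);
  const double b = std::exp(lb), s2e = std::exp(lse),
               s2E = std::exp(lsE), S = std::exp(lS);
  if (!arma::is_finite(theta)) return -arma::datum::inf;

  arma::mat Z(const_cast<double*>(theta.memptr()) + oUp, N, J, false, true);
  arma::mat Vraw(const_cast<double*>(theta.memptr()) + oVp, N, J, false, true);

  double lp = 0.0;

  // reconstruct the centered genetic effects U' from z
  arma::vec sqlam = arma::sqrt(M.lamg);
  arma::mat Az = M.Qg * (Z.each_col() % sqlam);   // N x J, G^{1/2} z
  arma::mat Up(N, J);
  arma::vec sdu(J);
  for (int j = 0; j < J; ++j) {
    sdu(j) = std::exp(0.5 * theta(oU + j));
    Up.col(j) = M.mU(j) + sdu(j) * Az.col(j);
  }

  // constrained V'' + Jacobian of the exp transform for truncated columns
  arma::mat V(N, J);
  for (int j = 0; j < J; ++j) {
    if (M.irrev(j)) {
      V.col(j) = M.alpha(j) + arma::exp(Vraw.col(j));
      lp += arma::accu(Vraw.col(j));
    } else {
      V.col(j) = Vraw.col(j);
    }
  }
  // Jacobians of log transforms of positive scalars
  lp += lb + lse + lsE + lS +
        arma::accu(theta.subvec(oV, oV + J - 1)) +
        arma::accu(theta.subvec(oU, oU + J - 1));
  arma::vec dV_flat(N * J, arma::fill::zeros);
  arma::mat dV(dV_flat.memptr(), N, J, false, true);
  arma::mat dU(N, J, arma::fill::zeros);

  // observation term: training genotypes only
  const int Ntr = M.train.n_elem;
  double SSo = 0.0, sum_r = 0.0, sum_rv = 0.0;
  for (int t = 0; t < Ntr; ++t) {
    int i = M.train(t);
    double r = M.Y(i) - a - b * V(i, M.tj);
    SSo += r * r;
    sum_r += r;
    sum_rv += r * V(i, M.tj);
    dV(i, M.tj) += b * r / s2e;
  }
  lp += -0.5 * Ntr * lse - SSo / (2.0 * s2e);
  double d_a = sum_r / s2e;          // d lp / d a
  double d_b = sum_rv / s2e;
  grad(2) += -0.5 * Ntr + SSo / (2.0 * s2e);

  // weighted constraint term over ALL genotypes
  double SSc = 0.0;
  for (int i = 0; i < N; ++i) {
    arma::vec resid = M.lhs.row(i).t() - M.Mdelta.slice(i) * V.row(i).t();
    SSc += arma::dot(resid, resid);
    dV.row(i) += (M.W / s2E) * (M.Mdelta.slice(i).t() * resid).t();
  }
  lp += M.W * (-0.5 * (double)N * K * lsE - SSc / (2.0 * s2E));
  grad(3) += M.W * (-0.5 * (double)N * K + SSc / (2.0 * s2E));

  // flux prior V'' ~ N(U' + alpha_j, s2V_j), truncated below at alpha_j
  // for irreversible reactions (normalizer -log Phi(U'/sV))
  for (int j = 0; j < J; ++j) {
    double s2v = std::exp(theta(oV + j));
    double sv = std::sqrt(s2v);
    double ssz = 0.0;
    for (int i = 0; i < N; ++i) {
      double z = (V(i, j) - Up(i, j) - M.alpha(j)) / sv;
      ssz += z * z;
      dV(i, j) += -z / sv;
      dU(i, j) += z / sv;
    }
    lp += -0.5 * N * (LOG2PI + theta(oV + j)) - 0.5 * ssz;
    grad(oV + j) += -0.5 * N + 0.5 * ssz;
    if (M.irrev(j)) {
      for (int i = 0; i < N; ++i) {
        double t = Up(i, j) / sv;
        double lphi = log_phi(t);
        lp -= lphi;
        double mills = mills_ratio(t, lphi);
        dU(i, j) += -mills / sv;
        grad(oV + j) += 0.5 * mills * t;
      }
    }
  }

  // genetic prior in non-centered form: z ~ N(0, I); backpropagate the
  // U' gradients to z and to log s2U
  lp += -0.5 * arma::accu(Z % Z) - 0.5 * (double)N * J * LOG2PI;
  arma::mat dUt = M.Qg.t() * dU;                // N x J
  for (int j = 0; j < J; ++j) {
    arma::vec gz = sdu(j) * (sqlam % dUt.col(j)) - Z.col(j);
    for (int i = 0; i < N; ++i) grad(oUp + j * N + i) += gz(i);
    grad(oU + j) += 0.5 * sdu(j) * arma::dot(Az.col(j), dU.col(j));
  }

  // hyperpriors: full Cauchy on the intercept, half-Cauchy elsewhere
  lp += -std::log(M_PI * M.hc_ab) -
        std::log1p((a / M.hc_ab) * (a / M.hc_ab));
  lp += lhc(b, M.hc_ab) + lhc(s2e, M.hc_e) + lhc(s2E, S);
  d_a += dlhc(a, M.hc_ab);
  d_b += dlhc(b, M.hc_ab);
  grad(2) += dlhc(s2e, M.hc_e) * s2e;
  grad(3) += dlhc(s2E, S) * s2E;
  // d/dS of lhc(x, S) = -1/S + 2 x^2 / (S (S^2 + x^2))
  double dS = -1.0 / S + 2.0 * s2E * s2E / (S * (S * S + s2E * s2E));
  // S ~ Gamma(shape, rate)
  lp += M.g_shape * std::log(M.g_rate) - std::lgamma(M.g_shape) +
        (M.g_shape - 1.0) * lS - M.g_rate * S;
  dS += (M.g_shape - 1.0) / S - M.g_rate;
  grad(4) += dS * S;
  for (int j = 0; j < J; ++j) {
    double s2v = std::exp(theta(oV + j)), s2u = std::exp(theta(oU + j));
    lp += lhc(s2v, M.hc_v) + lhc(s2u, M.hc_u);
    grad(oV + j) += dlhc(s2v, M.hc_v) * s2v;
    grad(oU + j) += dlhc(s2u, M.hc_u) * s2u;
  }

  grad(0) += d_a;
  grad(1) += d_b * b;

  // map flux gradients back to raw coordinates
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < N; ++i) {
      double g = dV(i, j);
      if (M.irrev(j))
        grad(oVp + j * N + i) += g * (V(i, j) - M.alpha(j)) + 1.0;
      else
        grad(oVp + j * N + i) += g;
    }
  }
  // Jacobian contributions of the scalar log transforms
  grad(1) += 1.0; grad(2) += 1.0; grad(3) += 1.0;
  grad(4) += 1.0;
  for (int j = 0; j < J; ++j) { grad(oV + j) += 1.0; grad(oU + j) += 1.0; }

  return lp;
}

// [[Rcpp::export]]
List flux_lp_grad(const arma::vec& theta, const List& model) {
  Model M = unpack(model);
  arma::vec grad;
  double lp = lp_grad(M, theta, grad);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// ---- NUTS ---------------------------------------------------------------

struct Hamiltonian {
  const Model& M;
  const arma::vec& vmass;   // inverse mass diagonal (posterior variances)
  Hamiltonian(const Model& m, const arma::vec& v) : M(m), vmass(v) {}
  double joint(const arma::vec& theta, const arma::vec& r,
               arma::vec& grad) const {
    double lp = lp_grad(M, theta, grad);
    return lp - 0.5 * arma::dot(vmass, r % r);
  }
  // advances (theta, r) one step and returns the log posterior at the
  // new position (grad is updated in place)
  double leapfrog(arma::vec& theta, arma::vec& r, arma::vec& grad,
                  double eps) const {
    r += 0.5 * eps * grad;
    theta += eps * (vmass % r);
    double lp = lp_grad(M, theta, grad);
    r += 0.5 * eps * grad;
    return lp;
  }
};

struct Tree {
  arma::vec theta_minus, r_minus, grad_minus;
  arma::vec theta_plus, r_plus, grad_plus;
  arma::vec theta_prime, grad_prime;
  double lp_prime;
  double n;          // slice-acceptable states in subtree
  bool s;            // subtree valid (no U-turn, no divergence)
  bool divergent;
  double alpha, nalpha;
};

static bool no_uturn(const arma::vec& tp, const arma::vec& tm,
                     const arma::vec& rp, const arma::vec& rm,
                     const arma::vec& vmass) {
  arma::vec d = tp - tm;
  return arma::dot(d, vmass % rm) >= 0 && arma::dot(d, vmass % rp) >= 0;
}

static void build_tree(const Hamiltonian& H, const arma::vec& theta,
                       const arma::vec& r, const arma::vec& grad,
                       double logu, int dir, int depth, double eps,
                       double joint0, Tree& out) {
  if (depth == 0) {
    out.theta_prime = theta; out.grad_prime = grad;
    arma::vec rp = r;
    double lp = H.leapfrog(out.theta_prime, rp, out.grad_prime, dir * eps);
    out.lp_prime = lp;
    double joint = lp - 0.5 * arma::dot(H.vmass, rp % rp);
    if (!std::isfinite(joint)) joint = -arma::datum::inf;
    out.n = (logu <= joint) ? 1.0 : 0.0;
    out.divergent = (logu - 1000.0 > joint);
    out.s = !out.divergent;
    out.theta_minus = out.theta_plus = out.theta_prime;
    out.r_minus = out.r_plus = rp;
    out.grad_minus = out.grad_plus = out.grad_prime;
    out.alpha = std::min(1.0, std::exp(joint - joint0));
    if (!std::isfinite(out.alpha)) out.alpha = 0.0;
    out.nalpha = 1.0;
    return;
  }
  Tree first;
  build_tree(H, theta, r, grad, logu, dir, depth - 1, eps, joint0, first);
  out = first;
  if (first.s) {
    Tree second;
    if (dir == -1) {
      build_tree(H, first.theta_minus, first.r_minus, first.grad_minus,
                 logu, dir, depth - 1, eps, joint0, second);
      out.theta_minus = second.theta_minus; out.r_minus = second.r_minus;
      out.grad_minus = second.grad_minus;
    } else {
      build_tree(H, first.theta_plus, first.r_plus, first.grad_plus,
                 logu, dir, depth - 1, eps, joint0, second);
      out.theta_plus = second.theta_plus; out.r_plus = second.r_plus;
      out.grad_plus = second.grad_plus;
    }
    double ntot = first.n + second.n;
    if (ntot > 0 && unif_rand() < second.n / ntot) {
      out.theta_prime = second.theta_prime;
      out.grad_prime = second.grad_prime;
      out.lp_prime = second.lp_prime;
    }
    out.n = ntot;
    out.divergent = first.divergent || second.divergent;
    out.s = second.s && no_uturn(out.theta_plus, out.theta_minus,
                                 out.r_plus, out.r_minus, H.vmass);
    out.alpha = first.alpha + second.alpha;
    out.nalpha = first.nalpha + second.nalpha;
  }
}

// One NUTS transition. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
List flux_nuts_step(const arma::vec& theta0, double eps,
                    const arma::vec& inv_mass, const List& model,
                    int max_depth = 10) {
  Model M = unpack(model);
  Hamiltonian H(M, inv_mass);
  const int D = theta0.n_elem;
  arma::vec r0(D);
  for (int i = 0; i < D; ++i)
    r0(i) = norm_rand() / std::sqrt(inv_mass(i));
  arma::vec grad0;
  double lp0 = lp_grad(M, theta0, grad0);
  double joint0 = lp0 - 0.5 * arma::dot(inv_mass, r0 % r0);
  double logu = joint0 + std::log(unif_rand());

  arma::vec theta_minus = theta0, theta_plus = theta0;
  arma::vec r_minus = r0, r_plus = r0;
  arma::vec grad_minus = grad0, grad_plus = grad0;
  arma::vec theta = theta0;
  double lp = lp0;
  double n = 1.0;
  bool s = true, any_div = false;
  int depth = 0;
  double alpha = 0.0, nalpha = 1.0;

  while (s && depth < max_depth) {
    int dir = (unif_rand() < 0.5) ? -1 : 1;
    Tree t;
    if (dir == -1)
      build_tree(H, theta_minus, r_minus, grad_minus, logu, dir, depth,
                 eps, joint0, t);
    else
      build_tree(H, theta_plus, r_plus, grad_plus, logu, dir, depth,
                 eps, joint0, t);
    if (dir == -1) {
      theta_minus = t.theta_minus; r_minus = t.r_minus;
      grad_minus = t.grad_minus;
    } else {
      theta_plus = t.theta_plus; r_plus = t.r_plus;
      grad_plus = t.grad_plus;
    }
    alpha = t.alpha; nalpha = t.nalpha;
    any_div = any_div || t.divergent;
    if (t.s && t.n > 0 && unif_rand() < std::min(1.0, t.n / n)) {
      theta = t.theta_prime;
      lp = t.lp_prime;
    }
    n += t.n;
    s = t.s && no_uturn(theta_plus, theta_minus, r_plus, r_minus, inv_mass);
    depth++;
  }
  return List::create(_["theta"] = theta, _["lp"] = lp,
                      _["accept_stat"] = (nalpha > 0 ? alpha / nalpha : 0.0),
                      _["depth"] = depth, _["divergent"] = any_div);
}

// Step-size heuristic: double/halve eps until the one-step acceptance
// probability crosses 0.5 (Hoffman & Gelman 2014).
// [[Rcpp::export]]
double flux_find_epsilon(const arma::vec& theta0, const arma::vec& inv_mass,
                         const List& model) {
  Model M = unpack(model);
  Hamiltonian H(M, inv_mass);
  const int D = theta0.n_elem;
  double eps = 0.1;
  arma::vec r0(D);
  for (int i = 0; i < D; ++i)
    r0(i) = norm_rand() / std::sqrt(inv_mass(i));
  arma::vec grad0;
  double lp0 = lp_grad(M, theta0, grad0);
  double joint0 = lp0 - 0.5 * arma::dot(inv_mass, r0 % r0);
  arma::vec th = theta0, r = r0, g = grad0;
  double lp1 = H.leapfrog(th, r, g, eps);
  double joint = lp1 - 0.5 * arma::dot(inv_mass, r % r);
  if (!std::isfinite(joint)) joint = joint0 - 1000.0;
  double dir = (joint - joint0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= std::pow(2.0, dir);
    th = theta0; r = r0; g = grad0;
    lp1 = H.leapfrog(th, r, g, eps);
    joint = lp1 - 0.5 * arma::dot(inv_mass, r % r);
    if (!std::isfinite(joint)) joint = joint0 - 1000.0;
    double crit = dir * (joint - joint0 - std::log(0.5));
    if (crit < 0) break;
  }
  return eps;
}
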