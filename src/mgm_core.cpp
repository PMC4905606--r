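// Core numerics for pairwise mixed graphical models:
//  - negative log-pseudolikelihood and its gradient in the
//    (beta, alpha, rho, phi) parameterization
//  - proximal operator of the three edge-type penalties with the
//    sum-to-zero reparameterization of indicator blocks
//  - accelerated proximal-gradient (FISTA) fit with backtracking and
//    monotone restart
//  - systematic-scan Gibbs sampler for drawing mixed observations
//
// Conventions: categorical variable j occupies rows/cols
// offs[j] .. offs[j]+L_j-1 of rho/phi; D is the n x totL one-hot
// indicator matrix; within-variable phi blocks are diagonal matrices
// (only phi_rr(k,k) enters the model).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static uvec block_offsets(const uvec& levels) {
  uvec offs(levels.n_elem);
  unsigned int a = 0;
  for (unsigned int j = 0; j < levels.n_elem; ++j) { offs[j] = a; a += levels[j]; }
  return offs;
}

// Negative log-pseudolikelihood summed over samples.  If wantgrad, the
// gradient matrices (same layout as the parameters, summed over samples)
// are filled in.  If per_sample is non-null it receives the per-sample
// contributions.
static double nlpl_core(const mat& X, const mat& D, const uvec& levels,
                        const uvec& offs,
                        const mat& beta, const vec& alpha, const mat& rho,
                        const mat& phi,
                        bool wantgrad,
                        mat& gbeta, vec& galpha, mat& grho, mat& gphi,
                        vec* per_sample) {
  const unsigned int p = beta.n_rows;
  const unsigned int q = levels.n_elem;
  const unsigned int n = (p > 0) ? X.n_rows : D.n_rows;
  const unsigned int totL = (q > 0) ? accu(levels) : 0;

  double val = 0.0;
  if (per_sample) per_sample->zeros(n);

  mat Rres;                         // residuals x_s - E[x_s | rest]
  vec bd;
  if (p > 0) {
    bd = beta.diag();
    if (any(bd <= 0.0))
      Rcpp::stop("nonpositive diagonal entry in beta: conditional variance undefined");
    mat Boff = beta; Boff.diag().zeros();
    mat Eta = -(X * Boff);
    Eta.each_row() += alpha.t();
    if (q > 0) Eta += D * rho;
    mat Mu = Eta; Mu.each_row() /= bd.t();
    Rres = X - Mu;
    for (unsigned int s = 0; s < p; ++s) {
      double c = 0.5 * std::log(2.0 * M_PI) - 0.5 * std::log(bd[s]);
      vec rs = Rres.col(s);
      val += n * c + 0.5 * bd[s] * dot(rs, rs);
      if (per_sample) *per_sample += c + 0.5 * bd[s] * square(rs);
    }
  }

  mat W;                            // probabilities minus indicators
  if (q > 0) {
    mat H = D * phi;
    if (p > 0) H += X * rho.t();
    W.set_size(n, totL);
    for (unsigned int r = 0; r < q; ++r) {
      const unsigned int a = offs[r], L = levels[r];
      mat Hb = H.cols(a, a + L - 1);
      const mat Db = D.cols(a, a + L - 1);
      vec pd = phi.submat(a, a, a + L - 1, a + L - 1).diag();
      // remove the phi_rr(y_r, .) contribution picked up through D*phi and
      // add the level-intercept phi_rr(k,k)
      Hb -= Db * diagmat(pd);
      Hb.each_row() += pd.t();
      vec m = max(Hb, 1);
      mat E = exp(Hb.each_col() - m);
      vec se = sum(E, 1);
      vec lse = m + log(se);
      vec obs = sum(Hb % Db, 1);
      val += accu(lse - obs);
      if (per_sample) *per_sample += lse - obs;
      W.cols(a, a + L - 1) = (E.each_col() / se) - Db;
    }
  }

  if (wantgrad) {
    if (p > 0) {
      mat RX = Rres.t() * X;        // p x p
      gbeta = RX + RX.t();
      vec r2 = sum(square(Rres), 0).t();
      for (unsigned int s = 0; s < p; ++s)
        gbeta(s, s) = -0.5 * n / bd[s] + RX(s, s) - 0.5 * r2[s];
      galpha = -sum(Rres, 0).t();
    } else {
      gbeta.set_size(0, 0); galpha.set_size(0);
    }
    if (q > 0) {
      if (p > 0) grho = W.t() * X - D.t() * Rres;
      else grho.set_size(totL, 0);
      mat WD = W.t() * D;
      gphi = WD + WD.t();
      rowvec wcs = sum(W, 0);
      for (unsigned int r = 0; r < q; ++r) {
        const unsigned int a = offs[r], L = levels[r];
        gphi.submat(a, a, a + L - 1, a + L - 1) =
          diagmat(wcs.subvec(a, a + L - 1).t());
      }
    } else {
      grho.set_size(0, (p > 0) ? p : 0); gphi.set_size(0, 0);
    }
  }
  return val;
}

static double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Edge-type penalty value: lcc * sum_{t<s} |beta_st| +
// lcd * sum_{s,j} ||rho_sj||_2 + ldd * sum_{r<j} ||phi_rj||_F.
static double penalty_core(const mat& beta, const mat& rho, const mat& phi,
                           const uvec& levels, const uvec& offs,
                           double lcc, double lcd, double ldd) {
  double pen = 0.0;
  const unsigned int p = beta.n_rows, q = levels.n_elem;
  if (p > 1) {
    for (unsigned int s = 1; s < p; ++s)
      for (unsigned int t = 0; t < s; ++t) pen += lcc * std::fabs(beta(s, t));
  }
  if (p > 0 && q > 0) {
    for (unsigned int j = 0; j < q; ++j) {
      const unsigned int a = offs[j], L = levels[j];
      for (unsigned int s = 0; s < p; ++s)
        pen += lcd * norm(rho.submat(a, s, a + L - 1, s), 2);
    }
  }
  if (q > 1) {
    for (unsigned int j = 1; j < q; ++j)
      for (unsigned int r = 0; r < j; ++r)
        pen += ldd * norm(phi.submat(offs[r], offs[j],
                                     offs[r] + levels[r] - 1,
                                     offs[j] + levels[j] - 1), "fro");
  }
  return pen;
}

// Projection of (rho, phi) onto the sum-to-zero subspace: every rho_sj
// vector is centered, every off-diagonal phi block doubly centered (zero
// row and column sums), within-variable blocks reduced to their centered
// diagonal.  The model is optimized in this restricted parameterization
// (the joint density is invariant to the removed shift directions, and
// centering never increases a group norm, so the restriction loses no
// optima); applying the same projection to the gradient yields the
// gradient of the restricted objective.
static void project_blocks(mat& rho, mat& phi, const uvec& levels,
                           const uvec& offs, unsigned int p) {
  const unsigned int q = levels.n_elem;
  if (q == 0) return;
  if (p > 0) {
    for (unsigned int j = 0; j < q; ++j) {
      const unsigned int a = offs[j], L = levels[j];
      for (unsigned int s = 0; s < p; ++s) {
        vec g = rho.submat(a, s, a + L - 1, s);
        rho.submat(a, s, a + L - 1, s) = g - mean(g);
      }
    }
  }
  for (unsigned int j = 0; j < q; ++j) {
    const unsigned int aj = offs[j], Lj = levels[j];
    for (unsigned int r = 0; r < j; ++r) {
      const unsigned int ar = offs[r], Lr = levels[r];
      mat B = 0.5 * (phi.submat(ar, aj, ar + Lr - 1, aj + Lj - 1) +
                     phi.submat(aj, ar, aj + Lj - 1, ar + Lr - 1).t());
      vec rm = mean(B, 1);
      rowvec cm = mean(B, 0);
      double tm = mean(rm);
      B.each_col() -= rm;
      B.each_row() -= cm;
      B += tm;
      phi.submat(ar, aj, ar + Lr - 1, aj + Lj - 1) = B;
      phi.submat(aj, ar, aj + Lj - 1, ar + Lr - 1) = B.t();
    }
    vec pd = phi.submat(aj, aj, aj + Lj - 1, aj + Lj - 1).diag();
    pd -= mean(pd);
    phi.submat(aj, aj, aj + Lj - 1, aj + Lj - 1) = diagmat(pd);
  }
}

// Proximal operator (in place): sum-to-zero projection, then elementwise
// soft-thresholding of off-diagonal beta at step*lcc and group
// soft-thresholding of rho vectors / off-diagonal phi blocks at step*lcd /
// step*ldd (group scaling preserves the centering).  Intercepts and the
// beta diagonal are unpenalized; the diagonal is clamped from below.
static void prox_core(mat& beta, vec& alpha, mat& rho, mat& phi,
                      const uvec& levels, const uvec& offs,
                      double step, double lcc, double lcd, double ldd,
                      double min_diag) {
  const unsigned int p = beta.n_rows, q = levels.n_elem;
  (void)alpha;
  project_blocks(rho, phi, levels, offs, p);
  if (p > 0) {
    for (unsigned int s = 0; s < p; ++s) {
      for (unsigned int t = 0; t < s; ++t) {
        double v = soft(0.5 * (beta(s, t) + beta(t, s)), step * lcc);
        beta(s, t) = v; beta(t, s) = v;
      }
      if (beta(s, s) < min_diag) beta(s, s) = min_diag;
    }
  }
  if (p > 0 && q > 0) {
    for (unsigned int j = 0; j < q; ++j) {
      const unsigned int a = offs[j], L = levels[j];
      for (unsigned int s = 0; s < p; ++s) {
        vec g = rho.submat(a, s, a + L - 1, s);
        double nrm = norm(g, 2), thr = step * lcd;
        if (nrm <= thr) g.zeros(); else g *= (1.0 - thr / nrm);
        rho.submat(a, s, a + L - 1, s) = g;
      }
    }
  }
  if (q > 1) {
    for (unsigned int j = 1; j < q; ++j) {
      const unsigned int aj = offs[j], Lj = levels[j];
      for (unsigned int r = 0; r < j; ++r) {
        const unsigned int ar = offs[r], Lr = levels[r];
        mat B = phi.submat(ar, aj, ar + Lr - 1, aj + Lj - 1);
        double nrm = norm(B, "fro"), thr = step * ldd;
        if (nrm <= thr) B.zeros(); else B *= (1.0 - thr / nrm);
        phi.submat(ar, aj, ar + Lr - 1, aj + Lj - 1) = B;
        phi.submat(aj, ar, aj + Lj - 1, ar + Lr - 1) = B.t();
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_nlpl(const arma::mat& X, const arma::mat& D,
                    const arma::uvec& levels,
                    const arma::mat& beta, const arma::vec& alpha,
                    const arma::mat& rho, const arma::mat& phi,
                    bool gradient = false, bool per_sample = false) {
  uvec offs = block_offsets(levels);
  mat gbeta, grho, gphi; vec galpha; vec ps;
  double val = nlpl_core(X, D, levels, offs, beta, alpha, rho, phi,
                         gradient, gbeta, galpha, grho, gphi,
                         per_sample ? &ps : nullptr);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("value") = val);
  if (gradient) {
    out["grad_beta"] = gbeta; out["grad_alpha"] = galpha;
    out["grad_rho"] = grho; out["grad_phi"] = gphi;
  }
  if (per_sample) out["per_sample"] = ps;
  return out;
}

// [[Rcpp::export]]
double cpp_penalty(const arma::mat& beta, const arma::mat& rho,
                   const arma::mat& phi, const arma::uvec& levels,
                   double lcc, double lcd, double ldd) {
  uvec offs = block_offsets(levels);
  return penalty_core(beta, rho, phi, levels, offs, lcc, lcd, ldd);
}

// [[Rcpp::export]]
Rcpp::List cpp_prox(const arma::mat& beta, const arma::vec& alpha,
                    const arma::mat& rho, const arma::mat& phi,
                    const arma::uvec& levels,
                    double step, double lcc, double lcd, double ldd,
                    double min_diag = 1e-6) {
  uvec offs = block_offsets(levels);
  mat b = beta, r = rho, f = phi; vec a = alpha;
  prox_core(b, a, r, f, levels, offs, step, lcc, lcd, ldd, min_diag);
  return Rcpp::List::create(Rcpp::Named("beta") = b, Rcpp::Named("alpha") = a,
                            Rcpp::Named("rho") = r, Rcpp::Named("phi") = f);
}

// Accelerated proximal gradient descent on nlpl/n + penalty.
// [[Rcpp::export]]
Rcpp::List cpp_fit(const arma::mat& X, const arma::mat& D,
                   const arma::uvec& levels,
                   double lcc, double lcd, double ldd,
                   arma::mat beta, arma::vec alpha, arma::mat rho,
                   arma::mat phi,
                   double tol = 1e-6, int maxit = 500,
                   double step0 = 1.0, double bt = 0.5,
                   bool accel = true, double min_diag = 1e-6) {
  const unsigned int p = beta.n_rows;
  const unsigned int n = (p > 0) ? X.n_rows : D.n_rows;
  uvec offs = block_offsets(levels);

  mat gbeta, grho, gphi; vec galpha;
  auto fval = [&](const mat& b, const vec& a, const mat& r, const mat& f) {
    mat d1, d3, d4; vec d2;
    return nlpl_core(X, D, levels, offs, b, a, r, f, false,
                     d1, d2, d3, d4, nullptr) / n;
  };
  auto penval = [&](const mat& b, const mat& r, const mat& f) {
    return penalty_core(b, r, f, levels, offs, lcc, lcd, ldd);
  };

  // iterates: x = (beta, alpha, rho, phi); y = extrapolation point;
  // start from the canonical (sum-to-zero) representative
  mat xb = beta, xr = rho, xf = phi; vec xa = alpha;
  project_blocks(xr, xf, levels, offs, p);
  mat yb = xb, yr = xr, yf = xf; vec ya = xa;
  mat xb_old = xb, xr_old = xr, xf_old = xf; vec xa_old = xa;

  double Fx = fval(xb, xa, xr, xf) + penval(xb, xr, xf);
  if (!std::isfinite(Fx)) Rcpp::stop("objective not finite at the initial point");
  std::vector<double> trace; trace.push_back(Fx);

  double step = step0, theta = 1.0;
  bool converged = false;
  int it = 0;
  std::string reason = "max_iterations";

  for (it = 1; it <= maxit; ++it) {
    double fy = nlpl_core(X, D, levels, offs, yb, ya, yr, yf, true,
                          gbeta, galpha, grho, gphi, nullptr) / n;
    if (p > 0) { gbeta /= n; galpha /= n; }
    if (levels.n_elem > 0) {
      grho /= n; gphi /= n;
      // gradient of the restricted (sum-to-zero) objective
      project_blocks(grho, gphi, levels, offs, p);
    }

    mat zb, zr, zf; vec za;
    double fz = 0.0;
    bool at_x = approx_equal(yb, xb, "absdiff", 0.0) &&
                (p == 0 || approx_equal(mat(ya), mat(xa), "absdiff", 0.0)) &&
                approx_equal(yr, xr, "absdiff", 0.0) &&
                approx_equal(yf, xf, "absdiff", 0.0);
    for (int btries = 0; ; ++btries) {
      zb = yb; za = ya; zr = yr; zf = yf;
      if (p > 0) { zb -= step * gbeta; za -= step * galpha; }
      if (levels.n_elem > 0) { zr -= step * grho; zf -= step * gphi; }
      prox_core(zb, za, zr, zf, levels, offs, step, lcc, lcd, ldd, min_diag);
      fz = fval(zb, za, zr, zf);
      // beta and phi store each unordered interaction in both mirrored
      // entries (with the full pair derivative in the gradient); the line
      // search works in half-vectorized coordinates, counting every pair
      // once: sum_halfvec = (full sum + diagonal sum) / 2
      auto half = [](const mat& a, const mat& b) {
        return 0.5 * (accu(a % b) + dot(a.diag(), b.diag()));
      };
      double lin = fy, sq = 0.0;
      if (p > 0) {
        mat dB = zb - yb;
        lin += half(gbeta, dB) + dot(galpha, za - ya);
        sq += half(dB, dB) + accu(square(za - ya));
      }
      if (levels.n_elem > 0) {
        mat dF = zf - yf;
        lin += accu(grho % (zr - yr)) + half(gphi, dF);
        sq += accu(square(zr - yr)) + half(dF, dF);
      }
      if (std::isfinite(fz) && fz <= lin + sq / (2.0 * step) + 1e-12) break;
      if (btries > 60)
        Rcpp::stop("backtracking line search failed at iteration %d", it);
      step *= bt;
    }
    double Fz = fz + penval(zb, zr, zf);
    if (!std::isfinite(Fz))
      Rcpp::stop("objective diverged (NaN/Inf) at iteration %d", it);

    if (Fz > Fx + 1e-12) {
      if (!at_x) {
        // acceleration overshot: monotone restart from the last iterate
        yb = xb; ya = xa; yr = xr; yf = xf;
        theta = 1.0;
        continue;
      }
      // already stepping from x: shrink the step; if no step helps the
      // iterate is numerically stationary
      if (step > 1e-12) { step *= bt; continue; }
      converged = true; reason = "tolerance"; break;
    }

    double rel = std::fabs(Fx - Fz) / std::max(1e-10, std::fabs(Fx));
    xb_old = xb; xa_old = xa; xr_old = xr; xf_old = xf;
    xb = zb; xa = za; xr = zr; xf = zf;
    double Fprev = Fx; Fx = std::min(Fz, Fx);
    trace.push_back(Fz);
    (void)Fprev;

    if (accel) {
      double theta_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * theta * theta));
      double w = (theta - 1.0) / theta_new;
      yb = xb + w * (xb - xb_old);
      if (p > 0) ya = xa + w * (xa - xa_old);
      yr = xr + w * (xr - xr_old);
      yf = xf + w * (xf - xf_old);
      theta = theta_new;
    } else {
      yb = xb; ya = xa; yr = xr; yf = xf;
    }

    if (rel < tol) { converged = true; reason = "tolerance"; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = xb, Rcpp::Named("alpha") = xa,
    Rcpp::Named("rho") = xr, Rcpp::Named("phi") = xf,
    Rcpp::Named("objective") = Fx,
    Rcpp::Named("iterations") = std::min(it, maxit),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("termination") = reason,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("step") = step);
}

// Systematic-scan Gibbs sampler.  Draws n retained samples after `burnin`
// full sweeps, keeping one sample every `thin` sweeps.  Uses R's RNG so
// results are reproducible via set.seed().
// [[Rcpp::export]]
Rcpp::List cpp_gibbs(const arma::mat& beta, const arma::vec& alpha,
                     const arma::mat& rho, const arma::mat& phi,
                     const arma::uvec& levels,
                     int n, int burnin = 200, int thin = 10) {
  const unsigned int p = beta.n_rows, q = levels.n_elem;
  uvec offs = block_offsets(levels);
  vec x(p, fill::zeros);
  uvec y(q, fill::zeros);            // 0-based level indices, start at level 1
  mat Xout(n, p);
  umat Yout(n, q);
  Rcpp::RNGScope scope;

  auto sweep = [&]() {
    for (unsigned int s = 0; s < p; ++s) {
      double num = alpha[s];
      for (unsigned int j = 0; j < q; ++j) num += rho(offs[j] + y[j], s);
      for (unsigned int t = 0; t < p; ++t)
        if (t != s) num -= beta(s, t) * x[t];
      double mu = num / beta(s, s);
      x[s] = R::rnorm(mu, 1.0 / std::sqrt(beta(s, s)));
    }
    for (unsigned int r = 0; r < q; ++r) {
      const unsigned int a = offs[r], L = levels[r];
      vec e(L);
      for (unsigned int k = 0; k < L; ++k) {
        double v = phi(a + k, a + k);
        for (unsigned int s = 0; s < p; ++s) v += rho(a + k, s) * x[s];
        for (unsigned int j = 0; j < q; ++j)
          if (j != r) v += phi(a + k, offs[j] + y[j]);
        e[k] = v;
      }
      e -= e.max();
      vec pr = exp(e); pr /= accu(pr);
      double u = R::unif_rand(), c = 0.0;
      unsigned int k = 0;
      for (; k < L; ++k) { c += pr[k]; if (u <= c) break; }
      y[r] = std::min(k, L - 1);
    }
  };

  for (int b = 0; b < burnin; ++b) sweep();
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < thin; ++t) sweep();
    for (unsigned int s = 0; s < p; ++s) Xout(i, s) = x[s];
    for (unsigned int r = 0; r < q; ++r) Yout(i, r) = y[r] + 1;
  }
  return Rcpp::List::create(Rcpp::Named("X") = Xout, Rcpp::Named("Y") = Yout);
}
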