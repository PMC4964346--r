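// Hot loops of the pipeline: per-voxel nonlinear tensor fits, batch 3x3
// eigendecomposition, wild-bootstrap refits, flat-kernel mean-shift and RK2
// streamline integration.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gauss-Newton with Levenberg damping for one voxel.
// Model: s_hat = exp(X * theta), theta = (log s0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
// scaled so that X already carries the -b factors. Returns iterations used,
// negative if not converged.
static int gn_voxel(const arma::mat& X, const arma::vec& s, arma::vec& theta,
                    arma::vec& resid, int max_iter, double tol) {
  const int p = X.n_cols;
  arma::vec shat = arma::exp(X * theta);
  resid = s - shat;
  double cost = arma::dot(resid, resid);
  double lambda = 1e-6;
  int it = 0;
  for (; it < max_iter; ++it) {
    arma::mat J = X.each_col() % shat;
    arma::mat JtJ = J.t() * J;
    arma::vec g = J.t() * resid;
    if (arma::norm(g, "inf") < tol * (1.0 + cost)) return it;
    bool stepped = false;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat A = JtJ;
      A.diag() += lambda * (JtJ.diag() + 1e-12);
      arma::vec delta;
      bool ok = arma::solve(delta, A, g, arma::solve_opts::no_approx);
      if (ok) {
        arma::vec theta_new = theta + delta;
        arma::vec shat_new = arma::exp(X * theta_new);
        arma::vec resid_new = s - shat_new;
        double cost_new = arma::dot(resid_new, resid_new);
        if (std::isfinite(cost_new) && cost_new <= cost) {
          double rel = std::abs(cost - cost_new) / (cost + 1e-300);
          theta = theta_new; shat = shat_new; resid = resid_new;
          cost = cost_new;
          lambda = std::max(lambda * 0.3, 1e-12);
          stepped = true;
          if (rel < tol) return it + 1;
          break;
        }
      }
      lambda *= 10.0;
    }
    if (!stepped) return it;  // damping exhausted: accept current estimate
  }
  return -max_iter;
}

// [[Rcpp::export]]
List cpp_fit_tensor_nlls(const arma::mat& S, const arma::mat& X,
                         const arma::mat& theta_init,
                         int max_iter, double tol) {
  const int nvox = S.n_cols;
  const int p = X.n_cols;
  arma::mat theta(p, nvox), resid(S.n_rows, nvox);
  IntegerVector iters(nvox);
  LogicalVector conv(nvox);
  arma::vec th(p), rv(S.n_rows);
  for (int v = 0; v < nvox; ++v) {
    th = theta_init.col(v);
    int it = gn_voxel(X, S.col(v), th, rv, max_iter, tol);
    theta.col(v) = th;
    resid.col(v) = rv;
    iters[v] = std::abs(it);
    conv[v] = it >= 0;
  }
  return List::create(_["theta"] = theta, _["residuals"] = resid,
                      _["iterations"] = iters, _["converged"] = conv);
}

static void sign_normalize(arma::vec& v) {
  // flip so the dot with the first coordinate axis of non-negligible
  // projection is positive (deterministic axial representative)
  for (int a = 0; a < 3; ++a) {
    if (std::abs(v[a]) > 1e-8) { if (v[a] < 0) v = -v; return; }
  }
}

static void eig3_desc(const arma::mat33& D, arma::vec3& lam, arma::mat33& V) {
  arma::vec l; arma::mat Vm;
  arma::eig_sym(l, Vm, arma::mat(D));  // ascending
  for (int k = 0; k < 3; ++k) {
    lam[k] = l[2 - k];
    arma::vec vk = Vm.col(2 - k);
    sign_normalize(vk);
    V.col(k) = vk;
  }
}

// D6 rows: xx, yy, zz, xy, xz, yz
// [[Rcpp::export]]
List cpp_eigen_batch(const arma::mat& D6) {
  const int nvox = D6.n_cols;
  arma::mat values(3, nvox);
  arma::mat vectors(9, nvox);
  arma::mat33 D, V; arma::vec3 lam;
  for (int v = 0; v < nvox; ++v) {
    D(0,0)=D6(0,v); D(1,1)=D6(1,v); D(2,2)=D6(2,v);
    D(0,1)=D(1,0)=D6(3,v); D(0,2)=D(2,0)=D6(4,v); D(1,2)=D(2,1)=D6(5,v);
    if (!D.is_finite()) {
      values.col(v).fill(NA_REAL); vectors.col(v).fill(NA_REAL);
      continue;
    }
    eig3_desc(D, lam, V);
    values.col(v) = lam;
    vectors.col(v) = arma::vectorise(V);
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}

// Wild bootstrap: S* = s_hat + resid .* rademacher, refit, store eigenvectors.
// Rademacher signs are i.i.d. per voxel-and-volume, drawn from the R RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_wild_bootstrap(const arma::mat& X, const arma::mat& theta0,
                        const arma::mat& resid, int nrep,
                        int max_iter, double tol, bool per_volume) {
  const int nvol = X.n_rows, nvox = theta0.n_cols, p = X.n_cols;
  NumericVector ens(9.0 * nvox * nrep);
  ens.attr("dim") = IntegerVector::create(9, nvox, nrep);
  NumericVector evals(3.0 * nvox * nrep);
  evals.attr("dim") = IntegerVector::create(3, nvox, nrep);
  arma::mat33 D, V; arma::vec3 lam;
  arma::vec th(p), rv(nvol), sstar(nvol), signs(nvol);
  for (int r = 0; r < nrep; ++r) {
    if (per_volume)
      for (int i = 0; i < nvol; ++i)
        signs[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;
    for (int v = 0; v < nvox; ++v) {
      arma::vec shat = arma::exp(X * theta0.col(v));
      if (!per_volume)
        for (int i = 0; i < nvol; ++i)
          signs[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;
      sstar = shat + resid.col(v) % signs;
      th = theta0.col(v);
      gn_voxel(X, sstar, th, rv, max_iter, tol);
      D(0,0)=th[1]; D(1,1)=th[2]; D(2,2)=th[3];
      D(0,1)=D(1,0)=th[4]; D(0,2)=D(2,0)=th[5]; D(1,2)=D(2,1)=th[6];
      eig3_desc(D, lam, V);
      double* e = &ens[9.0 * (v + (double)nvox * r)];
      for (int k = 0; k < 9; ++k) e[k] = V(k % 3, k / 3);
      double* lv = &evals[3.0 * (v + (double)nvox * r)];
      for (int k = 0; k < 3; ++k) lv[k] = lam[k];
    }
  }
  return List::create(_["vectors"] = ens, _["values"] = evals);
}

// Flat-kernel mean-shift on bandwidth-scaled features (kernel = unit ball).
// Points are iterated in storage order; converged points are frozen.
// [[Rcpp::export]]
List cpp_meanshift(const arma::mat& F, int max_iter, double tol) {
  const int n = F.n_rows, d = F.n_cols;
  arma::mat M = F;          // current positions of the shifted points
  arma::uvec active = arma::ones<arma::uvec>(n);
  arma::vec x(d), m(d);
  int it = 0;
  for (; it < max_iter; ++it) {
    bool any_active = false;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      x = M.row(i).t();
      m.zeros();
      int cnt = 0;
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double dk = x[k] - F(j, k);
          s += dk * dk;
          if (s > 1.0) break;
        }
        if (s <= 1.0) { m += F.row(j).t(); ++cnt; }
      }
      m /= cnt;
      double shift = arma::norm(m - x);
      M.row(i) = m.t();
      if (shift < tol) active[i] = 0; else any_active = true;
    }
    if (!any_active) break;
  }
  return List::create(_["modes"] = M, _["iterations"] = it + 1);
}

// ---- RK2 streamline integration on an axial unit-vector field -------------

struct Field {
  const double* f;   // (nx, ny, nz, 3)
  const int* mask;   // (nx, ny, nz)
  int nx, ny, nz;
  bool inside(double x, double y, double z) const {
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[i + (size_t)nx * (j + (size_t)ny * k)] != 0;
  }
  // trilinear interpolation with per-corner sign alignment to ref
  bool interp(double x, double y, double z, const arma::vec3& ref,
              arma::vec3& out) const {
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    out.zeros();
    for (int di = 0; di < 2; ++di) for (int dj = 0; dj < 2; ++dj)
      for (int dk = 0; dk < 2; ++dk) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        if (w == 0.0) continue;
        size_t base = i + (size_t)nx * (j + (size_t)ny * k);
        size_t stride = (size_t)nx * ny * nz;
        arma::vec3 v = {f[base], f[base + stride], f[base + 2 * stride]};
        if (arma::dot(v, ref) < 0) v = -v;
        out += w * v;
      }
    double n = arma::norm(out);
    if (n < 1e-8) return false;
    out /= n;
    return true;
  }
};

// grow one direction from seed; returns points (3 x m), excluding the seed
static arma::mat grow(const Field& fld, const arma::vec3& seed,
                      const arma::vec3& dir0, double step, double cos_thresh,
                      int max_steps) {
  std::vector<double> pts;
  arma::vec3 pos = seed, vprev = dir0, v1, vm;
  for (int s = 0; s < max_steps; ++s) {
    if (!fld.interp(pos[0], pos[1], pos[2], vprev, v1)) break;
    if (arma::dot(v1, vprev) < cos_thresh) break;
    arma::vec3 mid = pos + 0.5 * step * v1;
    if (!fld.interp(mid[0], mid[1], mid[2], v1, vm)) break;
    if (arma::dot(vm, v1) < cos_thresh) break;
    arma::vec3 nxt = pos + step * vm;
    if (!fld.inside(nxt[0], nxt[1], nxt[2])) break;
    pts.push_back(nxt[0]); pts.push_back(nxt[1]); pts.push_back(nxt[2]);
    vprev = vm; pos = nxt;
  }
  return arma::mat(pts.data(), 3, pts.size() / 3);
}

// seeds in continuous 0-based voxel coordinates; step in voxel units
// [[Rcpp::export]]
List cpp_streamlines(NumericVector field, IntegerVector mask,
                     IntegerVector dims, const arma::mat& seeds,
                     double step, double angle_threshold_deg, int max_steps) {
  Field fld{REAL(field), INTEGER(mask), dims[0], dims[1], dims[2]};
  double cos_thresh = std::cos(angle_threshold_deg * M_PI / 180.0);
  int nseed = seeds.n_rows;
  List tracks(nseed);
  arma::vec3 seed, d0;
  for (int s = 0; s < nseed; ++s) {
    seed = seeds.row(s).t();
    if (!fld.inside(seed[0], seed[1], seed[2]) ||
        !fld.interp(seed[0], seed[1], seed[2],
                    arma::vec3{1e-12, 1e-12, 1e-12}, d0)) {
      tracks[s] = NumericMatrix(0, 3);
      continue;
    }
    arma::mat fwd = grow(fld, seed, d0, step, cos_thresh, max_steps);
    arma::mat bwd = grow(fld, seed, -d0, step, cos_thresh, max_steps);
    arma::mat all(3, bwd.n_cols + 1 + fwd.n_cols);
    for (arma::uword c = 0; c < bwd.n_cols; ++c)
      all.col(c) = bwd.col(bwd.n_cols - 1 - c);
    all.col(bwd.n_cols) = seed;
    for (arma::uword c = 0; c < fwd.n_cols; ++c)
      all.col(bwd.n_cols + 1 + c) = fwd.col(c);
    tracks[s] = wrap(all.t());
  }
  return tracks;
}
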