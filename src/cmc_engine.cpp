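// Numerical engine for the canonical-microcircuit neural mass model:
//  - fixed-step RK4 integration of the delay differential equations, with
//    delayed voltages read from a ring buffer by linear interpolation;
//  - linearized transfer functions with delays as exact phase factors.
// All quantities are in SI-ish units: time in seconds, voltages in mV,
// synaptic drives in mV/s.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_integrate_cmc(const arma::mat& W0, const arma::mat& Wi,
                             const arma::mat& We, double taui, double taue,
                             const arma::vec& Tpop, const arma::vec& rho,
                             const arma::vec& Cdrive, const arma::mat& Lobs,
                             const arma::vec& drive, double dt, int nsteps,
                             const arma::vec& v0, const arma::vec& i0,
                             int decim) {
  const int np = (int)Tpop.n_elem;
  const vec invT = 1.0 / Tpop;
  const vec invT2 = invT % invT;
  const double li = taui / dt;  // delays in units of steps
  const double le = taue / dt;
  const bool use_e = (accu(abs(We)) > 0);

  int nbuf = (int)std::ceil(std::max(taui, taue) / dt) + 4;
  if (nbuf < 8) nbuf = 8;
  mat hist(np, nbuf);
  hist.col(0) = v0;

  vec v = v0, cur = i0;

  const int nrec = nsteps / decim + 1;
  mat obs((int)Lobs.n_rows, nrec);
  obs.col(0) = Lobs * v;
  int irec = 1;

  // workspaces
  vec sv(np), svdi(np), svde(np), u(np);
  vec dv1(np), dv2(np), dv3(np), dv4(np), di1(np), di2(np), di3(np), di4(np);
  vec vtmp(np), itmp(np), vdi(np), vde(np);

  // delayed voltage at real-valued step position p, written into out
  auto hist_at = [&](double p, long long curstep, vec& out) {
    if (p <= 0.0) { out = v0; return; }
    long long lo = (long long)std::floor(p);
    double w = p - (double)lo;
    long long hi = lo + 1;
    if (hi > curstep) { hi = curstep; lo = curstep; w = 0.0; }
    const double* a = hist.colptr(lo % nbuf);
    const double* b = hist.colptr(hi % nbuf);
    for (int j = 0; j < np; ++j) out[j] = (1.0 - w) * a[j] + w * b[j];
  };

  auto driveAt = [&](double p) -> double {
    if (p <= 0.0) return drive((uword)0);
    uword lo = (uword)std::floor(p);
    if (lo >= drive.n_elem - 1) return drive(drive.n_elem - 1);
    double w = p - (double)lo;
    return (1.0 - w) * drive(lo) + w * drive(lo + 1);
  };

  auto sigc = [&](const vec& x, vec& out) {
    for (int j = 0; j < np; ++j)
      out[j] = 1.0 / (1.0 + std::exp(-rho[j] * x[j])) - 0.5;
  };

  auto flow = [&](const vec& vv, const vec& ii, const vec& vdi_,
                  const vec& vde_, double ut, vec& dv, vec& di) {
    sigc(vv, sv);
    u = W0 * sv;
    sigc(vdi_, svdi);
    u += Wi * svdi;
    if (use_e) { sigc(vde_, svde); u += We * svde; }
    for (int j = 0; j < np; ++j) {
      u[j] += Cdrive[j] * ut;
      dv[j] = ii[j];
      di[j] = (u[j] - 2.0 * ii[j]) * invT[j] - vv[j] * invT2[j];
    }
  };

  for (long long n = 0; n < nsteps; ++n) {
    double u0 = driveAt((double)n), uh = driveAt((double)n + 0.5),
           u1 = driveAt((double)n + 1.0);

    hist_at((double)n - li, n, vdi);
    hist_at((double)n - le, n, vde);
    flow(v, cur, vdi, vde, u0, dv1, di1);

    hist_at((double)n + 0.5 - li, n, vdi);
    hist_at((double)n + 0.5 - le, n, vde);
    for (int j = 0; j < np; ++j) { vtmp[j] = v[j] + 0.5 * dt * dv1[j];
                                   itmp[j] = cur[j] + 0.5 * dt * di1[j]; }
    flow(vtmp, itmp, vdi, vde, uh, dv2, di2);
    for (int j = 0; j < np; ++j) { vtmp[j] = v[j] + 0.5 * dt * dv2[j];
                                   itmp[j] = cur[j] + 0.5 * dt * di2[j]; }
    flow(vtmp, itmp, vdi, vde, uh, dv3, di3);

    hist_at((double)n + 1.0 - li, n, vdi);
    hist_at((double)n + 1.0 - le, n, vde);
    for (int j = 0; j < np; ++j) { vtmp[j] = v[j] + dt * dv3[j];
                                   itmp[j] = cur[j] + dt * di3[j]; }
    flow(vtmp, itmp, vdi, vde, u1, dv4, di4);

    bool bad = false;
    for (int j = 0; j < np; ++j) {
      v[j] += dt / 6.0 * (dv1[j] + 2.0 * dv2[j] + 2.0 * dv3[j] + dv4[j]);
      cur[j] += dt / 6.0 * (di1[j] + 2.0 * di2[j] + 2.0 * di3[j] + di4[j]);
      if (!std::isfinite(v[j])) bad = true;
    }
    if (bad) {
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("t_fail") = (double)(n + 1) * dt);
    }
    hist.col((n + 1) % nbuf) = v;
    if ((n + 1) % decim == 0 && irec < nrec) obs.col(irec++) = Lobs * v;
  }

  return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("obs") = obs,
      Rcpp::Named("v") = v, Rcpp::Named("cur") = cur);
}

// Transfer matrices H(f) = C (i w I - A0 - Ai e^{-i w taui} - Ae e^{-i w taue})^{-1} B
// [[Rcpp::export]]
arma::cx_cube cpp_transfer(const arma::mat& A0, const arma::mat& Ai,
                           const arma::mat& Ae, double taui, double taue,
                           const arma::mat& B, const arma::mat& C,
                           const arma::vec& omega) {
  const uword n = A0.n_rows, nu = B.n_cols, ny = C.n_rows, nf = omega.n_elem;
  cx_mat A0c(A0, zeros(n, n)), Aic(Ai, zeros(n, n)), Aec(Ae, zeros(n, n));
  cx_mat Bc(B, zeros(n, nu)), Cc(C, zeros(ny, n));
  cx_cube H(ny, nu, nf);
  cx_mat M(n, n), X(n, nu);
  const std::complex<double> I1(0.0, 1.0);
  const bool use_e = (accu(abs(Ae)) > 0);
  for (uword k = 0; k < nf; ++k) {
    double w = omega(k);
    M = -A0c - Aic * std::exp(-I1 * w * taui);
    if (use_e) M -= Aec * std::exp(-I1 * w * taue);
    M.diag() += I1 * w;
    X = solve(M, Bc);
    H.slice(k) = Cc * X;
  }
  return H;
}
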