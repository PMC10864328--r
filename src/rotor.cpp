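#include <Rcpp.h>
using namespace Rcpp;

// Orthonormal tangent basis at unit vector v.
static inline void tangent_basis(const double v[3], double e1[3], double e2[3]) {
  // pick the coordinate axis least aligned with v
  int k = 0;
  if (std::fabs(v[1]) < std::fabs(v[k])) k = 1;
  if (std::fabs(v[2]) < std::fabs(v[k])) k = 2;
  double a[3] = {0.0, 0.0, 0.0};
  a[k] = 1.0;
  // e1 = normalize(a - (a.v) v)
  double dot = a[0]*v[0] + a[1]*v[1] + a[2]*v[2];
  for (int i = 0; i < 3; ++i) e1[i] = a[i] - dot * v[i];
  double n1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n1;
  // e2 = v x e1
  e2[0] = v[1]*e1[2] - v[2]*e1[1];
  e2[1] = v[2]*e1[0] - v[0]*e1[2];
  e2[2] = v[0]*e1[1] - v[1]*e1[0];
}

static inline void renorm(double v[3]) {
  double n = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
  for (int i = 0; i < 3; ++i) v[i] /= n;
}

// One Brownian step on the unit sphere: random rotation in the tangent
// plane with per-component standard deviation sigma (variance 2 D dt each,
// 4 D dt over the two rotational degrees of freedom).
static inline void sphere_step(double v[3], double sigma) {
  double e1[3], e2[3];
  tangent_basis(v, e1, e2);
  double d1 = sigma * norm_rand();
  double d2 = sigma * norm_rand();
  double ang = std::sqrt(d1*d1 + d2*d2);
  if (ang < 1e-300) return;
  double c = std::cos(ang), s = std::sin(ang);
  double t[3];
  for (int i = 0; i < 3; ++i) t[i] = (d1*e1[i] + d2*e2[i]) / ang;
  for (int i = 0; i < 3; ++i) v[i] = c*v[i] + s*t[i];
  renorm(v);
}

// [[Rcpp::export(name = ".cpp_isotropic_rotor")]]
NumericMatrix cpp_isotropic_rotor(int n_steps, double sigma,
                                  NumericVector v0) {
  NumericMatrix out(n_steps, 3);
  double v[3] = {v0[0], v0[1], v0[2]};
  renorm(v);
  for (int i = 0; i < 3; ++i) out(0, i) = v[i];
  for (int k = 1; k < n_steps; ++k) {
    sphere_step(v, sigma);
    for (int i = 0; i < 3; ++i) out(k, i) = v[i];
  }
  return out;
}

// Wobble-in-a-cone superposed on an isotropically diffusing director: the
// director n performs free rotational diffusion (sigma_dir); the bond
// vector v co-rotates with n, takes its own diffusive step (sigma_wob),
// and is reflected at the cone boundary cos(theta) = cos_theta0.
// [[Rcpp::export(name = ".cpp_two_mode_rotor")]]
NumericMatrix cpp_two_mode_rotor(int n_steps, double sigma_dir,
                                 double sigma_wob, double cos_theta0,
                                 NumericVector n0) {
  NumericMatrix out(n_steps, 3);
  double n[3] = {n0[0], n0[1], n0[2]};
  renorm(n);
  double v[3] = {n[0], n[1], n[2]};
  for (int i = 0; i < 3; ++i) out(0, i) = v[i];
  double theta0 = std::acos(cos_theta0);
  for (int k = 1; k < n_steps; ++k) {
    // director step, and co-rotation of v by the same rotation
    double n_old[3] = {n[0], n[1], n[2]};
    sphere_step(n, sigma_dir);
    double ax[3] = {n_old[1]*n[2] - n_old[2]*n[1],
                    n_old[2]*n[0] - n_old[0]*n[2],
                    n_old[0]*n[1] - n_old[1]*n[0]};
    double s = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
    double c = n_old[0]*n[0] + n_old[1]*n[1] + n_old[2]*n[2];
    if (s > 1e-15) {
      double u[3] = {ax[0]/s, ax[1]/s, ax[2]/s};
      double udotv = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
      double uxv[3] = {u[1]*v[2] - u[2]*v[1],
                       u[2]*v[0] - u[0]*v[2],
                       u[0]*v[1] - u[1]*v[0]};
      for (int i = 0; i < 3; ++i)
        v[i] = v[i]*c + uxv[i]*s + u[i]*udotv*(1.0 - c);
      renorm(v);
    }
    // internal wobble
    sphere_step(v, sigma_wob);
    // reflect at the cone boundary: theta -> 2 theta0 - theta
    double ct = v[0]*n[0] + v[1]*n[1] + v[2]*n[2];
    if (ct < cos_theta0) {
      double theta = std::acos(ct);
      double beta = 2.0 * (theta - theta0);
      double st = std::sin(theta);
      double w[3];  // unit vector in the (v, n) plane pointing from v to n
      for (int i = 0; i < 3; ++i) w[i] = (n[i] - v[i]*ct) / st;
      double cb = std::cos(beta), sb = std::sin(beta);
      for (int i = 0; i < 3; ++i) v[i] = v[i]*cb + w[i]*sb;
      renorm(v);
    }
    for (int i = 0; i < 3; ++i) out(k, i) = v[i];
  }
  return out;
}
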